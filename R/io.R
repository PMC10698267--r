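#' Read a genotype panel from CSV + population map
#'
#' The genotype file is a plain CSV with a header row of locus ids, sample
#' ids in the first column and cells in \code{\{0, 1, 2, NA\}}. The
#' population map is a 2-3 column tab-separated file without header:
#' sample id, population, optional collection year. Samples present in the
#' genotype file but absent from the map are an error.
#'
#' When the map (or \code{roles}) designates a \code{parental_south}
#' population the panel is oriented so that at every locus the counted
#' allele is the one at higher frequency in that population (see
#' \code{\link{orientPanel}}).
#'
#' @param genotype_path path to the genotype CSV.
#' @param popmap_path path to the population map TSV.
#' @param roles optional named list of population role tags (see
#'   \code{\link{GenotypePanel}}).
#' @param orient orient loci to the southern allele when a
#'   \code{parental_south} role is given (default \code{TRUE}).
#' @return a validated \linkS4class{GenotypePanel}.
#' @export
readPanel <- function(genotype_path, popmap_path, roles = list(),
                      orient = TRUE) {
    raw <- utils::read.csv(genotype_path, check.names = FALSE,
                           colClasses = "character")
    if (ncol(raw) < 2L)
        stop("genotype CSV needs a sample-id column plus >=1 locus column")
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate sample id(s) in genotype CSV: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    g <- as.matrix(raw[, -1L, drop = FALSE])
    ok <- g %in% c("0", "1", "2", "NA", "") | is.na(g)
    if (!all(ok)) {
        bad <- which(!ok, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "malformed genotype '%s' for sample '%s', locus '%s'",
            g[bad[1L], bad[2L]], ids[bad[1L]], colnames(g)[bad[2L]]))
    }
    g[g %in% c("NA", "")] <- NA
    storage.mode(g) <- "integer"
    rownames(g) <- ids

    pm <- readPopmap(popmap_path)
    absent <- setdiff(ids, pm$sample)
    if (length(absent))
        stop("samples missing from popmap: ", paste(absent, collapse = ", "))
    pm <- pm[match(ids, pm$sample), ]
    panel <- GenotypePanel(g, population = pm$population, year = pm$year,
                           roles = roles)
    south <- popRoles(panel)$parental_south
    if (orient && !is.null(south)) panel <- orientPanel(panel, south)
    panel
}

#' Read a 2-3 column population map
#'
#' @param path TSV path: sample, population, optional year; no header.
#' @return data.frame with columns \code{sample}, \code{population},
#'   \code{year}.
#' @export
readPopmap <- function(path) {
    pm <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", fill = FALSE)
    if (!ncol(pm) %in% 2:3)
        stop("popmap must have 2 or 3 tab-separated columns")
    names(pm)[1:2] <- c("sample", "population")
    pm$year <- if (ncol(pm) >= 3L) as.integer(pm[[3L]]) else NA_integer_
    if (anyDuplicated(pm$sample))
        stop("duplicate sample id(s) in popmap")
    pm[, c("sample", "population", "year")]
}

#' Write a panel as genotype CSV + popmap TSV
#'
#' Inverse of \code{\link{readPanel}}; the round trip is lossless for all
#' four genotype symbols.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param genotype_path,popmap_path output paths.
#' @return invisibly, the two paths.
#' @export
writePanel <- function(panel, genotype_path, popmap_path) {
    g <- genotypes(panel)
    df <- data.frame(sample = rownames(g), g, check.names = FALSE)
    utils::write.csv(df, genotype_path, row.names = FALSE, quote = FALSE,
                     na = "NA")
    y <- years(panel)
    pm <- data.frame(sample = sampleIDs(panel),
                     population = populations(panel))
    if (!all(is.na(y))) pm$year <- y
    utils::write.table(pm, popmap_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(c(genotype_path, popmap_path))
}

#' Read a biallelic-SNP VCF into a GenotypePanel
#'
#' Convenience reader for VCF 4.x with a GT field. Genotypes map as
#' 0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA; phase is ignored. Records that
#' are multiallelic or whose REF/ALT are not single bases are rejected.
#'
#' @param path VCF path (plain or bgzipped).
#' @param popmap_path population map TSV (see \code{\link{readPopmap}}).
#' @param roles optional role-tag list.
#' @param orient see \code{\link{readPanel}}.
#' @return a \linkS4class{GenotypePanel}.
#' @export
readVCF <- function(path, popmap_path, roles = list(), orient = TRUE) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))
        fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]
    ref <- fix[, "REF"]
    bad <- grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L
    if (any(bad))
        stop("multiallelic or non-SNP record(s): ",
             paste(sprintf("%s:%s", fix[bad, "CHROM"], fix[bad, "POS"]),
                   collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
    norm <- gsub("\\|", "/", gt)
    code[norm %in% c("0/0")] <- 0L
    code[norm %in% c("0/1", "1/0")] <- 1L
    code[norm %in% c("1/1")] <- 2L
    ids <- fix[, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
    rownames(code) <- ids

    pm <- readPopmap(popmap_path)
    absent <- setdiff(colnames(code), pm$sample)
    if (length(absent))
        stop("samples missing from popmap: ", paste(absent, collapse = ", "))
    pm <- pm[match(colnames(code), pm$sample), ]
    panel <- GenotypePanel(t(code), population = pm$population,
                           year = pm$year, roles = roles)
    south <- popRoles(panel)$parental_south
    if (orient && !is.null(south)) panel <- orientPanel(panel, south)
    panel
}

#' Orient loci so the counted allele is the southern-lineage allele
#'
#' Recodes loci (genotype -> 2 - genotype) wherever the reference southern
#' population carries the currently-counted allele at frequency < 0.5, so
#' that a genotype of 0 reads as "pure northern homozygote" at diagnostic
#' loci. Ties (frequency exactly 0.5, or no calls in the reference) keep the
#' existing orientation; flipped locus ids are recorded in
#' \code{metadata(x)$flipped_loci}.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param south_population name of the southern reference population.
#' @return the reoriented panel.
#' @export
orientPanel <- function(panel, south_population) {
    .checkPopulation(panel, south_population)
    fr <- alleleFrequencies(panel, south_population)
    flip <- !is.na(fr$freq) & fr$freq < 0.5
    if (any(flip)) {
        g <- SummarizedExperiment::assay(panel, "genotype")
        g[flip, ] <- 2L - g[flip, ]
        SummarizedExperiment::assay(panel, "genotype") <- g
    }
    S4Vectors::metadata(panel)$flipped_loci <- locusIDs(panel)[flip]
    panel
}

# shared TSV writer for result tables
.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
    invisible(path)
}
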