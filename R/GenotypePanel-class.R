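#' GenotypePanel: diploid biallelic genotypes for a sample panel
#'
#' An S4 container for a panel of individuals genotyped at a set of unlinked
#' biallelic SNPs, stored as a \linkS4class{SummarizedExperiment} with one
#' \code{"genotype"} assay (loci in rows, samples in columns). Genotypes are
#' coded as the number of copies of the designated lineage-B ("southern")
#' allele: 0, 1, 2, with \code{NA} for a failed call. Per-sample metadata
#' (population label, optional collection year) lives in \code{colData};
#' population role tags (\code{parental_north}, \code{parental_south},
#' \code{outgroup}) live in \code{metadata(x)$roles}.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#'
#' @seealso \code{\link{GenotypePanel}} (constructor),
#'   \code{\link{readPanel}}, \code{\link{genotypes}},
#'   \code{\link{alleleFrequencies}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "SummarizedExperiment")

.validGenotypePanel <- function(object) {
    msg <- NULL
    if (!"genotype" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'genotype' is required")
    else {
        g <- SummarizedExperiment::assay(object, "genotype")
        bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
        if (any(bad))
            msg <- c(msg, sprintf(
                "%d genotype entries outside {0,1,2,NA}", sum(bad)))
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate locus ids")
    cd <- SummarizedExperiment::colData(object)
    if (!"population" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'population' column")
    else if (any(is.na(cd$population)) || any(cd$population == ""))
        msg <- c(msg, "every sample needs a non-empty population label")
    roles <- S4Vectors::metadata(object)$roles
    if (!is.null(roles)) {
        known <- c("parental_north", "parental_south", "outgroup", "query")
        if (!all(names(roles) %in% known))
            msg <- c(msg, sprintf("unknown role tag(s): %s",
                paste(setdiff(names(roles), known), collapse = ", ")))
        fixed <- intersect(names(roles),
                           c("parental_north", "parental_south", "outgroup"))
        if (any(lengths(roles[fixed]) > 1))
            msg <- c(msg, "parental/outgroup roles must name one population")
        missing_pops <- setdiff(unlist(roles), unique(cd$population))
        if (length(missing_pops))
            msg <- c(msg, sprintf("role populations absent from panel: %s",
                                  paste(missing_pops, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param genotypes integer matrix, samples in rows and loci in columns
#'   (the orientation of the genotype CSV dialect); values in
#'   \code{\{0, 1, 2, NA\}} counting copies of the southern (lineage-B)
#'   allele. Row and column names become sample and locus ids; defaults
#'   (\code{S1..}, \code{L1..}) are supplied when absent.
#' @param population character vector of population labels, one per sample.
#' @param year optional integer vector of collection years, one per sample.
#' @param roles optional named list tagging populations with analysis roles,
#'   e.g. \code{list(parental_north = "WH", parental_south = "MI",
#'   outgroup = "NS")}.
#'
#' @return a validated \linkS4class{GenotypePanel}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("snp1", "snp2")))
#' gp <- GenotypePanel(g, population = c("N", "N", "S"))
#' gp
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @export
GenotypePanel <- function(genotypes, population, year = NULL, roles = list()) {
    genotypes <- as.matrix(genotypes)
    if (is.null(rownames(genotypes)))
        rownames(genotypes) <- paste0("S", seq_len(nrow(genotypes)))
    if (is.null(colnames(genotypes)))
        colnames(genotypes) <- paste0("L", seq_len(ncol(genotypes)))
    storage.mode(genotypes) <- "integer"
    if (length(population) != nrow(genotypes))
        stop("'population' must have one label per sample")
    cd <- S4Vectors::DataFrame(population = as.character(population),
                               row.names = rownames(genotypes))
    cd$year <- if (is.null(year)) NA_integer_ else as.integer(year)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(genotype = t(genotypes)), colData = cd)
    S4Vectors::metadata(se)$roles <- roles
    new("GenotypePanel", se)
}

#' @rdname GenotypePanel-accessors
#' @name GenotypePanel-accessors
#' @title Accessors for GenotypePanel objects
#' @description \code{genotypes} returns the genotype matrix in samples x
#'   loci orientation; \code{populations} the per-sample labels;
#'   \code{sampleIDs}/\code{locusIDs} the identifiers; \code{years} the
#'   per-sample collection year; \code{popRoles} the role-tag list.
#' @param x a \linkS4class{GenotypePanel}
#' @param value replacement value
#' @return see description
#' @aliases genotypes populations sampleIDs locusIDs years popRoles popRoles<-
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("genotypes", "GenotypePanel", function(x)
    t(SummarizedExperiment::assay(x, "genotype")))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("populations", "GenotypePanel", function(x) {
    p <- SummarizedExperiment::colData(x)$population
    names(p) <- colnames(x)
    p
})

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("sampleIDs", "GenotypePanel", function(x) colnames(x))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("locusIDs", function(x) standardGeneric("locusIDs"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("locusIDs", "GenotypePanel", function(x) rownames(x))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("years", function(x) standardGeneric("years"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("years", "GenotypePanel", function(x) {
    y <- SummarizedExperiment::colData(x)$year
    names(y) <- colnames(x)
    y
})

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("popRoles", function(x) standardGeneric("popRoles"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("popRoles", "GenotypePanel", function(x)
    S4Vectors::metadata(x)$roles)

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("popRoles<-", function(x, value) standardGeneric("popRoles<-"))

#' @rdname GenotypePanel-accessors
#' @export
setMethod("popRoles<-", "GenotypePanel", function(x, value) {
    S4Vectors::metadata(x)$roles <- value
    validObject(x)
    x
})

#' Subset a panel to one or more populations
#'
#' @param x a \linkS4class{GenotypePanel}
#' @param pops character vector of population names (all must exist).
#' @return a \linkS4class{GenotypePanel} containing only those samples.
#' @export
subsetPopulations <- function(x, pops) {
    pl <- populations(x)
    unknown <- setdiff(pops, unique(pl))
    if (length(unknown))
        stop("unknown population(s): ", paste(unknown, collapse = ", "))
    x[, pl %in% pops]
}

.checkPopulation <- function(x, population) {
    if (length(population) != 1L || !population %in% populations(x))
        stop("unknown population: ", paste(population, collapse = ", "))
    invisible(TRUE)
}

setMethod("show", "GenotypePanel", function(object) {
    cat(sprintf("GenotypePanel: %d samples x %d loci\n",
                ncol(object), nrow(object)))
    tab <- table(populations(object))
    cat("populations:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    g <- SummarizedExperiment::assay(object, "genotype")
    cat(sprintf("missing calls: %.2f%%\n", 100 * mean(is.na(g))))
    roles <- popRoles(object)
    if (length(roles))
        cat("roles:", paste(sprintf("%s=%s", names(roles),
            vapply(roles, paste, "", collapse = "+")), collapse = ", "), "\n")
    invisible(NULL)
})
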