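#' Per-locus allele counts for a population
#'
#' Counts copies of the B (southern) allele and called gene copies
#' (2 x called genotypes) per locus, skipping missing calls.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param population population name.
#' @return data.frame: \code{locus}, \code{count_B}, \code{called_copies}.
#' @export
alleleCounts <- function(panel, population) {
    .checkPopulation(panel, population)
    g <- SummarizedExperiment::assay(panel, "genotype")
    g <- g[, populations(panel) == population, drop = FALSE]
    data.frame(locus = rownames(g),
               count_B = rowSums(g, na.rm = TRUE),
               called_copies = 2L * rowSums(!is.na(g)),
               row.names = NULL)
}

#' Per-locus allele-B frequencies for a population
#'
#' Frequency of the counted (southern) allele over that population's called
#' genotypes; loci with no calls are returned as \code{NA} and flagged
#' undefined.
#'
#' @inheritParams alleleCounts
#' @return data.frame: \code{locus}, \code{freq} (allele B),
#'   \code{called_copies}, \code{undefined} (logical).
#' @export
alleleFrequencies <- function(panel, population) {
    ac <- alleleCounts(panel, population)
    freq <- ifelse(ac$called_copies > 0L, ac$count_B / ac$called_copies, NA)
    data.frame(locus = ac$locus, freq = freq,
               called_copies = ac$called_copies,
               undefined = ac$called_copies == 0L, row.names = NULL)
}

# frequency matrix (loci x populations) used by several statistics;
# entries NA where a population has no calls at a locus
.freqMatrix <- function(panel, pops) {
    vapply(pops, function(p) alleleFrequencies(panel, p)$freq,
           numeric(nrow(panel)))
}
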