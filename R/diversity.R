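#' Observed heterozygosity
#'
#' Fraction of called genotypes that are heterozygous, per locus, averaged
#' over loci. Loci with no calls in the population are excluded with a
#' warning.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param population population name.
#' @param per_locus return the per-locus vector instead of the mean.
#' @return numeric scalar (or per-locus vector).
#' @export
observedHeterozygosity <- function(panel, population, per_locus = FALSE) {
    .checkPopulation(panel, population)
    g <- SummarizedExperiment::assay(panel, "genotype")
    g <- g[, populations(panel) == population, drop = FALSE]
    called <- rowSums(!is.na(g))
    ho <- rowSums(g == 1L, na.rm = TRUE) / called
    names(ho) <- rownames(g)
    if (any(called == 0L)) {
        warning(sum(called == 0L), " all-missing locus/loci excluded")
        ho <- ho[called > 0L]
    }
    if (per_locus) ho else mean(ho)
}

#' Unbiased expected heterozygosity
#'
#' Per locus, Nei's unbiased gene diversity
#' \eqn{\hat{H}_e = \frac{2n}{2n-1}(1 - p^2 - q^2)} with \eqn{n} the number
#' of called individuals, averaged over loci. Monomorphic loci contribute 0.
#'
#' @inheritParams observedHeterozygosity
#' @return numeric scalar (or per-locus vector).
#' @export
expectedHeterozygosity <- function(panel, population, per_locus = FALSE) {
    .checkPopulation(panel, population)
    ac <- alleleCounts(subsetPopulations(panel, population), population)
    n <- ac$called_copies / 2
    p <- ifelse(ac$called_copies > 0L, ac$count_B / ac$called_copies, NA)
    he <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
    names(he) <- ac$locus
    if (any(ac$called_copies == 0L)) {
        warning(sum(ac$called_copies == 0L),
                " all-missing locus/loci excluded")
        he <- he[ac$called_copies > 0L]
    }
    if (per_locus) he else mean(he)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of \code{g}
#' gene copies (hypergeometric rarefaction): per locus
#' \eqn{AR = \sum_i [1 - C(N - N_i, g) / C(N, g)]} over alleles \eqn{i},
#' where \eqn{N} is the number of called gene copies and \eqn{N_i} the
#' copies of allele \eqn{i}. For biallelic loci \eqn{1 \le AR \le 2}.
#'
#' @inheritParams observedHeterozygosity
#' @param g rarefaction size in gene copies; defaults to twice the smallest
#'   per-locus number of called individuals in the population. Loci with
#'   fewer than \code{g} called copies are skipped with a warning.
#' @return numeric scalar (or per-locus vector).
#' @export
allelicRichness <- function(panel, population, g = NULL,
                            per_locus = FALSE) {
    .checkPopulation(panel, population)
    ac <- alleleCounts(subsetPopulations(panel, population), population)
    N <- ac$called_copies
    if (is.null(g)) g <- min(N[N > 0L])
    if (g < 1) stop("g must be >= 1")
    keep <- N >= g
    if (any(!keep))
        warning(sum(!keep), " locus/loci with < g called copies skipped")
    Nb <- ac$count_B[keep]
    N <- N[keep]
    term <- function(Ni) 1 - exp(lchoose(N - Ni, g) - lchoose(N, g))
    ar <- term(Nb) + term(N - Nb)
    names(ar) <- ac$locus[keep]
    if (per_locus) ar else mean(ar)
}

#' Compare diversity statistics across populations by one-way ANOVA
#'
#' For each statistic the per-locus values are grouped by population and
#' compared with \code{aov(value ~ population)}; loci are the observational
#' unit.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param pops populations to compare (>= 2); default all.
#' @param g rarefaction size for AR, shared across populations; default
#'   twice the smallest population's size.
#' @return data.frame: \code{statistic} (Ho, He, AR), \code{F}, \code{p}.
#' @export
compareDiversity <- function(panel, pops = NULL, g = NULL) {
    if (is.null(pops)) pops <- unique(populations(panel))
    if (length(pops) < 2L)
        stop("need >= 2 populations to compare")
    if (is.null(g))
        g <- 2L * min(table(populations(panel))[pops])
    stat_fun <- list(
        Ho = function(p) observedHeterozygosity(panel, p, per_locus = TRUE),
        He = function(p) expectedHeterozygosity(panel, p, per_locus = TRUE),
        AR = function(p) allelicRichness(panel, p, g = g, per_locus = TRUE))
    rows <- lapply(names(stat_fun), function(s) {
        long <- do.call(rbind, lapply(pops, function(p) {
            v <- suppressWarnings(stat_fun[[s]](p))
            data.frame(population = p, value = v)
        }))
        fit <- stats::aov(value ~ population, data = long)
        an <- summary(fit)[[1L]]
        data.frame(statistic = s, F = an$`F value`[1L],
                   p = an$`Pr(>F)`[1L])
    })
    do.call(rbind, rows)
}

#' Per-population diversity summary
#'
#' Ho, unbiased He, rarefied AR and sample size per population, with the
#' across-population one-way ANOVA for each statistic.
#'
#' @inheritParams compareDiversity
#' @return list with elements \code{table} (per-population data.frame) and
#'   \code{anova} (see \code{\link{compareDiversity}}).
#' @export
diversitySummary <- function(panel, pops = NULL, g = NULL) {
    if (is.null(pops)) pops <- unique(populations(panel))
    if (is.null(g))
        g <- 2L * min(table(populations(panel))[pops])
    tab <- do.call(rbind, lapply(pops, function(p) data.frame(
        population = p,
        n = sum(populations(panel) == p),
        Ho = suppressWarnings(observedHeterozygosity(panel, p)),
        He = suppressWarnings(expectedHeterozygosity(panel, p)),
        AR = suppressWarnings(allelicRichness(panel, p, g = g)))))
    anova <- if (length(pops) >= 2L) compareDiversity(panel, pops, g = g)
             else NULL
    list(table = tab, anova = anova)
}
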