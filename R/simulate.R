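#' Draw diagnostic two-lineage allele frequencies
#'
#' Generates per-locus allele-B frequencies for a northern and a southern
#' gene pool such that the absolute frequency differential at every locus is
#' at least \code{diagnosticity}. Allele B is by convention the southern
#' allele, so the southern pool always carries the higher B frequency. With
#' \code{diagnosticity = 1} the panel is fully diagnostic (frequencies
#' exactly 0 and 1).
#'
#' @param n_loci number of unlinked biallelic loci (default 96, the size of
#'   a Fluidigm 96.96 array panel).
#' @param diagnosticity minimum per-locus frequency differential, in (0, 1].
#' @param seed optional RNG seed.
#' @return a \code{LineageFrequencies} data.frame: \code{locus},
#'   \code{north}, \code{south} (allele-B frequency per pool).
#' @examples
#' makeLineageFrequencies(5, diagnosticity = 0.9, seed = 1)
#' @export
makeLineageFrequencies <- function(n_loci = 96, diagnosticity = 0.9,
                                   seed = NULL) {
    if (diagnosticity <= 0 || diagnosticity > 1)
        stop("diagnosticity must be in (0, 1]")
    if (n_loci < 1) stop("n_loci must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    d <- stats::runif(n_loci, min = diagnosticity, max = 1)
    north <- stats::runif(n_loci, min = 0, max = 1 - d)
    out <- data.frame(locus = paste0("L", seq_len(n_loci)),
                      north = north, south = north + d)
    class(out) <- c("LineageFrequencies", "data.frame")
    out
}

.checkFreqs <- function(freqs) {
    if (!all(c("north", "south") %in% names(freqs)))
        stop("'freqs' needs 'north' and 'south' frequency columns")
    if (any(freqs$north < 0 | freqs$north > 1 |
            freqs$south < 0 | freqs$south > 1))
        stop("frequencies must lie in [0, 1]")
    invisible(freqs)
}

#' Simulate pure-lineage individuals under Hardy-Weinberg
#'
#' Each genotype is drawn independently per locus as Binomial(2, pool
#' frequency): Hardy-Weinberg within the pool, linkage equilibrium across
#' loci.
#'
#' @param freqs a \code{LineageFrequencies} table
#'   (\code{\link{makeLineageFrequencies}}).
#' @param pool \code{"north"} or \code{"south"}.
#' @param n number of diploid individuals.
#' @param seed optional RNG seed.
#' @param population population label for the simulated samples
#'   (default the pool name).
#' @param prefix sample-id prefix.
#' @return a \linkS4class{GenotypePanel}.
#' @export
simulateParental <- function(freqs, pool = c("north", "south"), n,
                             seed = NULL, population = NULL,
                             prefix = NULL) {
    pool <- match.arg(pool)
    .checkFreqs(freqs)
    if (n < 1) stop("n must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    p <- freqs[[pool]]
    L <- length(p)
    g <- matrix(stats::rbinom(n * L, 2L, rep(p, each = n)), nrow = n)
    if (is.null(population)) population <- pool
    if (is.null(prefix)) prefix <- population
    dimnames(g) <- list(paste0(prefix, "_", seq_len(n)), freqs$locus)
    GenotypePanel(g, population = rep(population, n))
}

#' Simulate hybrid-category individuals from origin-pair triples
#'
#' For each individual and locus an unordered gene-pool origin pair is drawn
#' from the category's (p_NN, p_NS, p_SS) triple
#' (\code{\link{categoryTable}}); each gene copy is then drawn from its
#' pool's allele frequency. An NS pair draws one copy from each pool.
#'
#' @inheritParams simulateParental
#' @param category one of the twelve category names
#'   (\code{categoryTable()$category}).
#' @return a \linkS4class{GenotypePanel}.
#' @export
simulateCategory <- function(freqs, category, n, seed = NULL,
                             population = NULL, prefix = NULL) {
    .checkCategory(category)
    .checkFreqs(freqs)
    if (n < 1) stop("n must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    tab <- categoryTable()
    tri <- as.numeric(tab[tab$category == category, c("p_NN", "p_NS", "p_SS")])
    L <- nrow(freqs)
    pN <- rep(freqs$north, each = n)
    pS <- rep(freqs$south, each = n)
    w <- sample.int(3L, n * L, replace = TRUE, prob = tri)
    g <- integer(n * L)
    nn <- w == 1L; ns <- w == 2L; ss <- w == 3L
    g[nn] <- stats::rbinom(sum(nn), 2L, pN[nn])
    g[ns] <- stats::rbinom(sum(ns), 1L, pN[ns]) +
        stats::rbinom(sum(ns), 1L, pS[ns])
    g[ss] <- stats::rbinom(sum(ss), 2L, pS[ss])
    g <- matrix(g, nrow = n)
    if (is.null(population)) population <- category
    if (is.null(prefix)) prefix <- population
    dimnames(g) <- list(paste0(prefix, "_", seq_len(n)), freqs$locus)
    GenotypePanel(g, population = rep(population, n))
}

#' Simulate hybrid categories by explicit pedigree gamete sampling
#'
#' Distributional oracle for \code{\link{simulateCategory}}: founders are
#' drawn from the pool frequencies and every cross is performed explicitly,
#' each parent transmitting one of its two gene copies per locus with
#' probability 1/2 (free recombination). For unlinked loci the per-locus
#' genotype law is identical to class-based sampling.
#'
#' @inheritParams simulateCategory
#' @return a \linkS4class{GenotypePanel}.
#' @export
simulatePedigreeCategory <- function(freqs, category, n, seed = NULL,
                                     population = NULL, prefix = NULL) {
    .checkCategory(category)
    .checkFreqs(freqs)
    if (n < 1) stop("n must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    L <- nrow(freqs)
    sim <- function(cat) {
        # returns list(a1, a2): n x L haplotype matrices of B-allele dosage
        if (cat == "WH" || cat == "MI") {
            p <- if (cat == "WH") freqs$north else freqs$south
            pm <- rep(p, each = n)
            return(list(
                a1 = matrix(stats::rbinom(n * L, 1L, pm), nrow = n),
                a2 = matrix(stats::rbinom(n * L, 1L, pm), nrow = n)))
        }
        par <- .categoryPedigrees()[[cat]]
        gamete <- function(ind) {
            pick <- matrix(stats::rbinom(n * L, 1L, 0.5), nrow = n)
            pick * ind$a1 + (1L - pick) * ind$a2
        }
        list(a1 = gamete(sim(par[1L])), a2 = gamete(sim(par[2L])))
    }
    ind <- sim(category)
    g <- ind$a1 + ind$a2
    if (is.null(population)) population <- category
    if (is.null(prefix)) prefix <- population
    dimnames(g) <- list(paste0(prefix, "_", seq_len(n)), freqs$locus)
    GenotypePanel(g, population = rep(population, n))
}

#' Knock out genotype calls at random
#'
#' Sets each called entry to missing independently with probability
#' \code{rate}, emulating array no-calls.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param rate per-entry missingness probability in [0, 1).
#' @param seed optional RNG seed.
#' @return the panel with added missing calls.
#' @export
applyMissingness <- function(panel, rate, seed = NULL) {
    if (rate < 0 || rate >= 1)
        stop("rate must be in [0, 1)")
    if (rate == 0) return(panel)
    if (!is.null(seed)) set.seed(seed)
    g <- SummarizedExperiment::assay(panel, "genotype")
    drop <- matrix(stats::runif(length(g)) < rate, nrow = nrow(g))
    g[drop] <- NA_integer_
    SummarizedExperiment::assay(panel, "genotype") <- g
    panel
}

#' Combine panels over the same loci
#'
#' Column-binds panels sample-wise (all must share the locus set); sample
#' ids are made unique if needed.
#'
#' @param ... \linkS4class{GenotypePanel} objects.
#' @return a single \linkS4class{GenotypePanel}.
#' @export
combinePanels <- function(...) {
    panels <- list(...)
    if (length(panels) == 1L && is.list(panels[[1L]]) &&
        !is(panels[[1L]], "GenotypePanel"))
        panels <- panels[[1L]]
    ids <- make.unique(unlist(lapply(panels, colnames)))
    off <- 0L
    for (i in seq_along(panels)) {
        colnames(panels[[i]]) <- ids[off + seq_len(ncol(panels[[i]]))]
        off <- off + ncol(panels[[i]])
    }
    out <- do.call(SummarizedExperiment::cbind, panels)
    roles <- Reduce(utils::modifyList, lapply(panels, popRoles))
    S4Vectors::metadata(out)$roles <- roles
    new("GenotypePanel", out)
}

#' Simulate a complete two-lineage hybrid-zone panel
#'
#' Convenience generator producing one panel containing parental reference
#' populations and any requested mixture of the twelve categories, plus
#' optional missingness — the synthetic analogue of a genotyped hybrid-zone
#' survey, emitted in the package's standard container so every downstream
#' stage runs on it unchanged.
#'
#' @param freqs lineage frequencies (\code{\link{makeLineageFrequencies}}).
#' @param composition named integer vector: individuals per category
#'   (names from \code{categoryTable()$category}); each category becomes a
#'   population of the same name.
#' @param missing_rate per-entry no-call probability.
#' @param seed optional RNG seed.
#' @return a \linkS4class{GenotypePanel} with parental role tags set to the
#'   WH/MI populations when present.
#' @export
simulateHybridZonePanel <- function(freqs,
                                    composition = c(WH = 30, MI = 30,
                                                    F1 = 10, F2 = 10),
                                    missing_rate = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    panels <- lapply(names(composition), function(cat)
        simulateCategory(freqs, cat, composition[[cat]]))
    panel <- combinePanels(panels)
    roles <- list()
    if ("WH" %in% names(composition)) roles$parental_north <- "WH"
    if ("MI" %in% names(composition)) roles$parental_south <- "MI"
    popRoles(panel) <- roles
    if (missing_rate > 0) panel <- applyMissingness(panel, missing_rate)
    panel
}
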