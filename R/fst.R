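#' Weir-Cockerham F_ST between two populations
#'
#' Two-population Weir-Cockerham (1984) theta. Per-locus variance
#' components (a: among populations, b: among individuals within
#' populations, c: within individuals) are combined across loci as a ratio
#' of sums, \eqn{\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)} — the
#' multilocus estimator Arlequin reports. Loci monomorphic across both
#' populations, or uncalled in either, are excluded. Negative estimates are
#' reported as computed.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param popA,popB population names.
#' @return list: \code{theta}, \code{components} (per-locus data.frame with
#'   \code{locus}, \code{a}, \code{b}, \code{c}), \code{n_loci}.
#' @export
weirCockerhamFst <- function(panel, popA, popB) {
    .checkPopulation(panel, popA)
    .checkPopulation(panel, popB)
    g <- SummarizedExperiment::assay(panel, "genotype")
    pl <- populations(panel)
    comp <- .wcComponents(g[, pl == popA, drop = FALSE],
                          g[, pl == popB, drop = FALSE])
    if (nrow(comp) == 0L)
        stop("no shared informative loci between '", popA, "' and '",
             popB, "'")
    list(theta = sum(comp$a) / sum(comp$a + comp$b + comp$c),
         components = comp, n_loci = nrow(comp))
}

# per-locus WC (1984) components for two samples; g1, g2: loci x samples
.wcComponents <- function(g1, g2) {
    n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
    p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
    p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
    h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
    h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
    keep <- n1 >= 2L & n2 >= 2L
    poly <- keep & !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
    idx <- which(poly)
    r <- 2
    n1 <- n1[idx]; n2 <- n2[idx]; p1 <- p1[idx]; p2 <- p2[idx]
    h1 <- h1[idx]; h2 <- h2[idx]
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) /
             (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
             ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    locus <- rownames(g1)
    if (is.null(locus)) locus <- as.character(seq_len(nrow(g1)))
    data.frame(locus = locus[idx], a = a, b = b, c = cc, row.names = NULL)
}

# theta from two genotype submatrices (used by the permutation test)
.thetaTwo <- function(g1, g2) {
    comp <- .wcComponents(g1, g2)
    if (nrow(comp) == 0L) return(NA_real_)
    sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Permutation test for pairwise F_ST
#'
#' Individuals are permuted between the two populations and theta
#' recomputed; \eqn{p = (1 + \#\{\theta^* \ge \theta\}) / (n_{perm} + 1)}.
#'
#' @inheritParams weirCockerhamFst
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed.
#' @return list: \code{theta}, \code{p}, \code{n_perm}.
#' @export
fstPermutationTest <- function(panel, popA, popB, n_perm = 10000,
                               seed = NULL) {
    .checkPopulation(panel, popA)
    .checkPopulation(panel, popB)
    if (!is.null(seed)) set.seed(seed)
    g <- SummarizedExperiment::assay(panel, "genotype")
    pl <- populations(panel)
    gAB <- g[, pl %in% c(popA, popB), drop = FALSE]
    isA <- pl[pl %in% c(popA, popB)] == popA
    nA <- sum(isA); ntot <- ncol(gAB)
    obs <- .thetaTwo(gAB[, isA, drop = FALSE], gAB[, !isA, drop = FALSE])
    if (is.na(obs)) stop("theta undefined for observed data")
    hits <- 0L
    for (i in seq_len(n_perm)) {
        idx <- sample.int(ntot, nA)
        th <- .thetaTwo(gAB[, idx, drop = FALSE],
                        gAB[, -idx, drop = FALSE])
        if (!is.na(th) && th >= obs) hits <- hits + 1L
    }
    list(theta = obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' All pairwise F_ST with permutation p-values
#'
#' @inheritParams fstPermutationTest
#' @param pops populations (default all, in panel order of appearance).
#' @return list: \code{theta} (symmetric matrix, NA diagonal), \code{p}
#'   (matrix), \code{n_perm}.
#' @export
pairwiseFst <- function(panel, pops = NULL, n_perm = 10000, seed = NULL) {
    if (is.null(pops)) pops <- unique(populations(panel))
    if (!is.null(seed)) set.seed(seed)
    k <- length(pops)
    th <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
        res <- fstPermutationTest(panel, pops[i], pops[j], n_perm = n_perm)
        th[i, j] <- th[j, i] <- res$theta
        p[i, j] <- p[j, i] <- res$p
    }
    list(theta = th, p = p, n_perm = n_perm)
}

#' Test and pool temporal samples within locations
#'
#' For every population (location) sampled in exactly two years, theta and
#' its permutation p-value are computed between the year groups; the years
#' are pooled when the test is non-significant (\eqn{p \ge \alpha}).
#' Locations whose temporal samples differ significantly are split into
#' year-suffixed populations; single-year locations pass through.
#'
#' @param panel a \linkS4class{GenotypePanel} with per-sample years.
#' @param alpha pooling significance level (default 0.05).
#' @param n_perm permutations per test.
#' @param seed optional RNG seed.
#' @return list: \code{panel} (relabelled panel) and \code{report}
#'   (data.frame: population, yearA, yearB, theta, p, pooled).
#' @export
temporalPooling <- function(panel, alpha = 0.05, n_perm = 1000,
                            seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    pl <- populations(panel)
    yr <- years(panel)
    rows <- list()
    newpl <- pl
    for (pop in unique(pl)) {
        ys <- sort(unique(yr[pl == pop & !is.na(yr)]))
        if (length(ys) != 2L) next
        tmp <- panel[, pl == pop & !is.na(yr)]
        lab <- paste0(pop, "_", yr[pl == pop & !is.na(yr)])
        SummarizedExperiment::colData(tmp)$population <- lab
        res <- fstPermutationTest(tmp, paste0(pop, "_", ys[1L]),
                                  paste0(pop, "_", ys[2L]),
                                  n_perm = n_perm)
        pooled <- res$p >= alpha
        if (!pooled)
            newpl[pl == pop] <- paste0(pop, "_", yr[pl == pop])
        rows[[pop]] <- data.frame(population = pop, yearA = ys[1L],
                                  yearB = ys[2L], theta = res$theta,
                                  p = res$p, pooled = pooled)
    }
    SummarizedExperiment::colData(panel)$population <- newpl
    list(panel = panel,
         report = if (length(rows)) do.call(rbind, c(rows,
                      make.row.names = FALSE))
                  else data.frame(population = character(),
                                  yearA = integer(), yearB = integer(),
                                  theta = numeric(), p = numeric(),
                                  pooled = logical()))
}

#' Write a Table-1 style F_ST matrix (theta lower triangle, p upper)
#'
#' @param fst result of \code{\link{pairwiseFst}}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeFstTable <- function(fst, path) {
    m <- fst$theta
    out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
    out[lower.tri(out)] <- signif(m[lower.tri(m)], 3)
    out[upper.tri(out)] <- signif(fst$p[upper.tri(fst$p)], 3)
    df <- data.frame(population = rownames(out), out, check.names = FALSE)
    .writeTSV(df, path)
}
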