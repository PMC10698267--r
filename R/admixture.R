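#' Maximum-likelihood admixture inference by EM
#'
#' Fits the admixture model for biallelic genotypes: individual i's
#' genotype at locus l is Binomial(2, \eqn{\sum_k q_{ik} f_{kl}}), with
#' ancestry proportions q (rows summing to 1) and cluster allele
#' frequencies f. Both are estimated by alternating EM updates of the
#' binomial mixture; the log-likelihood is non-decreasing every iteration
#' and iteration stops when the gain drops below \code{tol}. Missing
#' genotypes are marginalised (the locus simply contributes nothing for
#' that individual).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param K number of ancestral clusters (>= 1).
#' @param seed RNG seed for the random initialisation.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood gain.
#' @return list of class \code{AdmixtureResult}: \code{K}, \code{Q}
#'   (samples x K ancestry proportions), \code{F} (K x loci cluster
#'   frequencies of allele B), \code{loglik}, \code{loglik_trace},
#'   \code{converged}, \code{n_iter}, \code{seed}.
#' @export
admixtureEM <- function(panel, K, seed = NULL, max_iter = 2000,
                        tol = 1e-6) {
    if (K < 1) stop("K must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    G <- genotypes(panel)                      # samples x loci
    n <- nrow(G); L <- ncol(G)
    M <- !is.na(G)
    if (any(rowSums(M) == 0L))
        stop("individual(s) with no called loci")
    Gm <- G; Gm[!M] <- 0L
    storage.mode(Gm) <- "double"
    Mn <- M * 1
    # binomial coefficient term, constant in the parameters
    const <- sum(log(choose(2, Gm[M])))
    eps <- 1e-9
    Q <- matrix(stats::runif(n * K, 0.1, 1), n, K)
    Q <- Q / rowSums(Q)
    Fm <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
        P <- Q %*% Fm
        P <- pmin(pmax(P, eps), 1 - eps)
        ll <- sum((Gm * log(P) + (2 - Gm) * log1p(-P)) * Mn) + const
        ll_trace <- c(ll_trace, ll)
        if (ll - ll_old < tol && it > 1L) { converged <- TRUE; break }
        ll_old <- ll
        A <- Mn * Gm / P
        B <- Mn * (2 - Gm) / (1 - P)
        AF <- A %*% t(Fm)                     # n x K
        BF <- B %*% t(1 - Fm)
        Qn <- Q * (AF + BF)
        Qnew <- Qn / rowSums(Qn)
        numF <- Fm * t(crossprod(A, Q))       # K x L: f_kl * sum_i q_ik A_il
        denF <- (1 - Fm) * t(crossprod(B, Q))
        Fnew <- numF / (numF + denF)
        Fnew[!is.finite(Fnew)] <- 0.5
        Q <- Qnew
        Fm <- pmin(pmax(Fnew, eps), 1 - eps)
    }
    rownames(Q) <- rownames(G)
    colnames(Q) <- paste0("q", seq_len(K))
    colnames(Fm) <- colnames(G)
    structure(list(K = K, Q = Q, F = Fm, loglik = ll_trace[length(ll_trace)],
                   loglik_trace = ll_trace, converged = converged,
                   n_iter = length(ll_trace), seed = seed),
              class = "AdmixtureResult")
}

#' Align cluster labels of one Q matrix to a reference
#'
#' Resolves label switching by choosing the column permutation of \code{Q}
#' minimising the total absolute difference to \code{Q_ref}.
#'
#' @param Q_ref,Q ancestry matrices with identical dimensions (K <= 8).
#' @return \code{Q} with permuted columns.
#' @export
alignClusters <- function(Q_ref, Q) {
    K <- ncol(Q)
    if (K != ncol(Q_ref)) stop("K mismatch")
    if (K == 1L) return(Q)
    perms <- .permutations(K)
    cost <- vapply(perms, function(p) sum(abs(Q[, p, drop = FALSE] - Q_ref)),
                   numeric(1))
    Q[, perms[[which.min(cost)]], drop = FALSE]
}

.permutations <- function(K) {
    if (K == 1L) return(list(1L))
    sub <- .permutations(K - 1L)
    out <- list()
    for (p in sub) for (pos in seq_len(K))
        out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
    out
}

#' Replicate admixture runs over a range of K
#'
#' Runs \code{\link{admixtureEM}} \code{n_replicates} times per K from
#' distinct seeds (the ML analogue of STRUCTURE's independent runs),
#' aligns replicate Q matrices within each K, and collects the replicate
#' log-likelihoods for \code{\link{evannoDeltaK}}.
#'
#' @inheritParams admixtureEM
#' @param K_range integer vector of K values (e.g. \code{1:5}).
#' @param n_replicates replicate runs per K (default 10).
#' @param seed base seed; replicate r of K uses \code{seed + 100*K + r}.
#' @param ... passed to \code{\link{admixtureEM}}.
#' @return list: \code{runs} (list over K of replicate results, Q aligned
#'   within K), \code{best} (highest-likelihood result per K),
#'   \code{logliks} (data.frame: K, replicate, loglik).
#' @export
runAdmixtureReplicates <- function(panel, K_range = 1:5,
                                   n_replicates = 10, seed = 1, ...) {
    runs <- list()
    ll <- list()
    for (K in K_range) {
        reps <- lapply(seq_len(n_replicates), function(r)
            admixtureEM(panel, K, seed = seed + 100L * K + r, ...))
        for (r in seq_along(reps))
            if (r > 1L)
                reps[[r]]$Q <- alignClusters(reps[[1L]]$Q, reps[[r]]$Q)
        runs[[as.character(K)]] <- reps
        ll[[as.character(K)]] <- data.frame(
            K = K, replicate = seq_len(n_replicates),
            loglik = vapply(reps, `[[`, numeric(1), "loglik"))
    }
    logliks <- do.call(rbind, c(ll, make.row.names = FALSE))
    best <- lapply(runs, function(reps)
        reps[[which.max(vapply(reps, `[[`, numeric(1), "loglik"))]])
    list(runs = runs, best = best, logliks = logliks)
}

#' Evanno delta-K model choice from replicate log-likelihoods
#'
#' \eqn{\Delta K = \mathrm{mean}(|L(K+1) - 2 L(K) + L(K-1)|) / \mathrm{SD}(L(K))},
#' the second difference of the likelihood curve paired across replicates,
#' scaled by the replicate SD; defined for interior K only. The chosen K
#' maximises delta-K.
#'
#' @param logliks data.frame with columns \code{K}, \code{replicate},
#'   \code{loglik} (as from \code{\link{runAdmixtureReplicates}}), covering
#'   a contiguous K range of length >= 3 with equal replicate counts.
#' @return list of class \code{DeltaKReport}: \code{summary} (per-K mean,
#'   sd of loglik, deltaK), \code{chosen_K}.
#' @export
evannoDeltaK <- function(logliks) {
    Ks <- sort(unique(logliks$K))
    if (length(Ks) < 3L)
        stop("need >= 3 consecutive K values (no interior K otherwise)")
    if (any(diff(Ks) != 1L)) stop("K range must be contiguous")
    byK <- split(logliks, logliks$K)
    nrep <- unique(vapply(byK, nrow, integer(1)))
    if (length(nrep) != 1L)
        stop("unequal replicate counts across K")
    mat <- vapply(byK, function(d)
        d$loglik[order(d$replicate)], numeric(nrep))   # replicates x K
    sds <- apply(mat, 2L, stats::sd)
    means <- colMeans(mat)
    interior <- seq(2L, length(Ks) - 1L)
    if (any(sds[interior] == 0))
        stop("replicate SD of log-likelihood is zero at interior K; ",
             "delta-K undefined")
    dK <- rep(NA_real_, length(Ks))
    for (j in interior)
        dK[j] <- mean(abs(mat[, j + 1L] - 2 * mat[, j] + mat[, j - 1L])) /
            sds[j]
    summary <- data.frame(K = Ks, mean_loglik = means, sd_loglik = sds,
                          deltaK = dK)
    structure(list(summary = summary,
                   chosen_K = Ks[interior][which.max(dK[interior])]),
              class = "DeltaKReport")
}

#' Summarise admixture proportions per population
#'
#' An individual's admixture proportion is its minor-cluster ancestry,
#' \eqn{1 - \max_k q_{ik}}; individuals with proportion above
#' \code{threshold} count as admixed.
#'
#' @param result an \code{AdmixtureResult}.
#' @param panel the panel the result was fitted to (for population
#'   labels).
#' @param threshold admixture-proportion cutoff (default 0.10).
#' @return data.frame per population: \code{n}, \code{pct_admixed},
#'   \code{min_admixture}, \code{max_admixture}.
#' @export
admixtureSummary <- function(result, panel, threshold = 0.10) {
    q <- result$Q
    prop <- 1 - apply(q, 1L, max)
    pl <- populations(panel)[rownames(q)]
    do.call(rbind, lapply(unique(pl), function(p) {
        v <- prop[pl == p]
        data.frame(population = p, n = length(v),
                   pct_admixed = 100 * mean(v > threshold),
                   min_admixture = min(v), max_admixture = max(v))
    }))
}

#' Write a STRUCTURE-style Q matrix TSV
#'
#' Columns: sample, population, q_1..q_K.
#'
#' @param result an \code{AdmixtureResult}.
#' @param panel the fitted panel.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeQMatrix <- function(result, panel, path) {
    df <- data.frame(sample = rownames(result$Q),
                     population = populations(panel)[rownames(result$Q)],
                     result$Q, check.names = FALSE)
    .writeTSV(df, path)
}

#' @export
print.AdmixtureResult <- function(x, ...) {
    cat(sprintf("Admixture EM: K = %d, %d samples, loglik = %.2f (%s)\n",
                x$K, nrow(x$Q), x$loglik,
                if (x$converged) sprintf("converged in %d iters", x$n_iter)
                else "NOT converged"))
    invisible(x)
}

#' @export
print.DeltaKReport <- function(x, ...) {
    print(x$summary, row.names = FALSE)
    cat("chosen K:", x$chosen_K, "\n")
    invisible(x)
}
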