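#' Frequency-weighted ABBA-BABA test (Patterson's D)
#'
#' For the population tree (((P1, P2), P3), O), alleles are polarised per
#' locus with the outgroup's major allele as ancestral. With \eqn{p_i} the
#' derived-allele frequency in population i, the per-locus weighted pattern
#' probabilities are \eqn{abba_l = (1 - p_1) p_2 p_3 (1 - p_O)} and
#' \eqn{baba_l = p_1 (1 - p_2) p_3 (1 - p_O)};
#' \eqn{D = (\sum abba - \sum baba) / (\sum abba + \sum baba)}. The
#' weighted sums are non-integer "counts". Significance comes from a
#' delete-one block jackknife over loci; an excess of ABBA (significant
#' positive D) indicates introgression from P3 into P2, an excess of BABA
#' excess shared ancestry between P1 and P3.
#'
#' Loci with no outgroup calls, or no calls in any of P1-P3, are dropped;
#' loci where the outgroup is polymorphic are retained but flagged.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param P1,P2,P3 population names (P3 the candidate introgression
#'   source).
#' @param outgroup outgroup population name (default the panel's
#'   \code{outgroup} role).
#' @param block_size loci per jackknife block (default 1: unlinked array
#'   SNPs).
#' @param alpha significance level for the direction label.
#' @return list of class \code{DStatResult}: \code{populations},
#'   \code{C_ABBA}, \code{C_BABA} (weighted sums), \code{abba_per_locus},
#'   \code{baba_per_locus}, \code{mean_abba}, \code{mean_baba} (per-locus
#'   means), \code{D}, \code{SE}, \code{Z}, \code{p}, \code{direction},
#'   \code{n_loci}, \code{n_outgroup_polymorphic}, \code{degenerate}.
#' @export
abbaBaba <- function(panel, P1, P2, P3, outgroup = NULL,
                     block_size = 1L, alpha = 0.05) {
    if (is.null(outgroup)) outgroup <- popRoles(panel)$outgroup
    if (is.null(outgroup)) stop("no outgroup given and no outgroup role set")
    pops <- c(P1, P2, P3, outgroup)
    for (p in pops) .checkPopulation(panel, p)
    fr <- .freqMatrix(panel, pops)             # loci x 4, allele-B freq
    keep <- stats::complete.cases(fr)
    fr <- fr[keep, , drop = FALSE]
    if (nrow(fr) < 2L)
        stop("need >= 2 loci with calls in all four populations")
    # polarise: ancestral = outgroup major allele
    fo <- fr[, 4L]
    flipped <- fo > 0.5
    der <- fr
    der[flipped, ] <- 1 - fr[flipped, , drop = FALSE]
    p1 <- der[, 1L]; p2 <- der[, 2L]; p3 <- der[, 3L]; pO <- der[, 4L]
    abba <- (1 - p1) * p2 * p3 * (1 - pO)
    baba <- p1 * (1 - p2) * p3 * (1 - pO)
    CA <- sum(abba); CB <- sum(baba)
    D <- if (CA + CB > 0) (CA - CB) / (CA + CB) else NA_real_
    jk <- if (is.na(D)) list(SE = NA_real_, Z = NA_real_, p = NA_real_,
                             degenerate = TRUE)
          else tryCatch(
              jackknifeSignificance(abba, baba, block_size = block_size),
              error = function(e) list(SE = NA_real_, Z = NA_real_,
                                       p = NA_real_, degenerate = TRUE))
    res <- structure(list(
        populations = c(P1 = P1, P2 = P2, P3 = P3, O = outgroup),
        C_ABBA = CA, C_BABA = CB,
        abba_per_locus = abba, baba_per_locus = baba,
        mean_abba = CA / length(abba), mean_baba = CB / length(baba),
        D = D, SE = jk$SE, Z = jk$Z, p = jk$p,
        degenerate = jk$degenerate,
        n_loci = nrow(der),
        n_outgroup_polymorphic = sum(pO > 0 & pO < 1)),
        class = "DStatResult")
    res$direction <- interpretDirection(res, alpha = alpha)
    res
}

#' Delete-one-block jackknife for Patterson's D
#'
#' Blocks of loci are deleted in turn and D recomputed from the remaining
#' weighted sums; the jackknife variance gives the SE, Z = D / SE, and a
#' two-sided normal p-value tests the null D = 0. When every block yields
#' the same D the SE is 0 and the test is flagged degenerate (p undefined).
#'
#' @param abba,baba per-locus weighted pattern values.
#' @param block_size loci per block (default 1).
#' @return list: \code{SE}, \code{Z}, \code{p}, \code{n_blocks},
#'   \code{degenerate}.
#' @export
jackknifeSignificance <- function(abba, baba, block_size = 1L) {
    stopifnot(length(abba) == length(baba))
    nb <- ceiling(length(abba) / block_size)
    if (nb < 3L) stop("need >= 3 jackknife blocks")
    blk <- rep(seq_len(nb), each = block_size)[seq_along(abba)]
    sa <- tapply(abba, blk, sum)
    sb <- tapply(baba, blk, sum)
    CA <- sum(sa); CB <- sum(sb)
    Dj <- ((CA - sa) - (CB - sb)) / ((CA - sa) + (CB - sb))
    ok <- is.finite(Dj)
    if (sum(ok) < 3L) stop("need >= 3 informative jackknife blocks")
    Dj <- Dj[ok]
    B <- length(Dj)
    v <- (B - 1) / B * sum((Dj - mean(Dj))^2)
    SE <- sqrt(v)
    D <- (CA - CB) / (CA + CB)
    if (SE == 0)
        return(list(SE = 0, Z = NA_real_, p = NA_real_, n_blocks = B,
                    degenerate = TRUE))
    Z <- D / SE
    list(SE = SE, Z = Z, p = 2 * stats::pnorm(-abs(Z)), n_blocks = B,
         degenerate = FALSE)
}

#' Interpret the direction of a significant D statistic
#'
#' Significant positive D (ABBA excess) is labelled introgression
#' \code{"P3->P2"}; significant negative D (BABA excess)
#' \code{"P1-P3 shared ancestry"}; otherwise \code{"none"}.
#'
#' @param result a \code{DStatResult}.
#' @param alpha significance level (default 0.05).
#' @return character label.
#' @export
interpretDirection <- function(result, alpha = 0.05) {
    if (is.na(result$D) || is.na(result$p) || result$p >= alpha)
        return("none")
    if (result$D > 0) "P3->P2" else "P1-P3 shared ancestry"
}

#' D-statistic sweep over (P1, P2) pairs
#'
#' Runs \code{\link{abbaBaba}} for every requested pair against a fixed P3
#' and outgroup, emitting one row per trio.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param P3 candidate source population.
#' @param outgroup outgroup population (default the panel role).
#' @param pairs data.frame (or 2-column matrix) of P1, P2 names; empty
#'   input yields an empty table.
#' @param ... passed to \code{\link{abbaBaba}}.
#' @return data.frame: P1, P2, P3, ABBA, BABA, mean_ABBA, mean_BABA, D,
#'   SE, Z, p, direction, n_loci.
#' @export
dstatSweep <- function(panel, P3, outgroup = NULL, pairs, ...) {
    pairs <- as.data.frame(pairs)
    empty <- data.frame(P1 = character(), P2 = character(),
                        P3 = character(), ABBA = numeric(),
                        BABA = numeric(), mean_ABBA = numeric(),
                        mean_BABA = numeric(), D = numeric(),
                        SE = numeric(), Z = numeric(), p = numeric(),
                        direction = character(), n_loci = integer())
    if (nrow(pairs) == 0L) return(empty)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        r <- abbaBaba(panel, pairs[i, 1L], pairs[i, 2L], P3,
                      outgroup = outgroup, ...)
        data.frame(P1 = pairs[i, 1L], P2 = pairs[i, 2L], P3 = P3,
                   ABBA = r$C_ABBA, BABA = r$C_BABA,
                   mean_ABBA = r$mean_abba, mean_BABA = r$mean_baba,
                   D = r$D, SE = r$SE, Z = r$Z, p = r$p,
                   direction = r$direction, n_loci = r$n_loci)
    })
    do.call(rbind, rows)
}

#' @export
print.DStatResult <- function(x, ...) {
    cat(sprintf("ABBA-BABA: P1=%s P2=%s P3=%s O=%s (%d loci)\n",
                x$populations["P1"], x$populations["P2"],
                x$populations["P3"], x$populations["O"], x$n_loci))
    cat(sprintf("ABBA = %.3f, BABA = %.3f, D = %.3f, Z = %.2f, p = %.3g\n",
                x$C_ABBA, x$C_BABA, x$D,
                if (is.na(x$Z)) NA else x$Z, x$p))
    cat("direction:", x$direction, "\n")
    invisible(x)
}
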