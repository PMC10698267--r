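# builds a panel whose population allele frequencies are exactly the given
# per-locus values by using large homogeneous genotype counts
freq_panel <- function(freq_list, n = 10) {
    # freq_list: named list pop -> vector of allele-B freqs; frequencies
    # must be multiples of 1/(2n)
    pans <- lapply(names(freq_list), function(pop) {
        fr <- freq_list[[pop]]
        g <- vapply(fr, function(p) {
            nb <- round(2 * n * p)
            copies <- c(rep(2L, nb %/% 2), rep(1L, nb %% 2))
            c(copies, rep(0L, n - length(copies)))
        }, integer(n))
        rownames(g) <- paste0(pop, "_", seq_len(n))
        colnames(g) <- paste0("l", seq_along(fr))
        GenotypePanel(g, population = rep(pop, n))
    })
    combinePanels(pans)
}

test_that("D is zero when P1 and P2 have identical frequencies", {
    pan <- freq_panel(list(P1 = c(0.2, 0.5, 0.1), P2 = c(0.2, 0.5, 0.1),
                           P3 = c(0.9, 0.8, 0.7), O = c(0, 0, 0)))
    res <- abbaBaba(pan, "P1", "P2", "P3", "O")
    expect_equal(res$D, 0)
    expect_equal(res$C_ABBA, res$C_BABA)
})

test_that("boundary pattern gives D = 1 and weighted counts match by hand", {
    pan <- freq_panel(list(P1 = c(0, 0.5, 0.5), P2 = c(1, 0.5, 0.5),
                           P3 = c(1, 0.5, 0.5), O = c(0, 0, 0)))
    res <- abbaBaba(pan, "P1", "P2", "P3", "O")
    # locus 1: abba = 1*1*1*1 = 1, baba = 0; loci 2-3 symmetric
    expect_equal(res$abba_per_locus[1], 1)
    expect_equal(res$baba_per_locus[1], 0)
    # 3-locus hand-summed products
    p1 <- c(0, 0.5, 0.5); p2 <- c(1, 0.5, 0.5); p3 <- c(1, 0.5, 0.5)
    expect_equal(res$C_ABBA, sum((1 - p1) * p2 * p3))
    expect_equal(res$C_BABA, sum(p1 * (1 - p2) * p3))
    one <- freq_panel(list(P1 = c(0, 0), P2 = c(1, 0), P3 = c(1, 0),
                           O = c(0, 0)))
    res1 <- abbaBaba(one, "P1", "P2", "P3", "O")
    expect_equal(res1$D, 1)
})

test_that("swapping P1 and P2 flips the sign of D exactly", {
    fr <- makeLineageFrequencies(200, 0.5, seed = 231)
    pan <- combinePanels(
        simulateParental(fr, "north", 15, seed = 232, population = "P1"),
        simulateParental(fr, "north", 15, seed = 233, population = "P2"),
        simulateParental(fr, "south", 15, seed = 234, population = "P3"),
        GenotypePanel(matrix(0L, 5, 200,
                             dimnames = list(paste0("o", 1:5), fr$locus)),
                      population = rep("O", 5)))
    a <- abbaBaba(pan, "P1", "P2", "P3", "O")
    b <- abbaBaba(pan, "P2", "P1", "P3", "O")
    expect_equal(a$D, -b$D, tolerance = 1e-12)
    expect_equal(a$C_ABBA, b$C_BABA, tolerance = 1e-12)
})

test_that("monomorphic-locus padding does not change D", {
    base <- list(P1 = c(0.2, 0.4), P2 = c(0.6, 0.3), P3 = c(0.9, 0.8),
                 O = c(0, 0))
    padded <- lapply(base, function(x) c(x, 0, 0))
    d1 <- abbaBaba(freq_panel(base), "P1", "P2", "P3", "O")$D
    d2 <- abbaBaba(freq_panel(padded), "P1", "P2", "P3", "O")$D
    expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("outgroup polarisation uses the major allele as ancestral", {
    # same data, outgroup near-fixed for allele B: derived becomes allele A
    panB <- freq_panel(list(P1 = c(0.2, 0.3), P2 = c(0.6, 0.5),
                            P3 = c(0.9, 0.9), O = c(0, 0)))
    panA <- freq_panel(list(P1 = 1 - c(0.2, 0.3), P2 = 1 - c(0.6, 0.5),
                            P3 = 1 - c(0.9, 0.9), O = c(1, 1)))
    rA <- abbaBaba(panA, "P1", "P2", "P3", "O")
    rB <- abbaBaba(panB, "P1", "P2", "P3", "O")
    expect_equal(rA$D, rB$D, tolerance = 1e-12)
})

test_that("jackknife: doubling loci keeps D, shrinks SE; degenerate flagged", {
    abba <- c(0.8, 0.3, 0.5, 0.9, 0.2, 0.7)
    baba <- c(0.2, 0.4, 0.3, 0.1, 0.5, 0.2)
    jk <- jackknifeSignificance(abba, baba)
    # oracle: explicit delete-one recomputation
    D_full <- (sum(abba) - sum(baba)) / (sum(abba) + sum(baba))
    Dj <- vapply(seq_along(abba), function(i) {
        (sum(abba[-i]) - sum(baba[-i])) / (sum(abba[-i]) + sum(baba[-i]))
    }, numeric(1))
    B <- length(Dj)
    se_oracle <- sqrt((B - 1) / B * sum((Dj - mean(Dj))^2))
    expect_equal(jk$SE, se_oracle, tolerance = 1e-12)
    expect_equal(jk$Z, D_full / se_oracle, tolerance = 1e-12)
    jk2 <- jackknifeSignificance(rep(abba, 2), rep(baba, 2))
    D2 <- (2 * sum(abba) - 2 * sum(baba)) / (2 * sum(abba) + 2 * sum(baba))
    expect_equal(D2, D_full)
    expect_lt(jk2$SE, jk$SE)
    # identical blocks: SE = 0, p undefined but flagged
    jk3 <- jackknifeSignificance(rep(0.5, 5), rep(0.25, 5))
    expect_true(jk3$degenerate)
    expect_true(is.na(jk3$p))
    expect_error(jackknifeSignificance(c(1, 1), c(0, 0)), ">= 3")
})

test_that("direction interpretation follows sign and significance", {
    mk <- function(D, p) structure(list(D = D, p = p),
                                   class = "DStatResult")
    expect_equal(interpretDirection(mk(0.42, 1e-4)), "P3->P2")
    expect_equal(interpretDirection(mk(0.00, 0.98)), "none")
    expect_equal(interpretDirection(mk(-0.3, 1e-3)),
                 "P1-P3 shared ancestry")
    expect_equal(interpretDirection(mk(0.4, 0.2)), "none")
})

test_that("dstat sweep emits one row per trio and validates populations", {
    fr <- makeLineageFrequencies(100, 0.8, seed = 241)
    pan <- combinePanels(
        simulateParental(fr, "north", 10, seed = 242, population = "A"),
        simulateParental(fr, "north", 10, seed = 243, population = "B"),
        simulateParental(fr, "north", 10, seed = 244, population = "C"),
        simulateParental(fr, "south", 10, seed = 245, population = "MI"),
        GenotypePanel(matrix(0L, 4, 100,
                             dimnames = list(paste0("o", 1:4), fr$locus)),
                      population = rep("O", 4)))
    pairs <- t(combn(c("A", "B", "C"), 2))
    tab <- dstatSweep(pan, P3 = "MI", outgroup = "O", pairs = pairs)
    expect_equal(nrow(tab), 3L)
    expect_true(all(c("ABBA", "BABA", "D", "p", "direction") %in%
                    names(tab)))
    empty <- dstatSweep(pan, P3 = "MI", outgroup = "O",
                        pairs = data.frame(P1 = character(),
                                           P2 = character()))
    expect_equal(nrow(empty), 0L)
    expect_error(dstatSweep(pan, P3 = "MI", outgroup = "O",
                            pairs = rbind(c("A", "nope"))),
                 "unknown population")
})
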