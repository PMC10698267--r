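test_that("observed heterozygosity counts called heterozygotes", {
    p1 <- toy_panel(matrix(c(0L, 1L, 1L, 2L), ncol = 1,
                           dimnames = list(paste0("s", 1:4), "l1")),
                    rep("P", 4))
    expect_equal(observedHeterozygosity(p1, "P"), 0.5)
    p2 <- toy_panel(matrix(1L, 3, 2, dimnames = list(paste0("s", 1:3),
                                                     c("l1", "l2"))),
                    rep("P", 3))
    expect_equal(observedHeterozygosity(p2, "P"), 1.0)
    p3 <- toy_panel(matrix(c(0L, 1L, NA), ncol = 1,
                           dimnames = list(paste0("s", 1:3), "l1")),
                    rep("P", 3))
    expect_equal(observedHeterozygosity(p3, "P"), 0.5)
})

test_that("unbiased expected heterozygosity matches the formula and HW", {
    p <- toy_panel(matrix(c(0L, 2L), ncol = 1,
                          dimnames = list(c("s1", "s2"), "l1")),
                   rep("P", 2))
    expect_equal(expectedHeterozygosity(p, "P"), (4 / 3) * 0.5)
    mono <- toy_panel(matrix(0L, 4, 1,
                             dimnames = list(paste0("s", 1:4), "l1")),
                      rep("P", 4))
    expect_equal(expectedHeterozygosity(mono, "P"), 0)
    # large Hardy-Weinberg sample at p = 0.5: He near 0.5
    fr <- data.frame(locus = paste0("l", 1:20), north = 0.5, south = 0.5)
    big <- simulateParental(fr, "north", 5000, seed = 51)
    expect_equal(expectedHeterozygosity(big, "north"), 0.5,
                 tolerance = 0.01)
})

test_that("rarefied allelic richness matches hypergeometric enumeration", {
    fixed <- toy_panel(matrix(2L, 5, 1,
                              dimnames = list(paste0("s", 1:5), "l1")),
                       rep("P", 5))
    expect_equal(allelicRichness(fixed, "P", g = 4), 1)
    # N = 40 copies, N_B = 10, g = 20
    g <- matrix(c(rep(1L, 10), rep(0L, 10)), ncol = 1,
                dimnames = list(paste0("s", 1:20), "l1"))
    p <- toy_panel(g, rep("P", 20))
    expect_equal(allelicRichness(p, "P", g = 20),
                 2 - choose(30, 20) / choose(40, 20))
    # g = 2 closed form 1 + 2pq N/(N-1), vs direct enumeration over pairs
    pfreq <- 10 / 40
    expect_equal(allelicRichness(p, "P", g = 2),
                 1 + 2 * pfreq * (1 - pfreq) * 40 / 39)
    copies <- c(rep(1, 10), rep(0, 30))
    pairs <- combn(40, 2)
    enum <- mean(apply(pairs, 2, function(ix)
        length(unique(copies[ix]))))
    expect_equal(allelicRichness(p, "P", g = 2), enum)
})

test_that("allelic richness is monotone in g and reaches the allele count", {
    set.seed(61)
    g <- matrix(sample(0:2, 60, replace = TRUE), ncol = 3,
                dimnames = list(paste0("s", 1:20), paste0("l", 1:3)))
    p <- toy_panel(g, rep("P", 20))
    ar <- vapply(2:40, function(gg) allelicRichness(p, "P", g = gg),
                 numeric(1))
    expect_true(all(diff(ar) >= -1e-12))
    n_alleles <- apply(g, 2, function(x)
        (sum(x) > 0) + (sum(x) < 2 * length(x)))
    expect_equal(allelicRichness(p, "P", g = 40, per_locus = TRUE),
                 n_alleles, ignore_attr = TRUE)
})

test_that("diversity ANOVA separates shifted groups, not identical ones", {
    fr <- makeLineageFrequencies(40, 0.9, seed = 71)
    a <- simulateParental(fr, "north", 15, seed = 72, population = "A")
    b <- simulateParental(fr, "north", 15, seed = 73, population = "B")
    hom <- compareDiversity(combinePanels(a, b))
    expect_true(all(hom$p > 0.001))
    # strong diversity shift: one population near-fixed everywhere
    frfix <- data.frame(locus = paste0("l", 1:40),
                        north = rep(0.5, 40), south = rep(0.01, 40))
    c1 <- simulateParental(frfix, "north", 15, seed = 74, population = "C")
    c2 <- simulateParental(frfix, "south", 15, seed = 75, population = "D")
    shift <- compareDiversity(combinePanels(c1, c2))
    expect_true(all(shift$p < 0.001))
    expect_error(compareDiversity(a), ">= 2 populations")
})

test_that("Weir-Cockerham theta: fixed difference, null, and oracle match", {
    fd <- makeLineageFrequencies(10, 1)
    pan <- combinePanels(simulateParental(fd, "north", 8, seed = 81),
                         simulateParental(fd, "south", 8, seed = 82))
    expect_equal(weirCockerhamFst(pan, "north", "south")$theta, 1)
    # two samples from one pool: theta near 0 (may be negative)
    fr <- makeLineageFrequencies(100, 0.5, seed = 83)
    null_pan <- combinePanels(
        simulateParental(fr, "north", 20, seed = 84, population = "X"),
        simulateParental(fr, "north", 20, seed = 85, population = "Y"))
    th <- weirCockerhamFst(null_pan, "X", "Y")$theta
    expect_lt(abs(th), 0.05)
    # toy genotypes against the scalar brute-force oracle
    toy <- toy_two_pop()
    got <- weirCockerhamFst(toy, "A", "B")$theta
    G <- genotypes(toy)
    want <- oracle_wc_theta(G[1:3, , drop = FALSE], G[4:6, , drop = FALSE])
    expect_equal(got, want, tolerance = 1e-12)
})

test_that("theta is invariant to allele relabeling and sample order", {
    fr <- makeLineageFrequencies(30, 0.6, seed = 91)
    pan <- combinePanels(simulateParental(fr, "north", 10, seed = 92),
                         simulateParental(fr, "south", 10, seed = 93))
    th <- weirCockerhamFst(pan, "north", "south")$theta
    G <- genotypes(pan)
    flip <- GenotypePanel(2L - G, population = populations(pan))
    expect_equal(weirCockerhamFst(flip, "north", "south")$theta, th)
    perm <- sample(nrow(G))
    shuf <- GenotypePanel(G[perm, ], population = populations(pan)[perm])
    expect_equal(weirCockerhamFst(shuf, "north", "south")$theta, th)
})

test_that("permutation test: fixed difference gives minimal p, reproducible", {
    fd <- makeLineageFrequencies(10, 1)
    pan <- combinePanels(simulateParental(fd, "north", 8, seed = 101),
                         simulateParental(fd, "south", 8, seed = 102))
    res <- fstPermutationTest(pan, "north", "south", n_perm = 99,
                              seed = 103)
    expect_equal(res$p, 1 / 100)
    res2 <- fstPermutationTest(pan, "north", "south", n_perm = 99,
                               seed = 103)
    expect_identical(res, res2)
    # same-pool samples: usually non-significant
    fr <- makeLineageFrequencies(50, 0.5, seed = 104)
    null_pan <- combinePanels(
        simulateParental(fr, "north", 12, seed = 105, population = "X"),
        simulateParental(fr, "north", 12, seed = 106, population = "Y"))
    pnull <- fstPermutationTest(null_pan, "X", "Y", n_perm = 199,
                                seed = 107)$p
    expect_gt(pnull, 0.01)
})

test_that("temporal pooling keeps homogeneous years, splits diverged ones", {
    fr <- makeLineageFrequencies(60, 0.9, seed = 111)
    # the pooling decision under the null keeps alpha = 5% false-split
    # probability, so assert over replicate panels rather than one draw
    pooled <- vapply(1:8, function(r) {
        same <- combinePanels(
            simulateParental(fr, "north", 12, seed = 500 + 2 * r,
                             population = "loc1"),
            simulateParental(fr, "north", 12, seed = 501 + 2 * r,
                             population = "loc1"))
        SummarizedExperiment::colData(same)$year <-
            rep(c(2018L, 2020L), each = 12)
        res <- temporalPooling(same, n_perm = 199, seed = 114)
        res$report$pooled
    }, logical(1))
    expect_gte(sum(pooled), 6L)
    # strongly diverged "years": one from each lineage
    diff <- combinePanels(
        simulateParental(fr, "north", 12, seed = 115, population = "loc2"),
        simulateParental(fr, "south", 12, seed = 116, population = "loc2"))
    SummarizedExperiment::colData(diff)$year <-
        rep(c(2018L, 2020L), each = 12)
    res2 <- temporalPooling(diff, n_perm = 199, seed = 117)
    expect_false(res2$report$pooled)
    expect_setequal(unique(populations(res2$panel)),
                    c("loc2_2018", "loc2_2020"))
    # single-year location passes through untouched
    solo <- simulateParental(fr, "north", 6, seed = 118,
                             population = "loc3")
    res3 <- temporalPooling(solo, n_perm = 99, seed = 119)
    expect_equal(nrow(res3$report), 0L)
    expect_equal(unique(populations(res3$panel)), "loc3")
})
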