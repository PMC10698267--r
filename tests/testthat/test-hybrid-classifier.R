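test_that("category triples equal the pedigree enumeration oracle exactly", {
    tab <- categoryTable()
    expect_equal(tab$p_NN + tab$p_NS + tab$p_SS, rep(1, 12))
    expect_equal(unlist(tab[tab$category == "WH", 2:4]), c(1, 0, 0),
                 ignore_attr = TRUE)
    expect_equal(unlist(tab[tab$category == "MI", 2:4]), c(0, 0, 1),
                 ignore_attr = TRUE)
    expect_equal(unlist(tab[tab$category == "F1", 2:4]), c(0, 1, 0),
                 ignore_attr = TRUE)
    for (i in seq_len(nrow(tab)))
        expect_identical(unname(unlist(tab[i, 2:4])),
                         unname(oracle_triple(tab$category[i])),
                         info = tab$category[i])
})

test_that("genotype likelihood kernel matches hand computations", {
    # fully diagnostic locus: NS pair forces heterozygosity
    expect_equal(genotypeLikelihood(1L, "NS", pN = 0, pS = 1), 1)
    expect_equal(genotypeLikelihood(0L, "NN", pN = 0, pS = 1), 1)
    # pN = 0.1, pS = 0.9, NS pair: P(1) = 0.1*0.1 + 0.9*0.9 = 0.82
    expect_equal(genotypeLikelihood(1L, "NS", pN = 0.1, pS = 0.9), 0.82)
    # kernel normalises over genotypes
    tot <- sum(vapply(0:2, genotypeLikelihood, numeric(1),
                      origin_pair = "NS", pN = 0.3, pS = 0.7))
    expect_equal(tot, 1)
    expect_error(genotypeLikelihood(3L, "NN", 0.5, 0.5), "0, 1 or 2")
})

test_that("single diagnostic heterozygous locus yields the p_NS posterior", {
    # uniform prior over 12 classes; likelihoods are the p_NS values, so
    # posterior(F1) = 1 / sum(p_NS) = 1/5.5 = 2/11 (verified against the
    # enumeration oracle)
    tab <- categoryTable()
    sum_pns <- sum(vapply(tab$category,
                          function(cc) oracle_triple(cc)[["p_NS"]],
                          numeric(1)))
    expect_equal(sum_pns, 5.5)
    g <- rbind(nb = 0L, nb2 = 0L, nb3 = 0L, nb4 = 0L, nb5 = 0L,
               sb = 2L, sb2 = 2L, sb3 = 2L, sb4 = 2L, sb5 = 2L,
               q1 = 1L)
    colnames(g) <- "l1"
    pan <- toy_panel(g, c(rep("N", 5), rep("S", 5), "Q"))
    res <- classifyHybrids(pan, north = "N", south = "S",
                           pseudocount = 0)
    post <- res$posterior["q1", ]
    expect_equal(unname(post["F1"]), 1 / sum_pns)
    expect_equal(unname(post["WH"]), 0)
    expect_equal(unname(post["bWHxMI"]), 0.75 / sum_pns)
})

test_that("pure individuals dominate toward their parental class", {
    fd <- makeLineageFrequencies(96, 1)
    pan <- combinePanels(
        simulateParental(fd, "north", 20, seed = 181, population = "WHb"),
        simulateParental(fd, "south", 20, seed = 182, population = "MIb"),
        simulateParental(fd, "north", 30, seed = 183, population = "Q"))
    res <- classifyHybrids(pan, north = "WHb", south = "MIb")
    expect_true(all(res$map == "WH"))
    expect_true(all(res$confidence > 0.99))
})

test_that("posterior is invariant to locus order and to all-missing loci", {
    fr <- makeLineageFrequencies(30, 0.9, seed = 191)
    pan <- combinePanels(
        simulateParental(fr, "north", 15, seed = 192, population = "N"),
        simulateParental(fr, "south", 15, seed = 193, population = "S"),
        simulateCategory(fr, "F2", 5, seed = 194, population = "Q"))
    base <- classifyHybrids(pan, north = "N", south = "S")
    perm <- sample(nrow(pan))
    shuffled <- classifyHybrids(pan[perm, ], north = "N", south = "S")
    expect_equal(shuffled$posterior, base$posterior, tolerance = 1e-12)
    # appending an all-missing locus changes nothing
    g2 <- cbind(genotypes(pan), Lx = NA_integer_)
    pan2 <- GenotypePanel(g2, population = populations(pan))
    aug <- classifyHybrids(pan2, north = "N", south = "S")
    expect_equal(aug$posterior, base$posterior, tolerance = 1e-12)
})

test_that("individuals with no called loci are flagged unclassifiable", {
    g <- rbind(n1 = c(0L, 0L), n2 = c(0L, 0L), n3 = c(0L, 0L),
               n4 = c(0L, 0L), n5 = c(0L, 0L),
               s1 = c(2L, 2L), s2 = c(2L, 2L), s3 = c(2L, 2L),
               s4 = c(2L, 2L), s5 = c(2L, 2L),
               q1 = c(NA_integer_, NA_integer_))
    colnames(g) <- c("l1", "l2")
    pan <- toy_panel(g, c(rep("N", 5), rep("S", 5), "Q"))
    res <- classifyHybrids(pan, north = "N", south = "S")
    expect_true(is.na(res$map["q1"] ))
    expect_true(all(is.na(res$posterior["q1", ])))
})

test_that("simulated F2 are called F2 with ~94% mean confidence at 96 loci", {
    # F2 are separated from F1 only by recombinant homozygous genotypes
    # and from second-generation backcrosses by genotype proportions; on a
    # fully diagnostic 96-locus panel the model puts their mean assignment
    # confidence near 94%
    fd <- makeLineageFrequencies(96, 1)
    set.seed(201)
    pan <- combinePanels(
        simulateParental(fd, "north", 30, population = "N"),
        simulateParental(fd, "south", 30, population = "S"),
        simulateCategory(fd, "F2", 2000, population = "Q"))
    res <- classifyHybrids(pan, north = "N", south = "S")
    correct <- res$map == "F2"
    expect_gte(mean(correct), 0.88)
    expect_equal(mean(res$confidence[correct]), 0.94, tolerance = 0.03)
    # F2 never drift to parental classes
    expect_false(any(res$map %in% c("WH", "MI")))
})

test_that("power simulation report is internally consistent", {
    fd <- makeLineageFrequencies(96, 1)
    rep <- powerSimulation(fd, n_per_category = 50, seed = 211,
                           n_baseline = 30)
    expect_equal(unname(rowSums(rep$confusion)), rep.int(50L, 12L))
    expect_equal(sum(rep$confusion), 12L * 50L)
    expect_equal(rep$summary$pct_correct[rep$summary$category == "WH"], 100)
    expect_equal(rep$summary$pct_correct[rep$summary$category == "MI"], 100)
    # F1 never lands in parental or backcross classes
    f1row <- rep$confusion["F1", ]
    expect_equal(sum(f1row[setdiff(names(f1row), c("F1", "F2"))]), 0)
    expect_gte(rep$summary$pct_correct_relaxed[
        rep$summary$category == "F1"], 100)
})

test_that("Gibbs classifier agrees with the plug-in on clear cases", {
    fd <- makeLineageFrequencies(40, 1)
    pan <- combinePanels(
        simulateParental(fd, "north", 15, seed = 221, population = "N"),
        simulateParental(fd, "south", 15, seed = 222, population = "S"),
        simulateCategory(fd, "F1", 5, seed = 223, population = "Q"))
    plug <- classifyHybrids(pan, north = "N", south = "S")
    gib <- classifyHybridsGibbs(pan, north = "N", south = "S",
                                n_sweeps = 50, burn_in = 5, seed = 224)
    expect_equal(gib$map, unname(plug$map))
    expect_true(all(gib$posterior_upper >= gib$posterior_lower))
})
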