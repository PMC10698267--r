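# Independent oracles used across the test files.

# --- exhaustive pedigree enumeration of origin-pair triples ---------------
# Represents a diploid's locus state as a distribution over ORDERED origin
# pairs (NN, NS, SN, SS) and pushes it through each cross explicitly: a
# parent transmits either copy with probability 1/2. Independent of the
# package's gamete-N recursion.
oracle_pair_dist <- function(category) {
    peds <- list(
        F1 = c("WH", "MI"), F2 = c("F1", "F1"),
        bWH = c("WH", "F1"), bMI = c("MI", "F1"),
        bWHxWH = c("bWH", "WH"), bWHxMI = c("bWH", "MI"),
        bWHxF1 = c("bWH", "F1"), bMIxMI = c("bMI", "MI"),
        bMIxWH = c("bMI", "WH"), bMIxF1 = c("bMI", "F1"))
    if (category == "WH") return(c(NN = 1, NS = 0, SN = 0, SS = 0))
    if (category == "MI") return(c(NN = 0, NS = 0, SN = 0, SS = 1))
    par <- peds[[category]]
    gam <- function(pd) {
        # P(transmitted copy is from the north pool)
        c(N = pd[["NN"]] + 0.5 * pd[["NS"]] + 0.5 * pd[["SN"]],
          S = pd[["SS"]] + 0.5 * pd[["NS"]] + 0.5 * pd[["SN"]])
    }
    g1 <- gam(oracle_pair_dist(par[1L]))
    g2 <- gam(oracle_pair_dist(par[2L]))
    c(NN = g1[["N"]] * g2[["N"]], NS = g1[["N"]] * g2[["S"]],
      SN = g1[["S"]] * g2[["N"]], SS = g1[["S"]] * g2[["S"]])
}

oracle_triple <- function(category) {
    pd <- oracle_pair_dist(category)
    c(p_NN = pd[["NN"]], p_NS = pd[["NS"]] + pd[["SN"]],
      p_SS = pd[["SS"]])
}

# --- brute-force Weir-Cockerham components (scalar transliteration) ------
# g1, g2: genotype vectors (one locus) for the two population samples.
oracle_wc_locus <- function(g1, g2) {
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    r <- 2
    n1 <- length(g1); n2 <- length(g2)
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                    ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
}

oracle_wc_theta <- function(G1, G2) {
    # G1, G2: samples x loci genotype matrices
    comp <- sapply(seq_len(ncol(G1)), function(l) {
        p1 <- mean(G1[, l], na.rm = TRUE) / 2
        p2 <- mean(G2[, l], na.rm = TRUE) / 2
        if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1))
            return(c(a = 0, b = 0, c = 0, use = 0))
        c(oracle_wc_locus(G1[, l], G2[, l]), use = 1)
    })
    keep <- comp["use", ] == 1
    sum(comp["a", keep]) /
        sum(comp["a", keep] + comp["b", keep] + comp["c", keep])
}

# --- small panel builders -------------------------------------------------
toy_panel <- function(genotypes, population, ...) {
    GenotypePanel(genotypes, population = population, ...)
}

# two-population toy from the differentiation examples:
# A: {0,1,1}; B: {2,2,1} at each of two loci (second locus shuffled)
toy_two_pop <- function() {
    g <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L),
               c(2L, 2L), c(2L, 1L), c(1L, 2L))
    rownames(g) <- paste0("s", 1:6)
    colnames(g) <- c("l1", "l2")
    GenotypePanel(g, population = c("A", "A", "A", "B", "B", "B"))
}
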