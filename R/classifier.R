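#' Genotype likelihood given a gene-pool origin pair
#'
#' Probability of a genotype code (0/1/2 copies of allele B) given the
#' unordered pool-of-origin pair of the two gene copies and the allele-B
#' frequencies of the two pools: an NN pair draws both copies from the
#' northern pool (Hardy-Weinberg), SS from the southern pool, and an NS
#' pair draws exactly one copy from each pool, so
#' P(0) = (1-pN)(1-pS), P(1) = pN(1-pS) + (1-pN)pS, P(2) = pN pS.
#' This is the likelihood kernel of the NEWHYBRIDS class model.
#'
#' @param genotype genotype code(s) in \{0, 1, 2\}.
#' @param origin_pair \code{"NN"}, \code{"NS"} or \code{"SS"}.
#' @param pN,pS allele-B frequency in the northern/southern pool
#'   (vectorised over loci).
#' @return probability vector.
#' @export
genotypeLikelihood <- function(genotype, origin_pair = c("NN", "NS", "SS"),
                               pN, pS) {
    origin_pair <- match.arg(origin_pair)
    if (any(!genotype %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
    p <- switch(origin_pair,
        NN = cbind((1 - pN)^2, 2 * pN * (1 - pN), pN^2),
        SS = cbind((1 - pS)^2, 2 * pS * (1 - pS), pS^2),
        NS = cbind((1 - pN) * (1 - pS),
                   pN * (1 - pS) + (1 - pN) * pS,
                   pN * pS))
    p[cbind(seq_along(genotype), genotype + 1L)]
}

# 3 x L x 12 array of P(genotype | locus, category); categories in
# categoryTable() order
.categoryGenotypeProbs <- function(pN, pS, tab = categoryTable()) {
    L <- length(pN)
    kern <- array(0, dim = c(3L, L, 3L))       # genotype x locus x pair
    kern[, , 1L] <- rbind((1 - pN)^2, 2 * pN * (1 - pN), pN^2)
    kern[, , 2L] <- rbind((1 - pN) * (1 - pS),
                          pN * (1 - pS) + (1 - pN) * pS, pN * pS)
    kern[, , 3L] <- rbind((1 - pS)^2, 2 * pS * (1 - pS), pS^2)
    out <- array(0, dim = c(3L, L, nrow(tab)),
                 dimnames = list(NULL, NULL, tab$category))
    for (k in seq_len(nrow(tab)))
        out[, , k] <- tab$p_NN[k] * kern[, , 1L] +
            tab$p_NS[k] * kern[, , 2L] + tab$p_SS[k] * kern[, , 3L]
    out
}

# pseudocount-smoothed pool frequencies from baseline populations
.baselineFrequencies <- function(panel, north, south, pseudocount) {
    fN <- alleleCounts(panel, north)
    fS <- alleleCounts(panel, south)
    list(pN = (fN$count_B + pseudocount) /
              (fN$called_copies + 2 * pseudocount),
         pS = (fS$count_B + pseudocount) /
              (fS$called_copies + 2 * pseudocount))
}

# core posterior computation; G: query samples x loci, prior over 12
.classifyCore <- function(G, pN, pS, prior, tab = categoryTable()) {
    probs <- .categoryGenotypeProbs(pN, pS, tab)
    n <- nrow(G); L <- ncol(G); K <- nrow(tab)
    pos <- (col(G) - 1L) * 3L + G + 1L         # NA where G missing
    ll <- matrix(0, n, K, dimnames = list(rownames(G), tab$category))
    for (k in seq_len(K)) {
        lp <- log(as.vector(probs[, , k]))[pos]
        ll[, k] <- rowSums(matrix(lp, n, L), na.rm = TRUE)
    }
    ll <- sweep(ll, 2L, -log(prior), "-")      # add log prior
    mx <- apply(ll, 1L, max)
    post <- exp(ll - mx)
    post <- post / rowSums(post)
    n_used <- rowSums(!is.na(G))
    post[n_used == 0L, ] <- NA_real_
    post
}

#' Classify individuals into the twelve hybrid categories
#'
#' Plug-in empirical-Bayes classifier: parental pool allele frequencies are
#' estimated from the two baseline populations with an additive
#' pseudocount, then each query individual's log-likelihood under every
#' category is the sum over its called loci of the log mixture of
#' origin-pair genotype likelihoods (\code{\link{genotypeLikelihood}})
#' weighted by the category's (p_NN, p_NS, p_SS) triple. Posterior =
#' normalised prior x likelihood; missing loci are skipped. Individuals
#' with no called loci are flagged unclassifiable (all-NA posterior).
#'
#' @param panel a \linkS4class{GenotypePanel} containing baselines and
#'   queries.
#' @param north,south baseline population names for the parental pools
#'   (default the panel's \code{parental_north}/\code{parental_south}
#'   roles). A warning is issued for baselines of fewer than 5 individuals.
#' @param query sample ids to classify; default all samples outside the
#'   two baseline populations.
#' @param prior prior over the 12 categories (default uniform), in
#'   \code{categoryTable()} order.
#' @param pseudocount additive pseudocount per allele for baseline
#'   frequency estimation (default 0.5).
#' @return list of class \code{ClassificationResult}: \code{posterior}
#'   (queries x 12), \code{map} (best category), \code{confidence} (MAP
#'   posterior), \code{n_loci_used}, \code{freqs} (estimated pN, pS),
#'   \code{prior}.
#' @export
classifyHybrids <- function(panel, north = NULL, south = NULL,
                            query = NULL, prior = NULL,
                            pseudocount = 0.5) {
    roles <- popRoles(panel)
    if (is.null(north)) north <- roles$parental_north
    if (is.null(south)) south <- roles$parental_south
    if (is.null(north) || is.null(south))
        stop("parental baseline populations not given and no ",
             "parental_north/parental_south roles set")
    .checkPopulation(panel, north)
    .checkPopulation(panel, south)
    tab <- categoryTable()
    if (is.null(prior)) prior <- rep(1 / nrow(tab), nrow(tab))
    if (length(prior) != nrow(tab) || any(prior < 0) || sum(prior) <= 0)
        stop("prior must be 12 non-negative weights")
    prior <- prior / sum(prior)
    nb <- sum(populations(panel) == north)
    sb <- sum(populations(panel) == south)
    if (min(nb, sb) < 5L)
        warning("parental baseline with < 5 individuals; frequency ",
                "estimates will be noisy")
    fr <- .baselineFrequencies(panel, north, south, pseudocount)
    pl <- populations(panel)
    if (is.null(query))
        query <- sampleIDs(panel)[!pl %in% c(north, south)]
    unknown <- setdiff(query, sampleIDs(panel))
    if (length(unknown))
        stop("unknown query sample(s): ", paste(unknown, collapse = ", "))
    G <- genotypes(panel)[query, , drop = FALSE]
    post <- .classifyCore(G, fr$pN, fr$pS, prior, tab)
    idx <- apply(post, 1L, function(r)
        if (anyNA(r)) NA_integer_ else which.max(r))
    map <- tab$category[idx]
    conf <- apply(post, 1L, function(r)
        if (anyNA(r)) NA_real_ else max(r))
    structure(list(posterior = post, map = map, confidence = conf,
                   n_loci_used = rowSums(!is.na(G)),
                   freqs = fr, prior = prior),
              class = "ClassificationResult")
}

#' @export
print.ClassificationResult <- function(x, ...) {
    ok <- !is.na(x$map)
    cat(sprintf("Hybrid classification of %d individuals (%d unclassifiable)\n",
                length(x$map), sum(!ok)))
    print(table(factor(x$map, levels = categoryTable()$category)))
    cat(sprintf("mean MAP confidence: %.3f\n", mean(x$confidence[ok])))
    invisible(x)
}

#' Write a classification result as TSV
#'
#' Columns: sample, population, the 12 posterior probabilities, MAP class
#' and confidence.
#'
#' @param result a \code{ClassificationResult}.
#' @param panel the classified panel.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeClassification <- function(result, panel, path) {
    df <- data.frame(sample = rownames(result$posterior),
                     population = populations(panel)[
                         rownames(result$posterior)],
                     result$posterior, map = result$map,
                     confidence = result$confidence, check.names = FALSE)
    .writeTSV(df, path)
}

#' Marker-power simulation for the twelve-category classifier
#'
#' Simulates \code{n_per_category} individuals for each of the twelve
#' categories from the supplied lineage frequencies
#' (\code{\link{simulateCategory}}), classifies them blind against
#' independently simulated parental baselines, and tabulates the confusion
#' matrix and assignment confidence. With 10,000 individuals per category
#' this reproduces a 120,000-individual power study.
#'
#' Reporting follows the field convention for F1: because F1 and F2 share
#' admixture proportions and F1 carries no genotype class absent from F2,
#' an F1 assigned to F2 is counted as a non-error in
#' \code{pct_correct_relaxed} (the raw confusion matrix is always emitted).
#'
#' @param freqs lineage frequencies (\code{\link{makeLineageFrequencies}}).
#' @param n_per_category simulated individuals per category.
#' @param seed RNG seed.
#' @param n_baseline parental baseline size (default 30 per lineage).
#' @param pseudocount,prior classifier settings
#'   (\code{\link{classifyHybrids}}).
#' @param confidence_threshold cutoff for "high confidence" assignment
#'   reporting (default 0.9).
#' @return list of class \code{PowerReport}: \code{confusion} (12 x 12
#'   counts, true category in rows), \code{summary} (per-category n,
#'   pct_correct, pct_correct_relaxed, mean confidence of correct calls,
#'   pct of correct calls above the confidence threshold),
#'   \code{n_per_category}, \code{settings}.
#' @export
powerSimulation <- function(freqs, n_per_category = 10000, seed = NULL,
                            n_baseline = 30, pseudocount = 0.5,
                            prior = NULL, confidence_threshold = 0.9) {
    if (n_per_category < 1) stop("n_per_category must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    tab <- categoryTable()
    if (is.null(prior)) prior <- rep(1 / nrow(tab), nrow(tab))
    prior <- prior / sum(prior)
    baseN <- simulateParental(freqs, "north", n_baseline)
    baseS <- simulateParental(freqs, "south", n_baseline)
    bpanel <- combinePanels(baseN, baseS)
    fr <- .baselineFrequencies(bpanel, "north", "south", pseudocount)
    cats <- tab$category
    confusion <- matrix(0L, 12L, 12L, dimnames = list(true = cats,
                                                      assigned = cats))
    rows <- list()
    for (cat in cats) {
        sim <- simulateCategory(freqs, cat, n_per_category)
        post <- .classifyCore(genotypes(sim), fr$pN, fr$pS, prior, tab)
        map <- cats[apply(post, 1L, which.max)]
        conf <- apply(post, 1L, max)
        confusion[cat, ] <- confusion[cat, ] +
            table(factor(map, levels = cats))
        correct <- map == cat
        relaxed <- if (cat == "F1") map %in% c("F1", "F2") else correct
        rows[[cat]] <- data.frame(
            category = cat, n = n_per_category,
            pct_correct = 100 * mean(correct),
            pct_correct_relaxed = 100 * mean(relaxed),
            mean_confidence_correct =
                if (any(correct)) mean(conf[correct]) else NA_real_,
            pct_high_confidence =
                if (any(correct))
                    100 * mean(conf[correct] > confidence_threshold)
                else NA_real_)
    }
    structure(list(confusion = confusion,
                   summary = do.call(rbind, c(rows,
                                              make.row.names = FALSE)),
                   n_per_category = n_per_category,
                   settings = list(n_baseline = n_baseline,
                                   pseudocount = pseudocount,
                                   confidence_threshold =
                                       confidence_threshold,
                                   seed = seed)),
              class = "PowerReport")
}

#' @export
print.PowerReport <- function(x, ...) {
    cat(sprintf("Power simulation: %d individuals x 12 categories\n",
                x$n_per_category))
    print(x$summary, row.names = FALSE, digits = 4)
    invisible(x)
}

#' Gibbs-sampling variant of the hybrid classifier
#'
#' Propagates parental allele-frequency uncertainty: each sweep draws the
#' pool frequencies from their Beta posterior given the baseline counts
#' (Jeffreys prior matching the plug-in pseudocount) and recomputes the
#' category posterior; sweeps after burn-in are averaged and give credible
#' intervals for the per-category posterior probabilities. The plug-in
#' classifier (\code{\link{classifyHybrids}}) is the deterministic default;
#' this sampler is for interval reporting.
#'
#' @inheritParams classifyHybrids
#' @param n_sweeps post-burn-in sweeps (default 200).
#' @param burn_in discarded initial sweeps (default 20).
#' @param seed RNG seed.
#' @param ci credible-interval mass (default 0.9).
#' @return list: \code{posterior_mean}, \code{posterior_lower},
#'   \code{posterior_upper} (queries x 12), \code{map}, \code{confidence}.
#' @export
classifyHybridsGibbs <- function(panel, north = NULL, south = NULL,
                                 query = NULL, prior = NULL,
                                 pseudocount = 0.5, n_sweeps = 200,
                                 burn_in = 20, seed = NULL, ci = 0.9) {
    roles <- popRoles(panel)
    if (is.null(north)) north <- roles$parental_north
    if (is.null(south)) south <- roles$parental_south
    .checkPopulation(panel, north)
    .checkPopulation(panel, south)
    if (!is.null(seed)) set.seed(seed)
    tab <- categoryTable()
    if (is.null(prior)) prior <- rep(1 / nrow(tab), nrow(tab))
    prior <- prior / sum(prior)
    fN <- alleleCounts(panel, north)
    fS <- alleleCounts(panel, south)
    pl <- populations(panel)
    if (is.null(query))
        query <- sampleIDs(panel)[!pl %in% c(north, south)]
    G <- genotypes(panel)[query, , drop = FALSE]
    draws <- array(NA_real_, dim = c(length(query), nrow(tab), n_sweeps))
    for (s in seq_len(burn_in + n_sweeps)) {
        pN <- stats::rbeta(nrow(fN), fN$count_B + pseudocount,
                           fN$called_copies - fN$count_B + pseudocount)
        pS <- stats::rbeta(nrow(fS), fS$count_B + pseudocount,
                           fS$called_copies - fS$count_B + pseudocount)
        if (s > burn_in)
            draws[, , s - burn_in] <- .classifyCore(G, pN, pS, prior, tab)
    }
    pm <- apply(draws, c(1L, 2L), mean)
    lo <- apply(draws, c(1L, 2L), stats::quantile, probs = (1 - ci) / 2)
    hi <- apply(draws, c(1L, 2L), stats::quantile, probs = 1 - (1 - ci) / 2)
    dimnames(pm) <- dimnames(lo) <- dimnames(hi) <-
        list(query, tab$category)
    map <- tab$category[apply(pm, 1L, which.max)]
    list(posterior_mean = pm, posterior_lower = lo, posterior_upper = hi,
         map = map, confidence = apply(pm, 1L, max))
}
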