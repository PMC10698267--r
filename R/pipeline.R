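#' Run the full hybrid-zone analysis pipeline
#'
#' Executes the standard analysis order on a genotype panel — diversity
#' statistics, temporal pooling, pairwise F_ST, PCA with Tracy-Widom axis
#' tests, replicate admixture runs with Evanno delta-K, twelve-category
#' hybrid classification, and ABBA-BABA tests — writing every stage's
#' result table, a run log with seeds, and a plain-text summary to the
#' output directory. The pipeline is a pure function of (inputs, config,
#' seed): identical configs give byte-identical outputs.
#'
#' The configuration (YAML file or list) must contain exactly one of:
#' \describe{
#'   \item{input}{\code{genotypes} + \code{popmap} paths
#'     (\code{\link{readPanel}}).}
#'   \item{synthetic}{\code{n_loci}, \code{diagnosticity},
#'     \code{composition} (named category counts), optional
#'     \code{missing_rate} and \code{outgroup_n} (simulates a
#'     fixed-ancestral outgroup population \code{"OUT"}).}
#' }
#' plus optional \code{roles}, \code{alpha} (pooling, 0.05),
#' \code{n_perm} (10000), \code{K_range} (c(1, 5)),
#' \code{replicates} (10), \code{classifier} (\code{pseudocount}),
#' \code{dstat} (\code{P3}, \code{pairs} as list of 2-vectors),
#' \code{seed} (1), \code{out_dir}.
#'
#' @param config YAML path or config list.
#' @param out_dir output directory (overrides the config entry).
#' @return invisibly, a list with the panel and every stage result.
#' @export
runPipeline <- function(config, out_dir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(out_dir)) out_dir <- config$out_dir
    if (is.null(out_dir)) stop("no output directory given")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    has_input <- !is.null(config$input)
    has_syn <- !is.null(config$synthetic)
    if (has_input == has_syn)
        stop("config must contain exactly one of 'input' and 'synthetic'")
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
    n_perm <- if (is.null(config$n_perm)) 10000L else config$n_perm
    Kr <- if (is.null(config$K_range)) c(1L, 5L) else config$K_range
    n_rep <- if (is.null(config$replicates)) 10L else config$replicates
    pc <- if (is.null(config$classifier$pseudocount)) 0.5
          else config$classifier$pseudocount
    log_path <- file.path(out_dir, "run_log.txt")
    logf <- function(...) cat(sprintf(...), "\n", sep = "",
                              file = log_path, append = TRUE)
    cat("", file = log_path)
    logf("HybridPanel pipeline, package version %s",
         as.character(utils::packageVersion("HybridPanel")))
    logf("seed: %d", seed)

    stage <- function(name, expr) {
        logf("stage: %s", name)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    panel <- stage("load", {
        if (has_input) {
            readPanel(config$input$genotypes, config$input$popmap,
                      roles = if (is.null(config$roles)) list()
                              else config$roles)
        } else {
            syn <- config$synthetic
            freqs <- makeLineageFrequencies(
                n_loci = if (is.null(syn$n_loci)) 96L else syn$n_loci,
                diagnosticity = if (is.null(syn$diagnosticity)) 0.9
                                else syn$diagnosticity,
                seed = seed)
            comp <- unlist(syn$composition)
            p <- simulateHybridZonePanel(
                freqs, composition = comp,
                missing_rate = if (is.null(syn$missing_rate)) 0
                               else syn$missing_rate,
                seed = seed + 1L)
            if (!is.null(syn$outgroup_n) && syn$outgroup_n > 0) {
                og <- GenotypePanel(
                    matrix(0L, nrow = syn$outgroup_n, ncol = nrow(p),
                           dimnames = list(
                               paste0("OUT_", seq_len(syn$outgroup_n)),
                               locusIDs(p))),
                    population = rep("OUT", syn$outgroup_n))
                p <- combinePanels(p, og)
                roles <- popRoles(p)
                roles$outgroup <- "OUT"
                popRoles(p) <- roles
            }
            if (!is.null(config$roles))
                popRoles(p) <- config$roles
            p
        }
    })
    logf("panel: %d samples x %d loci", ncol(panel), nrow(panel))

    div <- stage("diversity", {
        d <- diversitySummary(panel)
        .writeTSV(d$table, file.path(out_dir, "diversity.tsv"))
        if (!is.null(d$anova))
            .writeTSV(d$anova, file.path(out_dir, "diversity_anova.tsv"))
        d
    })

    pool <- stage("temporal_pooling", {
        tp <- temporalPooling(panel, alpha = alpha, n_perm = n_perm,
                              seed = seed + 2L)
        .writeTSV(tp$report, file.path(out_dir, "temporal_pooling.tsv"))
        for (i in seq_len(nrow(tp$report)))
            logf("pooling %s: theta=%.4f p=%.4f pooled=%s",
                 tp$report$population[i], tp$report$theta[i],
                 tp$report$p[i], tp$report$pooled[i])
        tp
    })
    panel <- pool$panel

    fst <- stage("pairwise_fst", {
        f <- pairwiseFst(panel, n_perm = n_perm, seed = seed + 3L)
        writeFstTable(f, file.path(out_dir, "fst_table.tsv"))
        f
    })

    pca <- stage("pca", {
        p <- pcaPanel(panel)
        .writeTSV(data.frame(sample = rownames(p$coordinates),
                             population = p$population,
                             p$coordinates, check.names = FALSE),
                  file.path(out_dir, "pca_coordinates.tsv"))
        if (!is.null(p$tw))
            .writeTSV(cbind(p$tw,
                            variance_explained =
                                p$variance_explained[p$tw$axis]),
                      file.path(out_dir, "pca_eigen.tsv"))
        p
    })

    adm <- stage("admixture", {
        reps <- runAdmixtureReplicates(panel,
                                       K_range = seq(Kr[1L], Kr[2L]),
                                       n_replicates = n_rep, seed = seed)
        dk <- evannoDeltaK(reps$logliks)
        best <- reps$best[[as.character(dk$chosen_K)]]
        writeQMatrix(best, panel, file.path(out_dir, "qmatrix.tsv"))
        .writeTSV(dk$summary, file.path(out_dir, "evanno_deltaK.tsv"))
        .writeTSV(admixtureSummary(best, panel),
                  file.path(out_dir, "admixture_summary.tsv"))
        logf("Evanno chosen K = %d", dk$chosen_K)
        list(replicates = reps, deltaK = dk, best = best)
    })

    cls <- stage("classification", {
        cl <- classifyHybrids(panel, pseudocount = pc)
        writeClassification(cl, panel,
                            file.path(out_dir, "classification.tsv"))
        cl
    })

    dst <- stage("dstat", {
        if (is.null(config$dstat)) {
            logf("dstat: no trios configured, stage skipped")
            NULL
        } else {
            pairs <- do.call(rbind, lapply(config$dstat$pairs, function(x)
                data.frame(P1 = x[[1L]], P2 = x[[2L]])))
            tab <- dstatSweep(panel, P3 = config$dstat$P3, pairs = pairs)
            .writeTSV(tab, file.path(out_dir, "dstat.tsv"))
            tab
        }
    })

    stage("summary", {
        con <- file(file.path(out_dir, "summary.txt"), "w")
        on.exit(close(con))
        writeLines(sprintf("samples: %d  loci: %d", ncol(panel),
                           nrow(panel)), con)
        writeLines(sprintf("chosen K: %d", adm$deltaK$chosen_K), con)
        ve <- 100 * pca$variance_explained
        writeLines(sprintf("PC1/PC2 variance: %.1f%% / %.1f%%",
                           ve[1L], if (length(ve) > 1) ve[2L] else NA),
                   con)
        cl_tab <- table(cls$map)
        writeLines(paste("hybrid classes:",
                         paste(sprintf("%s=%d", names(cl_tab),
                                       as.integer(cl_tab)),
                               collapse = " ")), con)
        if (!is.null(dst))
            writeLines(sprintf(
                "significant D tests: %d of %d",
                sum(dst$p < alpha, na.rm = TRUE), nrow(dst)), con)
        NULL
    })

    invisible(list(panel = panel, diversity = div, pooling = pool,
                   fst = fst, pca = pca, admixture = adm,
                   classification = cls, dstat = dst,
                   out_dir = out_dir))
}

#' Render standard figures from a pipeline output directory
#'
#' Deterministic plots built only from the stage TSVs: a PCA scatter
#' (PC1 vs PC2 coloured by population), stacked per-individual ancestry
#' bars from the Q matrix, and per-population hybrid-class composition
#' bars from the classification table.
#'
#' @param out_dir a directory written by \code{\link{runPipeline}}.
#' @return invisibly, the paths of the PDFs written.
#' @export
makeFigures <- function(out_dir) {
    paths <- character(0)
    qp <- file.path(out_dir, "qmatrix.tsv")
    pp <- file.path(out_dir, "pca_coordinates.tsv")
    cp <- file.path(out_dir, "classification.tsv")
    if (file.exists(pp)) {
        d <- utils::read.delim(pp, check.names = FALSE)
        if (nrow(d) == 0L) stop("empty PCA table")
        f <- file.path(out_dir, "pca_scatter.pdf")
        grDevices::pdf(f, width = 6, height = 5)
        pops <- factor(d$population)
        graphics::plot(d$PC1, d$PC2, col = as.integer(pops),
                       pch = 19, xlab = "PC1", ylab = "PC2",
                       main = "PCA of genotype panel")
        graphics::legend("topright", legend = levels(pops),
                         col = seq_along(levels(pops)), pch = 19,
                         cex = 0.7)
        grDevices::dev.off()
        paths <- c(paths, f)
    }
    if (file.exists(qp)) {
        q <- utils::read.delim(qp, check.names = FALSE)
        if (nrow(q) == 0L) stop("empty Q matrix")
        qm <- t(as.matrix(q[, grep("^q", names(q)), drop = FALSE]))
        ord <- order(q$population, -qm[1L, ])
        f <- file.path(out_dir, "ancestry_bars.pdf")
        grDevices::pdf(f, width = 8, height = 3)
        graphics::barplot(qm[, ord], col = seq_len(nrow(qm)) + 1L,
                          border = NA, space = 0, names.arg = rep("",
                          ncol(qm)), ylab = "ancestry q",
                          main = "Admixture proportions")
        grDevices::dev.off()
        paths <- c(paths, f)
    }
    if (file.exists(cp)) {
        cl <- utils::read.delim(cp, check.names = FALSE)
        if (nrow(cl) == 0L) stop("empty classification table")
        tab <- table(cl$map, cl$population)
        f <- file.path(out_dir, "class_composition.pdf")
        grDevices::pdf(f, width = 6, height = 5)
        graphics::barplot(prop.table(tab, 2L),
                          col = seq_len(nrow(tab)) + 1L, border = NA,
                          legend.text = rownames(tab),
                          ylab = "proportion",
                          main = "Hybrid class composition")
        grDevices::dev.off()
        paths <- c(paths, f)
    }
    if (!length(paths)) stop("no stage tables found in ", out_dir)
    invisible(paths)
}
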