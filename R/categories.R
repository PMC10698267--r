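#' The twelve hybrid genotype-frequency categories
#'
#' Each category of a two-lineage hybrid zone is characterised, at any
#' unlinked locus, by the probability that a diploid's two gene copies
#' descend from the (north, north), (north, south) or (south, south) gene
#' pools. The twelve categories are the two parentals (WH = pure northern,
#' MI = pure southern), F1, F2, the first-generation backcrosses
#' (bWH = WH x F1, bMI = MI x F1) and the six second-generation backcrosses
#' (bWH x WH, bWH x MI, bWH x F1, bMI x MI, bMI x WH, bMI x F1).
#'
#' Triples are computed by gamete-origin recursion: a category with
#' origin-pair triple (p_NN, p_NS, p_SS) transmits a northern-pool gamete
#' with probability p_NN + p_NS/2, and an offspring's triple is the product
#' of its two parents' independent gamete-origin distributions.
#'
#' @return data.frame with columns \code{category}, \code{p_NN},
#'   \code{p_NS}, \code{p_SS} (each row sums to 1), in the fixed order
#'   WH, MI, F1, F2, bWH, bMI, bWHxWH, bWHxMI, bWHxF1, bMIxMI, bMIxWH,
#'   bMIxF1.
#' @examples
#' categoryTable()
#' @export
categoryTable <- function() {
    ped <- .categoryPedigrees()
    triples <- vapply(names(ped), .categoryTriple, numeric(3))
    data.frame(category = names(ped),
               p_NN = triples[1L, ], p_NS = triples[2L, ],
               p_SS = triples[3L, ], row.names = NULL)
}

# pedigree: each non-parental category as (mother, father)
.categoryPedigrees <- function() {
    list(
        WH       = NULL,
        MI       = NULL,
        F1       = c("WH",  "MI"),
        F2       = c("F1",  "F1"),
        bWH      = c("WH",  "F1"),
        bMI      = c("MI",  "F1"),
        bWHxWH   = c("bWH", "WH"),
        bWHxMI   = c("bWH", "MI"),
        bWHxF1   = c("bWH", "F1"),
        bMIxMI   = c("bMI", "MI"),
        bMIxWH   = c("bMI", "WH"),
        bMIxF1   = c("bMI", "F1"))
}

.categoryTriple <- function(category) {
    if (category == "WH") return(c(1, 0, 0))
    if (category == "MI") return(c(0, 0, 1))
    par <- .categoryPedigrees()[[category]]
    if (is.null(par)) stop("unknown category: ", category)
    gN <- vapply(par, function(p) {
        t <- .categoryTriple(p)
        t[1L] + t[2L] / 2
    }, numeric(1))
    c(gN[1L] * gN[2L],
      gN[1L] * (1 - gN[2L]) + (1 - gN[1L]) * gN[2L],
      (1 - gN[1L]) * (1 - gN[2L]))
}

.checkCategory <- function(category) {
    valid <- names(.categoryPedigrees())
    if (length(category) != 1L || !category %in% valid)
        stop("unknown category '", paste(category, collapse = ","),
             "'; valid: ", paste(valid, collapse = ", "))
    invisible(category)
}
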