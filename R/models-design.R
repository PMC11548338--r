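#' Build the fixed-effect and marker design matrices
#'
#' Assembles the model inputs `y = Q beta + Z gamma + e`: `Q` is an
#' intercept column bound to the (row-aligned) structure covariates, and
#' `Z` is the dosage matrix centered by twice the allele frequency of each
#' SNP. At training time the frequencies are computed from `g` itself; for
#' prediction rows pass the training fit's frozen frequencies through
#' `centerFreqs` so new individuals are centered on the training scale.
#'
#' @param g an imputed [MarkerMatrix-class].
#' @param covariates optional [StructureCovariates-class]; its rows must
#'   cover the individuals of `g` (extra rows, e.g. from joint estimation
#'   over training + breeding sets, are fine and are subset).
#' @param centerFreqs optional named per-SNP allele frequencies to center
#'   with (defaults to the frequencies observed in `g`).
#' @return list with `Q` (n x l fixed design, intercept first), `Z`
#'   (centered n x m marker matrix) and `centerFreqs`.
#' @export
buildDesign <- function(g, covariates = NULL, centerFreqs = NULL) {
    stopifnot(is(g, "MarkerMatrix"))
    .assertImputed(g, "buildDesign")
    ids <- individualIds(g)
    n <- length(ids)
    Q <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
    if (!is.null(covariates)) {
        stopifnot(is(covariates, "StructureCovariates"))
        missing <- setdiff(ids, individualIds(covariates))
        if (length(missing))
            stop("covariates missing for individual(s): ",
                 paste(head(missing, 5), collapse = ", "), call. = FALSE)
        Q <- cbind(Q, covariates@design[ids, , drop = FALSE])
    }
    qrQ <- qr(Q)
    if (qrQ$rank < ncol(Q)) {
        bad <- colnames(Q)[qrQ$pivot[(qrQ$rank + 1):ncol(Q)]]
        stop("fixed-effect design is rank-deficient; collinear column(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    if (is.null(centerFreqs)) {
        centerFreqs <- colMeans(g@dosage) / 2
    } else {
        if (!all(snpIds(g) %in% names(centerFreqs)))
            stop("centerFreqs does not cover all SNPs", call. = FALSE)
        centerFreqs <- centerFreqs[snpIds(g)]
    }
    Z <- sweep(g@dosage, 2, 2 * centerFreqs)
    list(Q = Q, Z = Z, centerFreqs = centerFreqs)
}

# Align a named phenotype vector to design rows, dropping missing values
# with a message; errors if the remaining system is degenerate.
.alignPhenotypes <- function(y, Q, Z) {
    ids <- rownames(Q)
    if (!is.null(names(y))) {
        if (!all(ids %in% names(y)))
            stop("phenotypes missing for some training individuals",
                 call. = FALSE)
        y <- y[ids]
    } else if (length(y) != nrow(Q)) {
        stop("'y' must be named by individual or match nrow(Q)",
             call. = FALSE)
    }
    keep <- !is.na(y)
    if (!all(keep))
        message(sum(!keep), " individual(s) with missing phenotype dropped")
    list(y = unname(y[keep]), Q = Q[keep, , drop = FALSE],
         Z = Z[keep, , drop = FALSE], ids = ids[keep])
}
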