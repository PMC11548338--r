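#' @import methods
#' @importFrom stats cor optimize prcomp rnorm runif rbinom rexp var sd
#'   quantile t.test setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib psapgp, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' MarkerMatrix: individuals-by-SNPs allele dosage matrix
#'
#' The universal genotype carrier of the package. Dosages count copies of the
#' alternate allele; raw data are coded 0/1/2 and missing calls are `NA`
#' (the missing mask). After mean imputation dosages may be real-valued but
#' always stay inside \[0, 2\]. Rows are individuals, columns SNPs, both with
#' unique identifiers. Per-SNP metadata (chromosome, 1-based position,
#' ref/alt alleles) is optional and may be all-`NA` when the source is a bare
#' dosage table.
#'
#' @slot dosage numeric matrix, individuals x SNPs, dimnames set, values in
#'   \[0, 2\] or `NA`.
#' @slot snpMeta data.frame with one row per SNP (columns `chrom`, `pos`,
#'   `ref`, `alt`).
#' @export
setClass("MarkerMatrix",
    slots = c(dosage = "matrix", snpMeta = "data.frame"))

setValidity("MarkerMatrix", function(object) {
    d <- object@dosage
    if (!is.numeric(d)) return("dosage must be a numeric matrix")
    ids <- rownames(d); snps <- colnames(d)
    if ((nrow(d) > 0 && is.null(ids)) || (ncol(d) > 0 && is.null(snps)))
        return("dosage must have individual (row) and SNP (column) names")
    if (anyDuplicated(ids)) return("duplicate individual ids")
    if (anyDuplicated(snps)) return("duplicate SNP ids")
    v <- d[!is.na(d)]
    if (length(v) && (any(v < 0) || any(v > 2)))
        return("non-missing dosages must lie in [0, 2]")
    if (nrow(object@snpMeta) != ncol(d))
        return("snpMeta must have one row per SNP")
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(object@snpMeta)))
        return("snpMeta must have columns chrom, pos, ref, alt")
    TRUE
})

.emptySnpMeta <- function(snps) {
    data.frame(chrom = rep(NA_character_, length(snps)),
               pos = rep(NA_integer_, length(snps)),
               ref = rep(NA_character_, length(snps)),
               alt = rep(NA_character_, length(snps)),
               row.names = snps, stringsAsFactors = FALSE)
}

#' Construct a MarkerMatrix
#'
#' @param dosage numeric matrix (individuals x SNPs) with dimnames; `NA`
#'   marks missing calls.
#' @param snpMeta optional data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt` and one row per SNP; defaults to all-`NA` metadata.
#' @return A [MarkerMatrix-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 2), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("s1", "s2")))
#' MarkerMatrix(d)
#' @export
MarkerMatrix <- function(dosage, snpMeta = NULL) {
    storage.mode(dosage) <- "double"
    if (is.null(snpMeta)) snpMeta <- .emptySnpMeta(colnames(dosage))
    rownames(snpMeta) <- colnames(dosage)
    new("MarkerMatrix", dosage = dosage, snpMeta = snpMeta)
}

#' KinshipMatrix: additive genomic relationship matrix
#'
#' Symmetric realized-relationship matrix over a named individual set,
#' partitionable into training/breeding blocks.
#'
#' @slot values symmetric numeric matrix with identical row/column names.
#' @export
setClass("KinshipMatrix", slots = c(values = "matrix"))

setValidity("KinshipMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("kinship matrix must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        return("row and column names must be identical individual ids")
    if (anyDuplicated(rownames(v))) return("duplicate individual ids")
    if (max(abs(v - t(v))) > 1e-10) return("kinship matrix must be symmetric")
    if (any(diag(v) <= 0)) return("kinship diagonal must be strictly positive")
    TRUE
})

#' @rdname KinshipMatrix-class
#' @param values symmetric numeric matrix with individual ids as dimnames.
#' @export
KinshipMatrix <- function(values) new("KinshipMatrix", values = values)

#' StructureCovariates: fixed-effect design from population structure
#'
#' An n x l real design matrix built from principal-component scores,
#' one-hot cluster memberships, or admixture ancestry proportions
#' (Q-matrix), used as fixed-effect covariates in the prediction models.
#'
#' @slot design numeric matrix, rownames are individual ids.
#' @slot kind one of `"pca"`, `"pam_onehot"`, `"qmatrix"`.
#' @slot meta list of method details (e.g. K, variance explained).
#' @export
setClass("StructureCovariates",
    slots = c(design = "matrix", kind = "character", meta = "list"))

setValidity("StructureCovariates", function(object) {
    if (is.null(rownames(object@design)))
        return("design must have individual ids as rownames")
    if (!object@kind %in% c("pca", "pam_onehot", "qmatrix"))
        return("kind must be one of pca, pam_onehot, qmatrix")
    if (object@kind == "qmatrix" && any(object@design < -1e-9))
        return("qmatrix covariates must be non-negative")
    TRUE
})

#' @rdname StructureCovariates-class
#' @param design numeric matrix with individual ids as rownames.
#' @param kind covariate kind string.
#' @param meta list of method metadata.
#' @export
StructureCovariates <- function(design, kind, meta = list())
    new("StructureCovariates", design = design, kind = kind, meta = meta)

#' AdmixtureFit: maximum-likelihood admixture model fit
#'
#' Result of the EM algorithm for the admixture likelihood: individual
#' ancestry proportions `Q` (rows sum to 1), ancestral allele frequencies
#' `F` (clipped away from 0/1), and the log-likelihood trace, which is
#' non-decreasing by the EM guarantee.
#'
#' @slot Q n x K ancestry proportion matrix (rownames individual ids).
#' @slot F K x m ancestral allele frequency matrix.
#' @slot logLik per-iteration log-likelihood trace.
#' @slot K number of ancestral populations.
#' @slot seed integer seed used for initialization.
#' @slot iterations number of EM iterations run.
#' @slot converged logical.
#' @export
setClass("AdmixtureFit",
    slots = c(Q = "matrix", F = "matrix", logLik = "numeric", K = "integer",
              seed = "integer", iterations = "integer", converged = "logical"))

setValidity("AdmixtureFit", function(object) {
    if (ncol(object@Q) != object@K) return("Q must have K columns")
    if (nrow(object@F) != object@K) return("F must have K rows")
    if (any(abs(rowSums(object@Q) - 1) > 1e-6)) return("Q rows must sum to 1")
    if (any(object@F <= 0) || any(object@F >= 1))
        return("F entries must lie strictly inside (0, 1)")
    TRUE
})

#' GSFit: fitted genomic-selection model
#'
#' Holds the state needed to predict new individuals: fixed-effect estimates
#' (the first element is always the intercept), marker effects (REML
#' backsolve for GBLUP, posterior means for BayesB), variance components,
#' the training-set allele frequencies frozen for centering, and sampler /
#' optimizer settings.
#'
#' @slot kind `"gblup"` or `"bayesb"`.
#' @slot beta named fixed-effect estimates (intercept first).
#' @slot markerEffects named marker-effect vector (length = SNP count).
#' @slot varG additive (polygenic) variance component.
#' @slot varE residual variance component.
#' @slot lambda varE/varG ratio at the REML optimum (GBLUP; `NA` for BayesB).
#' @slot centerFreqs training allele frequencies used to center Z.
#' @slot fitted fitted values on the training individuals.
#' @slot pip per-marker posterior inclusion probabilities (BayesB only).
#' @slot control list of fitting settings (and seed for BayesB).
#' @slot trainIds training individual ids.
#' @export
setClass("GSFit",
    slots = c(kind = "character", beta = "numeric", markerEffects = "numeric",
              varG = "numeric", varE = "numeric", lambda = "numeric",
              centerFreqs = "numeric", fitted = "numeric", pip = "numeric",
              control = "list", trainIds = "character"))

setValidity("GSFit", function(object) {
    if (!object@kind %in% c("gblup", "bayesb"))
        return("kind must be gblup or bayesb")
    if (length(object@varG) && (is.na(object@varG) || object@varG < 0))
        return("varG must be >= 0")
    if (length(object@varE) && (is.na(object@varE) || object@varE < 0))
        return("varE must be >= 0")
    TRUE
})

#' TrainingSelection: MeanRel-optimized training subset
#'
#' @slot ids selected training individual ids.
#' @slot scores named MeanRel score per training individual (all candidates).
#' @slot rule `"top_n"` or `"mean_cutoff"`.
#' @slot meta list (e.g. n requested, cutoff used).
#' @export
setClass("TrainingSelection",
    slots = c(ids = "character", scores = "numeric", rule = "character",
              meta = "list"))

setValidity("TrainingSelection", function(object) {
    if (!all(object@ids %in% names(object@scores)))
        return("selected ids must be a subset of scored training ids")
    if (any(!is.finite(object@scores))) return("scores must be finite")
    TRUE
})

#' PredictionResult: predictions for a named individual set
#'
#' @slot ids individual ids.
#' @slot predicted predicted phenotypic values.
#' @slot observed observed values (`NA` when unavailable).
#' @slot accuracy Pearson correlation between predicted and observed
#'   (`NA` when observations are absent).
#' @slot meta scenario metadata (model, covariate kind, training size, ...).
#' @export
setClass("PredictionResult",
    slots = c(ids = "character", predicted = "numeric", observed = "numeric",
              accuracy = "numeric", meta = "list"))

setValidity("PredictionResult", function(object) {
    n <- length(object@ids)
    if (length(object@predicted) != n || length(object@observed) != n)
        return("ids, predicted and observed must be aligned")
    if (!is.na(object@accuracy) &&
        (object@accuracy < -1 - 1e-12 || object@accuracy > 1 + 1e-12))
        return("accuracy must lie in [-1, 1]")
    TRUE
})
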