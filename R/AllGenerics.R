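#' Individual identifiers
#' @param x an object carrying a named individual set.
#' @return character vector of individual ids.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' SNP identifiers
#' @param x an object carrying a SNP set.
#' @return character vector of SNP ids.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Dosage matrix accessor
#' @param x a [MarkerMatrix-class].
#' @return numeric individuals x SNPs matrix (`NA` = missing call).
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' SNP metadata accessor
#' @param x a [MarkerMatrix-class].
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
setGeneric("snpMeta", function(x) standardGeneric("snpMeta"))

#' Kinship values accessor
#' @param x a [KinshipMatrix-class].
#' @return symmetric numeric matrix.
#' @export
setGeneric("kinValues", function(x) standardGeneric("kinValues"))

#' Fixed-effect design accessor
#' @param x a [StructureCovariates-class].
#' @return numeric design matrix.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' Ancestry proportion (Q) matrix accessor
#' @param x an [AdmixtureFit-class].
#' @return n x K matrix with rows summing to 1.
#' @export
setGeneric("qMatrix", function(x) standardGeneric("qMatrix"))

#' Prediction accuracy accessor
#' @param x a [PredictionResult-class].
#' @return Pearson correlation (or `NA`).
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' Selected training ids accessor
#' @param x a [TrainingSelection-class].
#' @return character vector of selected ids.
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))

#' Predict phenotypes for new individuals from a fitted GS model
#'
#' Dispatches on the fitted model kind: for GBLUP the prediction is
#' `Q_new beta + Z_new gamma`; for BayesB the posterior means are used
#' (the intercept is the first element of `beta`).
#'
#' @param object a [GSFit-class].
#' @param Qnew fixed-effect design for the new individuals (intercept
#'   column first, same columns as at fit time).
#' @param Znew centered marker matrix for the new individuals; must be
#'   centered with the fit's frozen training allele frequencies (see
#'   [buildDesign()] with `centerFreqs = centerFreqs(fit)`).
#' @return named numeric vector of predicted values.
#' @export
setGeneric("predictGS", function(object, Qnew, Znew) standardGeneric("predictGS"))
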