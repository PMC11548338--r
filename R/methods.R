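#' @describeIn MarkerMatrix-class individual ids
#' @param x object.
#' @export
setMethod("individualIds", "MarkerMatrix", function(x) rownames(x@dosage))

#' @describeIn MarkerMatrix-class SNP ids
#' @export
setMethod("snpIds", "MarkerMatrix", function(x) colnames(x@dosage))

#' @describeIn MarkerMatrix-class dosage matrix
#' @export
setMethod("dosage", "MarkerMatrix", function(x) x@dosage)

#' @describeIn MarkerMatrix-class SNP metadata
#' @export
setMethod("snpMeta", "MarkerMatrix", function(x) x@snpMeta)

#' @describeIn MarkerMatrix-class dimensions (individuals, SNPs)
#' @export
setMethod("dim", "MarkerMatrix", function(x) dim(x@dosage))

#' Subset a MarkerMatrix
#'
#' `x[i, j]` keeps individuals `i` and SNPs `j` (character, integer or
#' logical indices), preserving SNP metadata.
#'
#' @param x a [MarkerMatrix-class].
#' @param i individual index.
#' @param j SNP index.
#' @param ... ignored.
#' @param drop ignored; result is always a MarkerMatrix.
#' @export
setMethod("[", "MarkerMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@dosage))
    if (missing(j)) j <- seq_len(ncol(x@dosage))
    MarkerMatrix(x@dosage[i, j, drop = FALSE],
                 x@snpMeta[j, , drop = FALSE])
})

setMethod("show", "MarkerMatrix", function(object) {
    d <- object@dosage
    nm <- sum(is.na(d))
    cat(sprintf("MarkerMatrix: %d individuals x %d SNPs (%d missing calls, %.2f%%)\n",
                nrow(d), ncol(d), nm, 100 * nm / max(1, length(d))))
    cat("  individuals:", .abbrevIds(rownames(d)), "\n")
    cat("  SNPs:       ", .abbrevIds(colnames(d)), "\n")
})

.abbrevIds <- function(ids) {
    if (length(ids) <= 4) return(paste(ids, collapse = ", "))
    paste0(paste(head(ids, 3), collapse = ", "), ", ..., ", ids[length(ids)])
}

#' @describeIn KinshipMatrix-class individual ids
#' @param x object.
#' @export
setMethod("individualIds", "KinshipMatrix", function(x) rownames(x@values))

#' @describeIn KinshipMatrix-class kinship values
#' @export
setMethod("kinValues", "KinshipMatrix", function(x) x@values)

#' @describeIn KinshipMatrix-class dimensions
#' @export
setMethod("dim", "KinshipMatrix", function(x) dim(x@values))

setMethod("show", "KinshipMatrix", function(object) {
    v <- object@values
    cat(sprintf("KinshipMatrix: %d individuals\n", nrow(v)))
    cat(sprintf("  diagonal mean %.3f; off-diagonal range [%.3f, %.3f]\n",
                mean(diag(v)),
                min(v[upper.tri(v)]), max(v[upper.tri(v)])))
})

#' @describeIn StructureCovariates-class individual ids
#' @param x object.
#' @export
setMethod("individualIds", "StructureCovariates", function(x) rownames(x@design))

#' @describeIn StructureCovariates-class design matrix
#' @export
setMethod("designMatrix", "StructureCovariates", function(x) x@design)

setMethod("show", "StructureCovariates", function(object) {
    cat(sprintf("StructureCovariates (%s): %d individuals x %d columns\n",
                object@kind, nrow(object@design), ncol(object@design)))
})

#' @describeIn AdmixtureFit-class ancestry proportions
#' @param x object.
#' @export
setMethod("qMatrix", "AdmixtureFit", function(x) x@Q)

setMethod("show", "AdmixtureFit", function(object) {
    cat(sprintf("AdmixtureFit: K = %d, n = %d, m = %d\n",
                object@K, nrow(object@Q), ncol(object@F)))
    cat(sprintf("  logLik %.2f after %d iterations (%s)\n",
                object@logLik[length(object@logLik)], object@iterations,
                if (object@converged) "converged" else "max iterations reached"))
})

setMethod("show", "GSFit", function(object) {
    cat(sprintf("GSFit (%s): %d training individuals, %d markers\n",
                object@kind, length(object@trainIds),
                length(object@markerEffects)))
    if (object@kind == "gblup")
        cat(sprintf("  varG = %.4g, varE = %.4g, lambda = %.4g, h2 = %.3f\n",
                    object@varG, object@varE, object@lambda,
                    object@varG / (object@varG + object@varE)))
    else
        cat(sprintf("  posterior mean varE = %.4g, mean inclusion = %.3f\n",
                    object@varE, mean(object@pip)))
})

#' @describeIn TrainingSelection-class selected ids
#' @param x object.
#' @export
setMethod("selectedIds", "TrainingSelection", function(x) x@ids)

setMethod("show", "TrainingSelection", function(object) {
    cat(sprintf("TrainingSelection (%s): %d of %d training individuals\n",
                object@rule, length(object@ids), length(object@scores)))
})

#' @describeIn PredictionResult-class Pearson accuracy (or NA)
#' @param x object.
#' @export
setMethod("accuracy", "PredictionResult", function(x) x@accuracy)

#' @describeIn PredictionResult-class individual ids
#' @export
setMethod("individualIds", "PredictionResult", function(x) x@ids)

setMethod("show", "PredictionResult", function(object) {
    cat(sprintf("PredictionResult: %d individuals", length(object@ids)))
    if (!is.na(object@accuracy))
        cat(sprintf("; Pearson accuracy = %.3f", object@accuracy))
    cat("\n")
    if (length(object@meta))
        cat("  scenario:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                                 sep = "=", collapse = ", "), "\n")
})

#' Coerce a PredictionResult to a data.frame
#' @param x a [PredictionResult-class].
#' @param ... ignored.
#' @return data.frame with columns id, predicted, observed.
#' @export
as.data.frame.PredictionResult <- function(x, ...) {
    data.frame(id = x@ids, predicted = x@predicted, observed = x@observed,
               stringsAsFactors = FALSE)
}
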