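# Plain-text serialization of covariates and fitted models, used by the
# command-line interface so each pipeline stage can feed the next.

#' Write / read structure covariates as TSV with a JSON sidecar
#'
#' TSV columns: `id` plus one column per covariate; the `<path>.json`
#' sidecar records the covariate kind and method metadata.
#'
#' @param cov a [StructureCovariates-class].
#' @param path TSV path.
#' @return `writeCovariates`: the path invisibly; `readCovariates`: a
#'   [StructureCovariates-class].
#' @export
writeCovariates <- function(cov, path) {
    tab <- data.frame(id = individualIds(cov), cov@design,
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(c(list(kind = cov@kind), cov@meta),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeCovariates
#' @export
readCovariates <- function(path) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    design <- as.matrix(tab[, -1, drop = FALSE])
    rownames(design) <- as.character(tab[[1]])
    side <- paste0(path, ".json")
    kind <- "pca"; meta <- list()
    if (file.exists(side)) {
        info <- jsonlite::read_json(side, simplifyVector = TRUE)
        kind <- info$kind
        meta <- info[setdiff(names(info), "kind")]
    }
    StructureCovariates(design, kind, meta)
}

#' Write / read a fitted GS model
#'
#' Scalars, settings and fixed effects go to `<prefix>.json`; marker
#' effects, posterior inclusion probabilities and the frozen centering
#' frequencies go to `<prefix>_markers.tsv`. Values are written at full
#' precision, so a round trip reproduces predictions exactly.
#'
#' @param fit a [GSFit-class].
#' @param prefix output path prefix.
#' @return `writeGSFit`: the prefix invisibly; `readGSFit`: a
#'   [GSFit-class].
#' @export
writeGSFit <- function(fit, prefix) {
    stopifnot(is(fit, "GSFit"))
    head <- list(kind = fit@kind, beta = as.list(fit@beta),
                 varG = if (length(fit@varG)) fit@varG else NULL,
                 varE = fit@varE,
                 lambda = if (length(fit@lambda)) fit@lambda else NULL,
                 control = fit@control[!vapply(fit@control, is.function,
                                               logical(1))],
                 trainIds = fit@trainIds)
    jsonlite::write_json(head, paste0(prefix, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    mk <- data.frame(snp = names(fit@markerEffects),
                     effect = unname(fit@markerEffects),
                     centerFreq = unname(fit@centerFreqs[names(fit@markerEffects)]),
                     pip = if (length(fit@pip))
                               unname(fit@pip[names(fit@markerEffects)])
                           else NA_real_)
    write.table(format(mk, digits = 17, scientific = TRUE, trim = TRUE),
                paste0(prefix, "_markers.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(prefix)
}

#' @rdname writeGSFit
#' @export
readGSFit <- function(prefix) {
    head <- jsonlite::read_json(paste0(prefix, ".json"),
                                simplifyVector = TRUE)
    mk <- read.delim(paste0(prefix, "_markers.tsv"),
                     stringsAsFactors = FALSE)
    kind <- head$kind
    new("GSFit", kind = kind,
        beta = unlist(head$beta),
        markerEffects = setNames(as.numeric(mk$effect), mk$snp),
        varG = if (kind == "gblup") as.numeric(head$varG) else numeric(),
        varE = as.numeric(head$varE),
        lambda = if (kind == "gblup") as.numeric(head$lambda) else numeric(),
        centerFreqs = setNames(as.numeric(mk$centerFreq), mk$snp),
        fitted = numeric(),
        pip = if (kind == "bayesb") setNames(as.numeric(mk$pip), mk$snp)
              else numeric(),
        control = as.list(head$control),
        trainIds = as.character(head$trainIds))
}
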