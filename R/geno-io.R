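#' Read genotypes from VCF or a dosage TSV
#'
#' VCF input is decoded to alternate-allele dosages: `0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`; `./.` and half-calls become missing. Multi-allelic records
#' are skipped with a message reporting the count. The dosage-TSV format is
#' a tab-separated table with header `id<TAB>snp1<TAB>...`, one row per
#' individual and `NA` for missing calls (the format written by
#' [writeGenotypes()]).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [MarkerMatrix-class]. VCF input fills the SNP metadata
#'   (chrom, 1-based pos, ref/alt); TSV input leaves it `NA`.
#' @seealso [writeGenotypes()], [imputeMissing()], [filterMAF()]
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
            "vcf" else "tsv"
    if (format == "vcf") .readVcf(path) else .readDosageTsv(path)
}

.readVcf <- function(path) {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
        message(sum(multi), " multi-allelic record(s) skipped")
    keep <- which(!multi)
    if (!length(keep)) stop("no biallelic records in ", path, call. = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]
    snps <- fix[, "ID"]
    auto <- is.na(snps) | snps == "."
    snps[auto] <- paste0(fix[auto, "CHROM"], "_", fix[auto, "POS"])
    if (anyDuplicated(snps)) stop("duplicate SNP ids in VCF", call. = FALSE)
    if (anyDuplicated(colnames(gt)))
        stop("duplicate sample ids in VCF", call. = FALSE)
    # strip phasing, count alt alleles; any '.' in the call -> missing
    alleles1 <- substr(gsub("\\|", "/", gt), 1, 1)
    alleles2 <- substring(gsub("\\|", "/", gt), 3, 3)
    d <- suppressWarnings(as.numeric(alleles1) + as.numeric(alleles2))
    d <- matrix(d, nrow = nrow(gt),
                dimnames = list(snps, colnames(gt)))
    if (any(d[!is.na(d)] > 2))
        stop("non-biallelic genotype codes encountered", call. = FALSE)
    meta <- data.frame(chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       row.names = snps, stringsAsFactors = FALSE)
    MarkerMatrix(t(d), meta)
}

.readDosageTsv <- function(path) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "id")
        stop("malformed dosage-TSV header (expected first column 'id') in ",
             path, call. = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) stop("duplicate individual ids in ", path,
                                 call. = FALSE)
    if (anyDuplicated(names(tab)[-1]))
        stop("duplicate SNP ids in ", path, call. = FALSE)
    d <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(d) <- "double"
    rownames(d) <- ids
    MarkerMatrix(d)
}

#' Write genotypes as a dosage TSV
#'
#' Lossless for 0/1/2 (+ `NA`) dosage matrices: [readGenotypes()] on the
#' written file reproduces the matrix exactly.
#'
#' @param g a [MarkerMatrix-class] with at least one individual and one SNP.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenotypes <- function(g, path) {
    stopifnot(is(g, "MarkerMatrix"))
    if (ncol(g@dosage) == 0 || nrow(g@dosage) == 0)
        stop("refusing to write an empty MarkerMatrix", call. = FALSE)
    tab <- data.frame(id = rownames(g@dosage), g@dosage,
                      check.names = FALSE, stringsAsFactors = FALSE)
    ok <- tryCatch(write.table(tab, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), error = function(e) e)
    if (inherits(ok, "error"))
        stop("cannot write '", path, "': ", conditionMessage(ok),
             call. = FALSE)
    invisible(path)
}

#' Read a hybrid cross table
#'
#' CSV with columns `hybrid`, `mother`, `father`; hybrid ids must be unique.
#'
#' @param path file path.
#' @return data.frame with columns hybrid, mother, father.
#' @export
readCrossTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    makeCrossTable(tab$hybrid, tab$mother, tab$father)
}

#' Construct a validated cross table
#'
#' @param hybrid,mother,father character vectors of equal length.
#' @return data.frame mapping each hybrid to its parents.
#' @export
makeCrossTable <- function(hybrid, mother, father) {
    if (is.null(hybrid) || is.null(mother) || is.null(father))
        stop("cross table needs hybrid, mother and father columns",
             call. = FALSE)
    if (anyDuplicated(hybrid)) stop("duplicate hybrid ids", call. = FALSE)
    data.frame(hybrid = as.character(hybrid), mother = as.character(mother),
               father = as.character(father), stringsAsFactors = FALSE)
}

#' Read a phenotype table
#'
#' CSV with columns `id`, `trait`, `value` holding one (typically
#' environment-adjusted BLUP) value per individual and trait.
#'
#' @param path file path.
#' @return long data.frame with columns id, trait, value.
#' @export
readPhenotypes <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "trait", "value") %in% names(tab)))
        stop("phenotype table needs columns id, trait, value", call. = FALSE)
    if (anyDuplicated(tab[, c("id", "trait")]))
        stop("one value per (individual, trait) is required", call. = FALSE)
    tab$value <- as.numeric(tab$value)
    tab[, c("id", "trait", "value")]
}

#' Extract one trait as a named numeric vector
#'
#' @param pheno long phenotype data.frame (id, trait, value).
#' @param trait trait name.
#' @param ids optional individual ids to align to (missing ids get `NA`).
#' @return named numeric vector.
#' @export
phenotypeVector <- function(pheno, trait, ids = NULL) {
    sub <- pheno[pheno$trait == trait, ]
    if (!nrow(sub)) stop("trait '", trait, "' not found", call. = FALSE)
    y <- setNames(sub$value, sub$id)
    if (!is.null(ids)) y <- setNames(y[ids], ids)
    y
}

#' Infer F1 hybrid genotypes from inbred parents
#'
#' For homozygous parents the F1 dosage at a locus is forced by Mendelian
#' inheritance: half the parental dosage sum (0x0 -> 0, 0x2 -> 1, 2x2 -> 2).
#' If either parental call is heterozygous (dosage 1) or missing, the hybrid
#' call is ambiguous and is set missing for downstream imputation.
#'
#' @param parents [MarkerMatrix-class] of the parental inbred lines.
#' @param crosses cross table (see [makeCrossTable()]).
#' @return [MarkerMatrix-class] over the hybrid ids, same SNP set/metadata
#'   as `parents`.
#' @export
inferHybridGenotypes <- function(parents, crosses) {
    stopifnot(is(parents, "MarkerMatrix"))
    ids <- individualIds(parents)
    missingPar <- setdiff(unique(c(crosses$mother, crosses$father)), ids)
    if (length(missingPar))
        stop("unknown parent id(s): ", paste(missingPar, collapse = ", "),
             call. = FALSE)
    M <- parents@dosage[crosses$mother, , drop = FALSE]
    P <- parents@dosage[crosses$father, , drop = FALSE]
    H <- (M + P) / 2
    bad <- !((M == 0 | M == 2) & (P == 0 | P == 2))
    H[is.na(bad) | bad] <- NA_real_
    rownames(H) <- crosses$hybrid
    MarkerMatrix(H, parents@snpMeta)
}

#' Impute missing dosage calls per SNP
#'
#' `mean` replaces missing calls with the per-SNP mean dosage (real-valued;
#' neutral under the model-side centering); `mode` uses the most frequent
#' dosage class with ties resolved toward the lower dosage.
#'
#' @param g a [MarkerMatrix-class].
#' @param method `"mean"` or `"mode"`.
#' @return imputed [MarkerMatrix-class] with an empty missing mask.
#' @export
imputeMissing <- function(g, method = c("mean", "mode")) {
    method <- match.arg(method)
    d <- g@dosage
    if (!anyNA(d)) return(g)
    nObs <- colSums(!is.na(d))
    if (any(nObs == 0))
        stop("SNP(s) with no observed calls: ",
             paste(colnames(d)[nObs == 0], collapse = ", "), call. = FALSE)
    fill <- if (method == "mean") {
        colMeans(d, na.rm = TRUE)
    } else {
        apply(d, 2, function(col) {
            counts <- c(sum(col == 0, na.rm = TRUE),
                        sum(col == 1, na.rm = TRUE),
                        sum(col == 2, na.rm = TRUE))
            c(0, 1, 2)[which.max(counts)]   # which.max takes the first
        })
    }
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- fill[idx[, 2]]
    MarkerMatrix(d, g@snpMeta)
}

#' Filter SNPs on minor allele frequency
#'
#' MAF = min(p, 1 - p) with p the mean dosage over non-missing calls
#' divided by 2. SNPs with MAF below the threshold are dropped; column
#' order is preserved, so the operation is idempotent.
#'
#' @param g a [MarkerMatrix-class].
#' @param threshold MAF threshold in \[0, 0.5\]; default 0.05.
#' @return filtered [MarkerMatrix-class].
#' @export
filterMAF <- function(g, threshold = 0.05) {
    if (!is.numeric(threshold) || length(threshold) != 1 ||
        threshold < 0 || threshold > 0.5)
        stop("'threshold' must lie in [0, 0.5]", call. = FALSE)
    p <- colMeans(g@dosage, na.rm = TRUE) / 2
    keep <- pmin(p, 1 - p) >= threshold
    g[, keep]
}

#' Intersect and harmonize the SNP sets of two MarkerMatrices
#'
#' SNPs are matched on (chromosome, position) when both matrices carry
#' complete metadata, otherwise on SNP id. At matched positions, identical
#' ref/alt pairs are kept as-is; swapped ref/alt pairs are harmonized by
#' flipping the second matrix's dosages `d -> 2 - d`; any other allele
#' combination is treated as non-matching and dropped. Both outputs carry
#' the identical ordered SNP set (first matrix's order).
#'
#' @param a,b [MarkerMatrix-class] objects.
#' @return list with elements `a` and `b`, reduced to the shared SNPs.
#' @export
intersectSnps <- function(a, b) {
    stopifnot(is(a, "MarkerMatrix"), is(b, "MarkerMatrix"))
    metaOk <- function(m) !anyNA(m@snpMeta$chrom) && !anyNA(m@snpMeta$pos)
    byPos <- metaOk(a) && metaOk(b)
    if (byPos) {
        keyA <- paste(a@snpMeta$chrom, a@snpMeta$pos)
        keyB <- paste(b@snpMeta$chrom, b@snpMeta$pos)
    } else {
        keyA <- snpIds(a); keyB <- snpIds(b)
    }
    idxB <- match(keyA, keyB)
    sel <- which(!is.na(idxB))
    flip <- logical(length(sel))
    if (byPos && length(sel)) {
        ra <- a@snpMeta$ref[sel]; aa <- a@snpMeta$alt[sel]
        rb <- b@snpMeta$ref[idxB[sel]]; ab <- b@snpMeta$alt[idxB[sel]]
        alleleOk <- !is.na(ra) & !is.na(rb)
        same <- alleleOk & ra == rb & aa == ab
        swapped <- alleleOk & ra == ab & aa == rb & !same
        keep <- !alleleOk | same | swapped
        flip <- swapped[keep]
        sel <- sel[keep]
    }
    if (!length(sel)) stop("no shared SNPs between the two matrices",
                           call. = FALSE)
    a2 <- a[, sel]
    b2 <- b[, idxB[sel]]
    if (any(flip)) {
        d <- b2@dosage
        d[, flip] <- 2 - d[, flip]
        meta <- b2@snpMeta
        meta$ref[flip] <- b2@snpMeta$alt[flip]
        meta$alt[flip] <- b2@snpMeta$ref[flip]
        colnames(d) <- snpIds(a2)
        rownames(meta) <- snpIds(a2)
        b2 <- MarkerMatrix(d, meta)
    } else {
        d <- b2@dosage
        colnames(d) <- snpIds(a2)
        meta <- b2@snpMeta
        rownames(meta) <- snpIds(a2)
        b2 <- MarkerMatrix(d, meta)
    }
    list(a = a2, b = b2)
}
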