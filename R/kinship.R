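#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' K = W W' / (2 * sum_j p_j (1 - p_j)), where W is the dosage matrix with
#' each column centered by twice its observed allele frequency p_j. The
#' frequencies are computed over all individuals in `g`, so when the matrix
#' spans both the training and breeding populations the result is the joint
#' relationship matrix those populations share. Row sums of W are zero by
#' construction, so K has zero row sums, and K is positive semi-definite.
#'
#' @param g an imputed [MarkerMatrix-class] with at least 2 SNPs.
#' @return a [KinshipMatrix-class].
#' @export
computeKinship <- function(g) {
    stopifnot(is(g, "MarkerMatrix"))
    .assertImputed(g, "computeKinship")
    d <- g@dosage
    if (ncol(d) < 2) stop("need at least 2 SNPs", call. = FALSE)
    p <- colMeans(d) / 2
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0)
        stop("all SNPs are monomorphic: kinship denominator is zero",
             call. = FALSE)
    W <- sweep(d, 2, 2 * p)
    K <- tcrossprod(W) / denom
    K <- (K + t(K)) / 2
    KinshipMatrix(K)
}

#' Partition a kinship matrix into training/breeding blocks
#'
#' Splits K into the 2x2 block form K = \[K11 K12; K21 K22\], with K11 the
#' training-training block, K22 the breeding-breeding block and K12 = K21'
#' the between-population relationships.
#'
#' @param k a [KinshipMatrix-class].
#' @param trainingIds,breedingIds disjoint id sets contained in `k`.
#' @return list with matrices `K11`, `K12`, `K21`, `K22`.
#' @export
partitionBlocks <- function(k, trainingIds, breedingIds) {
    stopifnot(is(k, "KinshipMatrix"))
    if (length(intersect(trainingIds, breedingIds)))
        stop("training and breeding id sets overlap", call. = FALSE)
    ids <- individualIds(k)
    unknown <- setdiff(c(trainingIds, breedingIds), ids)
    if (length(unknown))
        stop("ids not in kinship matrix: ", paste(unknown, collapse = ", "),
             call. = FALSE)
    v <- k@values
    list(K11 = v[trainingIds, trainingIds, drop = FALSE],
         K12 = v[trainingIds, breedingIds, drop = FALSE],
         K21 = v[breedingIds, trainingIds, drop = FALSE],
         K22 = v[breedingIds, breedingIds, drop = FALSE])
}

#' MeanRel: mean relationship of each training individual to the breeding set
#'
#' For each training individual, the average additive relationship to all
#' individuals of the breeding population, i.e. the row means of the K12
#' block. Used to rank training candidates by closeness to the prediction
#' target.
#'
#' @param k a [KinshipMatrix-class] spanning both populations.
#' @param trainingIds,breedingIds disjoint id sets.
#' @return named numeric vector of scores over `trainingIds`.
#' @export
meanRel <- function(k, trainingIds, breedingIds) {
    if (!length(breedingIds)) stop("empty breeding set", call. = FALSE)
    blocks <- partitionBlocks(k, trainingIds, breedingIds)
    rowMeans(blocks$K12)
}

#' Select an optimized training set from MeanRel scores
#'
#' `top_n` keeps the `n` highest-scoring training individuals (ties broken
#' by ascending id, so selection is deterministic). `mean_cutoff` keeps all
#' individuals whose score is strictly greater than the mean score, a
#' trait-independent rule for standardizing training-set size.
#'
#' @param scores named numeric vector (e.g. from [meanRel()]).
#' @param rule `"top_n"` or `"mean_cutoff"`.
#' @param n number to keep under `top_n`.
#' @return a [TrainingSelection-class].
#' @export
selectTraining <- function(scores, rule = c("top_n", "mean_cutoff"), n = NULL) {
    rule <- match.arg(rule)
    if (is.null(names(scores)) || anyDuplicated(names(scores)))
        stop("'scores' must be uniquely named", call. = FALSE)
    if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
    if (rule == "top_n") {
        n <- .assertScalarCount(n, "n")
        if (n > length(scores))
            stop("n exceeds the number of training candidates", call. = FALSE)
        ord <- order(-scores, names(scores))
        ids <- names(scores)[ord[seq_len(n)]]
        meta <- list(n = n)
    } else {
        cutoff <- mean(scores)
        ids <- names(scores)[scores > cutoff]
        meta <- list(cutoff = cutoff)
    }
    new("TrainingSelection", ids = ids, scores = scores, rule = rule,
        meta = meta)
}

#' Write / read a kinship matrix as TSV
#'
#' Square tab-separated table with ids as header row and first column.
#'
#' @param k a [KinshipMatrix-class].
#' @param path file path.
#' @return `writeKinship`: the path invisibly; `readKinship`: a
#'   [KinshipMatrix-class].
#' @export
writeKinship <- function(k, path) {
    tab <- data.frame(id = individualIds(k), k@values, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeKinship
#' @export
readKinship <- function(path) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    v <- as.matrix(tab[, -1, drop = FALSE])
    rownames(v) <- as.character(tab[[1]])
    v <- (v + t(v)) / 2   # absorb round-tripping noise below write precision
    KinshipMatrix(v)
}

#' Write a training selection as TSV plus a JSON sidecar
#'
#' The TSV lists every scored training individual (id, score, selected
#' flag); the sidecar records the selection rule and its parameters.
#'
#' @param sel a [TrainingSelection-class].
#' @param path TSV path (`<path>.json` gets the sidecar).
#' @return the path, invisibly.
#' @export
writeTrainingSelection <- function(sel, path) {
    tab <- data.frame(id = names(sel@scores), score = unname(sel@scores),
                      selected = names(sel@scores) %in% sel@ids)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(c(list(rule = sel@rule), sel@meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}
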