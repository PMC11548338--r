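#' Principal-component covariates from genotypes
#'
#' PCA of the column-centered (not standardized) dosage matrix. Scores of
#' the leading components, ordered by decreasing explained variance, become
#' fixed-effect covariates. A sign convention is applied per component (the
#' largest-magnitude loading is made positive) so results do not depend on
#' the eigensolver's arbitrary sign choice.
#'
#' @param g an imputed [MarkerMatrix-class].
#' @param nComponents number of components; default 6.
#' @return [StructureCovariates-class] of kind `"pca"`; `meta$varExplained`
#'   holds the per-component variance fractions.
#' @export
pcaCovariates <- function(g, nComponents = 6) {
    stopifnot(is(g, "MarkerMatrix"))
    .assertImputed(g, "pcaCovariates")
    nComponents <- .assertScalarCount(nComponents, "nComponents")
    d <- g@dosage
    if (nComponents >= min(dim(d)))
        stop("nComponents must be smaller than min(individuals, SNPs)",
             call. = FALSE)
    totVar <- sum(apply(d, 2, var))
    if (totVar == 0)
        stop("zero genotype variance: all individuals identical",
             call. = FALSE)
    pc <- prcomp(d, center = TRUE, scale. = FALSE, rank. = nComponents)
    scores <- pc$x[, seq_len(nComponents), drop = FALSE]
    for (j in seq_len(ncol(scores))) {
        load <- pc$rotation[, j]
        if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
    }
    rownames(scores) <- individualIds(g)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    StructureCovariates(scores, "pca",
                        meta = list(nComponents = nComponents,
                                    varExplained = ve[seq_len(nComponents)]))
}

# Dissimilarity for clustering: from a kinship matrix, d(i,j) = max(K) -
# K(i,j) with zero self-dissimilarity; a dist object or symmetric matrix
# passes through.
.asDissimilarity <- function(x) {
    if (is(x, "KinshipMatrix")) {
        v <- x@values
        d <- max(v) - v
        diag(d) <- 0
        stats::as.dist(d)
    } else if (inherits(x, "dist")) {
        x
    } else if (is.matrix(x)) {
        if (any(x < 0) || max(abs(x - t(x))) > 1e-8 || any(diag(x) != 0))
            stop("dissimilarity matrix must be symmetric, non-negative, zero-diagonal",
                 call. = FALSE)
        stats::as.dist(x)
    } else stop("expected a KinshipMatrix, dist or symmetric matrix",
                call. = FALSE)
}

#' Cluster individuals by partitioning around medoids (PAM)
#'
#' Full PAM (greedy BUILD initialization followed by SWAP local search until
#' no single-medoid swap improves the total dissimilarity). A
#' [KinshipMatrix-class] input is converted to dissimilarities via
#' `d(i,j) = max(K) - K(i,j)` so clustering and MeanRel share one kinship;
#' a `dist` or symmetric zero-diagonal matrix is used as-is.
#'
#' @param x [KinshipMatrix-class], `dist`, or symmetric dissimilarity matrix.
#' @param nClusters number of clusters (medoids).
#' @return list with `labels` (named integer vector in 1..nClusters),
#'   `medoids` (ids), `cost` (total dissimilarity to assigned medoids) and
#'   `buildCost` (total cost after the BUILD phase).
#' @export
pamCluster <- function(x, nClusters) {
    d <- .asDissimilarity(x)
    n <- attr(d, "Size")
    nClusters <- .assertScalarCount(nClusters, "nClusters")
    if (nClusters > n) stop("nClusters exceeds the number of individuals",
                            call. = FALSE)
    ids <- attr(d, "Labels")
    if (is.null(ids)) ids <- as.character(seq_len(n))
    if (nClusters == n) {
        # degenerate: every point is its own medoid
        return(list(labels = setNames(seq_len(n), ids), medoids = ids,
                    cost = 0, buildCost = 0))
    }
    fit <- cluster::pam(d, k = nClusters, diss = TRUE, cluster.only = FALSE)
    labels <- fit$clustering
    list(labels = labels, medoids = fit$medoids,
         cost = unname(fit$objective["swap"]) * n,
         buildCost = unname(fit$objective["build"]) * n)
}

#' Choose the number of PAM clusters
#'
#' Runs PAM over a range of k, recording the total within-cluster
#' dissimilarity (the scree curve, emitted for inspection) and the average
#' silhouette width. The returned `bestK` maximizes the average silhouette
#' width, making the choice algorithmic rather than a visual scree-plot
#' judgment.
#'
#' @param x as in [pamCluster()].
#' @param kRange candidate cluster counts, each in \[2, n - 1\].
#' @return list with `bestK` and a `diagnostics` data.frame
#'   (k, cost, silhouette).
#' @export
chooseNClusters <- function(x, kRange = 2:8) {
    d <- .asDissimilarity(x)
    n <- attr(d, "Size")
    kRange <- as.integer(kRange)
    if (!length(kRange)) stop("empty kRange", call. = FALSE)
    if (any(kRange < 2) || any(kRange > n - 1))
        stop("kRange values must lie in [2, n - 1]", call. = FALSE)
    diag <- data.frame(k = kRange, cost = NA_real_, silhouette = NA_real_)
    for (i in seq_along(kRange)) {
        fit <- cluster::pam(d, k = kRange[i], diss = TRUE)
        diag$cost[i] <- unname(fit$objective["swap"]) * n
        diag$silhouette[i] <- fit$silinfo$avg.width
    }
    list(bestK = kRange[which.max(diag$silhouette)], diagnostics = diag)
}

#' One-hot cluster-membership covariates
#'
#' Expands integer cluster labels into binary indicator columns. With
#' `dropLast = TRUE` (use whenever the downstream model carries an
#' intercept) the final category's column is removed to keep the combined
#' design full-rank.
#'
#' @param labels named integer vector of cluster labels in 1..C.
#' @param dropLast drop the last category's column.
#' @return [StructureCovariates-class] of kind `"pam_onehot"`.
#' @export
onehotCovariates <- function(labels, dropLast = FALSE) {
    if (is.null(names(labels))) stop("labels must be named by individual id",
                                     call. = FALSE)
    C <- max(labels)
    if (any(labels < 1 | labels != round(labels)))
        stop("labels must be integers in 1..C", call. = FALSE)
    design <- matrix(0, length(labels), C,
                     dimnames = list(names(labels),
                                     paste0("cluster", seq_len(C))))
    design[cbind(seq_along(labels), labels)] <- 1
    if (dropLast) design <- design[, -C, drop = FALSE]
    StructureCovariates(design, "pam_onehot",
                        meta = list(nClusters = C, dropLast = dropLast))
}

#' Admixture ancestry estimation by EM
#'
#' Maximizes the binomial admixture log-likelihood
#' `l = sum_ij [ g_ij log p_ij + (2 - g_ij) log(1 - p_ij) ]` with
#' `p_ij = sum_k q_ik f_kj` over ancestry proportions Q (rows on the
#' simplex) and ancestral allele frequencies F, using the classic EM
#' updates (posterior responsibilities of each ancestral origin per allele
#' copy). Dosages may be real-valued (treated as expected alt-allele
#' counts), so mean-imputed matrices are accepted. The log-likelihood is
#' non-decreasing at every iteration; F is clipped to \[1e-6, 1 - 1e-6\]
#' and Q rows are renormalized each step.
#'
#' Initialization is random (Dirichlet(1) rows for Q, observed frequencies
#' plus uniform jitter for F) and seeded, so fits are reproducible; as with
#' any admixture estimator, component labels are identified only up to
#' permutation (see [alignQMatrix()]).
#'
#' @param g an imputed [MarkerMatrix-class].
#' @param K number of ancestral populations (>= 1).
#' @param seed integer seed for the random initialization.
#' @param maxIter maximum EM iterations (default 2000).
#' @param tol stop when the log-likelihood improves by less than `tol`
#'   (default 1e-4).
#' @return an [AdmixtureFit-class].
#' @export
admixtureEM <- function(g, K, seed = 1, maxIter = 2000, tol = 1e-4) {
    stopifnot(is(g, "MarkerMatrix"))
    .assertImputed(g, "admixtureEM")
    K <- .assertScalarCount(K, "K")
    d <- g@dosage
    n <- nrow(d); m <- ncol(d)
    if (K > n) stop("K exceeds the number of individuals", call. = FALSE)
    eps <- 1e-6
    d <- pmin(pmax(d, 0), 2)
    init <- withSeed(seed, {
        Q <- rdirichlet(n, rep(1, K))
        phat <- colMeans(d) / 2
        F <- matrix(pmin(pmax(rep(phat, each = K) +
                              runif(K * m, -0.2, 0.2), eps), 1 - eps), K, m)
        list(Q = Q, F = F)
    })
    res <- admixture_em_cpp(d, init$Q, init$F, as.integer(maxIter),
                            as.numeric(tol), eps)
    if (!all(is.finite(res$logLik)))
        stop("non-finite admixture log-likelihood at iteration ",
             which(!is.finite(res$logLik))[1], call. = FALSE)
    Q <- res$Q
    rownames(Q) <- individualIds(g)
    colnames(Q) <- paste0("anc", seq_len(K))
    F <- res$F
    colnames(F) <- snpIds(g)
    rownames(F) <- paste0("anc", seq_len(K))
    new("AdmixtureFit", Q = Q, F = F, logLik = as.numeric(res$logLik),
        K = K, seed = as.integer(seed), iterations = as.integer(res$iter),
        converged = as.logical(res$converged))
}

#' Q-matrix fixed-effect covariates
#'
#' Uses the ancestry proportions of an [AdmixtureFit-class] as fixed-effect
#' covariates. Because Q rows sum to 1, the full Q together with an
#' intercept is rank-deficient; with `dropLast = TRUE` (the default, since
#' the prediction models always carry an intercept) the final ancestry
#' column is dropped.
#'
#' @param fit an [AdmixtureFit-class], or a bare n x K Q matrix with
#'   individual ids as rownames.
#' @param dropLast drop the last ancestry column (default `TRUE`).
#' @return [StructureCovariates-class] of kind `"qmatrix"`.
#' @export
qmatrixCovariates <- function(fit, dropLast = TRUE) {
    Q <- if (is(fit, "AdmixtureFit")) fit@Q else as.matrix(fit)
    if (is.null(rownames(Q)))
        stop("Q must carry individual ids as rownames", call. = FALSE)
    if (any(abs(rowSums(Q) - 1) > 1e-6))
        stop("Q rows must sum to 1", call. = FALSE)
    K <- ncol(Q)
    if (is.null(colnames(Q))) colnames(Q) <- paste0("anc", seq_len(K))
    design <- if (dropLast) Q[, -K, drop = FALSE] else Q
    StructureCovariates(design, "qmatrix",
                        meta = list(K = K, dropLast = dropLast))
}
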