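# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL uses the current
# stream.
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    force(code)
}

.assertScalarCount <- function(x, name) {
    if (length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x))
        stop(sprintf("'%s' must be a single positive integer", name),
             call. = FALSE)
    as.integer(x)
}

.assertImputed <- function(g, caller) {
    if (anyNA(g@dosage))
        stop(sprintf("%s requires a fully imputed MarkerMatrix; run imputeMissing() first",
                     caller), call. = FALSE)
    invisible(TRUE)
}

# Draw one Dirichlet(alpha) vector per row.
rdirichlet <- function(n, alpha) {
    k <- length(alpha)
    x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
    zero <- rowSums(x) == 0
    if (any(zero)) x[zero, ] <- 1 / k
    x / rowSums(x)
}

# All permutations of 1..k (k small).
.permutations <- function(k) {
    if (k == 1) return(matrix(1L, 1, 1))
    sub <- .permutations(k - 1)
    out <- matrix(0L, 0, k)
    for (i in seq_len(k)) {
        rest <- setdiff(seq_len(k), i)
        out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
    }
    unname(out)
}

#' Align an estimated Q-matrix to a reference by column permutation
#'
#' Admixture components are identified only up to label switching. This
#' helper finds the column permutation of `Qhat` minimizing the mean
#' absolute difference to `Qref` and returns the permuted matrix with the
#' achieved MAE as attribute `"mae"`.
#'
#' @param Qhat estimated n x K ancestry matrix.
#' @param Qref reference n x K ancestry matrix.
#' @return permuted `Qhat` with attribute `mae`.
#' @export
alignQMatrix <- function(Qhat, Qref) {
    stopifnot(ncol(Qhat) == ncol(Qref), nrow(Qhat) == nrow(Qref))
    perms <- .permutations(ncol(Qhat))
    best <- NULL; bestMae <- Inf
    for (r in seq_len(nrow(perms))) {
        Qp <- Qhat[, perms[r, ], drop = FALSE]
        mae <- mean(abs(Qp - Qref))
        if (mae < bestMae) { bestMae <- mae; best <- Qp }
    }
    attr(best, "mae") <- bestMae
    best
}
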