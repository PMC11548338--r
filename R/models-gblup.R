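#' Fit GBLUP by exact REML
#'
#' Mixed model `y = Q beta + Z gamma + e` with `gamma ~ N(0, I varG / m)`
#' and `e ~ N(0, I varE)`, fit in the equivalent genomic-relationship form
#' `y ~ N(Q beta, G varG + I varE)` with `G = Z Z' / m`. The restricted
#' likelihood is profiled down to the single ratio `lambda = varE / varG`
#' using one eigendecomposition of G, and maximized by 1-D bounded search
#' over `log(lambda)` in \[-10, 10\]. Fixed effects are GLS estimates at
#' the optimum and marker effects are recovered by the ridge backsolve
#' `gamma = Z' (Z Z' + lambda m I)^-1 (y - Q beta)`, making the fit
#' identical to the marker-effect (RR-BLUP) formulation.
#'
#' @param y named phenotype vector over the training individuals (missing
#'   values are dropped with a message).
#' @param Q fixed-effect design (intercept first; see [buildDesign()]).
#' @param Z centered marker matrix (see [buildDesign()]).
#' @param centerFreqs frozen centering frequencies recorded in the fit for
#'   later prediction (optional but recommended; [buildDesign()] returns
#'   them).
#' @return a [GSFit-class] of kind `"gblup"` with variance components
#'   `varG` (additive variance on the phenotype scale, i.e. the G-scale
#'   multiplier times the mean diagonal of G), `varE`, the profiled REML
#'   ratio `lambda`, fixed effects, marker effects and fitted values.
#' @references VanRaden, P.M. (2008) Efficient methods to compute genomic
#'   predictions. J. Dairy Sci. 91:4414-4423.
#' @export
gblupFit <- function(y, Q, Z, centerFreqs = numeric()) {
    al <- .alignPhenotypes(y, Q, Z)
    y <- al$y; Q <- al$Q; Z <- al$Z
    n <- nrow(Q); l <- ncol(Q); m <- ncol(Z)
    if (n <= l) stop("need more training individuals than fixed effects",
                     call. = FALSE)
    G <- tcrossprod(Z) / m
    eig <- eigen(G, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    U <- eig$vectors
    yt <- crossprod(U, y)
    Qt <- crossprod(U, Q)

    remlNegLogLik <- function(logLambda) {
        lam <- exp(logLambda)
        w <- d + lam
        XtVX <- crossprod(Qt, Qt / w)
        beta <- solve(XtVX, crossprod(Qt, yt / w))
        r <- yt - Qt %*% beta
        rss <- sum(r^2 / w)
        phi2 <- max(rss / (n - l), .Machine$double.xmin)
        ll <- -0.5 * ((n - l) * log(phi2) + sum(log(w)) +
                      as.numeric(determinant(XtVX)$modulus) + (n - l))
        if (is.nan(ll)) stop("non-finite REML likelihood", call. = FALSE)
        -ll
    }

    opt <- optimize(remlNegLogLik, interval = c(-10, 10), tol = 1e-9)
    lam <- exp(opt$minimum)
    w <- d + lam
    XtVX <- crossprod(Qt, Qt / w)
    beta <- drop(solve(XtVX, crossprod(Qt, yt / w)))
    r <- drop(yt - Qt %*% beta)
    phi2 <- sum(r^2 / w) / (n - l)
    resid <- y - drop(Q %*% beta)
    gamma <- drop(crossprod(Z, U %*% (crossprod(U, resid) / (m * w))))
    fitted <- drop(Q %*% beta + Z %*% gamma)
    # phi2 multiplies G = ZZ'/m, whose mean diagonal is not 1 in general;
    # the additive variance on the phenotype scale is phi2 * mean(diag(G)).
    cbar <- mean(d)
    new("GSFit", kind = "gblup",
        beta = setNames(beta, colnames(Q)),
        markerEffects = setNames(gamma, colnames(Z)),
        varG = phi2 * cbar, varE = lam * phi2, lambda = lam,
        centerFreqs = centerFreqs,
        fitted = setNames(fitted, al$ids), pip = numeric(),
        control = list(remlObjective = -opt$objective,
                       logLambdaBounds = c(-10, 10)),
        trainIds = al$ids)
}

#' REML log-likelihood profile of a GBLUP system
#'
#' Evaluates the profiled restricted log-likelihood over a grid of
#' `log(lambda)` values (the objective [gblupFit()] maximizes), useful for
#' inspecting the variance-ratio surface.
#'
#' @param y,Q,Z as in [gblupFit()].
#' @param logLambda grid of log variance-ratio values.
#' @return data.frame with columns `logLambda` and `logLik`.
#' @export
gblupProfile <- function(y, Q, Z, logLambda = seq(-10, 10, length.out = 201)) {
    al <- .alignPhenotypes(y, Q, Z)
    y <- al$y; Q <- al$Q; Z <- al$Z
    n <- nrow(Q); l <- ncol(Q); m <- ncol(Z)
    G <- tcrossprod(Z) / m
    eig <- eigen(G, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    yt <- crossprod(eig$vectors, y)
    Qt <- crossprod(eig$vectors, Q)
    ll <- vapply(logLambda, function(lg) {
        w <- d + exp(lg)
        XtVX <- crossprod(Qt, Qt / w)
        beta <- solve(XtVX, crossprod(Qt, yt / w))
        rss <- sum((yt - Qt %*% beta)^2 / w)
        phi2 <- max(rss / (n - l), .Machine$double.xmin)
        -0.5 * ((n - l) * log(phi2) + sum(log(w)) +
                as.numeric(determinant(XtVX)$modulus) + (n - l))
    }, numeric(1))
    data.frame(logLambda = logLambda, logLik = ll)
}

#' Predict new individuals from a GBLUP fit
#'
#' `yhat = Q_new beta + Z_new gamma`. `Z_new` must be centered with the
#' fit's frozen training frequencies and `Q_new` built with the same
#' covariate pipeline (structure estimated jointly over the combined
#' populations before the split).
#'
#' @param fit a [GSFit-class] of kind `"gblup"`.
#' @param Qnew,Znew designs for the new individuals.
#' @return named numeric vector of predictions.
#' @export
gblupPredict <- function(fit, Qnew, Znew) {
    stopifnot(is(fit, "GSFit"), fit@kind == "gblup")
    .checkPredictDims(fit, Qnew, Znew)
    drop(Qnew %*% fit@beta + Znew %*% fit@markerEffects)
}

.checkPredictDims <- function(fit, Qnew, Znew) {
    if (ncol(Qnew) != length(fit@beta))
        stop("Qnew has ", ncol(Qnew), " columns but the fit has ",
             length(fit@beta), " fixed effects", call. = FALSE)
    if (ncol(Znew) != length(fit@markerEffects))
        stop("marker-set mismatch: Znew has ", ncol(Znew),
             " markers but the fit has ", length(fit@markerEffects),
             call. = FALSE)
    if (!is.null(colnames(Znew)) &&
        !identical(colnames(Znew), names(fit@markerEffects)))
        stop("marker-set mismatch: Znew column names differ from the fit",
             call. = FALSE)
    invisible(TRUE)
}

#' @describeIn predictGS dispatches to [gblupPredict()] or
#'   [bayesbPredict()] according to the fit kind.
#' @export
setMethod("predictGS", "GSFit", function(object, Qnew, Znew) {
    if (object@kind == "gblup") gblupPredict(object, Qnew, Znew)
    else bayesbPredict(object, Qnew, Znew)
})

#' Estimated narrow-sense heritability of a GBLUP fit
#'
#' `varG / (varG + varE)` with `varG` the additive variance on the
#' phenotype scale.
#'
#' @param fit a [GSFit-class] of kind `"gblup"`.
#' @return heritability estimate in \[0, 1\].
#' @export
heritability <- function(fit) {
    stopifnot(is(fit, "GSFit"), fit@kind == "gblup")
    fit@varG / (fit@varG + fit@varE)
}

#' Access the frozen centering frequencies of a fit
#' @param fit a [GSFit-class].
#' @return named numeric vector of per-SNP training allele frequencies.
#' @export
centerFreqs <- function(fit) {
    stopifnot(is(fit, "GSFit"))
    fit@centerFreqs
}
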