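#' BayesB sampler settings
#'
#' Defaults are explicit and configurable: 3000 sweeps with 500 burn-in and
#' thinning 5; slab degrees of freedom 5; prior inclusion probability 0.05;
#' the slab scale is set automatically so the implied prior genetic
#' variance equals `r2` (default 0.5) times the phenotypic variance, and
#' the residual scale so the residual prior centers on `(1 - r2)` of it.
#'
#' @param nIter total Gibbs sweeps.
#' @param burnIn sweeps discarded before accumulation (< nIter).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; the sampler is bit-reproducible given the seed.
#' @param piInclusion prior probability a marker has a non-zero effect,
#'   in (0, 1\].
#' @param df slab (scaled-t) degrees of freedom, > 0.
#' @param scale slab scale, or `"auto"` (from `r2`).
#' @param dfE residual degrees of freedom.
#' @param scaleE residual scale, or `"auto"`.
#' @param r2 prior proportion of phenotypic variance attributed to markers,
#'   used by the `"auto"` scale rules.
#' @param updatePi if `TRUE`, sample the inclusion probability with a
#'   Beta(1, 1) hyperprior instead of keeping it fixed.
#' @return validated settings list of class `bayesbControl`.
#' @export
bayesbControl <- function(nIter = 3000, burnIn = 500, thin = 5, seed = 1,
                          piInclusion = 0.05, df = 5, scale = "auto",
                          dfE = 5, scaleE = "auto", r2 = 0.5,
                          updatePi = FALSE) {
    nIter <- .assertScalarCount(nIter, "nIter")
    burnIn <- as.integer(burnIn)
    if (burnIn < 0 || burnIn >= nIter)
        stop("burnIn must satisfy 0 <= burnIn < nIter", call. = FALSE)
    thin <- .assertScalarCount(thin, "thin")
    if (piInclusion <= 0 || piInclusion > 1)
        stop("piInclusion must lie in (0, 1]", call. = FALSE)
    if (df <= 0) stop("df must be > 0", call. = FALSE)
    if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)", call. = FALSE)
    structure(list(nIter = nIter, burnIn = burnIn, thin = thin,
                   seed = as.integer(seed), piInclusion = piInclusion,
                   df = df, scale = scale, dfE = dfE, scaleE = scaleE,
                   r2 = r2, updatePi = isTRUE(updatePi)),
              class = "bayesbControl")
}

#' Fit BayesB by single-site Gibbs sampling
#'
#' `y = Q beta + Z gamma + e` with a flat prior on the fixed effects
#' (intercept included as the first column of `Q`) and, per marker, a
#' two-component mixture prior on the effect: a point mass at zero with
#' probability `1 - pi` and a scaled-t slab — represented as a normal with
#' marker-specific variance drawn from a scaled inverse chi-square — with
#' probability `pi`. Each sweep samples the fixed effects, then for every
#' marker the inclusion indicator (from the marginal likelihood ratio with
#' the effect integrated out), the effect, and its variance, and finally
#' the residual variance. Posterior means of all quantities and per-marker
#' posterior inclusion probabilities are accumulated after burn-in with
#' thinning. Runs are bit-reproducible from the control seed.
#'
#' @param y named phenotype vector over the training individuals.
#' @param Q,Z designs from [buildDesign()].
#' @param control a [bayesbControl()] list.
#' @param centerFreqs frozen centering frequencies stored for prediction.
#' @return a [GSFit-class] of kind `"bayesb"`; `slot pip` holds posterior
#'   inclusion probabilities and `varE` the posterior mean residual
#'   variance.
#' @references Meuwissen, T.H.E., Hayes, B.J., Goddard, M.E. (2001)
#'   Prediction of total genetic value using genome-wide dense marker maps.
#'   Genetics 157:1819-1829.
#' @export
bayesbFit <- function(y, Q, Z, control = bayesbControl(),
                      centerFreqs = numeric()) {
    stopifnot(inherits(control, "bayesbControl"))
    al <- .alignPhenotypes(y, Q, Z)
    y <- al$y; Q <- al$Q; Z <- al$Z
    n <- nrow(Q)
    if (n <= ncol(Q))
        stop("need more training individuals than fixed effects",
             call. = FALSE)
    vy <- var(y)
    sumVarZ <- sum(apply(Z, 2, var))
    S <- control$scale
    if (identical(S, "auto")) {
        if (sumVarZ <= 0) stop("all markers are constant", call. = FALSE)
        # prior genetic variance pi * sumVarZ * E[s2_j] == r2 * var(y)
        S <- if (control$df > 2)
            control$r2 * vy * (control$df - 2) /
                (control$df * control$piInclusion * sumVarZ)
        else control$r2 * vy / (control$piInclusion * sumVarZ)
    }
    SE <- control$scaleE
    if (identical(SE, "auto")) SE <- (1 - control$r2) * vy
    res <- withSeed(control$seed,
        bayesb_gibbs_cpp(y, Q, Z, control$nIter, control$burnIn,
                         control$thin, control$piInclusion, control$df, S,
                         control$dfE, SE, control$updatePi))
    beta <- setNames(as.numeric(res$beta), colnames(Q))
    gamma <- setNames(as.numeric(res$gamma), colnames(Z))
    fitted <- drop(Q %*% beta + Z %*% gamma)
    ctl <- unclass(control)
    ctl$scale <- S; ctl$scaleE <- SE
    ctl$posteriorPi <- res$pi; ctl$nSamples <- res$nSamples
    new("GSFit", kind = "bayesb", beta = beta, markerEffects = gamma,
        varG = numeric(), varE = as.numeric(res$sigma2),
        lambda = numeric(), centerFreqs = centerFreqs,
        fitted = setNames(fitted, al$ids),
        pip = setNames(as.numeric(res$pip), colnames(Z)),
        control = ctl, trainIds = al$ids)
}

#' Predict new individuals from a BayesB fit
#'
#' `yhat = mu + Q_new beta + Z_new gamma` using posterior means (the
#' intercept `mu` is the first element of `beta` since `Q` carries the
#' intercept column). `Z_new` must be centered with the fit's frozen
#' training frequencies.
#'
#' @param fit a [GSFit-class] of kind `"bayesb"`.
#' @param Qnew,Znew designs for the new individuals.
#' @return named numeric vector of predictions.
#' @export
bayesbPredict <- function(fit, Qnew, Znew) {
    stopifnot(is(fit, "GSFit"), fit@kind == "bayesb")
    .checkPredictDims(fit, Qnew, Znew)
    drop(Qnew %*% fit@beta + Znew %*% fit@markerEffects)
}

#' Posterior inclusion probabilities of a BayesB fit
#' @param fit a [GSFit-class] of kind `"bayesb"`.
#' @return named numeric vector in \[0, 1\] per marker.
#' @export
inclusionProbabilities <- function(fit) {
    stopifnot(is(fit, "GSFit"), fit@kind == "bayesb")
    fit@pip
}
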