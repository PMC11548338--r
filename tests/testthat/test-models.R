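test_that("design construction centers markers and guards collinearity", {
    g <- randomMarkerMatrix(12, 20, seed = 60)
    bd <- buildDesign(g)
    expect_equal(unname(bd$Q), matrix(1, 12, 1))
    expect_lt(max(abs(colMeans(bd$Z))), 1e-10)
    expect_equal(bd$centerFreqs, colMeans(dosage(g)) / 2)
    # a full (undropped) Q-matrix plus intercept is collinear
    withr::with_seed(61, {
        Q <- matrix(rexp(12 * 3), 12, 3)
        Q <- Q / rowSums(Q)
    })
    rownames(Q) <- individualIds(g)
    colnames(Q) <- paste0("anc", 1:3)
    full <- qmatrixCovariates(Q, dropLast = FALSE)
    expect_error(buildDesign(g, full), "rank-deficient")
    ok <- buildDesign(g, qmatrixCovariates(Q))
    expect_equal(ncol(ok$Q), 3)   # intercept + K - 1
    # frozen frequencies center new individuals on the training scale
    g2 <- randomMarkerMatrix(5, 20, seed = 62, prefix = "new")
    nd <- buildDesign(g2, centerFreqs = bd$centerFreqs)
    expect_equal(nd$Z, sweep(dosage(g2), 2, 2 * bd$centerFreqs),
                 ignore_attr = FALSE)
})

test_that("pure fixed-effect data drives the genetic variance to zero", {
    withr::with_seed(63, {
        g <- randomMarkerMatrix(40, 30)
        x <- rnorm(40)
    })
    cov <- StructureCovariates(matrix(x, dimnames = list(individualIds(g),
                                                         "x")), "pca")
    bd <- buildDesign(g, cov)
    beta <- c(2, 1.5)
    y <- setNames(drop(bd$Q %*% beta), individualIds(g))
    fit <- gblupFit(y, bd$Q, bd$Z)
    expect_lt(fit@varG, 1e-6 * var(y))
    expect_equal(unname(fit@beta), beta, tolerance = 1e-6)
})

test_that("GBLUP backsolve agrees with the relationship-matrix block route", {
    inst <- simGSInstance(50, 80, 15, 0.5, seed = 64)
    trainIdx <- 1:40
    yTr <- inst$y[trainIdx]
    Qtr <- inst$Q[trainIdx, , drop = FALSE]
    Ztr <- inst$Z[trainIdx, , drop = FALSE]
    fit <- gblupFit(yTr, Qtr, Ztr)
    m <- ncol(Ztr)
    Gall <- tcrossprod(inst$Z) / m
    G11 <- Gall[trainIdx, trainIdx]
    G21 <- Gall[-trainIdx, trainIdx]
    V <- G11 + fit@lambda * diag(length(trainIdx))
    Vi <- solve(V)
    beta2 <- solve(t(Qtr) %*% Vi %*% Qtr, t(Qtr) %*% Vi %*% yTr)
    expect_equal(unname(fit@beta), unname(drop(beta2)), tolerance = 1e-8)
    r <- yTr - drop(Qtr %*% beta2)
    fitted2 <- drop(Qtr %*% beta2) + drop(G11 %*% Vi %*% r)
    expect_equal(unname(fit@fitted), unname(fitted2), tolerance = 1e-8)
    predBlock <- drop(inst$Q[-trainIdx, ] %*% beta2) +
        drop(G21 %*% Vi %*% r)
    predBack <- gblupPredict(fit, inst$Q[-trainIdx, , drop = FALSE],
                             inst$Z[-trainIdx, , drop = FALSE])
    expect_equal(unname(predBack), unname(predBlock), tolerance = 1e-8)
})

test_that("GBLUP predictions are consistent on training rows and at the centering mean", {
    inst <- simGSInstance(30, 40, 10, 0.6, seed = 65)
    fit <- gblupFit(inst$y, inst$Q, inst$Z)
    expect_equal(predictGS(fit, inst$Q, inst$Z), fit@fitted)
    Z0 <- matrix(0, 2, ncol(inst$Z),
                 dimnames = list(c("n1", "n2"), colnames(inst$Z)))
    Q0 <- matrix(1, 2, 1, dimnames = list(c("n1", "n2"), "(Intercept)"))
    expect_equal(unname(predictGS(fit, Q0, Z0)),
                 rep(unname(fit@beta[1]), 2))
    expect_error(gblupPredict(fit, Q0, Z0[, 1:10]), "marker-set mismatch")
})

test_that("missing training phenotypes are dropped with a message", {
    inst <- simGSInstance(25, 30, 8, 0.5, seed = 66)
    y <- inst$y
    y[c(3, 7)] <- NA
    expect_message(fit <- gblupFit(y, inst$Q, inst$Z), "2 individual")
    expect_length(fit@trainIds, 23)
})

test_that("BayesB collapses to the fixed-effect model when inclusion vanishes", {
    inst <- simGSInstance(60, 40, 10, 0.5, seed = 67)
    ctl <- bayesbControl(nIter = 1200, burnIn = 200, seed = 3,
                         piInclusion = 1e-12)
    fit <- bayesbFit(inst$y, inst$Q, inst$Z, control = ctl)
    expect_lt(max(abs(fit@markerEffects)), 1e-6)
    ols <- drop(solve(crossprod(inst$Q), crossprod(inst$Q, inst$y)))
    expect_equal(unname(fit@beta), unname(ols), tolerance = 0.05 * sd(inst$y))
})

test_that("BayesB is reproducible from its seed and stable across seeds", {
    inst <- simGSInstance(80, 100, 10, 0.7, seed = 68)
    ctl <- bayesbControl(nIter = 800, burnIn = 200, seed = 5)
    f1 <- bayesbFit(inst$y, inst$Q, inst$Z, control = ctl)
    f2 <- bayesbFit(inst$y, inst$Q, inst$Z, control = ctl)
    expect_identical(f1@markerEffects, f2@markerEffects)
    expect_identical(f1@beta, f2@beta)
    f3 <- bayesbFit(inst$y, inst$Q, inst$Z,
                    control = bayesbControl(nIter = 800, burnIn = 200,
                                            seed = 6))
    expect_gt(cor(f1@markerEffects, f3@markerEffects), 0.9)
})

test_that("BayesB predictions respect the intercept and marker ordering", {
    inst <- simGSInstance(50, 30, 8, 0.6, seed = 69)
    ctl <- bayesbControl(nIter = 600, burnIn = 100, seed = 2)
    fit <- bayesbFit(inst$y, inst$Q, inst$Z, control = ctl)
    Z0 <- matrix(0, 3, 30, dimnames = list(paste0("n", 1:3),
                                           colnames(inst$Z)))
    Q0 <- matrix(1, 3, 1)
    expect_equal(unname(bayesbPredict(fit, Q0, Z0)),
                 rep(unname(fit@beta[1]), 3))
    # reordering markers consistently in the fit and in Z_new leaves
    # predictions unchanged
    perm <- withr::with_seed(70, sample(30))
    fitP <- fit
    fitP@markerEffects <- fit@markerEffects[perm]
    fitP@pip <- fit@pip[perm]
    expect_equal(bayesbPredict(fitP, inst$Q, inst$Z[, perm]),
                 bayesbPredict(fit, inst$Q, inst$Z))
})

test_that("BayesB control validates its arguments", {
    expect_error(bayesbControl(burnIn = 3000), "burnIn")
    expect_error(bayesbControl(piInclusion = 0), "piInclusion")
    expect_error(bayesbControl(piInclusion = 1.2), "piInclusion")
    expect_error(bayesbControl(df = -1), "df")
})

test_that("fit serialization round-trips predictions exactly", {
    inst <- simGSInstance(40, 25, 8, 0.5, seed = 71)
    fit <- gblupFit(inst$y, inst$Q, inst$Z, centerFreqs = inst$centerFreqs)
    prefix <- withr::local_tempfile()
    writeGSFit(fit, prefix)
    back <- readGSFit(prefix)
    expect_equal(back@beta, fit@beta, tolerance = 1e-12)
    expect_equal(back@markerEffects, fit@markerEffects, tolerance = 1e-12)
    expect_equal(centerFreqs(back), centerFreqs(fit), tolerance = 1e-12)
    expect_equal(predictGS(back, inst$Q, inst$Z),
                 predictGS(fit, inst$Q, inst$Z), tolerance = 1e-10)
})
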