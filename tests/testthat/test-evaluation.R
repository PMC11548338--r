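test_that("Pearson accuracy matches hand arithmetic and guards degeneracy", {
    expect_equal(pearsonAccuracy(1:5, 1:5), 1)
    expect_equal(pearsonAccuracy(1:5, -(1:5)), -1)
    # hand oracle: centered cross-product / sqrt of products
    pred <- c(1, 2, 3, 4); obs <- c(2, 1, 4, 3)
    byHand <- sum((pred - 2.5) * (obs - 2.5)) /
        sqrt(sum((pred - 2.5)^2) * sum((obs - 2.5)^2))
    expect_equal(pearsonAccuracy(pred, obs), byHand)
    expect_equal(byHand, 0.6)
    expect_error(pearsonAccuracy(c(1, 1, 1), c(1, 2, 3)), "zero variance")
    expect_error(pearsonAccuracy(1:2, 2:1), "at least 3")
})

test_that("CV folds partition every individual exactly once per repeat", {
    scheme <- cvScheme(nFolds = 5, nRepeats = 4, seed = 3)
    folds <- psapgp:::.makeFolds(10, scheme)
    expect_length(folds, 4)
    for (labels in folds) {
        expect_equal(sort(unique(labels)), 1:5)
        expect_true(all(table(labels) == 2))
    }
    # same seed reproduces assignments exactly
    expect_identical(folds, psapgp:::.makeFolds(10, scheme))
    expect_error(psapgp:::.makeFolds(5, cvScheme(4, 1, 1)), "fewer than 2")
    expect_error(cvScheme(nFolds = 1), "nFolds")
})

test_that("cross-validation is deterministic and tracks the signal level", {
    highs <- lows <- numeric(3)
    for (r in 1:3) {
        hi <- simGSInstance(120, 150, 30, 0.9, seed = 80 + r)
        lo <- simGSInstance(120, 150, 30, 0.2, seed = 80 + r)
        scheme <- cvScheme(5, 3, seed = r)
        accHi <- crossValidate(hi$y, hi$Q, hi$Z, "gblup", scheme)
        accLo <- crossValidate(lo$y, lo$Q, lo$Z, "gblup", scheme)
        expect_identical(as.numeric(accHi),
                         as.numeric(crossValidate(hi$y, hi$Q, hi$Z, "gblup",
                                                  scheme)))
        highs[r] <- attr(accHi, "mean"); lows[r] <- attr(accLo, "mean")
        # accuracy varies over repeats on noisy data (no silent leakage)
        expect_gt(attr(accLo, "sd"), 0)
    }
    expect_true(all(highs > lows))
})

test_that("across-population runs forbid leakage and marker mismatches", {
    st <- simulateStudy(simConfig(seed = 81, nSnps = 120, nMothers = 10,
                                  nFathers = 4, nParents2 = 15,
                                  nCrosses2 = 30, nQtl = 20))
    yT <- phenotypeVector(st$trainPheno, "trait",
                          individualIds(st$trainGeno))
    yB <- phenotypeVector(st$breedPheno, "trait",
                          individualIds(st$breedGeno))
    res <- acrossPopulationRun(st$trainGeno, yT, st$breedGeno, yB, "gblup")
    expect_s4_class(res, "PredictionResult")
    expect_true(abs(accuracy(res)) <= 1)
    expect_equal(res@meta$trainingSize, 40)
    # overlap raises
    leaky <- st$trainGeno
    rownames(leaky@dosage)[1] <- individualIds(st$breedGeno)[1]
    expect_error(acrossPopulationRun(leaky, yT, st$breedGeno, yB, "gblup"),
                 "leakage")
    # marker mismatch raises
    expect_error(acrossPopulationRun(st$trainGeno[, 1:100], yT,
                                     st$breedGeno, yB, "gblup"),
                 "marker-set mismatch")
    # MeanRel selection restricts the training size
    kin <- computeKinship(MarkerMatrix(rbind(dosage(st$trainGeno),
                                             dosage(st$breedGeno))))
    sel <- selectTraining(meanRel(kin, individualIds(st$trainGeno),
                                  individualIds(st$breedGeno)),
                          "top_n", 25)
    res2 <- acrossPopulationRun(st$trainGeno, yT, st$breedGeno, yB,
                                "gblup", selection = sel)
    expect_equal(res2@meta$trainingSize, 25)
})

test_that("improvement ratio and paired comparison behave", {
    expect_equal(improvementRatio(0.44, 0.40), 10)
    expect_equal(improvementRatio(0.5, 0.5), 0)
    # hand formula oracle
    expect_equal(improvementRatio(0.338, 0.311),
                 100 * (0.338 - 0.311) / 0.311)
    expect_error(improvementRatio(0.3, 0), "zero")
    ht <- accuracyComparisonTest(c(0.5, 0.62, 0.55), c(0.4, 0.5, 0.41))
    expect_s3_class(ht, "htest")
    expect_true(ht$p.value < 0.05)
    expect_error(accuracyComparisonTest(1:3, 1:4), "paired")
})

test_that("the experiment grid produces one row per scenario combination", {
    st <- simulateStudy(simConfig(seed = 82, nSnps = 100, nMothers = 8,
                                  nFathers = 4, nParents2 = 12,
                                  nCrosses2 = 25, nQtl = 15, KTrue = 2,
                                  alpha1 = c(2, 0.5), alpha2 = c(0.5, 2)))
    res <- runGrid(st$trainGeno, st$trainPheno, st$breedGeno, st$breedPheno,
                   models = "gblup", scenarios = c("none", "qmatrix:2"),
                   trainingSizes = c(20, 30), pamKRange = 2:4,
                   emMaxIter = 200)
    expect_equal(nrow(res), 4)
    expect_setequal(unique(res$trainingSize), c(20, 30))
    expect_true(all(is.finite(res$accuracy)))
})
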