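test_that("PCA covariates match a dense eigendecomposition oracle", {
    g <- randomMarkerMatrix(20, 50, seed = 30)
    cov <- pcaCovariates(g, 5)
    scores <- designMatrix(cov)
    X <- scale(dosage(g), center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)$values
    expect_equal(unname(apply(scores, 2, var)), ev[1:5], tolerance = 1e-8)
    # column orthogonality
    cp <- crossprod(scores)
    expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
    expect_equal(cov@meta$nComponents, 5)
})

test_that("PCA rejects degenerate inputs and bad component counts", {
    same <- MarkerMatrix(matrix(1, 5, 10,
                                dimnames = list(letters[1:5],
                                                paste0("s", 1:10))))
    expect_error(pcaCovariates(same, 2), "identical")
    g <- randomMarkerMatrix(6, 10, seed = 1)
    expect_error(pcaCovariates(g, 0), "positive")
    expect_error(pcaCovariates(g, 6), "smaller")
})

test_that("PAM recovers well-separated clusters and degenerates sensibly", {
    withr::with_seed(40, {
        centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
        pts <- do.call(rbind, lapply(1:3, function(k)
            sweep(matrix(rnorm(16, sd = 0.3), 8, 2), 2, centers[k, ], "+")))
    })
    rownames(pts) <- sprintf("p%02d", 1:24)
    d <- as.matrix(dist(pts))
    res <- pamCluster(d, 3)
    expect_equal(adjustedRand(res$labels, rep(1:3, each = 8)), 1)
    expect_lte(res$cost, res$buildCost)
    # one cluster per point: zero cost
    res1 <- pamCluster(d, nrow(d))
    expect_equal(res1$cost, 0)
    expect_error(pamCluster(d, 30), "exceeds")
})

test_that("silhouette-based cluster-number choice finds the truth", {
    withr::with_seed(41, {
        centers <- matrix(rnorm(8, sd = 20), 4, 2)
        pts <- do.call(rbind, lapply(1:4, function(k)
            sweep(matrix(rnorm(12, sd = 0.3), 6, 2), 2, centers[k, ], "+")))
    })
    rownames(pts) <- sprintf("p%02d", 1:24)
    d <- as.matrix(dist(pts))
    out <- chooseNClusters(d, 2:7)
    expect_equal(out$bestK, 4)
    expect_equal(nrow(out$diagnostics), 6)
    # length-1 range returns that k
    expect_equal(chooseNClusters(d, 3)$bestK, 3)
    expect_error(chooseNClusters(d, integer(0)), "empty")
})

test_that("kinship converts to a valid dissimilarity for PAM", {
    K <- computeKinship(randomMarkerMatrix(10, 40, seed = 42))
    res <- pamCluster(K, 2)
    expect_length(res$labels, 10)
    expect_setequal(unique(res$labels), 1:2)
    expect_true(all(res$medoids %in% individualIds(K)))
})

test_that("one-hot coding partitions individuals", {
    labels <- c(a = 1L, b = 2L, c = 1L)
    full <- designMatrix(onehotCovariates(labels))
    expect_equal(unname(full), rbind(c(1, 0), c(0, 1), c(1, 0)))
    expect_true(all(rowSums(full) == 1))
    dropped <- designMatrix(onehotCovariates(labels, dropLast = TRUE))
    expect_equal(unname(dropped), cbind(c(1, 0, 1)))
})

test_that("admixture EM hits the K = 1 closed form and never decreases", {
    g <- randomMarkerMatrix(30, 40, seed = 50)
    fit1 <- admixtureEM(g, 1)
    expect_true(all(qMatrix(fit1) == 1))
    target <- pmin(pmax(colMeans(dosage(g)) / 2, 1e-6), 1 - 1e-6)
    expect_equal(unname(fit1@F[1, ]), unname(target), tolerance = 1e-12)
    # monotone likelihood on integer and real-valued (imputed) dosages
    for (gg in list(g, imputeMissing(randomMarkerMatrix(25, 30,
                                                        missingRate = 0.1,
                                                        seed = 51), "mean"))) {
        fit <- admixtureEM(gg, 3, seed = 2, maxIter = 150)
        expect_true(all(diff(fit@logLik) >= -1e-8))
        expect_equal(unname(rowSums(qMatrix(fit))), rep(1, nrow(dosage(gg))))
    }
    expect_error(admixtureEM(g, 31), "exceeds")
})

test_that("admixture components are stable across seeds up to label switching", {
    withr::with_seed(52, {
        f <- simulateFounderFrequencies(2, 300, 0.35)
        par <- simulateInbredParents(f, 120, c(0.5, 0.5))
    })
    fitA <- admixtureEM(par$geno, 2, seed = 1)
    fitB <- admixtureEM(par$geno, 2, seed = 99)
    aligned <- alignQMatrix(qMatrix(fitB), qMatrix(fitA))
    expect_lt(attr(aligned, "mae"), 0.05)
})

test_that("Q-matrix covariates drop a column exactly when an intercept needs it", {
    Q <- rbind(a = c(0.7, 0.3), b = c(0.2, 0.8), c = c(0.5, 0.5))
    colnames(Q) <- c("anc1", "anc2")
    expect_equal(unname(designMatrix(qmatrixCovariates(Q))),
                 cbind(c(0.7, 0.2, 0.5)))
    full <- designMatrix(qmatrixCovariates(Q, dropLast = FALSE))
    expect_equal(unname(rowSums(full)), rep(1, 3))
    # intercept + dropped design has rank K on generic Q
    withr::with_seed(53, {
        Qr <- rdirichletLike <- matrix(rexp(40 * 4), 40, 4)
        Qr <- Qr / rowSums(Qr)
    })
    rownames(Qr) <- sprintf("i%02d", 1:40)
    D <- designMatrix(qmatrixCovariates(Qr))
    expect_equal(qr(cbind(1, D))$rank, 4)
    expect_error(qmatrixCovariates(Qr * 2), "sum to 1")
})
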