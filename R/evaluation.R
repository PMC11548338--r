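#' Pearson prediction accuracy
#'
#' Sample Pearson correlation between predicted and observed phenotypic
#' values, the standard accuracy measure in genomic selection. Errors
#' (rather than returning `NaN`) when either vector has zero variance.
#'
#' @param pred,obs numeric vectors of length >= 3.
#' @return Pearson correlation in \[-1, 1\].
#' @export
pearsonAccuracy <- function(pred, obs) {
    if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
    keep <- !is.na(pred) & !is.na(obs)
    pred <- pred[keep]; obs <- obs[keep]
    if (length(pred) < 3)
        stop("need at least 3 paired observations", call. = FALSE)
    if (sd(pred) == 0 || sd(obs) == 0)
        stop("zero variance in predictions or observations", call. = FALSE)
    cor(pred, obs)
}

#' Cross-validation scheme
#'
#' @param nFolds number of folds (>= 2).
#' @param nRepeats number of repeated randomizations; default 20 repeats of
#'   5-fold CV.
#' @param seed seed for the fold shuffles.
#' @return validated scheme list of class `cvScheme`.
#' @export
cvScheme <- function(nFolds = 5, nRepeats = 20, seed = 1) {
    nFolds <- .assertScalarCount(nFolds, "nFolds")
    if (nFolds < 2) stop("nFolds must be >= 2", call. = FALSE)
    nRepeats <- .assertScalarCount(nRepeats, "nRepeats")
    structure(list(nFolds = nFolds, nRepeats = nRepeats,
                   seed = as.integer(seed)), class = "cvScheme")
}

# Seeded fold assignments: one shuffled-then-contiguous partition per
# repeat. Returns a list of integer label vectors (1..nFolds) per repeat.
.makeFolds <- function(n, scheme) {
    withSeed(scheme$seed, {
        lapply(seq_len(scheme$nRepeats), function(r) {
            perm <- sample.int(n)
            sizes <- rep(n %/% scheme$nFolds, scheme$nFolds)
            extra <- n %% scheme$nFolds
            if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
            if (any(sizes < 2))
                stop("fold with fewer than 2 individuals", call. = FALSE)
            labels <- integer(n)
            labels[perm] <- rep(seq_len(scheme$nFolds), times = sizes)
            labels
        })
    })
}

#' Repeated k-fold cross-validation of a GS model
#'
#' For every repeat, individuals are shuffled (seeded) and split into
#' contiguous folds; each fold is predicted from a model fit on the
#' remaining folds, held-out predictions are pooled across folds within
#' the repeat, and one Pearson accuracy per repeat is computed from the
#' pooled predictions. The default scheme is 20 repeats of 5-fold CV.
#'
#' @param y named phenotype vector.
#' @param Q,Z designs over the same individuals (see [buildDesign()]).
#' @param model `"gblup"` or `"bayesb"`.
#' @param scheme a [cvScheme()].
#' @param control [bayesbControl()] settings when `model = "bayesb"`.
#' @return numeric vector of per-repeat accuracies with attributes `mean`
#'   and `sd`.
#' @export
crossValidate <- function(y, Q, Z, model = c("gblup", "bayesb"),
                          scheme = cvScheme(), control = bayesbControl()) {
    model <- match.arg(model)
    al <- .alignPhenotypes(y, Q, Z)
    y <- setNames(al$y, al$ids); Q <- al$Q; Z <- al$Z
    n <- length(y)
    folds <- .makeFolds(n, scheme)
    acc <- vapply(folds, function(labels) {
        pred <- numeric(n)
        for (f in seq_len(scheme$nFolds)) {
            test <- labels == f
            fit <- if (model == "gblup")
                gblupFit(y[!test], Q[!test, , drop = FALSE],
                         Z[!test, , drop = FALSE])
            else
                bayesbFit(y[!test], Q[!test, , drop = FALSE],
                          Z[!test, , drop = FALSE], control = control)
            pred[test] <- predictGS(fit, Q[test, , drop = FALSE],
                                    Z[test, , drop = FALSE])
        }
        pearsonAccuracy(pred, y)
    }, numeric(1))
    structure(acc, mean = mean(acc), sd = sd(acc))
}

#' Across-population prediction run
#'
#' Fits a GS model on the training population (optionally reduced to a
#' MeanRel-optimized subset) and predicts every breeding individual. The
#' fit only ever receives training phenotypes, and any overlap between the
#' two individual sets raises a leakage error. The training allele
#' frequencies are frozen for centering the breeding genotypes, and
#' structure covariates — which must have been estimated jointly on the
#' combined individual set beforehand — are subset per population.
#'
#' @param trainGeno,breedGeno imputed [MarkerMatrix-class] objects sharing
#'   one harmonized ordered SNP set (see [intersectSnps()]).
#' @param trainPheno named phenotype vector over the training individuals.
#' @param breedPheno optional named phenotype vector over the breeding
#'   individuals, used only to compute the reported accuracy.
#' @param model `"gblup"` or `"bayesb"`.
#' @param covariates optional [StructureCovariates-class] covering both
#'   populations.
#' @param selection optional [TrainingSelection-class]; only its ids are
#'   used for fitting.
#' @param control [bayesbControl()] settings for BayesB.
#' @return a [PredictionResult-class] over the breeding individuals.
#' @export
acrossPopulationRun <- function(trainGeno, trainPheno, breedGeno,
                                breedPheno = NULL,
                                model = c("gblup", "bayesb"),
                                covariates = NULL, selection = NULL,
                                control = bayesbControl()) {
    model <- match.arg(model)
    stopifnot(is(trainGeno, "MarkerMatrix"), is(breedGeno, "MarkerMatrix"))
    if (!identical(snpIds(trainGeno), snpIds(breedGeno)))
        stop("marker-set mismatch between populations; run intersectSnps() first",
             call. = FALSE)
    overlap <- intersect(individualIds(trainGeno), individualIds(breedGeno))
    if (length(overlap))
        stop("leakage: individual(s) present in both populations: ",
             paste(head(overlap, 5), collapse = ", "), call. = FALSE)
    if (!is.null(selection)) {
        stopifnot(is(selection, "TrainingSelection"))
        trainGeno <- trainGeno[selectedIds(selection), ]
    }
    bd <- buildDesign(trainGeno, covariates)
    fit <- if (model == "gblup")
        gblupFit(trainPheno, bd$Q, bd$Z, centerFreqs = bd$centerFreqs)
    else
        bayesbFit(trainPheno, bd$Q, bd$Z, control = control,
                  centerFreqs = bd$centerFreqs)
    nd <- buildDesign(breedGeno, covariates, centerFreqs = bd$centerFreqs)
    pred <- predictGS(fit, nd$Q, nd$Z)
    ids <- individualIds(breedGeno)
    obs <- rep(NA_real_, length(ids))
    if (!is.null(breedPheno)) obs <- unname(breedPheno[ids])
    acc <- if (all(is.na(obs))) NA_real_ else pearsonAccuracy(pred, obs)
    new("PredictionResult", ids = ids, predicted = unname(pred),
        observed = obs, accuracy = acc,
        meta = list(model = model,
                    covariates = if (is.null(covariates)) "none"
                                 else covariates@kind,
                    trainingSize = length(individualIds(trainGeno))))
}

#' Relative accuracy improvement in percent
#'
#' `100 * (rNew - rBase) / rBase`, the improvement-ratio convention used
#' when comparing structure-aware models to a baseline.
#'
#' @param rNew,rBase accuracies to compare; `rBase` must be non-zero.
#' @return percentage improvement.
#' @export
improvementRatio <- function(rNew, rBase) {
    if (any(rBase == 0)) stop("baseline accuracy is zero", call. = FALSE)
    100 * (rNew - rBase) / rBase
}

#' Paired comparison of two CV accuracy vectors
#'
#' Paired two-sided t-test across the per-repeat accuracies of two models
#' evaluated under the same fold scheme.
#'
#' @param accA,accB per-repeat accuracy vectors of equal length.
#' @return an object of class `htest`.
#' @export
accuracyComparisonTest <- function(accA, accB) {
    if (length(accA) != length(accB))
        stop("accuracy vectors must be paired", call. = FALSE)
    t.test(as.numeric(accA), as.numeric(accB), paired = TRUE)
}

#' Run a full across-population experiment grid
#'
#' Executes the cross product of traits, models, structure-covariate
#' scenarios and (optionally) MeanRel training-set sizes as
#' across-population runs. Covariates are estimated once per scenario on
#' the combined training + breeding individual set before any split.
#' Scenario strings: `"none"`, `"pca"`, `"pam"`, `"qmatrix:K"` (e.g.
#' `"qmatrix:6"`).
#'
#' @param trainGeno,breedGeno imputed [MarkerMatrix-class] objects with a
#'   shared SNP set.
#' @param trainPheno,breedPheno long phenotype data.frames (id, trait,
#'   value).
#' @param traits trait names to evaluate (default: all in `trainPheno`).
#' @param models subset of `c("gblup", "bayesb")`.
#' @param scenarios covariate scenario strings.
#' @param trainingSizes optional MeanRel `top_n` sizes; `NULL` uses the
#'   full training set.
#' @param nComponents PCs for the `"pca"` scenario.
#' @param pamKRange candidate cluster counts for the `"pam"` scenario
#'   (chosen by silhouette).
#' @param seed seed for admixture initialization.
#' @param emMaxIter,emTol EM settings for the `"qmatrix"` scenarios.
#' @param control [bayesbControl()] settings for BayesB runs.
#' @return tidy data.frame with one row per scenario combination
#'   (trait, model, scenario, trainingSize, accuracy, nTrain, nBreed).
#' @export
runGrid <- function(trainGeno, trainPheno, breedGeno, breedPheno,
                    traits = unique(trainPheno$trait),
                    models = c("gblup", "bayesb"),
                    scenarios = c("none", "pca", "pam",
                                  paste0("qmatrix:", 3:7)),
                    trainingSizes = NULL, nComponents = 6, pamKRange = 2:8,
                    seed = 1, emMaxIter = 2000, emTol = 1e-4,
                    control = bayesbControl()) {
    models <- match.arg(models, several.ok = TRUE)
    combined <- MarkerMatrix(rbind(trainGeno@dosage, breedGeno@dosage),
                             trainGeno@snpMeta)
    kin <- NULL
    needKin <- "pam" %in% scenarios || !is.null(trainingSizes)
    if (needKin) kin <- computeKinship(combined)
    covs <- lapply(setNames(nm = scenarios), function(sc) {
        if (sc == "none") return(NULL)
        if (sc == "pca") return(pcaCovariates(combined, nComponents))
        if (sc == "pam") {
            k <- chooseNClusters(kin, pamKRange)$bestK
            labels <- pamCluster(kin, k)$labels
            return(onehotCovariates(labels, dropLast = TRUE))
        }
        if (grepl("^qmatrix:", sc)) {
            K <- as.integer(sub("^qmatrix:", "", sc))
            fit <- admixtureEM(combined, K, seed = seed,
                               maxIter = emMaxIter, tol = emTol)
            return(qmatrixCovariates(fit, dropLast = TRUE))
        }
        stop("unknown scenario: ", sc, call. = FALSE)
    })
    trainIds <- individualIds(trainGeno)
    breedIds <- individualIds(breedGeno)
    sizes <- if (is.null(trainingSizes)) NA_integer_ else trainingSizes
    rows <- list()
    for (trait in traits) {
        yTrain <- phenotypeVector(trainPheno, trait, trainIds)
        yBreed <- phenotypeVector(breedPheno, trait, breedIds)
        for (size in sizes) {
            sel <- NULL
            if (!is.na(size)) {
                scores <- meanRel(kin, trainIds, breedIds)
                sel <- selectTraining(scores, "top_n", n = size)
            }
            for (model in models) for (sc in scenarios) {
                res <- acrossPopulationRun(trainGeno, yTrain, breedGeno,
                                           yBreed, model = model,
                                           covariates = covs[[sc]],
                                           selection = sel,
                                           control = control)
                rows[[length(rows) + 1]] <- data.frame(
                    trait = trait, model = model, scenario = sc,
                    trainingSize = res@meta$trainingSize,
                    accuracy = accuracy(res),
                    nBreed = length(breedIds), stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}
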