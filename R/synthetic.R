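#' Configuration for the synthetic hybrid study generator
#'
#' Defines the conditions of a two-population hybrid study: shared admixed
#' founders with divergent ancestry proportions, fully homozygous inbred
#' parents, F1 hybrids from a maternal x paternal factorial (training
#' population) and from a sparse diallel (breeding population), a sparse
#' additive trait architecture, ancestry-linked intercept shifts
#' (structure confounding) and a target heritability.
#'
#' The defaults are a desk-scale replica of a large maize-hybrid study
#' design: a 40 x 10 factorial giving 400 training hybrids, a breeding
#' population of 100 hybrids from a sparse diallel over parents drawn from
#' five ancestral groups, 500 independent SNPs with Balding-Nichols-style
#' divergence 0.2, 50 QTL, h2 = 0.5, and structure-shift standard
#' deviation equal to the genetic standard deviation (`delta = 1`).
#'
#' @param seed master seed; the whole study is deterministic given it.
#' @param KTrue number of ancestral populations.
#' @param nSnps number of (independent) SNPs.
#' @param divergence Balding-Nichols divergence parameter in (0, 1).
#' @param nMothers,nFathers factorial dimensions of the training crosses.
#' @param nParents2 breeding-population parent count.
#' @param nCrosses2 breeding-population hybrid count (sparse diallel).
#' @param alpha1,alpha2 Dirichlet concentration vectors (length `KTrue`)
#'   for the two populations' ancestry draws; divergent by default.
#' @param nQtl number of causal loci.
#' @param h2 narrow-sense heritability target, in (0, 1) exclusive.
#' @param delta structure-confounding effect size: the ancestry-linked
#'   intercept shift is scaled to `delta` times the genetic SD.
#' @param hetRate residual parental heterozygosity rate (0 = idealized
#'   inbreds; > 0 exercises the missing-call/imputation path).
#' @param traitName trait label for the phenotype tables.
#' @return validated configuration list of class `simConfig`.
#' @export
simConfig <- function(seed = 1, KTrue = 5, nSnps = 500, divergence = 0.2,
                      nMothers = 40, nFathers = 10, nParents2 = 50,
                      nCrosses2 = 100,
                      alpha1 = c(2, 2, 2, 0.5, 0.5)[seq_len(KTrue)],
                      alpha2 = rev(c(2, 2, 2, 0.5, 0.5)[seq_len(KTrue)]),
                      nQtl = 50, h2 = 0.5, delta = 1, hetRate = 0,
                      traitName = "trait") {
    if (h2 <= 0 || h2 >= 1)
        stop("h2 must lie strictly inside (0, 1)", call. = FALSE)
    if (divergence <= 0 || divergence >= 1)
        stop("divergence must lie in (0, 1)", call. = FALSE)
    if (nQtl > nSnps) stop("nQtl cannot exceed nSnps", call. = FALSE)
    for (nm in c("KTrue", "nSnps", "nMothers", "nFathers", "nParents2",
                 "nCrosses2", "nQtl"))
        assign(nm, .assertScalarCount(get(nm), nm))
    if (length(alpha1) != KTrue || length(alpha2) != KTrue ||
        any(alpha1 <= 0) || any(alpha2 <= 0))
        stop("alpha vectors must be positive and of length KTrue",
             call. = FALSE)
    if (delta < 0) stop("delta must be >= 0", call. = FALSE)
    if (hetRate < 0 || hetRate >= 1)
        stop("hetRate must lie in [0, 1)", call. = FALSE)
    structure(list(seed = as.integer(seed), KTrue = KTrue, nSnps = nSnps,
                   divergence = divergence, nMothers = nMothers,
                   nFathers = nFathers, nParents2 = nParents2,
                   nCrosses2 = nCrosses2, alpha1 = alpha1, alpha2 = alpha2,
                   nQtl = nQtl, h2 = h2, delta = delta, hetRate = hetRate,
                   traitName = traitName), class = "simConfig")
}

#' Simulate diverged ancestral allele frequencies
#'
#' Balding-Nichols model: a shared ancestral frequency `p_j ~ U(0.1, 0.9)`
#' per SNP, and population-specific frequencies
#' `f_kj ~ Beta(p (1-c)/c, (1-p)(1-c)/c)` with `c` the divergence
#' parameter (the expected Fst-like differentiation among populations).
#'
#' @param K number of ancestral populations.
#' @param m number of SNPs.
#' @param divergence `c` in (0, 1).
#' @return K x m frequency matrix, entries strictly inside (0, 1).
#' @export
simulateFounderFrequencies <- function(K, m, divergence) {
    if (divergence <= 0 || divergence >= 1)
        stop("divergence must lie in (0, 1)", call. = FALSE)
    p <- runif(m, 0.1, 0.9)
    ratio <- (1 - divergence) / divergence
    f <- matrix(0, K, m)
    for (k in seq_len(K))
        f[k, ] <- stats::rbeta(m, p * ratio, (1 - p) * ratio)
    pmin(pmax(f, 1e-6), 1 - 1e-6)
}

#' Simulate admixed, fully homozygous inbred parents
#'
#' Each parent draws ancestry proportions `q ~ Dirichlet(alpha)`; its
#' per-SNP allele frequency is `pi_j = sum_k q_k f_kj` and the inbred
#' genotype is `2 * Bernoulli(pi_j)` (dosages 0/2 only). A positive
#' `hetRate` replaces that fraction of cells with `Binomial(2, pi_j)`
#' draws, injecting residual heterozygosity.
#'
#' @param freqs K x m ancestral frequency matrix.
#' @param nParents number of parents.
#' @param alpha Dirichlet concentration vector (length K).
#' @param prefix id prefix.
#' @param hetRate residual heterozygosity rate in \[0, 1).
#' @return list with `geno` ([MarkerMatrix-class]) and `Q` (true ancestry
#'   proportions, n x K).
#' @export
simulateInbredParents <- function(freqs, nParents, alpha, prefix = "p",
                                  hetRate = 0) {
    K <- nrow(freqs); m <- ncol(freqs)
    if (length(alpha) != K) stop("alpha must have length K", call. = FALSE)
    Q <- rdirichlet(nParents, alpha)
    Pi <- Q %*% freqs
    d <- matrix(2 * rbinom(nParents * m, 1, Pi), nParents, m)
    if (hetRate > 0) {
        het <- runif(nParents * m) < hetRate
        d[het] <- rbinom(sum(het), 2, Pi[het])
    }
    ids <- sprintf("%s%03d", prefix, seq_len(nParents))
    dimnames(d) <- list(ids, sprintf("snp%05d", seq_len(m)))
    rownames(Q) <- ids
    colnames(Q) <- paste0("anc", seq_len(K))
    list(geno = MarkerMatrix(d), Q = Q)
}

#' Simulate a crossing design and the resulting F1 hybrids
#'
#' `"factorial"` crosses every mother with every father;
#' `"sparse_diallel"` samples `nCrosses` unordered parent pairs (no
#' self-crosses) from one parent pool. Hybrid genotypes come from
#' [inferHybridGenotypes()], so with fully homozygous parents they carry
#' no missing calls by construction.
#'
#' @param parents [MarkerMatrix-class] of the parents.
#' @param design `"factorial"` or `"sparse_diallel"`.
#' @param mothers,fathers parent id vectors (factorial design).
#' @param nCrosses number of crosses to sample (sparse diallel).
#' @param prefix hybrid id prefix.
#' @return list with `crosses` (hybrid/mother/father table) and `hybrids`
#'   ([MarkerMatrix-class]).
#' @export
simulateCrosses <- function(parents, design = c("factorial", "sparse_diallel"),
                            mothers = NULL, fathers = NULL, nCrosses = NULL,
                            prefix = "h") {
    design <- match.arg(design)
    if (design == "factorial") {
        if (is.null(mothers) || is.null(fathers))
            stop("factorial design needs mother and father id vectors",
                 call. = FALSE)
        pairs <- expand.grid(mother = mothers, father = fathers,
                             stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
    } else {
        ids <- individualIds(parents)
        all <- utils::combn(ids, 2)
        nAvail <- ncol(all)
        nCrosses <- .assertScalarCount(nCrosses, "nCrosses")
        if (nCrosses > nAvail)
            stop("requested ", nCrosses, " crosses but only ", nAvail,
                 " distinct parent pairs exist", call. = FALSE)
        sel <- sample.int(nAvail, nCrosses)
        pairs <- data.frame(mother = all[1, sel], father = all[2, sel],
                            stringsAsFactors = FALSE)
    }
    if (any(pairs$mother == pairs$father))
        stop("self-crosses are not allowed", call. = FALSE)
    crosses <- makeCrossTable(sprintf("%s%04d", prefix, seq_len(nrow(pairs))),
                              pairs$mother, pairs$father)
    list(crosses = crosses,
         hybrids = inferHybridGenotypes(parents, crosses))
}

#' Simulate phenotypes with a sparse additive architecture
#'
#' Samples `nQtl` causal loci with N(0, 1) effects; the genetic value is
#' the centered-dosage weighted effect sum. Structure confounding adds an
#' ancestry-linked shift: the projection of each individual's true
#' ancestry row onto a population-shift vector, standardized and scaled to
#' `delta` times the genetic SD. Residual noise is scaled so
#' `var(g) / (var(g) + varE) = h2` on the realized genetic values.
#'
#' @param hybrids imputed [MarkerMatrix-class] of the phenotyped
#'   individuals.
#' @param QTrue true ancestry proportions (n x K, rows aligned).
#' @param nQtl number of causal loci.
#' @param h2 target heritability, in (0, 1) exclusive.
#' @param delta structure-confounding size (in genetic-SD units).
#' @param shiftVector optional length-K ancestry shift direction
#'   (defaults to a N(0, 1) draw).
#' @param traitName trait label.
#' @return list with `pheno` (long data.frame id/trait/value) and `truth`
#'   (qtl indices, effects, genetic values, shift, h2).
#' @export
simulatePhenotypes <- function(hybrids, QTrue, nQtl, h2, delta = 0,
                               shiftVector = NULL, traitName = "trait") {
    if (h2 <= 0 || h2 >= 1)
        stop("h2 must lie strictly inside (0, 1); h2 = 1 is not a valid target",
             call. = FALSE)
    .assertImputed(hybrids, "simulatePhenotypes")
    d <- hybrids@dosage
    n <- nrow(d); m <- ncol(d)
    nQtl <- .assertScalarCount(nQtl, "nQtl")
    if (nQtl > m) stop("nQtl cannot exceed the SNP count", call. = FALSE)
    qtl <- sort(sample.int(m, nQtl))
    effects <- rnorm(nQtl)
    Zq <- sweep(d[, qtl, drop = FALSE], 2, colMeans(d[, qtl, drop = FALSE]))
    g <- drop(Zq %*% effects)
    if (var(g) == 0)
        stop("zero genetic variance: sampled QTL are all monomorphic",
             call. = FALSE)
    shift <- rep(0, n)
    if (delta > 0) {
        if (is.null(shiftVector)) shiftVector <- rnorm(ncol(QTrue))
        raw <- drop(QTrue[individualIds(hybrids), , drop = FALSE] %*% shiftVector)
        if (sd(raw) > 0)
            shift <- delta * sd(g) * (raw - mean(raw)) / sd(raw)
    }
    varE <- var(g) * (1 - h2) / h2
    e <- rnorm(n, 0, sqrt(varE))
    y <- g + shift + e
    list(pheno = data.frame(id = individualIds(hybrids), trait = traitName,
                            value = y, stringsAsFactors = FALSE),
         truth = list(qtl = qtl, effects = effects, gvalues = g,
                      shift = shift, shiftVector = shiftVector, h2 = h2,
                      varE = varE))
}

#' Simulate a complete two-population hybrid study
#'
#' Orchestrates the generator: shared ancestral founder frequencies, two
#' admixed inbred parent pools with divergent ancestry proportions, a
#' maternal x paternal factorial training population and a sparse-diallel
#' breeding population, and one jointly simulated trait (one QTL set and
#' one ancestry-shift direction across both populations, as required for
#' across-population prediction to be meaningful). Fully deterministic
#' given `config$seed`.
#'
#' @param config a [simConfig()].
#' @return list with `trainGeno`, `breedGeno` ([MarkerMatrix-class]),
#'   `trainPheno`, `breedPheno` (long data.frames), `crosses1`, `crosses2`,
#'   `parents1`, `parents2`, and `truth` (founder frequencies, true Q per
#'   parent and hybrid, QTL, genetic values, shifts).
#' @export
simulateStudy <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    withSeed(config$seed, {
        freqs <- simulateFounderFrequencies(config$KTrue, config$nSnps,
                                            config$divergence)
        par1 <- simulateInbredParents(freqs,
                                      config$nMothers + config$nFathers,
                                      config$alpha1, prefix = "t",
                                      hetRate = config$hetRate)
        par2 <- simulateInbredParents(freqs, config$nParents2,
                                      config$alpha2, prefix = "b",
                                      hetRate = config$hetRate)
        ids1 <- individualIds(par1$geno)
        cr1 <- simulateCrosses(par1$geno, "factorial",
                               mothers = ids1[seq_len(config$nMothers)],
                               fathers = ids1[config$nMothers +
                                              seq_len(config$nFathers)],
                               prefix = "T")
        cr2 <- simulateCrosses(par2$geno, "sparse_diallel",
                               nCrosses = config$nCrosses2, prefix = "B")
        hyb1 <- cr1$hybrids
        hyb2 <- cr2$hybrids
        if (anyNA(hyb1@dosage)) hyb1 <- imputeMissing(hyb1, "mean")
        if (anyNA(hyb2@dosage)) hyb2 <- imputeMissing(hyb2, "mean")
        hybQ <- function(cr, Q) {
            (Q[cr$crosses$mother, , drop = FALSE] +
             Q[cr$crosses$father, , drop = FALSE]) / 2
        }
        Q1 <- hybQ(cr1, par1$Q); rownames(Q1) <- cr1$crosses$hybrid
        Q2 <- hybQ(cr2, par2$Q); rownames(Q2) <- cr2$crosses$hybrid
        combined <- MarkerMatrix(rbind(hyb1@dosage, hyb2@dosage),
                                 hyb1@snpMeta)
        QAll <- rbind(Q1, Q2)
        ph <- simulatePhenotypes(combined, QAll, config$nQtl, config$h2,
                                 delta = config$delta,
                                 traitName = config$traitName)
        isTrain <- ph$pheno$id %in% cr1$crosses$hybrid
        list(trainGeno = hyb1, breedGeno = hyb2,
             trainPheno = ph$pheno[isTrain, ],
             breedPheno = ph$pheno[!isTrain, ],
             crosses1 = cr1$crosses, crosses2 = cr2$crosses,
             parents1 = par1$geno, parents2 = par2$geno,
             truth = c(ph$truth,
                       list(founderFreqs = freqs, QParents1 = par1$Q,
                            QParents2 = par2$Q, QTrain = Q1, QBreed = Q2)),
             config = config)
    })
}
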