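# Programmatic fixtures shared across the suite.

# Random 0/1/2 dosage matrix with optional missing rate.
randomMarkerMatrix <- function(n, m, missingRate = 0, seed = NULL,
                               prefix = "i") {
    draw <- function() {
        p <- runif(m, 0.1, 0.9)
        d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
                    dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                                    sprintf("s%04d", seq_len(m))))
        if (missingRate > 0)
            d[runif(n * m) < missingRate] <- NA_real_
        MarkerMatrix(d)
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Unstructured simulated genotypes + sparse additive phenotypes, for the
# model-recovery checks.
simGSInstance <- function(n, m, nQtl, h2, seed) {
    withr::with_seed(seed, {
        p <- simulateInbredParents(simulateFounderFrequencies(1, m, 0.2),
                                   n, c(1))
        ph <- simulatePhenotypes(p$geno, p$Q, nQtl, h2)
        bd <- buildDesign(p$geno)
        list(geno = p$geno, Q = bd$Q, Z = bd$Z,
             y = setNames(ph$pheno$value, ph$pheno$id),
             truth = ph$truth, centerFreqs = bd$centerFreqs)
    })
}

# Minimal single-chromosome VCF text fixture (3 samples, 5 records: one
# multi-allelic, one with a missing call, one with a half call).
writeTinyVcf <- function(path) {
    lines <- c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "sampleA", "sampleB", "sampleC",
              sep = "\t"),
        paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
              "0/0", "0/1", "1/1", sep = "\t"),
        paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
              "./.", "0|1", "1|1", sep = "\t"),
        paste("1", "300", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
              "0/1", "0/2", "1/2", sep = "\t"),
        paste("1", "400", ".", "T", "C", ".", "PASS", ".", "GT",
              "1/1", "0/0", "./0", sep = "\t"),
        paste("2", "150", "rs5", "G", "C", ".", "PASS", ".", "GT",
              "0/0", "0/0", "0/1", sep = "\t"))
    writeLines(lines, path)
    path
}

# Total PAM cost of assigning every point to its nearest medoid.
pamAssignmentCost <- function(d, medoids) {
    sum(apply(d[, medoids, drop = FALSE], 1, min))
}

# Exhaustive k = 2 medoid search.
bruteForcePamCost <- function(d) {
    n <- nrow(d)
    pairs <- utils::combn(n, 2)
    min(apply(pairs, 2, function(pr) pamAssignmentCost(d, pr)))
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumIj <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    nAll <- comb2(sum(tab))
    expected <- sumI * sumJ / nAll
    (sumIj - expected) / ((sumI + sumJ) / 2 - expected)
}
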