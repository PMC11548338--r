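test_that("VCF genotypes decode to alt-allele dosages with missing handling", {
    vcf <- writeTinyVcf(withr::local_tempfile(fileext = ".vcf"))
    expect_message(g <- readGenotypes(vcf), "multi-allelic")
    # the multi-allelic record is skipped
    expect_equal(snpIds(g), c("rs1", "rs2", "1_400", "rs5"))
    expect_equal(individualIds(g), c("sampleA", "sampleB", "sampleC"))
    d <- dosage(g)
    expect_equal(unname(d[, "rs1"]), c(0, 1, 2))
    expect_true(is.na(d["sampleA", "rs2"]))          # ./.
    expect_equal(unname(d[c("sampleB", "sampleC"), "rs2"]), c(1, 2))  # phased
    expect_true(is.na(d["sampleC", "1_400"]))        # half call
    expect_equal(snpMeta(g)$pos, c(100L, 200L, 400L, 150L))
    expect_equal(snpMeta(g)$alt, c("G", "T", "C", "C"))
})

test_that("dosage-TSV write/read round trip is lossless", {
    g <- randomMarkerMatrix(3, 2, missingRate = 0.3, seed = 5)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypes(g, path)
    g2 <- readGenotypes(path, format = "tsv")
    expect_identical(dosage(g2), dosage(g))
    # writing the re-read matrix reproduces the file byte-for-byte
    path2 <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypes(g2, path2)
    expect_identical(readBin(path, "raw", file.size(path)),
                     readBin(path2, "raw", file.size(path2)))
    # 1 x 1 matrix round-trips too
    g1 <- g[1, 1]
    writeGenotypes(g1, path)
    expect_identical(dosage(readGenotypes(path, "tsv")), dosage(g1))
})

test_that("empty and malformed genotype inputs error clearly", {
    g <- randomMarkerMatrix(3, 2, seed = 1)
    expect_error(writeGenotypes(g[, integer(0)], tempfile()), "empty")
    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("wrong\theader", "a\t1"), bad)
    expect_error(readGenotypes(bad, "tsv"), "header")
    dup <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id\ts1", "a\t1", "a\t2"), dup)
    expect_error(readGenotypes(dup, "tsv"), "duplicate")
    expect_error(readGenotypes(tempfile(), "tsv"), "not found")
})

test_that("hybrid genotypes follow Mendelian F1 rules of homozygous parents", {
    d <- rbind(mom1 = c(0, 2, 1, 0),
               mom2 = c(2, 2, 0, NA),
               dad1 = c(2, 2, 0, 2))
    colnames(d) <- paste0("s", 1:4)
    parents <- MarkerMatrix(d)
    crosses <- makeCrossTable(c("h1", "h2"), c("mom1", "mom2"),
                              c("dad1", "dad1"))
    h <- inferHybridGenotypes(parents, crosses)
    expect_equal(unname(dosage(h)["h1", c("s1", "s2")]), c(1, 2))
    expect_true(is.na(dosage(h)["h1", "s3"]))   # heterozygous mother
    expect_true(is.na(dosage(h)["h2", "s4"]))   # missing mother call
    expect_error(inferHybridGenotypes(parents,
                                      makeCrossTable("x", "ghost", "dad1")),
                 "ghost")
})

test_that("fully homozygous parents give complete hybrid dosages equal to the parental mean", {
    withr::with_seed(21, {
        f <- simulateFounderFrequencies(2, 60, 0.2)
        par <- simulateInbredParents(f, 12, c(1, 1))
        cr <- simulateCrosses(par$geno, "sparse_diallel", nCrosses = 20)
    })
    H <- dosage(cr$hybrids)
    expect_false(anyNA(H))
    M <- dosage(par$geno)[cr$crosses$mother, ]
    P <- dosage(par$geno)[cr$crosses$father, ]
    expect_equal(unname(H), unname((M + P) / 2))
})

test_that("imputation fills by per-SNP mean or mode and is identity without missingness", {
    d <- rbind(a = c(0, 0, 1), b = c(2, 0, 1), c = c(NA, 2, 1),
               d = c(NA, NA, 1))
    colnames(d) <- paste0("s", 1:3)
    g <- MarkerMatrix(d)
    gm <- imputeMissing(g, "mean")
    expect_equal(unname(dosage(gm)[c("c", "d"), "s1"]), c(1, 1))
    expect_equal(unname(dosage(gm)["d", "s2"]), 2 / 3)
    gmo <- imputeMissing(g, "mode")
    expect_equal(unname(dosage(gmo)[c("c", "d"), "s1"]), c(0, 0))
    full <- randomMarkerMatrix(4, 3, seed = 2)
    expect_identical(dosage(imputeMissing(full, "mean")), dosage(full))
    allNA <- MarkerMatrix(matrix(NA_real_, 2, 1,
                                 dimnames = list(c("a", "b"), "bad")))
    expect_error(imputeMissing(allNA), "bad")
})

test_that("mode imputation breaks ties toward the lower dosage", {
    d <- matrix(c(0, 2, NA), 3, 1, dimnames = list(letters[1:3], "s1"))
    expect_equal(unname(dosage(imputeMissing(MarkerMatrix(d), "mode"))["c", ]),
                 0)
})

test_that("MAF filtering matches a brute-force per-SNP recount", {
    # boundary examples
    d <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 0), d = c(2, 1))
    colnames(d) <- c("common", "rare")   # p = 0.5 and p = 0.125
    g <- MarkerMatrix(d)
    expect_equal(snpIds(filterMAF(g, 0.05)), c("common", "rare"))
    expect_equal(snpIds(filterMAF(g, 0.2)), "common")
    expect_error(filterMAF(g, 0.6), "threshold")
    # derived oracle on a 1000-SNP matrix
    big <- randomMarkerMatrix(100, 1000, seed = 9)
    kept <- filterMAF(big, 0.05)
    mafs <- vapply(seq_len(1000), function(j) {
        p <- mean(dosage(big)[, j]) / 2
        min(p, 1 - p)
    }, numeric(1))
    expect_equal(snpIds(kept), snpIds(big)[mafs >= 0.05])
    # idempotence
    expect_identical(dosage(filterMAF(kept, 0.05)), dosage(kept))
})

test_that("SNP intersection harmonizes order, ids and allele swaps", {
    meta <- function(chrom, pos, ref, alt, ids)
        data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   row.names = ids)
    da <- matrix(c(0, 1, 2, 2, 1, 0), 2, 3,
                 dimnames = list(c("x", "y"), c("s1", "s2", "s3")))
    db <- matrix(c(2, 1, 0, 2, 2, 2), 2, 3,
                 dimnames = list(c("u", "v"), c("t2", "t3", "t4")))
    a <- MarkerMatrix(da, meta("1", c(10L, 20L, 30L), c("A", "C", "G"),
                               c("G", "T", "A"), colnames(da)))
    # t2 matches s2 with swapped ref/alt; t3 matches s3 unchanged
    b <- MarkerMatrix(db, meta("1", c(20L, 30L, 40L), c("T", "G", "A"),
                               c("C", "A", "C"), colnames(db)))
    out <- intersectSnps(a, b)
    expect_identical(snpIds(out$a), snpIds(out$b))
    expect_equal(snpIds(out$a), c("s2", "s3"))
    expect_equal(unname(dosage(out$b)[, "s2"]), c(0, 1))  # flipped 2,1
    expect_equal(unname(dosage(out$b)[, "s3"]), c(0, 2))  # unchanged
    # without metadata matching falls back to SNP ids, which here share none
    expect_error(intersectSnps(MarkerMatrix(da), MarkerMatrix(db)),
                 "no shared SNPs")
})

test_that("disjoint SNP sets raise an error and shared ids intersect", {
    a <- randomMarkerMatrix(2, 3, seed = 1)
    b <- randomMarkerMatrix(2, 3, seed = 2)
    colnames(b@dosage) <- paste0("other", 1:3)
    expect_error(intersectSnps(a, b), "no shared SNPs")
    c <- b
    colnames(c@dosage) <- c("s0001", "zzz", "s0003")
    out <- intersectSnps(a, MarkerMatrix(c@dosage))
    expect_equal(snpIds(out$a), c("s0001", "s0003"))
    expect_identical(snpIds(out$a), snpIds(out$b))
})

test_that("phenotype and cross tables validate and round-trip", {
    ph <- data.frame(id = c("a", "b"), trait = "tr", value = c(1.5, 2.5))
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(ph, path, row.names = FALSE)
    back <- readPhenotypes(path)
    expect_equal(back$value, c(1.5, 2.5))
    y <- phenotypeVector(back, "tr", c("b", "a", "c"))
    expect_equal(unname(y), c(2.5, 1.5, NA))
    expect_error(phenotypeVector(back, "nope"), "not found")
    expect_error(makeCrossTable(c("h", "h"), c("m", "m"), c("f", "f")),
                 "duplicate")
})
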