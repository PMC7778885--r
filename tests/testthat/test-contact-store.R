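test_that("triples round-trip and fold symmetrically", {
    set.seed(11)
    bt <- makeBinTable(c(chr1 = 30 * 1e4, chr2 = 20 * 1e4), 1e4)
    dense <- randomDenseCounts(nBins(bt))
    cm <- denseToContactMatrix(bt, dense)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeContacts(cm, path)
    cm2 <- readContacts(path, bt)
    expect_equal(contactCounts(cm2), contactCounts(cm))

    # (i,j) and (j,i) records sum into one entry
    path2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("chr1\t0\tchr1\t10000\t3", "chr1\t10000\tchr1\t0\t4"), path2)
    cm3 <- readContacts(path2, bt)
    expect_equal(contactCounts(cm3, i = 0L, j = 1L), 7)
    expect_equal(contactCounts(cm3, i = 1L, j = 0L), 7)

    # empty file gives the all-zero matrix
    path3 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(character(), path3)
    expect_equal(sum(contactCounts(readContacts(path3, bt))), 0)

    # format errors
    path4 <- withr::local_tempfile(fileext = ".tsv")
    writeLines("chr1\t5000\tchr1\t10000\t3", path4)  # start off the bin grid
    expect_error(readContacts(path4, bt), "binsize")
    writeLines("chr1\t0\tchr1\t10000\t-3", path4)
    expect_error(readContacts(path4, bt), "negative")
    writeLines("chr9\t0\tchr1\t10000\t3", path4)
    expect_error(readContacts(path4, bt), "unknown chromosome")
})

test_that("coverage marginals sum symmetrically with the diagonal once", {
    bt <- makeBinTable(c(c1 = 200), 100)
    cm <- contactMatrix(bt, i = c(0L, 0L, 1L), j = c(0L, 1L, 1L), x = c(4, 2, 6))
    expect_equal(coverageProfile(cm), c(6, 8))
    expect_equal(coverageProfile(contactMatrix(bt)), c(0, 0))

    # marginals permute with the bins
    set.seed(3)
    bt4 <- makeBinTable(c(c1 = 800), 100)
    dense <- randomDenseCounts(8)
    perm <- sample(8)
    m1 <- coverageProfile(denseToContactMatrix(bt4, dense))
    m2 <- coverageProfile(denseToContactMatrix(bt4, dense[perm, perm]))
    expect_equal(m2, m1[perm])
})

test_that("coverage normalization preserves mass and profile shape", {
    set.seed(5)
    bt <- makeBinTable(c(c1 = 1200), 100)
    dense <- randomDenseCounts(12) + 1L  # strictly positive marginals
    cm <- coverageNormalize(denseToContactMatrix(bt, dense))
    expect_equal(sum(cm@values@x), sum(cm@counts@x), tolerance = 1e-9)

    # equal marginals: values proportional to counts
    btE <- makeBinTable(c(c1 = 300), 100)
    cmE <- contactMatrix(btE, i = c(0L, 1L, 2L), j = c(1L, 2L, 0L), x = c(5, 5, 5))
    cmE <- coverageNormalize(cmE)
    ratio <- cmE@values@x / cmE@counts@x
    expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)

    # dense-arithmetic oracle for the marginal-product rescaling, including a
    # matrix with one doubled row/column (marginal m_i scales accordingly)
    for (mat in list(dense, {
        d2 <- dense; d2[3, ] <- d2[3, ] * 2; d2[, 3] <- t(d2)[, 3]; d2
    })) {
        marg <- rowSums(mat)  # diagonal once: dense already stores it once
        raw <- mat / outer(marg, marg)
        up <- upper.tri(mat, diag = TRUE)
        S <- sum(mat[up]) / sum(raw[up])
        got <- as.matrix(contactValues(coverageNormalize(denseToContactMatrix(bt, mat))))
        expect_equal(got, raw * S, tolerance = 1e-9, ignore_attr = TRUE)
    }

    expect_error(coverageNormalize(contactMatrix(bt)), "all-zero")

    # zero-coverage bins are flagged and yield zero
    denseZ <- dense; denseZ[5, ] <- 0; denseZ[, 5] <- 0
    cmZ <- coverageNormalize(denseToContactMatrix(bt, denseZ))
    expect_true(4L %in% cmZ@zeroCoverage)
    expect_equal(as.matrix(contactValues(cmZ))[5, ], rep(0, 12))
})

test_that("expected-by-distance is the mean over all cis pairs", {
    # 3-bin chromosome, d=1 values {4, 8} over exactly 2 pairs -> mean 6
    bt <- makeBinTable(c(c1 = 300), 100)
    cm <- contactMatrix(bt, i = c(0L, 1L), j = c(1L, 2L), x = c(4, 8))
    prof <- expectedByDistance(cm, scope = "pooled", smoothWindow = 1)
    expect_equal(expectedAt(prof, 1), 6)

    # constant on each diagonal: expected equals the constant, smoothing a no-op
    n <- 12L
    btc <- makeBinTable(c(c1 = n * 100), 100)
    dense <- outer(1:n, 1:n, function(i, j) 50 / (1 + abs(i - j)))
    cmc <- denseToContactMatrix(btc, dense)
    prof1 <- expectedByDistance(cmc, scope = "pooled", smoothWindow = 1)
    expect_equal(prof1@pooled, 50 / (1 + 0:(n - 1)))
    # smoothing on an exact power law in log space deviates from the raw
    # profile by less than the inter-distance spacing, and is positive
    prof3 <- expectedByDistance(cmc, scope = "pooled", smoothWindow = 3)
    expect_true(all(prof3@pooled > 0))

    # structural zeros count in the denominator
    btz <- makeBinTable(c(c1 = 400), 100)
    cmz <- contactMatrix(btz, i = 0L, j = 1L, x = 9)  # other d=1 pairs are zero
    profz <- expectedByDistance(cmz, scope = "pooled", smoothWindow = 1)
    expect_equal(expectedAt(profz, 1), 3)  # 9 / 3 pairs

    expect_error(expectedAt(profz, 99), "missing profile distance")
})

test_that("distance normalization yields fold changes around 1", {
    n <- 15L
    bt <- makeBinTable(c(c1 = n * 100), 100)
    dense <- outer(1:n, 1:n, function(i, j) 40 / (1 + abs(i - j))^0.8)
    cm <- denseToContactMatrix(bt, dense)
    cm <- distanceNormalize(cm, expectedByDistance(cm, smoothWindow = 1))
    expect_equal(range(cm@values@x), c(1, 1), tolerance = 1e-9)

    # hand example: d=1 values {4, 8}, expected 6 -> FC {0.667, 1.333}
    bt3 <- makeBinTable(c(c1 = 300), 100)
    cm3 <- contactMatrix(bt3, i = c(0L, 1L), j = c(1L, 2L), x = c(4, 8))
    cm3 <- distanceNormalize(cm3, expectedByDistance(cm3, scope = "pooled",
                                                     smoothWindow = 1))
    expect_equal(contactValues(cm3, i = c(0L, 1L), j = c(1L, 2L)),
                 c(4 / 6, 8 / 6))

    # FC invariant to global scaling; trans pairs divided by the trans mean
    set.seed(8)
    bt2 <- makeBinTable(c(chr1 = 1000, chr2 = 800), 100)
    dense2 <- randomDenseCounts(nBins(bt2)) + 1L
    fc1 <- {
        a <- distanceNormalize(denseToContactMatrix(bt2, dense2))
        as.matrix(contactValues(a))
    }
    fc5 <- {
        a <- distanceNormalize(denseToContactMatrix(bt2, dense2 * 5L))
        as.matrix(contactValues(a))
    }
    expect_equal(fc5, fc1, tolerance = 1e-12)

    trans <- dense2[1:10, 11:18]
    expect_equal(fc1[1, 11], dense2[1, 11] / mean(trans), tolerance = 1e-9)
})

test_that("mean cis fold change at each distance is 1 by construction", {
    set.seed(21)
    bt <- makeBinTable(c(chr1 = 4000, chr2 = 2500), 100)
    dense <- randomDenseCounts(nBins(bt))
    cm <- distanceNormalize(denseToContactMatrix(bt, dense),
                            expectedByDistance(denseToContactMatrix(bt, dense),
                                               smoothWindow = 1))
    fc <- as.matrix(contactValues(cm))
    for (chrom in list(1:40, 41:65)) {
        sub <- fc[chrom, chrom]
        for (d in 1:5) {
            vals <- sub[col(sub) - row(sub) == d]
            expect_equal(mean(vals), 1, tolerance = 1e-6)
        }
    }
    # symmetry preserved by every operation
    expect_equal(fc, t(fc))
    cn <- coverageNormalize(denseToContactMatrix(bt, dense + 1L))
    vv <- as.matrix(contactValues(cn))
    expect_equal(vv, t(vv))
})

test_that("interaction tables export as 7-column BED pairs", {
    bt <- makeBinTable(c(c1 = 300), 100)
    cm <- contactMatrix(bt, i = c(0L, 1L), j = c(1L, 2L), x = c(4, 8))
    cm <- distanceNormalize(cm, expectedByDistance(cm, scope = "pooled",
                                                   smoothWindow = 1))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeInteractionTable(cm, path)
    df <- read.table(path, sep = "\t")
    expect_equal(ncol(df), 7L)
    expect_equal(df$V2, c(0, 100))
    expect_equal(df$V7, c(4 / 6, 8 / 6), tolerance = 1e-9)
})
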