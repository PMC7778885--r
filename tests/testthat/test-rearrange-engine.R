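toyBinMap <- function(nbins = 6L, binsize = 100) {
    bt <- makeBinTable(c(chrT = nbins * binsize), binsize)
    identityBinMap(bt, "chrT")
}

test_that("single edits act on the current derivative axis", {
    bm <- toyBinMap(6L)
    inv <- applyEdit(bm, editOp("invert", start = 2L, end = 5L))
    expect_equal(entries(inv)$sourceBin, c(0L, 4L, 3L, 2L, 1L, 5L))
    expect_equal(entries(inv)$orientation, c("+", rep("-", 4), "+"))
    # involution
    expect_equal(entries(applyEdit(inv, editOp("invert", start = 2L, end = 5L))),
                 entries(bm))

    del <- applyEdit(bm, editOp("delete", start = 3L, end = 4L))
    expect_equal(entries(del)$sourceBin, c(0L, 1L, 4L, 5L))

    dup <- applyEdit(bm, editOp("duplicate", start = 3L, end = 4L))
    expect_equal(entries(dup)$sourceBin, c(0L, 1L, 2L, 3L, 2L, 3L, 4L, 5L))

    expect_error(applyEdit(bm, editOp("delete", start = 0L, end = 2L)), "out of range")
    expect_error(applyEdit(bm, editOp("delete", start = 2L, end = 9L)), "out of range")
    expect_error(applyEdit(bm, editOp("join")), "list")
})

test_that("join fuses the selected sides of two derivatives", {
    bt <- makeBinTable(c(chrA = 600, chrB = 400), 100)
    maps <- list(derA = identityBinMap(bt, "chrA"), derB = identityBinMap(bt, "chrB"))
    # 3' side of derA cut 3 with 5' side of derB cut 1: [0,1,2] + [7,8,9]
    joined <- applyEdit(maps, editOp("join", der = "derA", cut = 3L, side = 3L,
                                     der2 = "derB", cut2 = 1L, side2 = 5L))
    expect_length(joined, 1L)
    expect_equal(entries(joined$derA)$sourceBin, c(0L, 1L, 2L, 7L, 8L, 9L))
    # 5'/3' sides require flips so the cut ends meet
    maps2 <- list(derA = identityBinMap(bt, "chrA"), derB = identityBinMap(bt, "chrB"))
    j2 <- applyEdit(maps2, editOp("join", der = "derA", cut = 4L, side = 5L,
                                  der2 = "derB", cut2 = 2L, side2 = 3L))
    expect_equal(entries(j2$derA)$sourceBin, c(5L, 4L, 7L, 6L))
    expect_equal(entries(j2$derA)$orientation, rep("-", 4))
    expect_error(applyEdit(maps2, editOp("join", der = "derA", cut = 0L, side = 3L,
                                         der2 = "derB", cut2 = 1L, side2 = 5L)),
                 "empty")
})

test_that("edit sequences fold left with an undo stack", {
    bm <- toyBinMap(20L)
    # empty edit list is the identity
    s0 <- applyEditSequence(bm, list())
    expect_equal(entries(sessionBinMaps(s0)$der1), entries(bm))

    # deletion followed by inversion equals the brute-force list editor
    edits <- list(editOp("delete", "der1", start = 5L, end = 9L),
                  editOp("invert", "der1", start = 3L, end = 8L))
    s <- applyEditSequence(bm, edits)
    state <- oracleIdentity(20L)
    for (e in edits) state <- oracleApply(state, e)
    expect_equal(entries(sessionBinMaps(s)$der1)$sourceBin, state$der1$bin)
    expect_equal(entries(sessionBinMaps(s)$der1)$orientation, state$der1$orient)

    # k edits then k undos returns the original
    s2 <- s
    for (i in seq_along(edits)) s2 <- undoEdit(s2)
    expect_equal(entries(sessionBinMaps(s2)$der1), entries(bm))
    expect_error(undoEdit(s2), "nothing to undo")

    # the first invalid edit aborts with its index
    bad <- list(editOp("delete", "der1", start = 1L, end = 2L),
                editOp("invert", "der1", start = 30L, end = 40L))
    expect_error(applyEditSequence(bm, bad), "edit 2 invalid")
})

test_that("order specs parse, convert coordinates, and round-trip", {
    bt <- makeBinTable(c(chr1 = 300000, chr2 = 300000), 100000)
    ders <- parseOrderSpec("der1\tchr1:1-200000+;chr2:100001-300000-", bt)
    expect_equal(fragments(ders$der1),
                 data.frame(chrom = c("chr1", "chr2"), start = c(0, 100000),
                            end = c(200000, 300000), strand = c("+", "-")))

    ident <- parseOrderSpec("whole\tchr1:1-300000", bt)
    expect_equal(entries(derivativeToBinMap(bt, ident$whole))$sourceBin, 0:2)

    two <- parseOrderSpec(c("derA\tchr1:1-300000+", "derB\tchr2:1-300000-"), bt)
    expect_length(two, 2L)
    cm <- denseToContactMatrix(bt, randomDenseCounts(6))
    rm <- materialize(cm, lapply(two, derivativeToBinMap, bt = bt))
    expect_equal(rm@derivativeBoundaries, 3L)

    # serialize -> parse round trip
    expect_equal(lapply(parseOrderSpec(formatOrderSpec(ders), bt), fragments),
                 lapply(ders, fragments))

    expect_error(parseOrderSpec("d\tchr1:1-200000junk", bt), "cannot parse")
    expect_error(parseOrderSpec("d\tchr1:200-100", bt), "start > end")
    expect_error(parseOrderSpec("d\tchr9:1-100", bt), "unknown chromosome")
    expect_error(parseOrderSpec("justonefield", bt), "expected")
})

test_that("edit scripts parse and round-trip", {
    txt <- c("# a comment", "DEL der1:12-40", "INV der1:5-9", "DUP der1:20-24",
             "JOIN der1:15/3 der2:0/5")
    edits <- parseEditScript(txt)
    expect_length(edits, 4L)
    expect_equal(edits[[1L]]$kind, "delete")
    expect_equal(edits[[4L]]$cut2, 0L)
    expect_equal(formatEditScript(parseEditScript(formatEditScript(edits))),
                 formatEditScript(edits))
    expect_error(parseEditScript("SPLICE der1:1-2"), "unknown edit")
    expect_error(parseEditScript("JOIN der1:15/4 der2:0/5"), "cannot parse")
})

test_that("materialization reproduces sources, weights, and hand examples", {
    bt <- makeBinTable(c(chrA = 300), 100)
    M <- matrix(c(10, 5, 1, 5, 8, 4, 1, 4, 9), 3, 3)
    cm <- denseToContactMatrix(bt, M)

    # identity is bit-exact
    expect_identical(rearrangedMatrix(materialize(cm, identityBinMap(bt))), M)

    # whole-chromosome inversion reverses both axes
    inv <- derivativeToBinMap(bt, derivativeGenome("i", "chrA", 0, 300, "-"))
    expect_equal(rearrangedMatrix(materialize(cm, inv)), M[3:1, 3:1])

    # trans weight scales inter-chromosomal sources only
    bt2 <- makeBinTable(c(chrA = 200, chrB = 100), 100)
    M2 <- matrix(c(5, 3, 2, 3, 7, 1, 2, 1, 6), 3, 3)
    cm2 <- denseToContactMatrix(bt2, M2)
    rm1 <- rearrangedMatrix(materialize(cm2, identityBinMap(bt2), w = 1))
    rm3 <- rearrangedMatrix(materialize(cm2, identityBinMap(bt2), w = 3))
    expect_equal(rm1, M2)
    expect_equal(rm3[1:2, 1:2], M2[1:2, 1:2])      # cis untouched
    expect_equal(rm3[1:2, 3], M2[1:2, 3] * 3)      # trans tripled
    expect_equal(rm3[3, 1:2], M2[3, 1:2] * 3)
    expect_equal(rm3, t(rm3))

    # permutation-only binmaps preserve the value multiset
    set.seed(9)
    dense <- randomDenseCounts(3)
    cmp <- denseToContactMatrix(bt, dense)
    permDer <- derivativeGenome("p", c("chrA", "chrA"), c(200, 0), c(300, 200),
                                c("+", "-"))
    mp <- rearrangedMatrix(materialize(cmp, derivativeToBinMap(bt, permDer)))
    expect_equal(sort(as.vector(mp)), sort(as.vector(dense)))
})

test_that("duplicated source bins replicate rows, columns, and self-blocks", {
    bt <- makeBinTable(c(chrA = 500), 100)
    dense <- randomDenseCounts(5)
    cm <- denseToContactMatrix(bt, dense)
    bm <- applyEdit(identityBinMap(bt, "chrA"), editOp("duplicate", start = 2L, end = 3L))
    mp <- rearrangedMatrix(materialize(cm, bm))
    src <- entries(bm)$sourceBin + 1L
    expect_equal(mp, dense[src, src])
    # dup-dup block equals the source self-block
    expect_equal(mp[4:5, 2:3], dense[2:3, 2:3])
})

test_that("engine output equals the brute-force per-bin-list oracle", {
    set.seed(1234)
    for (trial in 1:25) {
        fx <- randomGenomeFixture(100L, 200L)
        state <- lapply(seq_along(chromNames(fx$bt)), function(ci) {
            bins <- which(fx$chromOfBin0 == ci) - 1L
            data.frame(bin = bins, orient = "+", stringsAsFactors = FALSE)
        })
        names(state) <- chromNames(fx$bt)
        binmaps <- lapply(chromNames(fx$bt), function(ch) identityBinMap(fx$bt, ch))
        names(binmaps) <- chromNames(fx$bt)
        edits <- list()
        for (k in seq_len(sample(0:5, 1))) {
            e <- randomEdit(state)
            state <- oracleApply(state, e)
            edits[[length(edits) + 1L]] <- e
        }
        session <- applyEditSequence(binmaps, edits)
        w <- sample(1:3, 1)
        got <- rearrangedMatrix(materialize(fx$cm, session, w = w))
        want <- oracleMaterialize(fx$dense, state, fx$chromOfBin0, w = w)
        expect_identical(got, want)
        expect_equal(got, t(got))
    }
})

test_that("junction smoothness handles zero windows and bad input", {
    bt <- makeBinTable(c(chrA = 4000), 100)
    dense <- matrix(0, 40, 40)
    dense[21:40, 21:40] <- 5  # right block only; left window all zero
    cm <- denseToContactMatrix(bt, dense)
    rm <- materialize(cm, identityBinMap(bt))
    prof <- expectedByDistance(rearrangedToContactMatrix(rm), scope = "pooled")
    rep0 <- junctionSmoothness(rm, prof, 20L, k = 5L)
    expect_equal(smoothnessScore(rep0), 0)
    expect_gt(rep0@nPairs, 0L)
    expect_error(junctionSmoothness(rm, prof, 20L, k = 0L), "k must be")
    expect_error(junctionSmoothness(rm, prof, 40L, k = 5L), "each side")
    expect_error(junctionSmoothness(rm, prof, 0L, k = 5L), "each side")
})

test_that("rearranged matrices re-enter the contact-store machinery", {
    set.seed(17)
    fx <- randomGenomeFixture(60L, 80L)
    bm <- applyEdit(identityBinMap(fx$bt, chromNames(fx$bt)[1L]),
                    editOp("invert", start = 2L, end = 5L))
    rm <- materialize(fx$cm, bm)
    cm2 <- rearrangedToContactMatrix(rm)
    expect_equal(as.matrix(contactCounts(cm2)), rearrangedMatrix(rm),
                 ignore_attr = TRUE)
    expect_equal(binsize(cm2), binsize(fx$cm))
})
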