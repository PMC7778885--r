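## Brute-force oracle: rearrangement as explicit per-bin list editing.
## Deliberately independent of the package's BinMap machinery — plain
## vectors and loops only.

## state: list of data.frames (one per derivative) with columns bin (0-based
## source bin) and orient ("+"/"-")

oracleIdentity <- function(nbins) {
    list(der1 = data.frame(bin = seq_len(nbins) - 1L, orient = "+",
                           stringsAsFactors = FALSE))
}

oracleFlip <- function(df) {
    df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$orient <- ifelse(df$orient == "+", "-", "+")
    rownames(df) <- NULL
    df
}

oracleDelete <- function(state, der, start, end) {
    state[[der]] <- state[[der]][-(start:end), , drop = FALSE]
    rownames(state[[der]]) <- NULL
    state
}

oracleInvert <- function(state, der, start, end) {
    df <- state[[der]]
    df[start:end, ] <- oracleFlip(df[start:end, , drop = FALSE])
    state[[der]] <- df
    state
}

oracleDuplicate <- function(state, der, start, end) {
    df <- state[[der]]
    n <- nrow(df)
    out <- rbind(df[seq_len(end), , drop = FALSE],
                 df[start:end, , drop = FALSE],
                 if (end < n) df[(end + 1L):n, , drop = FALSE])
    rownames(out) <- NULL
    state[[der]] <- out
    state
}

oracleJoin <- function(state, der1, cut1, side1, der2, cut2, side2) {
    pick <- function(df, cut, side) {
        if (side == 3L) df[seq_len(cut), , drop = FALSE]
        else df[(cut + 1L):nrow(df), , drop = FALSE]
    }
    left <- pick(state[[der1]], cut1, side1)
    right <- pick(state[[der2]], cut2, side2)
    if (side1 == 5L) left <- oracleFlip(left)
    if (side2 == 3L) right <- oracleFlip(right)
    merged <- rbind(left, right)
    rownames(merged) <- NULL
    state[[der1]] <- merged
    state[names(state) != der2]
}

oracleApply <- function(state, edit) {
    switch(edit$kind,
           delete = oracleDelete(state, edit$der, edit$start, edit$end),
           invert = oracleInvert(state, edit$der, edit$start, edit$end),
           duplicate = oracleDuplicate(state, edit$der, edit$start, edit$end),
           join = oracleJoin(state, edit$der, edit$cut, edit$side,
                             edit$der2, edit$cut2, edit$side2))
}

## fill M'[a, b] = M[list[a], list[b]], trans entries scaled by w
oracleMaterialize <- function(denseM, state, chromOfBin0, w = 1) {
    bins <- unlist(lapply(state, function(df) df$bin), use.names = FALSE)
    n <- length(bins)
    out <- matrix(0, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
        v <- denseM[bins[a] + 1L, bins[b] + 1L]
        if (chromOfBin0[bins[a] + 1L] != chromOfBin0[bins[b] + 1L]) v <- v * w
        out[a, b] <- v
    }
    out
}

## surviving reference bin list of an intra-chromosomal DEL/DUP, built from
## first principles (floor-division junction-bin retention)
oracleDelBins <- function(nbins, r, p1, p2) {
    left <- 0:floor((p1 - 1) / r)
    right <- floor(p2 / r):(nbins - 1L)
    c(left, right)
}

oracleDupBins <- function(nbins, r, p1, p2) {
    prefix <- 0:floor((p2 - 1) / r)
    suffix <- floor(p1 / r):(nbins - 1L)
    c(prefix, suffix)
}

## random symmetric integer count matrix over a BinTable
randomDenseCounts <- function(nbins, maxCount = 20L) {
    m <- matrix(as.numeric(sample.int(maxCount + 1L, nbins * nbins,
                                      replace = TRUE) - 1L), nbins, nbins)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
}

denseToContactMatrix <- function(bt, m) {
    up <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    contactMatrix(bt, i = up[, 1L] - 1L, j = up[, 2L] - 1L, x = m[up])
}

## random edit valid for the current state; join only when >= 2 derivatives
randomEdit <- function(state) {
    kinds <- c("delete", "invert", "duplicate")
    if (length(state) >= 2L) kinds <- c(kinds, "join")
    repeat {
        kind <- sample(kinds, 1L)
        if (kind == "join") {
            ij <- sample(names(state), 2L)
            n1 <- nrow(state[[ij[1L]]]); n2 <- nrow(state[[ij[2L]]])
            side1 <- sample(c(3L, 5L), 1L); side2 <- sample(c(3L, 5L), 1L)
            cut1 <- if (side1 == 3L) sample(n1, 1L) else sample(n1, 1L) - 1L
            cut2 <- if (side2 == 3L) sample(n2, 1L) else sample(n2, 1L) - 1L
            return(editOp("join", der = ij[1L], cut = cut1, side = side1,
                          der2 = ij[2L], cut2 = cut2, side2 = side2))
        }
        der <- sample(names(state), 1L)
        n <- nrow(state[[der]])
        if (n < 2L) next
        start <- sample(n - 1L, 1L)
        end <- start + sample(min(n - start, 30L), 1L) - 1L
        if (kind == "delete" && start == 1L && end == n) next
        return(editOp(kind, der = der, start = start, end = end))
    }
}

## shared scaffold: random 1-3 chromosome genome and matching matrix
randomGenomeFixture <- function(minBins = 100L, maxBins = 300L, binsize = 1000) {
    nchrom <- sample(3L, 1L)
    total <- sample(minBins:maxBins, 1L)
    splits <- sort(sample(total - 1L, nchrom - 1L))
    per <- diff(c(0L, splits, total))
    sizes <- stats::setNames(per * binsize, paste0("chr", seq_len(nchrom)))
    bt <- makeBinTable(sizes, binsize)
    dense <- randomDenseCounts(sum(per))
    list(bt = bt, dense = dense, cm = denseToContactMatrix(bt, dense),
         chromOfBin0 = rep(seq_len(nchrom), per))
}
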