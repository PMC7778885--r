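#' Parse a fragment-order specification
#'
#' One derivative chromosome per line: \code{name TAB frag(;frag)*} with
#' \code{frag := chrom ":" start "-" end ("+"|"-")?}, coordinates 1-based
#' inclusive (converted to the internal 0-based half-open form), default
#' strand "+". Genomic regions that are not entered are treated as
#' deletions — they simply never appear on the rearranged axis.
#'
#' @param text character vector of lines (or one string with newlines).
#' @param bt a [BinTable-class] used to check chromosomes and ranges.
#' @return list of [DerivativeGenome-class], one per line.
#' @examples
#' bt <- makeBinTable(c(chr1 = 300000, chr2 = 300000), 100000)
#' parseOrderSpec("der1\tchr1:1-200000+;chr2:100001-300000-", bt)
#' @export
parseOrderSpec <- function(text, bt) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
    out <- list()
    for (ln in seq_along(lines)) {
        s <- trimws(lines[ln])
        if (!nzchar(s) || startsWith(s, "#")) next
        parts <- strsplit(s, "\t")[[1L]]
        if (length(parts) != 2L)
            stop(sprintf("order spec line %d: expected 'name<TAB>fragments'", ln))
        name <- parts[1L]
        frags <- strsplit(parts[2L], ";", fixed = TRUE)[[1L]]
        rows <- lapply(seq_along(frags), function(fi) {
            fs <- trimws(frags[fi])
            m <- regmatches(fs, regexec(
                "^([^:]+):([0-9]+)-([0-9]+)([+-−]?)$", fs))[[1L]]
            if (!length(m))
                stop(sprintf("order spec line %d, fragment %d: cannot parse '%s'",
                             ln, fi, fs))
            chrom <- m[2L]
            start1 <- as.numeric(m[3L]); end1 <- as.numeric(m[4L])
            if (start1 > end1)
                stop(sprintf("order spec line %d, fragment %d: start > end", ln, fi))
            ci <- match(chrom, bt@chromNames)
            if (is.na(ci))
                stop(sprintf("order spec line %d, fragment %d: unknown chromosome '%s'",
                             ln, fi, chrom))
            if (end1 > bt@chromLengths[ci])
                stop(sprintf("order spec line %d, fragment %d: end beyond %s length",
                             ln, fi, chrom))
            strand <- if (m[5L] %in% c("-", "−")) "-" else "+"
            data.frame(chrom = chrom, start = start1 - 1, end = end1,
                       strand = strand, stringsAsFactors = FALSE)
        })
        out[[name]] <- new("DerivativeGenome", name = name,
                           fragments = do.call(rbind, rows))
    }
    out
}

#' @rdname parseOrderSpec
#' @param derivatives list of [DerivativeGenome-class].
#' @return \code{formatOrderSpec}: character vector of spec lines.
#' @export
formatOrderSpec <- function(derivatives) {
    vapply(derivatives, function(d) {
        f <- fragments(d)
        frag <- sprintf("%s:%.0f-%.0f%s", f$chrom, f$start + 1, f$end,
                        ifelse(f$strand == "-", "-", "+"))
        paste0(d@name, "\t", paste(frag, collapse = ";"))
    }, character(1L))
}

#' @rdname parseOrderSpec
#' @param path file path.
#' @export
readOrderSpec <- function(path, bt) parseOrderSpec(readLines(path), bt)

## ---- edits ------------------------------------------------------------

#' Describe one contact-map edit
#'
#' Edits are expressed on the *current* derivative bin axis — what an
#' interactive user sees — with 1-based inclusive bin indices.
#' \code{delete}, \code{invert} and \code{duplicate} act on the interval
#' \code{[start, end]} of derivative \code{der}; \code{join} cuts two
#' derivatives and fuses the selected sides (side code 3 = the part before
#' the cut, 5 = the part after; a 5' piece on the left or a 3' piece on the
#' right is reversed so the cut ends meet), replacing \code{der} and
#' removing \code{der2}.
#'
#' @param kind "delete", "invert", "duplicate" or "join".
#' @param der derivative name (or index in the binmap list).
#' @param start,end 1-based inclusive bin interval on the derivative axis.
#' @param cut,cut2 join cut indices: number of bins before the cut (0..len).
#' @param side,side2 join side codes, 3 or 5.
#' @param der2 second derivative for join.
#' @return an edit description (list of class "hicEdit").
#' @export
editOp <- function(kind = c("delete", "invert", "duplicate", "join"),
                   der = 1L, start = NULL, end = NULL,
                   cut = NULL, side = NULL, der2 = NULL, cut2 = NULL,
                   side2 = NULL) {
    kind <- match.arg(kind)
    structure(list(kind = kind, der = der, start = start, end = end,
                   cut = cut, side = side, der2 = der2, cut2 = cut2,
                   side2 = side2), class = "hicEdit")
}

#' Parse an edit-script file
#'
#' One edit per line: \code{DEL der:12-40}, \code{INV der:5-9},
#' \code{DUP der:20-24}, or \code{JOIN der1:15/3 der2:0/5} (cut index /
#' side code). Bin intervals are 1-based inclusive on the current
#' derivative axis. '#' lines are skipped.
#'
#' @param text character vector of lines (or one string with newlines).
#' @return list of edits (see [editOp()]).
#' @export
parseEditScript <- function(text) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
    edits <- list()
    for (ln in seq_along(lines)) {
        s <- trimws(lines[ln])
        if (!nzchar(s) || startsWith(s, "#")) next
        tok <- strsplit(s, "[ \t]+")[[1L]]
        op <- toupper(tok[1L])
        if (op %in% c("DEL", "INV", "DUP")) {
            if (length(tok) != 2L)
                stop(sprintf("edit script line %d: expected '%s der:start-end'", ln, op))
            m <- regmatches(tok[2L], regexec("^(.+):([0-9]+)-([0-9]+)$", tok[2L]))[[1L]]
            if (!length(m)) stop(sprintf("edit script line %d: cannot parse '%s'",
                                         ln, tok[2L]))
            kind <- c(DEL = "delete", INV = "invert", DUP = "duplicate")[op]
            edits[[length(edits) + 1L]] <- editOp(kind, der = m[2L],
                                                  start = as.integer(m[3L]),
                                                  end = as.integer(m[4L]))
        } else if (op == "JOIN") {
            if (length(tok) != 3L)
                stop(sprintf("edit script line %d: expected 'JOIN der1:cut/side der2:cut/side'", ln))
            p <- lapply(tok[2:3], function(t) {
                m <- regmatches(t, regexec("^(.+):([0-9]+)/(3|5)$", t))[[1L]]
                if (!length(m)) stop(sprintf("edit script line %d: cannot parse '%s'", ln, t))
                list(der = m[2L], cut = as.integer(m[3L]), side = as.integer(m[4L]))
            })
            edits[[length(edits) + 1L]] <- editOp("join", der = p[[1L]]$der,
                                                  cut = p[[1L]]$cut, side = p[[1L]]$side,
                                                  der2 = p[[2L]]$der, cut2 = p[[2L]]$cut,
                                                  side2 = p[[2L]]$side)
        } else stop(sprintf("edit script line %d: unknown edit '%s'", ln, op))
    }
    edits
}

#' @rdname parseEditScript
#' @param edits list of edits.
#' @return \code{formatEditScript}: character vector of script lines.
#' @export
formatEditScript <- function(edits) {
    vapply(edits, function(e) {
        switch(e$kind,
               delete = sprintf("DEL %s:%d-%d", e$der, e$start, e$end),
               invert = sprintf("INV %s:%d-%d", e$der, e$start, e$end),
               duplicate = sprintf("DUP %s:%d-%d", e$der, e$start, e$end),
               join = sprintf("JOIN %s:%d/%d %s:%d/%d", e$der, e$cut, e$side,
                              e$der2, e$cut2, e$side2))
    }, character(1L))
}

## Recompute fragment indices as maximal oriented consecutive-bin runs.
.renumberFragments <- function(entries, bt) {
    n <- nrow(entries)
    if (n == 0L) return(entries)
    chrom <- .chromOfBin(bt, entries$sourceBin)
    newFrag <- integer(n)
    newFrag[1L] <- 1L
    if (n > 1L) {
        step <- ifelse(entries$orientation[-1L] == "+", 1L, -1L)
        contiguous <- entries$orientation[-1L] == entries$orientation[-n] &
            entries$sourceBin[-1L] == entries$sourceBin[-n] + step &
            chrom[-1L] == chrom[-n]
        newFrag[-1L] <- 1L + cumsum(!contiguous)
    }
    entries$fragmentIndex <- newFrag
    entries
}

.flipEntries <- function(e) {
    e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
    e$orientation <- ifelse(e$orientation == "+", "-", "+")
    rownames(e) <- NULL
    e
}

.resolveDer <- function(binmaps, der) {
    if (is.character(der)) {
        i <- match(der, names(binmaps))
        if (is.na(i)) stop("unknown derivative '", der, "'")
        i
    } else {
        if (der < 1L || der > length(binmaps)) stop("derivative index out of range")
        as.integer(der)
    }
}

#' Apply one edit to a BinMap (or a named list of BinMaps)
#'
#' \code{delete} removes the interval; \code{invert} reverses it and flips
#' orientations; \code{duplicate} inserts a tandem copy immediately after
#' it; \code{join} fuses two derivatives at cut points (list input only).
#' Fragment indices are renumbered to maximal oriented runs after every
#' edit.
#'
#' @param x a [BinMap-class], or a named list of them.
#' @param edit an edit from [editOp()] / [parseEditScript()].
#' @return object of the same shape as \code{x}.
#' @export
setMethod("applyEdit", "BinMap", function(x, edit, ...) {
    if (edit$kind == "join")
        stop("join requires a list of BinMaps")
    n <- length(x)
    if (is.null(edit$start) || is.null(edit$end) ||
        edit$start < 1L || edit$end > n || edit$start > edit$end)
        stop(sprintf("edit interval [%s, %s] out of range 1..%d",
                     edit$start, edit$end, n))
    e <- x@entries
    idx <- edit$start:edit$end
    e2 <- switch(edit$kind,
        delete = e[-idx, , drop = FALSE],
        invert = {
            e[idx, ] <- .flipEntries(e[idx, , drop = FALSE])
            e
        },
        duplicate = rbind(e[seq_len(edit$end), , drop = FALSE],
                          e[idx, , drop = FALSE],
                          if (edit$end < n) e[(edit$end + 1L):n, , drop = FALSE]))
    if (nrow(e2) == 0L) stop("edit would leave an empty derivative")
    rownames(e2) <- NULL
    new("BinMap", bintable = x@bintable,
        entries = .renumberFragments(e2, x@bintable))
})

#' @rdname applyEdit-BinMap-method
#' @export
setMethod("applyEdit", "list", function(x, edit, ...) {
    i <- .resolveDer(x, edit$der)
    if (edit$kind != "join") {
        x[[i]] <- applyEdit(x[[i]], edit)
        return(x)
    }
    j <- .resolveDer(x, edit$der2)
    if (i == j) stop("join requires two distinct derivatives")
    pick <- function(bm, cut, side) {
        n <- length(bm)
        if (cut < 0L || cut > n) stop("join cut outside derivative (0..", n, ")")
        e <- bm@entries
        if (side == 3L) {
            if (cut == 0L) stop("3' side of cut 0 is empty")
            e[seq_len(cut), , drop = FALSE]
        } else {
            if (cut == n) stop("5' side of cut ", n, " is empty")
            e[(cut + 1L):n, , drop = FALSE]
        }
    }
    left <- pick(x[[i]], edit$cut, edit$side)
    right <- pick(x[[j]], edit$cut2, edit$side2)
    ## orient the pieces so the two cut ends meet at the junction
    if (edit$side == 5L) left <- .flipEntries(left)
    if (edit$side2 == 3L) right <- .flipEntries(right)
    merged <- rbind(left, right)
    rownames(merged) <- NULL
    bt <- x[[i]]@bintable
    x[[i]] <- new("BinMap", bintable = bt,
                  entries = .renumberFragments(merged, bt))
    x[-j]
})

#' Apply a sequence of edits with an undo log
#'
#' Left-fold of [applyEdit()] over the edit list, recording each prior
#' state so edits can be reverted last-in-first-out, as in interactive
#' manipulation. The first invalid edit aborts with its index.
#'
#' @param binmaps a [BinMap-class] or named list of them (a bare BinMap is
#'   wrapped as list(der1 = ...)).
#' @param edits list of edits.
#' @return An [EditSession-class].
#' @export
applyEditSequence <- function(binmaps, edits = list()) {
    if (is(binmaps, "BinMap")) binmaps <- list(der1 = binmaps)
    session <- new("EditSession", binmaps = binmaps, history = list())
    for (k in seq_along(edits)) {
        nxt <- tryCatch(applyEdit(session@binmaps, edits[[k]]),
                        error = function(e)
                            stop(sprintf("edit %d invalid: %s", k, conditionMessage(e)),
                                 call. = FALSE))
        session@history <- c(session@history, list(session@binmaps))
        session@binmaps <- nxt
    }
    session
}

#' @rdname applyEditSequence
#' @param session an [EditSession-class].
#' @return \code{undoEdit}: the session with the last edit reverted.
#' @export
undoEdit <- function(session) {
    h <- length(session@history)
    if (h == 0L) stop("nothing to undo")
    session@binmaps <- session@history[[h]]
    session@history <- session@history[-h]
    session
}

#' @rdname applyEditSequence
#' @export
sessionBinMaps <- function(session) session@binmaps

setMethod("show", "EditSession", function(object) {
    cat(sprintf("EditSession: %d derivative(s), %d edit(s) applied\n",
                length(object@binmaps), length(object@history)))
})

## ---- materialization --------------------------------------------------

#' Materialize a rearranged contact matrix
#'
#' Builds the dense symmetric matrix over the concatenated derivative axis:
#' \code{M'[a, b] = M[src(a), src(b)]}, multiplied by the trans weight
#' \code{w} when the two source bins lie on different reference
#' chromosomes. Duplicated source bins replicate their source
#' rows/columns, including a dup-dup block equal to the source self-block.
#' Derivative and fragment boundaries are recorded for rendering.
#'
#' @param x a [ContactMatrix-class].
#' @param binmaps a [BinMap-class], a named list of them, or an
#'   [EditSession-class].
#' @param w trans enhancement factor ("Weight score"), >= 0; purely a
#'   display-time multiplier, never persisted into counts.
#' @param what materialize raw "counts" (default) or normalized "values".
#' @return A [RearrangedMatrix-class].
#' @export
setMethod("materialize", "ContactMatrix",
          function(x, binmaps, w = 1, what = c("counts", "values")) {
    what <- match.arg(what)
    if (is(binmaps, "EditSession")) binmaps <- binmaps@binmaps
    if (is(binmaps, "BinMap")) binmaps <- list(der1 = binmaps)
    if (!length(binmaps)) stop("no binmaps to materialize")
    if (is.null(names(binmaps)) || any(!nzchar(names(binmaps))))
        names(binmaps) <- paste0("der", seq_along(binmaps))
    if (w < 0) stop("weight must be >= 0")
    bt <- x@bintable
    lens <- vapply(binmaps, length, integer(1L))
    if (any(lens == 0L)) stop("empty BinMap")
    axis <- do.call(rbind, lapply(seq_along(binmaps), function(i) {
        e <- binmaps[[i]]@entries
        data.frame(derivative = names(binmaps)[i], e, stringsAsFactors = FALSE)
    }))
    rownames(axis) <- NULL
    info <- binInfo(bt, axis$sourceBin)
    axis$chrom <- info$chrom
    axis$binStart <- info$start
    src <- axis$sourceBin + 1L
    S <- denseCounts(x, what = what)
    M <- S[src, src, drop = FALSE]
    chromIdx <- .chromOfBin(bt, axis$sourceBin)
    if (w != 1) {
        transMask <- outer(chromIdx, chromIdx, "!=")
        M[transMask] <- M[transMask] * w
    }
    cum <- cumsum(lens)
    derivB <- as.integer(cum[-length(cum)])
    fragB <- integer()
    pos <- 0L
    for (i in seq_along(binmaps)) {
        e <- binmaps[[i]]@entries
        r <- rle(e$fragmentIndex)
        ends <- pos + cumsum(r$lengths)
        fragB <- c(fragB, as.integer(ends[-length(ends)]))
        pos <- pos + nrow(e)
    }
    fragB <- sort(unique(c(fragB, derivB)))
    dimnames(M) <- NULL
    new("RearrangedMatrix", matrix = M, axis = axis,
        derivativeBoundaries = derivB, fragmentBoundaries = fragB,
        weight = as.numeric(w), binsize = binsize(bt))
})

#' Accessors for rearranged matrices
#'
#' @param x a [RearrangedMatrix-class].
#' @name rearranged-accessors
NULL

#' @rdname rearranged-accessors
#' @export
rearrangedMatrix <- function(x) x@matrix

#' @rdname rearranged-accessors
#' @export
axisProvenance <- function(x) x@axis

#' @rdname rearranged-accessors
#' @export
junctions <- function(x) x@fragmentBoundaries

setMethod("show", "RearrangedMatrix", function(object) {
    cat(sprintf(
        "RearrangedMatrix: %d x %d axis bins, %d derivative(s), %d junction(s), w = %g\n",
        nrow(object@matrix), ncol(object@matrix),
        length(object@derivativeBoundaries) + 1L,
        length(object@fragmentBoundaries), object@weight))
})

#' Export a rearranged matrix as dense TSV
#'
#' Row/column names encode the axis provenance as
#' \code{derivative|chrom:binStart|orientation}.
#'
#' @param rm a [RearrangedMatrix-class].
#' @param path output path.
#' @export
writeRearranged <- function(rm, path) {
    lab <- sprintf("%s|%s:%.0f|%s", rm@axis$derivative, rm@axis$chrom,
                   rm@axis$binStart, rm@axis$orientation)
    m <- rm@matrix
    dimnames(m) <- list(lab, lab)
    utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
}

## ---- junction smoothness ----------------------------------------------

#' Score contact continuity across a junction
#'
#' For the k bins on each side of an axis cut, computes the mean
#' observed/expected fold change \code{S = mean(M'[a, b] / expected(d))},
#' where d is the pair distance *on the rearranged axis* — the
#' neo-adjacency hypothesis. Pairs whose expected value is at the profile
#' floor are excluded and counted. A true SV junction in a correctly
#' rearranged map scores near 1 ("smooth linkage" of signal across the
#' breakpoint); a spurious junction scores well below 1.
#'
#' @param rm a [RearrangedMatrix-class].
#' @param profile an [ExpectedProfile-class]; its pooled profile is used.
#' @param junction axis cut position: number of bins to the left of the
#'   cut (see [junctions()] for the fragment junctions of a map).
#' @param k window half-width in bins (>= 1); clipped to the available
#'   bins on each side.
#' @return A [SmoothnessReport-class].
#' @export
junctionSmoothness <- function(rm, profile, junction, k = 10L) {
    n <- nrow(rm@matrix)
    k <- as.integer(k)
    junction <- as.integer(junction)
    if (k < 1L) stop("k must be >= 1")
    if (junction < 1L || junction >= n)
        stop("junction must have at least one bin on each side")
    kl <- min(k, junction)
    kr <- min(k, n - junction)
    a <- (junction - kl + 1L):junction
    b <- (junction + 1L):(junction + kr)
    obs <- rm@matrix[a, b, drop = FALSE]
    d <- outer(a, b, function(u, v) v - u)
    e <- matrix(expectedAt(profile, as.vector(d)), nrow = kl)
    usable <- e > profile@epsilon
    nUse <- sum(usable)
    S <- if (nUse) mean(obs[usable] / e[usable]) else 0
    new("SmoothnessReport", junction = junction, k = k, score = S,
        nPairs = as.integer(nUse), nExcluded = as.integer(sum(!usable)))
}

#' @export
setMethod("smoothnessScore", "SmoothnessReport", function(x) x@score)

setMethod("show", "SmoothnessReport", function(object) {
    cat(sprintf(
        "SmoothnessReport: junction %d, k = %d, S = %.4g (%d pairs, %d excluded)\n",
        object@junction, object@k, object@score, object@nPairs, object@nExcluded))
})

#' Re-express a rearranged matrix as a ContactMatrix
#'
#' Builds a synthetic "derivative genome" [BinTable-class] with one
#' chromosome per derivative and copies the rearranged values into sparse
#' symmetric storage, so normalization and expected-profile machinery can
#' run on rearranged coordinates (e.g. to score junctions against the
#' rearranged map's own distance decay).
#'
#' @param rm a [RearrangedMatrix-class].
#' @return A [ContactMatrix-class] over the synthetic derivative BinTable.
#' @export
rearrangedToContactMatrix <- function(rm) {
    lens <- as.numeric(table(factor(rm@axis$derivative,
                                    levels = unique(rm@axis$derivative))))
    sizes <- stats::setNames(lens * rm@binsize, unique(rm@axis$derivative))
    bt <- makeBinTable(sizes, rm@binsize)
    up <- which(upper.tri(rm@matrix, diag = TRUE) & rm@matrix != 0, arr.ind = TRUE)
    contactMatrix(bt, i = up[, 1L] - 1L, j = up[, 2L] - 1L,
                  x = rm@matrix[up])
}
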