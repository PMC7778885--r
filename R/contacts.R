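#' Construct a sparse symmetric ContactMatrix
#'
#' Entries are folded into upper-triangular storage: an (i, j) and a (j, i)
#' record of the same pair are summed into one entry.
#'
#' @param bintable a [BinTable-class].
#' @param i,j 0-based global bin ids of each record.
#' @param x non-negative counts.
#' @return A [ContactMatrix-class].
#' @export
contactMatrix <- function(bintable, i = integer(), j = integer(), x = numeric()) {
    nb <- nBins(bintable)
    if (length(i) != length(j) || length(j) != length(x))
        stop("i, j, x must have equal length")
    if (any(x < 0)) stop("negative count")
    if (length(i) && (any(i < 0) || any(j < 0) || any(i >= nb) || any(j >= nb)))
        stop("bin id out of range")
    ii <- pmin(i, j); jj <- pmax(i, j)
    m <- Matrix::sparseMatrix(i = ii + 1L, j = jj + 1L, x = x,
                              dims = c(nb, nb), repr = "C")
    new("ContactMatrix", bintable = bintable, counts = Matrix::drop0(m),
        values = NULL, zeroCoverage = integer())
}

#' @export
setMethod("nBins", "ContactMatrix", function(x) nBins(x@bintable))

#' @export
setMethod("binsize", "ContactMatrix", function(x) binsize(x@bintable))

#' Accessors for contact data
#'
#' \code{bintable()} returns the governing bin table; \code{contactCounts()}
#' the raw counts and \code{contactValues()} the normalized values, each
#' either as the full symmetric sparse matrix or, when \code{i}/\code{j} are
#' given, as the symmetric lookup of those pairs. \code{denseCounts()}
#' returns a dense symmetric matrix (of values when \code{what = "values"}).
#'
#' @param x a [ContactMatrix-class].
#' @param i,j optional 0-based bin ids to query.
#' @param what "counts" or "values".
#' @name contact-accessors
NULL

#' @rdname contact-accessors
#' @export
bintable <- function(x) x@bintable

.symmetrize <- function(up) {
    full <- up + Matrix::t(up)
    Matrix::diag(full) <- Matrix::diag(up)
    full
}

#' @rdname contact-accessors
#' @export
setMethod("contactCounts", "ContactMatrix", function(x, i = NULL, j = NULL) {
    if (is.null(i)) return(.symmetrize(x@counts))
    ii <- pmin(i, j) + 1L; jj <- pmax(i, j) + 1L
    x@counts[cbind(ii, jj)]
})

#' @rdname contact-accessors
#' @export
setMethod("contactValues", "ContactMatrix", function(x, i = NULL, j = NULL) {
    if (is.null(x@values)) stop("no normalized values; run a normalization first")
    if (is.null(i)) return(.symmetrize(x@values))
    ii <- pmin(i, j) + 1L; jj <- pmax(i, j) + 1L
    x@values[cbind(ii, jj)]
})

#' @rdname contact-accessors
#' @export
setMethod("denseCounts", "ContactMatrix", function(x, what = c("counts", "values")) {
    what <- match.arg(what)
    m <- if (what == "counts") x@counts else {
        if (is.null(x@values)) stop("no normalized values")
        x@values
    }
    as.matrix(.symmetrize(m))
})

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix: %d bins (%d chromosome(s), binsize %g bp)\n",
                nBins(object), length(object@bintable@chromNames),
                binsize(object)))
    cat(sprintf("  %d stored pairs, total count %g%s\n",
                length(object@counts@x), sum(object@counts@x),
                if (is.null(object@values)) "" else ", normalized values present"))
})

.chromOfBin <- function(bt, bins0) findInterval(bins0, bt@offsets)

#' Read a contact matrix from sparse text triples
#'
#' Line format: \code{chrom1 start1 chrom2 start2 count}, whitespace
#' separated, where start is the 0-based bp start of the bin (BED
#' convention) and must be a multiple of the binsize. '#' lines are
#' skipped. Duplicate (i,j)/(j,i) records are summed.
#'
#' @param path file path.
#' @param bintable a [BinTable-class] giving the genome and binsize.
#' @return A [ContactMatrix-class].
#' @export
readContacts <- function(path, bintable) {
    if (!file.exists(path)) stop("matrix file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    lines <- lines[keep]
    if (!length(lines)) return(contactMatrix(bintable))
    df <- utils::read.table(text = lines, header = FALSE,
                            col.names = c("chrom1", "start1", "chrom2", "start2", "count"),
                            colClasses = c("character", "numeric", "character",
                                           "numeric", "numeric"))
    r <- binsize(bintable)
    if (any(df$start1 %% r != 0) || any(df$start2 %% r != 0))
        stop("bin start not a multiple of binsize ", r, "; inconsistent binsize?")
    if (any(df$count < 0)) stop("negative count")
    i <- posToBin(bintable, df$chrom1, df$start1)
    j <- posToBin(bintable, df$chrom2, df$start2)
    contactMatrix(bintable, i, j, df$count)
}

#' Write a contact matrix as sparse text triples
#'
#' Emits one upper-triangular stored entry per line (see [readContacts()]
#' for the format). \code{what = "values"} writes normalized values instead
#' of counts.
#'
#' @param cm a [ContactMatrix-class].
#' @param path output path.
#' @param what "counts" or "values".
#' @export
writeContacts <- function(cm, path, what = c("counts", "values")) {
    what <- match.arg(what)
    m <- as(if (what == "counts") cm@counts else cm@values, "TsparseMatrix")
    bi <- binInfo(cm@bintable, m@i)
    bj <- binInfo(cm@bintable, m@j)
    ord <- order(m@i, m@j)
    writeLines(sprintf("%s\t%.0f\t%s\t%.0f\t%.10g", bi$chrom[ord], bi$start[ord],
                       bj$chrom[ord], bj$start[ord], m@x[ord]), path)
}

#' Export normalized interactions as a BED-pair style table
#'
#' Seven tab-separated columns: chrom1 start1 end1 chrom2 start2 end2 value
#' (0-based half-open bin intervals), one line per stored upper-triangular
#' pair.
#'
#' @param cm a [ContactMatrix-class] carrying normalized values.
#' @param path output path.
#' @param what "values" (default) or "counts".
#' @export
writeInteractionTable <- function(cm, path, what = c("values", "counts")) {
    what <- match.arg(what)
    m <- as(if (what == "counts") cm@counts else {
        if (is.null(cm@values)) stop("no normalized values")
        cm@values
    }, "TsparseMatrix")
    bi <- binInfo(cm@bintable, m@i)
    bj <- binInfo(cm@bintable, m@j)
    ord <- order(m@i, m@j)
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%.0f\t%.0f\t%.10g",
                       bi$chrom[ord], bi$start[ord], bi$end[ord],
                       bj$chrom[ord], bj$start[ord], bj$end[ord], m@x[ord]), path)
}

#' Per-bin coverage (marginal) profile
#'
#' \code{marginal[i] = sum_j counts(i, j)} with the diagonal counted once —
#' the covariate a coverage-based normalizer regresses on.
#'
#' @param cm a [ContactMatrix-class].
#' @return numeric vector of marginals, one per bin.
#' @export
coverageProfile <- function(cm) {
    nb <- nBins(cm)
    m <- as(cm@counts, "TsparseMatrix")
    marg <- numeric(nb)
    if (length(m@x)) {
        agg_i <- rowsum(m@x, m@i)
        marg[as.integer(rownames(agg_i)) + 1L] <-
            marg[as.integer(rownames(agg_i)) + 1L] + agg_i[, 1L]
        off <- m@i != m@j
        if (any(off)) {
            agg_j <- rowsum(m@x[off], m@j[off])
            marg[as.integer(rownames(agg_j)) + 1L] <-
                marg[as.integer(rownames(agg_j)) + 1L] + agg_j[, 1L]
        }
    }
    marg
}

#' Coverage normalization by marginal-product scaling
#'
#' A simplified coverage normalizer: \code{value(i,j) = counts(i,j) /
#' (m_i * m_j) * S}, where m are the per-bin marginals and S rescales so
#' total mass (the sum over stored upper-triangular entries) is preserved.
#' Bins with zero marginal yield zero values and are flagged in the
#' \code{zeroCoverage} slot. An alternative normalizer can be plugged in via
#' \code{normalizer}, which receives the counts matrix and the marginals
#' and must return values on the same sparsity pattern.
#'
#' @param cm a [ContactMatrix-class].
#' @param normalizer optional function(counts_upper, marginals) -> values.
#' @return \code{cm} with the \code{values} slot filled.
#' @export
coverageNormalize <- function(cm, normalizer = NULL) {
    marg <- coverageProfile(cm)
    if (all(marg == 0)) stop("all-zero matrix: nothing to normalize")
    if (!is.null(normalizer)) {
        cm@values <- normalizer(cm@counts, marg)
        return(cm)
    }
    m <- as(cm@counts, "TsparseMatrix")
    mi <- marg[m@i + 1L]; mj <- marg[m@j + 1L]
    raw <- ifelse(mi > 0 & mj > 0, m@x / (mi * mj), 0)
    S <- if (sum(raw) > 0) sum(m@x) / sum(raw) else 1
    v <- Matrix::sparseMatrix(i = m@i + 1L, j = m@j + 1L, x = raw * S,
                              dims = dim(m), repr = "C")
    cm@values <- v
    cm@zeroCoverage <- as.integer(which(marg == 0) - 1L)
    cm
}

.movingAverageLog <- function(y, window, eps) {
    y <- pmax(y, eps)
    if (window <= 1L || length(y) < 2L) return(y)
    ly <- log(y)
    half <- floor(window / 2)
    n <- length(ly)
    out <- vapply(seq_len(n), function(k) {
        lo <- max(1L, k - half); hi <- min(n, k + half)
        mean(ly[lo:hi])
    }, numeric(1L))
    pmax(exp(out), eps)
}

.cisDiagonalStats <- function(m, bt) {
    ## per-chromosome sums and pair counts at each bin distance d
    ci <- .chromOfBin(bt, m@i)
    cj <- .chromOfBin(bt, m@j)
    cis <- ci == cj
    list(ci = ci[cis], d = m@j[cis] - m@i[cis], x = m@x[cis],
         transTotal = sum(m@x[!cis]))
}

#' Expected contact value by genomic distance
#'
#' \code{expected(d)} is the mean count over all cis pairs at bin distance
#' d — structural zeros included in the denominator — smoothed by a
#' log-space moving average of width \code{smoothWindow} and floored at
#' \code{epsilon}. The per-chromosome scope keeps one profile per
#' chromosome; the pooled profile (always computed) averages over all
#' chromosomes and is used for junction scoring and as the trans baseline.
#'
#' @param cm a [ContactMatrix-class] with at least one cis pair possible.
#' @param scope "per-chromosome" (default) or "pooled".
#' @param smoothWindow moving-average window in bins (1 = no smoothing).
#' @param epsilon positive floor.
#' @return An [ExpectedProfile-class].
#' @export
expectedByDistance <- function(cm, scope = c("per-chromosome", "pooled"),
                               smoothWindow = 3, epsilon = 1e-8) {
    scope <- match.arg(scope)
    bt <- cm@bintable
    nper <- bt@nBinsPerChrom
    if (all(nper < 1L)) stop("no cis pairs")
    m <- as(cm@counts, "TsparseMatrix")
    st <- .cisDiagonalStats(m, bt)
    maxd <- max(nper) - 1L
    nchrom <- length(nper)
    sums <- matrix(0, nrow = nchrom, ncol = maxd + 1L)
    if (length(st$x)) {
        key <- (st$ci - 1L) * (maxd + 1L) + st$d
        agg <- rowsum(st$x, key)
        k <- as.integer(rownames(agg))
        sums[cbind(k %/% (maxd + 1L) + 1L, k %% (maxd + 1L) + 1L)] <- agg[, 1L]
    }
    ## pairs at distance d on a chromosome of n bins: n - d (0 when d >= n)
    npairs <- outer(nper, 0:maxd, function(n, d) pmax(n - d, 0L))
    pooledRaw <- colSums(sums) / pmax(colSums(npairs), 1L)
    pooledRaw[colSums(npairs) == 0] <- 0
    pooled <- .movingAverageLog(pooledRaw, smoothWindow, epsilon)
    profiles <- list()
    if (scope == "per-chromosome") {
        for (c in seq_len(nchrom)) {
            nd <- nper[c]
            if (nd < 1L) next
            raw <- sums[c, seq_len(nd)] / npairs[c, seq_len(nd)]
            profiles[[bt@chromNames[c]]] <- .movingAverageLog(raw, smoothWindow, epsilon)
        }
    }
    nb <- nBins(bt)
    nTransPairs <- (nb * (nb + 1)) / 2 - sum(nper * (nper + 1) / 2)
    new("ExpectedProfile", scope = scope, profiles = profiles, pooled = pooled,
        transMean = if (nTransPairs > 0) st$transTotal / nTransPairs else NA_real_,
        smoothWindow = as.numeric(smoothWindow), epsilon = epsilon)
}

setMethod("show", "ExpectedProfile", function(object) {
    cat(sprintf("ExpectedProfile (%s): %d distances, window %g, trans mean %s\n",
                object@scope, length(object@pooled), object@smoothWindow,
                format(object@transMean, digits = 4)))
})

#' Look up expected values
#'
#' @param profile an [ExpectedProfile-class].
#' @param d bin distance(s).
#' @param chrom chromosome name (per-chromosome scope; ignored when pooled).
#' @return expected value(s) at those distances.
#' @export
expectedAt <- function(profile, d, chrom = NULL) {
    vec <- if (profile@scope == "per-chromosome" && !is.null(chrom)) {
        p <- profile@profiles[[chrom]]
        if (is.null(p)) stop("no profile for chromosome ", chrom)
        p
    } else profile@pooled
    if (any(d < 0) || any(d >= length(vec)))
        stop("missing profile distance ", max(d))
    vec[d + 1L]
}

#' Distance (observed/expected) normalization
#'
#' Cis pairs become fold changes \code{FC(i,j) = counts(i,j) /
#' expected(|i-j|)}; trans pairs are divided by the pooled trans mean.
#' Sparsity is unchanged.
#'
#' @param cm a [ContactMatrix-class].
#' @param profile an [ExpectedProfile-class]; computed from \code{cm} with
#'   default settings when omitted.
#' @return \code{cm} with fold-change \code{values}.
#' @export
distanceNormalize <- function(cm, profile = NULL) {
    if (is.null(profile)) profile <- expectedByDistance(cm)
    bt <- cm@bintable
    m <- as(cm@counts, "TsparseMatrix")
    ci <- .chromOfBin(bt, m@i)
    cj <- .chromOfBin(bt, m@j)
    fc <- numeric(length(m@x))
    cis <- ci == cj
    if (any(cis)) {
        d <- m@j[cis] - m@i[cis]
        if (profile@scope == "per-chromosome") {
            e <- numeric(sum(cis))
            for (c in unique(ci[cis])) {
                sel <- ci[cis] == c
                e[sel] <- expectedAt(profile, d[sel], bt@chromNames[c])
            }
        } else e <- expectedAt(profile, d)
        fc[cis] <- m@x[cis] / e
    }
    if (any(!cis)) {
        if (!is.finite(profile@transMean) || profile@transMean <= 0)
            stop("trans pairs present but no positive trans mean in profile")
        fc[!cis] <- m@x[!cis] / profile@transMean
    }
    cm@values <- Matrix::sparseMatrix(i = m@i + 1L, j = m@j + 1L, x = fc,
                                      dims = dim(m), repr = "C")
    cm
}
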