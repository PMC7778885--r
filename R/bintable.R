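#' Build a BinTable from chromosome sizes
#'
#' Partitions each chromosome into \code{ceiling(length / binsize)} bins of
#' \code{binsize} bp (the last bin may be partial). Global 0-based bin ids
#' are assigned contiguously in the input chromosome order.
#'
#' @param chromSizes named numeric vector of chromosome lengths in bp, or a
#'   two-column data.frame (name, length) as read from a UCSC-style
#'   chrom.sizes file.
#' @param binsize bin width in bp; 40000 is conventional for cancer Hi-C
#'   maps, 5000 for deeply binned normal maps.
#' @return A [BinTable-class] object.
#' @examples
#' bt <- makeBinTable(c(chrA = 400000, chrB = 200000), 100000)
#' nBins(bt)  # 6
#' @export
makeBinTable <- function(chromSizes, binsize) {
    if (is.data.frame(chromSizes)) {
        stopifnot(ncol(chromSizes) >= 2L)
        nm <- as.character(chromSizes[[1L]])
        len <- as.numeric(chromSizes[[2L]])
    } else {
        nm <- names(chromSizes)
        len <- as.numeric(chromSizes)
    }
    if (is.null(nm) || any(!nzchar(nm)))
        stop("chromosome sizes must be named")
    if (anyDuplicated(nm))
        stop("duplicate chromosome name: ", nm[duplicated(nm)][1L])
    if (any(len < 1)) stop("chromosome lengths must be >= 1")
    if (length(binsize) != 1L || binsize < 1) stop("binsize must be >= 1")
    nbin <- as.integer(ceiling(len / binsize))
    new("BinTable",
        chromNames = nm, chromLengths = len, binsize = as.numeric(binsize),
        nBinsPerChrom = nbin,
        offsets = as.integer(cumsum(c(0L, nbin))[seq_along(nm)]))
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two-column whitespace-separated text: chromosome name, length in bp.
#' Chromosome order follows the file, it is never sorted.
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, header = FALSE, col.names = c("name", "length"),
                            colClasses = c("character", "numeric"))
    stats::setNames(df$length, df$name)
}

#' @describeIn makeBinTable total number of bins.
#' @param x a BinTable (or object governed by one).
#' @export
setMethod("nBins", "BinTable", function(x) sum(x@nBinsPerChrom))

#' @export
setMethod("binsize", "BinTable", function(x) x@binsize)

#' @export
setMethod("chromNames", "BinTable", function(x) x@chromNames)

#' @export
setMethod("chromLengths", "BinTable",
          function(x) stats::setNames(x@chromLengths, x@chromNames))

setMethod("show", "BinTable", function(object) {
    cat(sprintf("BinTable: %d chromosome(s), binsize %g bp, %d bins\n",
                length(object@chromNames), object@binsize, nBins(object)))
    n <- min(5L, length(object@chromNames))
    for (i in seq_len(n))
        cat(sprintf("  %s: %g bp, bins %d..%d\n", object@chromNames[i],
                    object@chromLengths[i], object@offsets[i],
                    object@offsets[i] + object@nBinsPerChrom[i] - 1L))
    if (length(object@chromNames) > n) cat("  ...\n")
})

.chromIndex <- function(bt, chrom) {
    i <- match(chrom, bt@chromNames)
    if (anyNA(i)) stop("unknown chromosome: ", chrom[is.na(i)][1L])
    i
}

#' Map genomic positions to global bin ids
#'
#' Breakpoints that do not fall on a bin boundary are assigned by floor
#' division: bin \code{floor(pos / binsize)} within the chromosome.
#'
#' @param bt a [BinTable-class].
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s) in bp, \code{0 <= pos < length}.
#' @return integer global 0-based bin id(s).
#' @examples
#' bt <- makeBinTable(c(chr6 = 170805979), 40000)
#' posToBin(bt, "chr6", 75343990)  # 1883
#' @export
posToBin <- function(bt, chrom, pos) {
    ci <- .chromIndex(bt, chrom)
    if (any(pos < 0) || any(pos >= bt@chromLengths[ci]))
        stop("position out of range for its chromosome")
    as.integer(bt@offsets[ci] + floor(pos / bt@binsize))
}

#' Describe global bins
#'
#' @param bt a [BinTable-class].
#' @param bin 0-based global bin id(s).
#' @return data.frame with chrom, start, end (bp, 0-based half-open,
#'   clipped to the chromosome length) per bin.
#' @export
binInfo <- function(bt, bin) {
    bin <- as.integer(bin)
    if (any(bin < 0L) || any(bin >= nBins(bt))) stop("bin id out of range")
    ci <- findInterval(bin, bt@offsets)
    local <- bin - bt@offsets[ci]
    start <- local * bt@binsize
    data.frame(chrom = bt@chromNames[ci], start = start,
               end = pmin(start + bt@binsize, bt@chromLengths[ci]),
               stringsAsFactors = FALSE)
}

#' Construct a derivative chromosome
#'
#' @param name identifier.
#' @param chrom,start,end,strand parallel vectors describing the ordered
#'   fragments; coordinates 0-based half-open; strand "+" (default) or "-".
#' @return A [DerivativeGenome-class].
#' @export
derivativeGenome <- function(name, chrom, start, end, strand = "+") {
    n <- length(chrom)
    new("DerivativeGenome", name = as.character(name),
        fragments = data.frame(chrom = as.character(chrom),
                               start = as.numeric(start), end = as.numeric(end),
                               strand = rep_len(as.character(strand), n),
                               stringsAsFactors = FALSE))
}

#' @export
setMethod("fragments", "DerivativeGenome", function(x) x@fragments)

setMethod("show", "DerivativeGenome", function(object) {
    f <- object@fragments
    cat(sprintf("DerivativeGenome '%s': %d fragment(s)\n", object@name, nrow(f)))
    for (i in seq_len(min(nrow(f), 8L)))
        cat(sprintf("  %s:%.0f-%.0f%s\n", f$chrom[i], f$start[i], f$end[i], f$strand[i]))
    if (nrow(f) > 8L) cat("  ...\n")
})

#' Bins overlapped by one oriented fragment
#'
#' Every bin overlapping \code{[start, end)} is included, so bins only
#' partially covered at a junction are retained. "+" fragments yield bins in
#' ascending order, "-" fragments in descending order.
#'
#' @param bt a [BinTable-class].
#' @param chrom,start,end,strand one fragment (0-based half-open, bp).
#' @return integer vector of 0-based global bin ids, in fragment order.
#' @export
fragmentToBins <- function(bt, chrom, start, end, strand = "+") {
    ci <- .chromIndex(bt, chrom)
    if (start < 0 || end > bt@chromLengths[ci] || start >= end)
        stop(sprintf("fragment %s:%g-%g outside chromosome or empty", chrom, start, end))
    first <- floor(start / bt@binsize)
    last <- floor((end - 1) / bt@binsize)
    bins <- as.integer(bt@offsets[ci] + first:last)
    if (strand == "-") rev(bins) else bins
}

#' Reduce a derivative chromosome to a BinMap
#'
#' Concatenates [fragmentToBins()] over the derivative's fragments, tagging
#' each entry with its 1-based fragment index. The BinMap is the single
#' source of truth for all downstream matrix rearrangement.
#'
#' @param bt a [BinTable-class].
#' @param d a [DerivativeGenome-class].
#' @return A [BinMap-class].
#' @export
derivativeToBinMap <- function(bt, d) {
    f <- fragments(d)
    if (nrow(f) == 0L) stop("empty derivative")
    pieces <- lapply(seq_len(nrow(f)), function(i) {
        b <- fragmentToBins(bt, f$chrom[i], f$start[i], f$end[i], f$strand[i])
        data.frame(sourceBin = b, orientation = f$strand[i], fragmentIndex = i)
    })
    new("BinMap", bintable = bt, entries = do.call(rbind, pieces))
}

#' Identity BinMap over one or all chromosomes
#'
#' @param bt a [BinTable-class].
#' @param chrom chromosome name, or NULL for the whole genome.
#' @return A [BinMap-class] listing bins in ascending order, "+" oriented.
#' @export
identityBinMap <- function(bt, chrom = NULL) {
    if (is.null(chrom)) {
        bins <- seq_len(nBins(bt)) - 1L
        ci <- findInterval(bins, bt@offsets)
        ent <- data.frame(sourceBin = bins, orientation = "+", fragmentIndex = ci)
    } else {
        i <- .chromIndex(bt, chrom)
        bins <- bt@offsets[i] + seq_len(bt@nBinsPerChrom[i]) - 1L
        ent <- data.frame(sourceBin = bins, orientation = "+", fragmentIndex = 1L)
    }
    new("BinMap", bintable = bt, entries = ent)
}

#' @export
setMethod("entries", "BinMap", function(x) x@entries)

#' @export
setMethod("length", "BinMap", function(x) nrow(x@entries))

setMethod("show", "BinMap", function(object) {
    e <- object@entries
    cat(sprintf("BinMap: %d entries, %d fragment run(s)\n",
                nrow(e), length(rle(e$fragmentIndex)$values)))
})
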