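#' @import methods
#' @importFrom Matrix sparseMatrix
NULL

#' Fixed-resolution binning of a reference genome
#'
#' A \code{BinTable} partitions a set of chromosomes into consecutive bins of
#' \code{binsize} base pairs (the last bin of each chromosome may be partial).
#' Global bin ids are 0-based, contiguous, and ordered by chromosome order
#' then position; chromosome order is the input order, never sorted.
#'
#' @slot chromNames character, unique chromosome identifiers, in input order.
#' @slot chromLengths numeric, chromosome lengths in bp.
#' @slot binsize numeric scalar, bin width in bp (e.g. 40000 for cancer-map
#'   workflows, 5000 for normal-map workflows).
#' @slot nBinsPerChrom integer, \code{ceiling(length / binsize)} per chromosome.
#' @slot offsets integer, global id of each chromosome's first bin.
#'
#' @seealso [makeBinTable()], [posToBin()], [fragmentToBins()]
#' @export
setClass("BinTable", representation(
    chromNames = "character",
    chromLengths = "numeric",
    binsize = "numeric",
    nBinsPerChrom = "integer",
    offsets = "integer"
))

setValidity("BinTable", function(object) {
    msg <- character()
    if (length(object@binsize) != 1L || object@binsize < 1)
        msg <- c(msg, "binsize must be a single value >= 1")
    if (anyDuplicated(object@chromNames))
        msg <- c(msg, "duplicate chromosome names")
    if (length(object@chromNames) != length(object@chromLengths))
        msg <- c(msg, "chromNames and chromLengths lengths differ")
    if (any(object@chromLengths < 1))
        msg <- c(msg, "all chromosome lengths must be >= 1")
    expect <- as.integer(ceiling(object@chromLengths / object@binsize))
    if (!identical(object@nBinsPerChrom, expect))
        msg <- c(msg, "nBinsPerChrom inconsistent with lengths and binsize")
    if (!identical(object@offsets,
                   as.integer(cumsum(c(0L, object@nBinsPerChrom))[
                       seq_along(object@chromNames)])))
        msg <- c(msg, "offsets are not contiguous")
    if (length(msg)) msg else TRUE
})

#' Derivative chromosome: an ordered list of oriented reference fragments
#'
#' Fragments are reference intervals (0-based, half-open) with a strand; they
#' may repeat (duplication), overlap, and span multiple chromosomes. Omitted
#' reference regions simply never appear, which is how deletions are encoded.
#'
#' @slot name identifier of the derivative chromosome.
#' @slot fragments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, 0-based half-open) and \code{strand} ("+" or "-").
#' @export
setClass("DerivativeGenome", representation(
    name = "character",
    fragments = "data.frame"
))

setValidity("DerivativeGenome", function(object) {
    f <- object@fragments
    msg <- character()
    need <- c("chrom", "start", "end", "strand")
    if (!all(need %in% names(f)))
        return("fragments must have columns chrom, start, end, strand")
    if (nrow(f) < 1L) msg <- c(msg, "a derivative needs at least one fragment")
    if (any(f$start < 0) || any(f$start >= f$end))
        msg <- c(msg, "fragments must satisfy 0 <= start < end")
    if (!all(f$strand %in% c("+", "-")))
        msg <- c(msg, "fragment strand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' Bin-level description of one rearranged axis
#'
#' A \code{BinMap} is the canonical reduction of every rearrangement: an
#' ordered list of (source bin, orientation, fragment index) entries over a
#' governing [BinTable]. Entries of one fragment form a contiguous run;
#' within a run, "+" entries have strictly increasing source bins and "-"
#' entries strictly decreasing ones.
#'
#' @slot bintable the governing [BinTable].
#' @slot entries data.frame with columns \code{sourceBin} (0-based global bin
#'   id), \code{orientation} ("+"/"-"), \code{fragmentIndex} (1-based).
#' @export
setClass("BinMap", representation(
    bintable = "BinTable",
    entries = "data.frame"
))

setValidity("BinMap", function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("sourceBin", "orientation", "fragmentIndex") %in% names(e)))
        return("entries must have columns sourceBin, orientation, fragmentIndex")
    nb <- nBins(object@bintable)
    if (nrow(e)) {
        if (any(e$sourceBin < 0L) || any(e$sourceBin >= nb))
            msg <- c(msg, "sourceBin out of range for the governing BinTable")
        if (!all(e$orientation %in% c("+", "-")))
            msg <- c(msg, "orientation must be '+' or '-'")
        runs <- rle(e$fragmentIndex)
        if (anyDuplicated(runs$values))
            msg <- c(msg, "fragment indices must form contiguous runs")
        pos <- 1L
        for (ri in seq_along(runs$lengths)) {
            len <- runs$lengths[ri]
            if (len > 1L) {
                seg <- e[pos:(pos + len - 1L), ]
                d <- diff(seg$sourceBin)
                ok <- if (seg$orientation[1L] == "+") all(d == 1L) else all(d == -1L)
                if (!ok || length(unique(seg$orientation)) != 1L)
                    msg <- c(msg, sprintf(
                        "fragment run %d is not a consistent oriented bin run",
                        runs$values[ri]))
            }
            pos <- pos + len
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

#' Sparse symmetric contact matrix over a BinTable
#'
#' Counts are stored upper-triangular (i <= j, 0-based global bin ids);
#' queries are symmetric. \code{values} optionally holds normalized values on
#' the same sparsity pattern (see [coverageNormalize()], [distanceNormalize()]).
#'
#' @slot bintable the governing [BinTable].
#' @slot counts upper-triangular sparse \code{dgCMatrix} of raw counts.
#' @slot values upper-triangular sparse matrix of normalized values, or NULL.
#' @slot zeroCoverage 0-based ids of bins flagged as zero-coverage by
#'   normalization.
#' @export
setClass("ContactMatrix", representation(
    bintable = "BinTable",
    counts = "ANY",
    values = "ANY",
    zeroCoverage = "integer"
))

setValidity("ContactMatrix", function(object) {
    nb <- nBins(object@bintable)
    m <- object@counts
    msg <- character()
    if (!is(m, "sparseMatrix") || nrow(m) != nb || ncol(m) != nb)
        msg <- c(msg, "counts must be an nBins x nBins sparse matrix")
    else {
        tm <- as(m, "TsparseMatrix")
        if (any(tm@x < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(tm@i > tm@j)) msg <- c(msg, "counts must be stored upper-triangular")
    }
    if (length(msg)) msg else TRUE
})

#' Distance-expected contact profile
#'
#' Mean contact value at each cis bin-distance d = |i - j| (structural zeros
#' included in the mean), smoothed by a log-space moving average and floored
#' at a small epsilon. Holds per-chromosome profiles and/or a pooled profile,
#' plus the pooled trans mean used to normalize trans pairs.
#'
#' @slot scope "per-chromosome" or "pooled".
#' @slot profiles named list, chromosome -> numeric vector indexed by d + 1.
#' @slot pooled pooled profile (always present; used for junction scoring).
#' @slot transMean mean count over all trans pairs (NA if no trans pairs).
#' @slot smoothWindow moving-average window in bins.
#' @slot epsilon positive floor applied after smoothing.
#' @export
setClass("ExpectedProfile", representation(
    scope = "character",
    profiles = "list",
    pooled = "numeric",
    transMean = "numeric",
    smoothWindow = "numeric",
    epsilon = "numeric"
))

#' A contact matrix materialized on a rearranged axis
#'
#' The axis is the concatenation of one [BinMap] per derivative; every value
#' is the source contact value at the mapped bin pair, times the trans
#' weight \code{w} when the two source bins come from different chromosomes.
#'
#' @slot matrix dense symmetric matrix over the concatenated axis.
#' @slot axis data.frame provenance, one row per axis position: derivative
#'   name, source bin id, orientation, fragment index, source chromosome and
#'   bin start (bp).
#' @slot derivativeBoundaries axis positions (1-based, counting bins to the
#'   left) after which a derivative boundary falls.
#' @slot fragmentBoundaries axis positions after which a fragment junction
#'   falls (includes derivative boundaries).
#' @slot weight the trans enhancement factor w >= 0 that was applied.
#' @slot binsize bin width in bp of the source matrix.
#' @export
setClass("RearrangedMatrix", representation(
    matrix = "matrix",
    axis = "data.frame",
    derivativeBoundaries = "integer",
    fragmentBoundaries = "integer",
    weight = "numeric",
    binsize = "numeric"
))

#' Cross-junction continuity score
#'
#' Mean observed/expected fold change over the k x k bin pairs flanking a
#' junction, with distance taken on the rearranged (derivative) axis. Values
#' near 1 indicate the junction behaves like ordinary contiguous chromatin;
#' values far below 1 indicate the two sides do not contact each other.
#'
#' @slot junction axis cut position scored (bins to the left of the cut).
#' @slot k window half-width in bins.
#' @slot score mean fold change S >= 0.
#' @slot nPairs number of pairs used.
#' @slot nExcluded pairs dropped for zero/floored expected values.
#' @export
setClass("SmoothnessReport", representation(
    junction = "integer",
    k = "integer",
    score = "numeric",
    nPairs = "integer",
    nExcluded = "integer"
))

#' Parameters of the synthetic Hi-C generator
#'
#' Cis contacts decay as \code{A * (1 + d)^(-alpha)} with bin distance d,
#' boosted by \code{beta} for pairs in the same TAD; trans contacts have flat
#' mean \code{t * A}. Counts are Poisson. The seed is mandatory: the
#' generator has no implicit randomness.
#'
#' @slot chromSizes named numeric, chromosome lengths in bp.
#' @slot binsize bin width in bp.
#' @slot A amplitude (> 0), the mean count at distance 0.
#' @slot alpha decay exponent (> 0).
#' @slot tadBoundaries optional named list, chromosome -> boundary bp
#'   positions, used when simulating on reference coordinates.
#' @slot nTads number of TADs to draw randomly per derivative when no
#'   explicit boundaries apply (0 = no TAD structure).
#' @slot beta within-TAD boost (>= 1).
#' @slot t trans contact level in [0, 1], as a fraction of A.
#' @slot seed integer RNG seed.
#' @export
setClass("SimParams", representation(
    chromSizes = "numeric",
    binsize = "numeric",
    A = "numeric",
    alpha = "numeric",
    tadBoundaries = "list",
    nTads = "numeric",
    beta = "numeric",
    t = "numeric",
    seed = "numeric"
))

setValidity("SimParams", function(object) {
    msg <- character()
    if (is.null(names(object@chromSizes)) || anyDuplicated(names(object@chromSizes)))
        msg <- c(msg, "chromSizes must be uniquely named")
    if (any(object@chromSizes < 1)) msg <- c(msg, "chromosome sizes must be >= 1")
    if (object@binsize < 1) msg <- c(msg, "binsize must be >= 1")
    if (object@A <= 0) msg <- c(msg, "A must be > 0")
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
    if (object@beta < 1) msg <- c(msg, "beta must be >= 1")
    if (object@t < 0 || object@t > 1) msg <- c(msg, "t must be in [0, 1]")
    if (object@nTads < 0) msg <- c(msg, "nTads must be >= 0")
    if (length(object@seed) != 1L || !is.finite(object@seed))
        msg <- c(msg, "a single finite seed is mandatory")
    if (length(msg)) msg else TRUE
})

#' An editing session over one or more derivative BinMaps
#'
#' Holds the current named list of [BinMap]s and a history stack so applied
#' edits can be reverted one at a time, mirroring interactive manipulation
#' of a contact map.
#'
#' @slot binmaps named list of [BinMap], the current state.
#' @slot history list of previous binmap states, most recent last.
#' @export
setClass("EditSession", representation(
    binmaps = "list",
    history = "list"
))
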