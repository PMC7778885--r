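#' Parameters for the synthetic Hi-C generator
#'
#' Defaults give a plain power-law map: mean cis count \code{A * (1 +
#' d)^(-alpha)} at bin distance d, flat trans background \code{t * A},
#' Poisson emission. TAD block structure is opt-in: set \code{nTads > 0} to
#' draw random TAD boundaries per derivative (boost \code{beta} within a
#' TAD), or give explicit per-chromosome boundary positions.
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param binsize bin width in bp.
#' @param A amplitude, mean count at distance 0 (default 100).
#' @param alpha decay exponent (default 1.0, a typical Hi-C contact-decay
#'   slope).
#' @param tadBoundaries named list, chromosome -> bp boundary positions.
#' @param nTads TADs to draw randomly per derivative when no explicit
#'   boundaries are given (default 0 = none).
#' @param beta within-TAD boost factor >= 1 (default 1.5).
#' @param t trans level as a fraction of A (default 0.05).
#' @param seed mandatory integer seed; the generator has no implicit
#'   randomness.
#' @return A [SimParams-class].
#' @export
simParams <- function(chromSizes, binsize, A = 100, alpha = 1,
                      tadBoundaries = list(), nTads = 0, beta = 1.5,
                      t = 0.05, seed) {
    if (missing(seed)) stop("seed is mandatory")
    new("SimParams", chromSizes = chromSizes, binsize = as.numeric(binsize),
        A = A, alpha = alpha, tadBoundaries = tadBoundaries, nTads = nTads,
        beta = beta, t = t, seed = as.numeric(seed))
}

#' Read generator parameters from a YAML config
#'
#' Keys: \code{chrom_sizes} (map name -> bp), \code{binsize}, \code{A},
#' \code{alpha}, \code{beta}, \code{t}, \code{n_tads},
#' \code{tad_boundaries} (map name -> list of bp), \code{seed}.
#'
#' @param path YAML file path.
#' @param seed overrides the config seed when given.
#' @return A [SimParams-class].
#' @export
readSimConfig <- function(path, seed = NULL) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$chrom_sizes) || is.null(cfg$binsize))
        stop("config needs chrom_sizes and binsize")
    get <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
    if (is.null(seed)) seed <- cfg$seed
    if (is.null(seed)) stop("config has no seed and none was given")
    simParams(chromSizes = unlist(cfg$chrom_sizes), binsize = cfg$binsize,
              A = get("A", 100), alpha = get("alpha", 1),
              tadBoundaries = lapply(get("tad_boundaries", list()), unlist),
              nTads = get("n_tads", 0), beta = get("beta", 1.5),
              t = get("t", 0.05), seed = seed)
}

## TAD id per axis position. Boundaries are drawn on the derivative axis
## (what the rearranged genome actually folds on); explicit reference
## boundaries, when given, are carried through the axis provenance.
.axisTads <- function(p, bt, binmaps) {
    ids <- integer(0)
    boundariesOut <- list()
    nextTad <- 1L
    for (nm in names(binmaps)) {
        n <- length(binmaps[[nm]])
        if (length(p@tadBoundaries)) {
            e <- binmaps[[nm]]@entries
            info <- binInfo(bt, e$sourceBin)
            tad <- integer(n)
            for (chrom in unique(info$chrom)) {
                sel <- info$chrom == chrom
                bp <- sort(unlist(p@tadBoundaries[[chrom]]))
                tad[sel] <- findInterval(info$start[sel], bp)
            }
            key <- paste(info$chrom, tad)
            ids <- c(ids, nextTad - 1L + as.integer(factor(key, levels = unique(key))))
            nextTad <- max(ids) + 1L
            boundariesOut[[nm]] <- which(diff(tad) != 0)
        } else if (p@nTads > 0 && n > 1L) {
            nb <- min(p@nTads - 1, n - 1L)
            cuts <- if (nb > 0) sort(sample.int(n - 1L, nb)) else integer()
            tad <- findInterval(seq_len(n) - 1L, cuts)
            ids <- c(ids, nextTad + tad)
            nextTad <- nextTad + length(cuts) + 1L
            boundariesOut[[nm]] <- cuts
        } else {
            ids <- c(ids, rep.int(nextTad, n))
            nextTad <- nextTad + 1L
            boundariesOut[[nm]] <- integer()
        }
    }
    list(ids = ids, boundaries = boundariesOut)
}

## Simulate counts on a derivative axis and project to reference bins.
.simulateCore <- function(p, binmaps) {
    bt <- makeBinTable(p@chromSizes, p@binsize)
    set.seed(as.integer(p@seed) %% .Machine$integer.max)
    tads <- .axisTads(p, bt, binmaps)
    src <- unlist(lapply(binmaps, function(b) b@entries$sourceBin), use.names = FALSE)
    der <- rep(seq_along(binmaps), vapply(binmaps, length, integer(1L)))
    n <- length(src)
    up <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    a <- up[, 1L]; b <- up[, 2L]
    sameDer <- der[a] == der[b]
    d <- b - a
    lambda <- ifelse(sameDer,
                     p@A * (1 + d)^(-p@alpha) *
                         ifelse(tads$ids[a] == tads$ids[b], p@beta, 1),
                     p@t * p@A)
    x <- stats::rpois(length(lambda), lambda)
    keep <- x > 0
    ri <- src[a[keep]]; rj <- src[b[keep]]
    cm <- contactMatrix(bt, i = pmin(ri, rj), j = pmax(ri, rj), x = x[keep])
    list(cm = cm, bt = bt, tadBoundaries = tads$boundaries,
         axisCounts = x, axisN = n)
}

#' Simulate a reference-coordinate Hi-C contact map
#'
#' Cis counts are Poisson with mean \code{A * (1 + d)^(-alpha)}, boosted by
#' \code{beta} within a TAD; trans counts are Poisson with mean
#' \code{t * A}. Deterministic given the seed.
#'
#' @param p a [SimParams-class].
#' @return list with \code{cm} (the [ContactMatrix-class]),
#'   \code{bintable}, and \code{tadBoundaries} (truth, bins after which a
#'   TAD boundary falls, per chromosome).
#' @export
simulateReference <- function(p) {
    res <- simulateRearranged(p, svs = NULL)
    list(cm = res$cm, bintable = res$bintable, tadBoundaries = res$tadBoundaries)
}

## Truth derivative set of an SV list: whole-genome, one derivative per
## junction product, untouched chromosomes as identity derivatives.
.truthDerivatives <- function(bt, svs) {
    ders <- list()
    touched <- character()
    if (!is.null(svs) && nrow(svs)) {
        for (k in seq_len(nrow(svs))) {
            sv <- svs[k, ]
            chroms <- unique(c(sv$chrom1, sv$chrom2))
            if (any(chroms %in% touched))
                stop("the truth builder supports at most one SV per chromosome")
            touched <- c(touched, chroms)
            if (sv$chrom1 == sv$chrom2 && sv$svtype == "INV") {
                ## a full inversion has two junctions; emit the balanced
                ## three-fragment derivative rather than one junction product
                L <- bt@chromLengths[.chromIndex(bt, sv$chrom1)]
                ders[[length(ders) + 1L]] <- derivativeGenome(
                    sprintf("der_INV_%s_%.0f_%.0f", sv$chrom1, sv$pos1, sv$pos2),
                    chrom = rep(sv$chrom1, 3L),
                    start = c(0, sv$pos1, sv$pos2),
                    end = c(sv$pos1, sv$pos2, L),
                    strand = c("+", "-", "+"))
            } else {
                ders[[length(ders) + 1L]] <- svToDerivative(bt, sv)
                if (sv$chrom1 != sv$chrom2) {
                    recip <- sv
                    recip$orientation <- c("3to5" = "5to3", "5to3" = "3to5",
                                           "3to3" = "5to5", "5to5" = "3to3")[sv$orientation]
                    ders[[length(ders) + 1L]] <- svToDerivative(bt, recip)
                }
            }
        }
    }
    for (chrom in setdiff(bt@chromNames, touched)) {
        L <- bt@chromLengths[.chromIndex(bt, chrom)]
        ders[[length(ders) + 1L]] <- derivativeGenome(chrom, chrom, 0, L, "+")
    }
    names(ders) <- vapply(ders, function(d) d@name, character(1L))
    ders
}

#' Simulate a Hi-C map of a rearranged genome, in reference coordinates
#'
#' Builds the truth derivative genome from the SV records (reciprocal
#' products for translocations, the balanced three-fragment derivative for
#' inversions, identity derivatives for untouched chromosomes), simulates
#' contacts on derivative coordinates exactly as [simulateReference()]
#' does, then projects every derivative bin pair back to its reference
#' source bins, accumulating counts. Bins duplicated by a DUP therefore
#' pile up their projected counts, as sequencing from two copies piles onto
#' one reference bin. With an empty SV list the result is identical to
#' [simulateReference()] at the same seed. Total counts are conserved by
#' the projection.
#'
#' @param p a [SimParams-class].
#' @param svs SV record data.frame (see [parseSVTable()]), or NULL.
#' @return list with \code{cm} (reference-coordinate
#'   [ContactMatrix-class]), \code{bintable}, truth \code{derivatives},
#'   truth \code{binmaps}, \code{tadBoundaries}, and \code{totalCount}.
#' @export
simulateRearranged <- function(p, svs = NULL) {
    bt <- makeBinTable(p@chromSizes, p@binsize)
    ders <- .truthDerivatives(bt, svs)
    binmaps <- lapply(ders, function(d) derivativeToBinMap(bt, d))
    res <- .simulateCore(p, binmaps)
    list(cm = res$cm, bintable = bt, derivatives = ders, binmaps = binmaps,
         tadBoundaries = res$tadBoundaries,
         totalCount = sum(res$axisCounts))
}

#' Estimate the contact-decay exponent of a map
#'
#' Least-squares slope of \code{log expected(d)} versus \code{log(1 + d)}
#' over the unsmoothed pooled cis expected profile, negated. Distances
#' with zero expectation are excluded; at least \code{minDistances}
#' distinct usable distances are required.
#'
#' @param cm a [ContactMatrix-class].
#' @param minDistances minimum usable distances (default 50).
#' @return the exponent estimate (positive for decaying maps).
#' @export
estimateDecayExponent <- function(cm, minDistances = 50L) {
    prof <- expectedByDistance(cm, scope = "pooled", smoothWindow = 1,
                               epsilon = 1e-300)
    e <- prof@pooled
    d <- seq_along(e) - 1L
    use <- e > 1e-290
    if (sum(use) < minDistances)
        stop("insufficient range: only ", sum(use), " distances with nonzero expectation")
    fit <- stats::lm.fit(cbind(1, log(1 + d[use])), log(e[use]))
    -unname(fit$coefficients[2L])
}

#' Write simulation truth to disk
#'
#' Emits the truth in the package's text dialects so every other module can
#' consume it: the SV table (when SVs were given) and the derivative order
#' spec.
#'
#' @param sim result of [simulateRearranged()].
#' @param dir output directory (created if needed).
#' @param svs the SV records that were simulated, or NULL.
#' @return invisibly, the paths written.
#' @export
writeSimTruth <- function(sim, dir, svs = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(order = file.path(dir, "truth_order.txt"))
    writeLines(formatOrderSpec(sim$derivatives), paths[["order"]])
    if (!is.null(svs) && nrow(svs)) {
        paths <- c(paths, sv = file.path(dir, "truth_sv.txt"))
        writeSVTable(svs, paths[["sv"]])
    }
    invisible(paths)
}
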