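#' Rendering options for contact-map heatmaps
#'
#' @param colormap "reds" (white-to-red, the field's convention), "heat" or
#'   "greys".
#' @param percentile saturation percentile in (0, 100]: values at or above
#'   this percentile of the nonzero values map to the top color.
#' @param triangle draw the rotated upper-triangle view instead of the
#'   square matrix.
#' @param tickSpacing ruler tick spacing in bp (> 0).
#' @param tracks character vector of BED/bedGraph file paths drawn as lanes
#'   below the map.
#' @param width,height figure size in inches.
#' @param res raster resolution in pixels per inch (PNG only).
#' @return validated options list of class "RenderOptions".
#' @export
renderOptions <- function(colormap = c("reds", "heat", "greys"),
                          percentile = 98, triangle = FALSE,
                          tickSpacing = 1e6, tracks = character(),
                          width = 6, height = 6, res = 96) {
    colormap <- match.arg(colormap)
    if (percentile <= 0 || percentile > 100)
        stop("percentile must be in (0, 100]")
    if (tickSpacing <= 0) stop("tickSpacing must be > 0")
    structure(list(colormap = colormap, percentile = percentile,
                   triangle = triangle, tickSpacing = tickSpacing,
                   tracks = tracks, width = width, height = height,
                   res = res), class = "RenderOptions")
}

.palette <- function(name, n = 64L) {
    ramp <- switch(name,
                   reds = grDevices::colorRampPalette(c("#FFFFFF", "#FDD49E",
                                                        "#EF6548", "#7F0000")),
                   heat = function(k) rev(grDevices::heat.colors(k)),
                   greys = grDevices::colorRampPalette(c("#FFFFFF", "#000000")))
    ramp(n)
}

.readTrack <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (!file.exists(path)) stop("track file not found: ", path)
    if (!ext %in% c("bed", "bedgraph", "bg"))
        stop("unknown track format: ", path)
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
        gr <- as.data.frame(rtracklayer::import(
            path, format = if (ext == "bed") "BED" else "bedGraph"))
        df <- data.frame(chrom = as.character(gr$seqnames),
                         start = gr$start - 1L, end = gr$end,
                         stringsAsFactors = FALSE)
        if (ext != "bed" && !is.null(gr$score)) df$score <- gr$score
        df
    } else {
        df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
        names(df)[1:3] <- c("chrom", "start", "end")
        if (ext != "bed" && ncol(df) >= 4L) names(df)[4L] <- "score"
        df
    }
}

## axis rows (1-based positions) overlapped by a reference interval
.trackHits <- function(axis, binsizeBp, chrom, start, end) {
    which(axis$chrom == chrom & axis$binStart < end &
              (axis$binStart + binsizeBp) > start)
}

.renderCore <- function(M, axis, derivB, fragB, binsizeBp, opts, file) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "png") {
        grDevices::png(file, width = opts$width * opts$res,
                       height = opts$height * opts$res, res = opts$res)
    } else if (ext == "svg") {
        grDevices::svg(file, width = opts$width, height = opts$height)
    } else stop("unknown output format: .", ext)
    on.exit(grDevices::dev.off())

    n <- nrow(M)
    nz <- M[M > 0]
    vmax <- if (length(nz)) stats::quantile(nz, opts$percentile / 100) else 1
    Mc <- pmin(M, vmax)
    pal <- .palette(opts$colormap)
    nTracks <- length(opts$tracks)
    heights <- c(10, 1.2, rep(0.8, nTracks))
    graphics::layout(matrix(seq_len(2L + nTracks), ncol = 1), heights = heights)
    graphics::par(mar = c(0.4, 4, 2, 2))

    if (opts$triangle) {
        graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0, n / 2 + 1),
                       xlab = "", ylab = "distance (bins)", xaxt = "n",
                       main = "", asp = NA)
        cols <- pal[pmax(1L, ceiling(as.vector(Mc) / max(vmax, 1e-12) * length(pal)))]
        dim(cols) <- dim(Mc)
        for (a in seq_len(n)) for (b in a:n) {
            cx <- (a + b) / 2; cy <- (b - a) / 2
            graphics::polygon(cx + c(-0.5, 0, 0.5, 0), cy + c(0, 0.5, 0, -0.5),
                              col = cols[a, b], border = NA)
        }
        graphics::abline(v = derivB + 0.5, col = "blue", lwd = 1.5, lty = 2)
    } else {
        graphics::image(x = seq_len(n), y = seq_len(n), z = t(Mc[n:1, , drop = FALSE]),
                        col = pal, zlim = c(0, max(vmax, 1e-12)),
                        xlab = "", ylab = "", xaxt = "n", yaxt = "n", useRaster = FALSE)
        graphics::abline(v = derivB + 0.5, col = "blue", lwd = 1.5)
        graphics::abline(h = n - derivB + 0.5, col = "blue", lwd = 1.5)
        graphics::abline(v = setdiff(fragB, derivB) + 0.5, col = "grey40", lty = 3)
        graphics::abline(h = n - setdiff(fragB, derivB) + 0.5, col = "grey40", lty = 3)
    }

    ## chromosome/ruler lane with fragment-orientation triangles
    graphics::par(mar = c(2.2, 4, 0.2, 2))
    graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0, 1), xlab = "",
                   ylab = "", axes = FALSE)
    bounds <- c(0L, fragB, n)
    bounds <- sort(unique(bounds))
    chromCols <- grDevices::hcl.colors(max(3L, length(unique(axis$chrom))), "Dark 3")
    names(chromCols)[seq_along(unique(axis$chrom))] <- unique(axis$chrom)
    for (i in seq_len(length(bounds) - 1L)) {
        lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
        graphics::rect(lo - 0.5, 0.35, hi + 0.5, 0.75,
                       col = chromCols[axis$chrom[lo]], border = "black")
        ## 5' -> 3' direction glyph
        dirRight <- axis$orientation[lo] == "+"
        mid <- (lo + hi) / 2
        wgl <- min(1.5, (hi - lo + 1) / 3)
        xs <- if (dirRight) c(mid - wgl, mid + wgl, mid - wgl)
              else c(mid + wgl, mid - wgl, mid + wgl)
        graphics::polygon(xs, c(0.38, 0.55, 0.72), col = "royalblue", border = NA)
    }
    ## ruler ticks every tickSpacing bp of axis run length
    tickEvery <- max(1L, round(opts$tickSpacing / binsizeBp))
    at <- seq(1L, n, by = tickEvery)
    graphics::axis(1, at = at, labels = sprintf("%.1f Mb", (at - 1L) * binsizeBp / 1e6),
                   cex.axis = 0.7)

    trackGlyphs <- integer(length(opts$tracks))
    names(trackGlyphs) <- opts$tracks
    for (ti in seq_along(opts$tracks)) {
        tr <- .readTrack(opts$tracks[ti])
        graphics::par(mar = c(0.4, 4, 0.2, 2))
        graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0, 1), xlab = "",
                       ylab = "", axes = FALSE)
        graphics::mtext(basename(opts$tracks[ti]), side = 2, cex = 0.5, las = 2)
        hasScore <- "score" %in% names(tr)
        smax <- if (hasScore) max(abs(tr$score), 1e-12) else 1
        count <- 0L
        for (ri in seq_len(nrow(tr))) {
            hits <- .trackHits(axis, binsizeBp, tr$chrom[ri], tr$start[ri], tr$end[ri])
            if (!length(hits)) next
            count <- count + 1L
            h <- if (hasScore) 0.1 + 0.85 * abs(tr$score[ri]) / smax else 0.8
            for (rng in split(hits, cumsum(c(1L, diff(hits) != 1L))))
                graphics::rect(min(rng) - 0.5, 0.05, max(rng) + 0.5, 0.05 + h,
                               col = "darkgreen", border = NA)
        }
        trackGlyphs[ti] <- count
    }
    list(nBoundaries = length(derivB), trackGlyphs = trackGlyphs)
}

#' Render a contact map heatmap
#'
#' Writes a PNG or SVG (chosen by file extension) with the heatmap, a
#' chromosome/fragment lane with 5'->3' orientation triangles, a bp ruler,
#' and optional BED/bedGraph track lanes. Derivative boundaries are drawn
#' as solid separators, fragment junctions as dotted ones. Output is
#' deterministic for fixed input and options.
#'
#' @param x a [RearrangedMatrix-class] or [ContactMatrix-class].
#' @param file output path ending in .png or .svg.
#' @param opts a [renderOptions()] list.
#' @param what for ContactMatrix input, "counts" or "values".
#' @return invisibly, a metadata list: pixel dimensions, number of boundary
#'   separators drawn, and per-track glyph counts.
#' @export
setMethod("renderHeatmap", "RearrangedMatrix", function(x, file, opts = renderOptions(), ...) {
    if (nrow(x@matrix) == 0L) stop("empty matrix")
    meta <- .renderCore(x@matrix, x@axis, x@derivativeBoundaries,
                        x@fragmentBoundaries, x@binsize, opts, file)
    invisible(c(list(file = file,
                     width_px = round(opts$width * opts$res),
                     height_px = round(opts$height * opts$res)), meta))
})

#' @rdname renderHeatmap-RearrangedMatrix-method
#' @export
setMethod("renderHeatmap", "ContactMatrix",
          function(x, file, opts = renderOptions(), what = c("counts", "values"), ...) {
    what <- match.arg(what)
    rm <- materialize(x, identityBinMap(x@bintable), w = 1, what = what)
    ## identity view: one lane block per chromosome
    renderHeatmap(rm, file, opts)
})
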