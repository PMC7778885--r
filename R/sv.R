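.SV_TYPES <- c("DEL", "DUP", "INV", "TRA")
.SV_ORIENTS <- c("3to5", "5to3", "3to3", "5to5")

## Orientation consistent with each intra-chromosomal type (TRA accepts any).
.TYPE_ORIENT <- list(DEL = "3to5", DUP = "5to3", INV = c("3to3", "5to5"))

#' Construct a structural-variant breakend record
#'
#' A record names one junction: two genomic cut coordinates, a declared type
#' and a breakend orientation code. A position p is the cut after the p-th
#' base, i.e. the 0-based half-open boundary between \code{[0, p)} and
#' \code{[p, L)}; this is the number printed in WGS SV tables.
#'
#' @param chrom1,pos1,chrom2,pos2 the two breakpoints (bp cut coordinates).
#' @param svtype one of DEL, DUP, INV, TRA.
#' @param orientation one of 3to5, 5to3, 3to3, 5to5 — which side (3' or 5')
#'   of each breakpoint is fused at the junction.
#' @return one-row data.frame; intra-chromosomal records are normalized so
#'   pos1 <= pos2 (swapping also swaps the orientation sides).
#' @export
svRecord <- function(chrom1, pos1, chrom2, pos2, svtype, orientation) {
    sv <- data.frame(chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                     chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                     svtype = as.character(svtype),
                     orientation = as.character(orientation),
                     stringsAsFactors = FALSE)
    .normalizeSV(sv)
}

.swapOrient <- c("3to5" = "5to3", "5to3" = "3to5", "3to3" = "3to3", "5to5" = "5to5")

.normalizeSV <- function(sv) {
    flip <- sv$chrom1 == sv$chrom2 & sv$pos1 > sv$pos2
    if (any(flip)) {
        tmp <- sv$pos1[flip]
        sv$pos1[flip] <- sv$pos2[flip]
        sv$pos2[flip] <- tmp
        sv$orientation[flip] <- .swapOrient[sv$orientation[flip]]
    }
    sv
}

#' Parse the whitespace-separated SV table dialect
#'
#' One record per line: \code{chrom1 pos1 chrom2 pos2 TYPE ORIENT}, e.g.
#' \code{"chr6 75343990 chr6 125216780 DEL 3to5"}. Lines starting with '#'
#' and blank lines are skipped. Serializing with [formatSVTable()] and
#' re-parsing round-trips exactly (modulo whitespace normalization).
#'
#' @param text character vector of lines (or one string with newlines).
#' @return data.frame of records (columns chrom1, pos1, chrom2, pos2,
#'   svtype, orientation), intra-chromosomal records normalized to
#'   pos1 <= pos2.
#' @export
parseSVTable <- function(text) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
    out <- vector("list", length(lines))
    for (ln in seq_along(lines)) {
        s <- trimws(lines[ln])
        if (!nzchar(s) || startsWith(s, "#")) next
        tok <- strsplit(s, "[ \t]+")[[1L]]
        if (length(tok) != 6L)
            stop(sprintf("SV table line %d: expected 6 columns, got %d", ln, length(tok)))
        p1 <- suppressWarnings(as.numeric(tok[2L]))
        p2 <- suppressWarnings(as.numeric(tok[4L]))
        if (is.na(p1) || is.na(p2) || p1 != round(p1) || p2 != round(p2))
            stop(sprintf("SV table line %d: non-integer position", ln))
        if (!(tok[5L] %in% .SV_TYPES))
            stop(sprintf("SV table line %d: unknown TYPE '%s'", ln, tok[5L]))
        if (!(tok[6L] %in% .SV_ORIENTS))
            stop(sprintf("SV table line %d: unknown ORIENT '%s'", ln, tok[6L]))
        out[[ln]] <- data.frame(chrom1 = tok[1L], pos1 = p1, chrom2 = tok[3L],
                                pos2 = p2, svtype = tok[5L], orientation = tok[6L],
                                stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out))
        return(data.frame(chrom1 = character(), pos1 = numeric(),
                          chrom2 = character(), pos2 = numeric(),
                          svtype = character(), orientation = character(),
                          stringsAsFactors = FALSE))
    .normalizeSV(do.call(rbind, out))
}

#' @rdname parseSVTable
#' @param path file path.
#' @export
readSVTable <- function(path) parseSVTable(readLines(path))

#' @rdname parseSVTable
#' @param sv SV record data.frame.
#' @return \code{formatSVTable}: character vector of dialect lines.
#' @export
formatSVTable <- function(sv) {
    sprintf("%s %.0f %s %.0f %s %s", sv$chrom1, sv$pos1, sv$chrom2, sv$pos2,
            sv$svtype, sv$orientation)
}

#' @rdname parseSVTable
#' @export
writeSVTable <- function(sv, path) writeLines(formatSVTable(sv), path)

#' Read breakend records from a 10-column BEDPE file
#'
#' Strand pairs map to orientation codes: (+,-) -> 3to5, (-,+) -> 5to3,
#' (+,+) -> 3to3, (-,-) -> 5to5. Start coordinates (0-based, BED convention)
#' are used as the breakpoints. The type is taken from the name field when
#' it is one of DEL/DUP/INV/TRA, otherwise inferred: inter-chromosomal
#' records become TRA, intra-chromosomal ones the type consistent with the
#' orientation (3to5 -> DEL, 5to3 -> DUP, 3to3/5to5 -> INV).
#'
#' @param path BEDPE file path.
#' @return SV record data.frame as from [parseSVTable()].
#' @export
readBEDPE <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 10L) stop("BEDPE requires 10 columns")
    key <- paste0(df[[9L]], df[[10L]])
    orient <- c("+-" = "3to5", "-+" = "5to3", "++" = "3to3", "--" = "5to5")[key]
    if (anyNA(orient)) stop("BEDPE strand columns must be '+' or '-'")
    svtype <- toupper(df[[7L]])
    infer <- !(svtype %in% .SV_TYPES)
    intra <- df[[1L]] == df[[4L]]
    svtype[infer & !intra] <- "TRA"
    svtype[infer & intra] <- c("3to5" = "DEL", "5to3" = "DUP", "3to3" = "INV",
                               "5to5" = "INV")[orient[infer & intra]]
    .normalizeSV(data.frame(chrom1 = df[[1L]], pos1 = as.numeric(df[[2L]]),
                            chrom2 = df[[4L]], pos2 = as.numeric(df[[5L]]),
                            svtype = svtype, orientation = unname(orient),
                            stringsAsFactors = FALSE))
}

#' Check a breakend record against a BinTable
#'
#' Returns human-readable findings instead of raising: unknown chromosomes,
#' out-of-range positions, and intra-chromosomal type/orientation
#' inconsistency (DEL expects 3to5, DUP 5to3, INV 3to3 or 5to5).
#'
#' @param bt a [BinTable-class].
#' @param sv a one-row SV record.
#' @return character vector of findings; empty when the record is clean.
#' @export
validateSV <- function(bt, sv) {
    findings <- character()
    for (side in 1:2) {
        chrom <- sv[[paste0("chrom", side)]]
        pos <- sv[[paste0("pos", side)]]
        ci <- match(chrom, bt@chromNames)
        if (is.na(ci)) {
            findings <- c(findings, sprintf("unknown chromosome '%s'", chrom))
        } else if (pos <= 0 || pos >= bt@chromLengths[ci]) {
            findings <- c(findings, sprintf(
                "position %.0f outside (0, %g) on %s", pos,
                bt@chromLengths[ci], chrom))
        }
    }
    if (sv$chrom1 == sv$chrom2 && sv$svtype %in% names(.TYPE_ORIENT) &&
        !(sv$orientation %in% .TYPE_ORIENT[[sv$svtype]])) {
        findings <- c(findings, sprintf(
            "intra-chromosomal %s expects orientation %s, got %s", sv$svtype,
            paste(.TYPE_ORIENT[[sv$svtype]], collapse = " or "), sv$orientation))
    }
    findings
}

#' Build the single-junction derivative chromosome of one breakend record
#'
#' The junction fuses side s1 of pos1 with side s2 of pos2, where "side 3 at
#' p" is the segment \code{[0, p)} in + orientation ending at p and "side 5
#' at p" is \code{[p, L)} in + orientation starting at p:
#' \itemize{
#'   \item 3to5: \code{[c1:0-p1 +] [c2:p2-L2 +]} — the DEL-joined product.
#'   \item 5to3: \code{[c2:0-p2 +] [c1:p1-L1 +]} — intra-chromosomally a
#'     tandem duplication of \code{[p1, p2)}.
#'   \item 3to3: \code{[c1:0-p1 +] [c2:0-p2 -]} — two 3' sides head-to-head.
#'   \item 5to5: \code{[c1:p1-L1 -] [c2:p2-L2 +]} — two 5' sides fused; no
#'     orientation of this derivative starts with a + fragment.
#' }
#' The derivative starts with a + fragment whenever the junction algebra
#' allows it. Type/orientation inconsistency for intra-chromosomal records
#' is a warning by default and an error with \code{strict = TRUE}.
#'
#' @param bt a [BinTable-class].
#' @param sv a one-row SV record (see [svRecord()], [parseSVTable()]).
#' @param strict error (rather than warn) on type/orientation inconsistency.
#' @return A [DerivativeGenome-class] with one junction.
#' @examples
#' bt <- makeBinTable(c(chr6 = 170805979), 40000)
#' sv <- svRecord("chr6", 75343990, "chr6", 125216780, "DEL", "3to5")
#' fragments(svToDerivative(bt, sv))
#' @export
svToDerivative <- function(bt, sv, strict = FALSE) {
    findings <- validateSV(bt, sv)
    hard <- findings[!grepl("expects orientation", findings)]
    if (length(hard)) stop(paste(hard, collapse = "; "))
    if (length(findings) > length(hard)) {
        if (strict) stop(findings[grepl("expects orientation", findings)])
        warning(findings[grepl("expects orientation", findings)])
    }
    L1 <- bt@chromLengths[.chromIndex(bt, sv$chrom1)]
    L2 <- bt@chromLengths[.chromIndex(bt, sv$chrom2)]
    p1 <- sv$pos1; p2 <- sv$pos2
    name <- sprintf("der_%s_%s_%.0f_%s_%.0f", sv$svtype, sv$chrom1, p1, sv$chrom2, p2)
    f <- switch(sv$orientation,
        "3to5" = data.frame(chrom = c(sv$chrom1, sv$chrom2), start = c(0, p2),
                            end = c(p1, L2), strand = "+"),
        "5to3" = data.frame(chrom = c(sv$chrom2, sv$chrom1), start = c(0, p1),
                            end = c(p2, L1), strand = "+"),
        "3to3" = data.frame(chrom = c(sv$chrom1, sv$chrom2), start = c(0, 0),
                            end = c(p1, p2), strand = c("+", "-")),
        "5to5" = data.frame(chrom = c(sv$chrom1, sv$chrom2), start = c(p1, p2),
                            end = c(L1, L2), strand = c("-", "+")),
        stop("unknown orientation: ", sv$orientation))
    new("DerivativeGenome", name = name,
        fragments = data.frame(f, stringsAsFactors = FALSE))
}

#' Reverse a derivative chromosome end-to-end
#'
#' Reverses the fragment order and flips every strand; the rearranged
#' contact map of the result is the input's map with both axes reversed.
#'
#' @param d a [DerivativeGenome-class].
#' @return the reversed [DerivativeGenome-class].
#' @export
reverseDerivative <- function(d) {
    f <- fragments(d)[rev(seq_len(nrow(fragments(d)))), , drop = FALSE]
    f$strand <- ifelse(f$strand == "+", "-", "+")
    rownames(f) <- NULL
    new("DerivativeGenome", name = d@name, fragments = f)
}
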