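#' Extract fragment 5' or 3' end positions
#'
#' Coordinates are 0-based half-open, so the last covered base of a
#' fragment `[start, end)` is `end - 1`. The 5' end of a Watson fragment
#' is `start` and its 3' end `end - 1`; for a Crick fragment the 5' end
#' is `end - 1` and the 3' end `start`.
#'
#' @param frags An [ok_fragments()] set.
#' @param which `"five_prime"` or `"three_prime"`.
#' @return Data frame with columns `chrom`, `pos`, `strand` (one row per
#'   fragment).
#' @export
fragment_end_positions <- function(frags, which = c("five_prime", "three_prime")) {
  which <- match.arg(which)
  w <- frags$strand == "Watson"
  pos <- if (which == "five_prime") {
    ifelse(w, frags$start, frags$end - 1)
  } else {
    ifelse(w, frags$end - 1, frags$start)
  }
  data.frame(chrom = frags$chrom, pos = pos, strand = frags$strand,
             stringsAsFactors = FALSE)
}

#' Offset histogram of fragment ends around nucleosome dyads
#'
#' Metagene aggregation: every (end, dyad) pair with `|end - dyad| <=
#' window` increments the offset `end - dyad`, so all dyads within the
#' window contribute (not nearest-dyad-only). Dyads are strandless;
#' offsets are not flipped. Use the `strand` argument to stratify by
#' fragment strand.
#'
#' @param ends Data frame (`chrom`, `pos`) from
#'   [fragment_end_positions()].
#' @param dyads Data frame (`chrom`, `pos`) of dyad positions (non-empty).
#' @param window Half-width in bp (>= 1).
#' @param normalization `"counts"` (default) or `"density"` (sums to 1).
#' @param strand Optional `"Watson"`/`"Crick"` to keep only ends of one
#'   fragment strand (requires a `strand` column in `ends`).
#' @return An `offset_histogram`: data frame with `offset` in
#'   `[-window, window]` and `count`; attribute `total` is the number of
#'   in-window (end, dyad) pairs.
#' @export
dyad_offset_histogram <- function(ends, dyads, window = 200,
                                  normalization = c("counts", "density"),
                                  strand = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(dyads) || !nrow(dyads)) stop("empty dyad list")
  if (window < 1) stop("window must be >= 1")
  if (!is.null(strand)) ends <- ends[ends$strand == strand, , drop = FALSE]
  offs <- (-window):window
  counts <- numeric(length(offs))
  for (ch in unique(ends$chrom)) {
    d <- sort(dyads$pos[dyads$chrom == ch])
    if (!length(d)) next
    e <- ends$pos[ends$chrom == ch]
    lo <- findInterval(e - window - 0.5, d) + 1L
    hi <- findInterval(e + window + 0.5, d)
    nmatch <- hi - lo + 1L
    keep <- nmatch > 0L
    if (!any(keep)) next
    d_idx <- sequence(nmatch[keep], from = lo[keep])
    off <- rep.int(e[keep], nmatch[keep]) - d[d_idx]
    counts <- counts + tabulate(off + window + 1L, nbins = length(offs))
  }
  total <- sum(counts)
  value <- if (normalization == "density" && total > 0) counts / total else counts
  structure(data.frame(offset = offs, count = value),
            total = total, normalization = normalization,
            class = c("offset_histogram", "data.frame"))
}

#' @export
print.offset_histogram <- function(x, ...) {
  cat(sprintf("<offset_histogram> +/-%d bp, %s pairs (%s)\n",
              max(x$offset), format(attr(x, "total"), big.mark = ","),
              attr(x, "normalization")))
  invisible(x)
}

#' @export
plot.offset_histogram <- function(x, ...) {
  graphics::plot(x$offset, x$count, type = "h",
                 xlab = "offset from dyad (bp)",
                 ylab = attr(x, "normalization"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Peak-to-background ratio of a dyad offset histogram
#'
#' Summary of nucleosome phasing strength: the mean count within
#' `peak_halfwidth` of offset 0 divided by the mean count over the whole
#' histogram (the uniform-background expectation). An unphased library
#' gives ~1; the ratio grows as ends concentrate at dyads, up to
#' `(2*window+1) / (2*peak_halfwidth+1)` when all in-window mass sits in
#' the peak, so it stays finite even for perfectly phased input.
#'
#' @param hist An `offset_histogram`.
#' @param peak_halfwidth Peak half-width in bp.
#' @return A single ratio (> 1 indicates dyad enrichment).
#' @export
phasing_ratio <- function(hist, peak_halfwidth = 5) {
  bg <- mean(hist$count)
  if (bg == 0) stop("histogram is empty")
  mean(hist$count[abs(hist$offset) <= peak_halfwidth]) / bg
}

#' Fragment length distribution
#'
#' @param frags An [ok_fragments()] set (non-empty).
#' @param bin Histogram bin width in bp.
#' @return A `length_distribution`: list with `histogram` (data frame
#'   `length` = bin left edge, `count`), `mean`, `median`, `mode` (left
#'   edge of the modal histogram bin; smallest on ties) and the raw
#'   `lengths`.
#' @export
length_distribution <- function(frags, bin = 10) {
  if (!nrow(frags)) stop("empty fragment set")
  len <- frags$end - frags$start
  edges <- seq(0, max(len) + bin, by = bin)
  cnt <- tabulate(findInterval(len, edges), nbins = length(edges) - 1L)
  structure(list(histogram = data.frame(length = edges[-length(edges)],
                                        count = cnt),
                 mean = mean(len), median = stats::median(len),
                 mode = edges[which.max(cnt)], lengths = len),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("<length_distribution> n = %s, mean %.1f, median %g, mode %g bp\n",
              format(length(x$lengths), big.mark = ","), x$mean, x$median,
              x$mode))
  invisible(x)
}

#' @export
plot.length_distribution <- function(x, ...) {
  graphics::plot(x$histogram$length, x$histogram$count, type = "s",
                 xlab = "fragment length (bp)", ylab = "count", ...)
  invisible(x)
}
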