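#' G1-normalised S-phase copy-number track
#'
#' Builds the S/G1 read-depth ratio from binned counts. Pipeline order:
#' mask bins overlapping the exclusion list, scale each sample to
#' reads-per-million (over unmasked bins), divide each sample by its own
#' median unmasked bin value, then take the per-bin ratio S/G1. Bins with
#' zero G1 signal are masked. The two scalings make the ratio invariant
#' to sequencing depth, and re-applying the normalisation leaves the
#' ratio unchanged.
#'
#' @param s_counts,g1_counts [binned_counts()] on the same genome and bin
#'   grid (S-phase pool and G1 control).
#' @param exclusions Optional data frame (`chrom`, `start`, `end`) of
#'   regions to mask, as from [read_exclusions()].
#' @return A `cn_track`: bin size, genome, per-chromosome `ratio` vectors
#'   (`NA` = masked) and processing `state` (`"normalized"`).
#' @export
normalize_track <- function(s_counts, g1_counts, exclusions = NULL) {
  stopifnot(inherits(s_counts, "binned_counts"),
            inherits(g1_counts, "binned_counts"))
  if (s_counts$bin_size != g1_counts$bin_size ||
      !identical(s_counts$genome$chrom, g1_counts$genome$chrom))
    stop("S and G1 counts must share one genome and bin grid")
  genome <- s_counts$genome
  bin <- s_counts$bin_size
  mask <- lapply(genome$chrom, function(ch)
    rep(FALSE, length(s_counts$values[[ch]])))
  names(mask) <- genome$chrom
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      ch <- exclusions$chrom[i]
      if (!ch %in% genome$chrom) stop("exclusion on unknown chromosome: ", ch)
      i0 <- floor(exclusions$start[i] / bin) + 1L
      i1 <- ceiling(exclusions$end[i] / bin)
      i1 <- min(i1, length(mask[[ch]]))
      if (i0 <= i1) mask[[ch]][i0:i1] <- TRUE
    }
  }
  norm_sample <- function(values) {
    v <- lapply(genome$chrom, function(ch) {
      x <- as.numeric(values[[ch]])
      x[mask[[ch]] | is.na(x)] <- NA_real_
      x
    })
    names(v) <- genome$chrom
    tot <- sum(unlist(v), na.rm = TRUE)
    if (tot <= 0) stop("all bins masked or zero")
    v <- lapply(v, function(x) x / tot * 1e6)
    med <- stats::median(unlist(v), na.rm = TRUE)
    if (med <= 0) stop("median unmasked bin value is zero")
    lapply(v, function(x) x / med)
  }
  s_n <- norm_sample(s_counts$values)
  g_n <- norm_sample(g1_counts$values)
  ratio <- lapply(genome$chrom, function(ch) {
    r <- s_n[[ch]] / g_n[[ch]]
    r[!is.finite(r)] <- NA_real_
    r
  })
  names(ratio) <- genome$chrom
  if (all(is.na(unlist(ratio)))) stop("all bins masked")
  structure(list(bin_size = bin, genome = genome, ratio = ratio,
                 state = "normalized"),
            class = "cn_track")
}

#' @export
print.cn_track <- function(x, ...) {
  v <- unlist(x$ratio)
  cat(sprintf("<cn_track> bin %d bp, state %s, %d/%d bins defined, median ratio %.3f\n",
              x$bin_size, x$state, sum(!is.na(v)), length(v),
              stats::median(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.cn_track <- function(x, chrom = x$genome$chrom[1], ...) {
  v <- x$ratio[[chrom]]
  pos <- (seq_along(v) - 0.5) * x$bin_size / 1000
  graphics::plot(pos, v, type = "l", xlab = sprintf("%s position (kb)", chrom),
                 ylab = "S/G1 ratio", ...)
  invisible(x)
}

#' Loess-smooth a copy-number track
#'
#' Per-chromosome local linear regression with tricube weights
#' (`stats::loess`, degree 1) over a window spanning `span_fraction` of
#' the chromosome's bins. Masked bins are skipped; output is defined only
#' where at least `min_window_points` unmasked bins fall inside the
#' centred smoothing window.
#'
#' @param track A `cn_track` from [normalize_track()].
#' @param span_fraction Window width as a fraction of chromosome bins,
#'   in (0, 1].
#' @param min_window_points Minimum unmasked bins per window.
#' @return A `cn_track` with `state = "smoothed"`.
#' @export
loess_smooth <- function(track, span_fraction = 0.02, min_window_points = 10) {
  stopifnot(inherits(track, "cn_track"))
  if (track$state != "normalized" && track$state != "smoothed")
    stop("track must be normalized before smoothing")
  if (!(span_fraction > 0 && span_fraction <= 1))
    stop("span_fraction must be in (0,1]")
  out <- track$ratio
  for (ch in track$genome$chrom) {
    v <- track$ratio[[ch]]
    n <- length(v)
    ok <- which(!is.na(v))
    sm <- rep(NA_real_, n)
    if (length(ok) >= min_window_points) {
      fit <- stats::loess(v[ok] ~ ok, span = span_fraction, degree = 1,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      pred <- stats::predict(fit, newdata = data.frame(ok = ok))
      # window support: unmasked bins within half the span window
      half <- max(1, floor(span_fraction * n / 2))
      inwin <- vapply(ok, function(i)
        sum(ok >= i - half & ok <= i + half), integer(1))
      good <- inwin >= min_window_points
      sm[ok[good]] <- pred[good]
    }
    out[[ch]] <- sm
  }
  structure(list(bin_size = track$bin_size, genome = track$genome,
                 ratio = out, state = "smoothed"),
            class = "cn_track")
}

#' Meta-origin coverage profile
#'
#' Re-bins the ratio track to `smooth_bin` block means and averages it
#' around origin midpoints with equal origin weight, for all origins or
#' a timing-defined subset.
#'
#' @param track A `cn_track`.
#' @param origins An [origin_table()].
#' @param window Half-width in bp (multiple of `smooth_bin`).
#' @param smooth_bin Block size in bp for re-binning (default 1000).
#' @param subset `NULL` for all origins, or a list
#'   `list(t_rep_below = theta)` / `list(t_rep_above = theta)` selecting
#'   origins with `t_rep < theta` or `>= theta`, or a character vector of
#'   origin names.
#' @return A `meta_profile` of mean coverage ratio per offset block.
#' @export
meta_origin_coverage <- function(track, origins, window = 10000,
                                 smooth_bin = 1000, subset = NULL) {
  stopifnot(inherits(track, "cn_track"))
  if (window %% smooth_bin != 0) stop("smooth_bin must divide window")
  if (window < smooth_bin) stop("window must be >= smooth_bin")
  org <- origins
  if (!is.null(subset)) {
    if (is.character(subset)) {
      org <- org[org$name %in% subset, , drop = FALSE]
    } else if (!is.null(subset$t_rep_below)) {
      org <- org[!is.na(org$t_rep) & org$t_rep < subset$t_rep_below, , drop = FALSE]
    } else if (!is.null(subset$t_rep_above)) {
      org <- org[!is.na(org$t_rep) & org$t_rep >= subset$t_rep_above, , drop = FALSE]
    } else stop("unknown subset specification")
  }
  if (!nrow(org)) stop("empty origin subset")
  bin <- track$bin_size
  if (smooth_bin %% bin != 0) stop("track bin size must divide smooth_bin")
  offs <- seq(-window, window - smooth_bin, by = smooth_bin)
  acc_sum <- numeric(length(offs)); acc_n <- numeric(length(offs))
  for (i in seq_len(nrow(org))) {
    ch <- org$chrom[i]; m <- org$midpoint[i]
    v <- track$ratio[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    for (k in seq_along(offs)) {
      a <- m + offs[k]; b <- a + smooth_bin
      i0 <- max(1, ceiling((a + bin / 2) / bin))
      i1 <- min(length(v), ceiling(b / bin + 0.5) - 1)
      if (i1 < i0) next
      vals <- v[i0:i1]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        acc_sum[k] <- acc_sum[k] + mean(vals)
        acc_n[k] <- acc_n[k] + 1
      }
    }
  }
  value <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  structure(data.frame(offset = offs, value = value),
            n_origins = nrow(org), normalized = FALSE,
            quantity = "coverage_ratio",
            class = c("meta_profile", "data.frame"))
}
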