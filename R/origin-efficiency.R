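#' Origin Efficiency Metric for one origin
#'
#' The OEM is the difference in Watson-strand fragment fraction between
#' the left and right 10 kb flanks of an origin midpoint:
#' `OEM = W_L/(W_L+C_L) - W_R/(W_R+C_R)` with left flank
#' `[m - window, m)` and right flank `[m, m + window)`. Because Watson
#' fragments derive from leftward-moving forks, an origin that fires in
#' every cell has OEM 1; one that never fires locally, 0; the OEM of an
#' origin firing in a fraction `f` of cells approximates `f`. The OEM is
#' undefined (`NA`) when either flank holds fewer than `min_count`
#' fragments. Flanks truncated by a chromosome end use the available bins.
#'
#' @param cov A `stranded_coverage` from [stranded_counts()].
#' @param chrom,midpoint Origin location.
#' @param window Flank width in bp (default 10000; must be >= the
#'   coverage bin size).
#' @param min_count Minimum `W + C` per flank for a defined OEM.
#' @return One-row data frame: `oem`, `w_l`, `c_l`, `w_r`, `c_r`,
#'   `defined`.
#' @export
oem <- function(cov, chrom, midpoint, window = 10000, min_count = 50) {
  if (window < cov$bin_size) stop("window must be >= coverage bin size")
  L <- chrom_length(cov$genome, chrom)
  left <- flank_counts(cov, chrom, max(0, midpoint - window), midpoint)
  right <- flank_counts(cov, chrom, midpoint, min(L, midpoint + window))
  nl <- left[["W"]] + left[["C"]]
  nr <- right[["W"]] + right[["C"]]
  defined <- nl >= min_count && nr >= min_count
  val <- if (defined) left[["W"]] / nl - right[["W"]] / nr else NA_real_
  data.frame(oem = val, w_l = left[["W"]], c_l = left[["C"]],
             w_r = right[["W"]], c_r = right[["C"]], defined = defined)
}

#' Genome-wide OEM table
#'
#' Applies [oem()] to every origin, preserving origin order.
#'
#' @param cov A `stranded_coverage`.
#' @param origins An [origin_table()] (non-empty).
#' @inheritParams oem
#' @return An `oem_table`: data frame with origin annotation columns plus
#'   `oem`, the four flank counts and `defined`. `summary()` reports
#'   median, quartiles and range over defined records only.
#' @export
oem_table <- function(cov, origins, window = 10000, min_count = 50) {
  if (!nrow(origins)) stop("empty origin table")
  recs <- lapply(seq_len(nrow(origins)), function(i)
    oem(cov, origins$chrom[i], origins$midpoint[i], window, min_count))
  out <- cbind(as.data.frame(origins), do.call(rbind, recs))
  structure(out, window = window, min_count = min_count,
            class = c("oem_table", "data.frame"))
}

#' @export
print.oem_table <- function(x, ...) {
  cat(sprintf("<oem_table> %d origins, %d defined (window %d bp)\n",
              nrow(x), sum(x$defined), attr(x, "window")))
  print(utils::head(as.data.frame(x)[, c("name", "chrom", "midpoint", "oem",
                                         "defined")], 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.oem_table <- function(object, ...) {
  v <- object$oem[object$defined]
  if (!length(v)) stop("no defined OEM records")
  out <- c(n = nrow(object), n_defined = length(v),
           min = min(v), q1 = unname(stats::quantile(v, 0.25)),
           median = stats::median(v),
           q3 = unname(stats::quantile(v, 0.75)), max = max(v))
  class(out) <- "summary.oem_table"
  out
}

#' @export
print.summary.oem_table <- function(x, ...) {
  cat(sprintf("OEM over %d origins (%d defined):\n", x[["n"]], x[["n_defined"]]))
  cat(sprintf("  min %.3f | Q1 %.3f | median %.3f | Q3 %.3f | max %.3f\n",
              x[["min"]], x[["q1"]], x[["median"]], x[["q3"]], x[["max"]]))
  invisible(x)
}

#' Write an OEM table to TSV
#' @param x An `oem_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oem_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Meta-origin Watson-fraction profile
#'
#' For each offset bin in `[-window, window)` relative to the origin
#' midpoint, averages the per-origin Watson fraction with equal origin
#' weight (origins contributing zero counts to a bin are omitted from
#' that bin's mean). Optionally divides the profile by its maximum, the
#' normalisation used for meta-origin strand plots.
#'
#' @param cov A `stranded_coverage`.
#' @param origins An [origin_table()] (non-empty).
#' @param window Half-width in bp.
#' @param bin Offset bin width in bp; must divide `window`.
#' @param normalize_max Divide by the profile maximum.
#' @return A `meta_profile`: data frame with `offset` (bin left edge
#'   relative to the midpoint) and `value`; attribute `n_origins`.
#' @export
meta_origin_profile <- function(cov, origins, window = 10000, bin = 100,
                                normalize_max = FALSE) {
  if (!nrow(origins)) stop("no origins")
  if (window %% bin != 0) stop("bin must divide window")
  offs <- seq(-window, window - bin, by = bin)
  acc_sum <- numeric(length(offs))
  acc_n <- numeric(length(offs))
  for (i in seq_len(nrow(origins))) {
    ch <- origins$chrom[i]; m <- origins$midpoint[i]
    L <- chrom_length(cov$genome, ch)
    for (k in seq_along(offs)) {
      a <- m + offs[k]; b <- a + bin
      if (b <= 0 || a >= L) next
      n <- flank_counts(cov, ch, max(0, a), min(L, b))
      tot <- n[["W"]] + n[["C"]]
      if (tot > 0) {
        acc_sum[k] <- acc_sum[k] + n[["W"]] / tot
        acc_n[k] <- acc_n[k] + 1
      }
    }
  }
  value <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  if (normalize_max) {
    mx <- max(value, na.rm = TRUE)
    if (mx > 0) value <- value / mx
  }
  structure(data.frame(offset = offs, value = value),
            n_origins = nrow(origins), normalized = normalize_max,
            quantity = "watson_fraction",
            class = c("meta_profile", "data.frame"))
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %s over %d origins, offsets %d..%d bp%s\n",
              attr(x, "quantity"), attr(x, "n_origins"),
              min(x$offset), max(x$offset),
              if (isTRUE(attr(x, "normalized"))) " (max-normalized)" else ""))
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$offset, x$value, type = "l",
                 xlab = "offset from origin midpoint (bp)",
                 ylab = attr(x, "quantity"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Split origins into groups and compare OEM distributions
#'
#' Partitions annotated origins by a scheme and runs a two-sided unpaired
#' t-test (Welch by default) between two named groups:
#' * `timing_median`: early (`t_rep` below the median timing of annotated
#'   origins) vs late (at or above).
#' * `fkh`: Forkhead classes; compares the pair named in `groups`.
#' * `earliest_k`: `t_rep < theta` vs the remaining origins.
#'
#' Origins lacking the needed annotation or a defined OEM are excluded
#' and counted.
#'
#' @param tab An `oem_table` from [oem_table()].
#' @param scheme `"timing_median"`, `"fkh"` or `"earliest_k"`.
#' @param theta Timing threshold in minutes for `earliest_k`.
#' @param groups For `fkh`: the two classes to compare.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List with `groups` (named list of OEM vectors), `test`
#'   (`t`, `df`, `p`), `n_excluded`.
#' @export
split_and_compare <- function(tab, scheme = c("timing_median", "fkh", "earliest_k"),
                              theta = 18, groups = c("activated", "repressed"),
                              var_equal = FALSE) {
  scheme <- match.arg(scheme)
  def <- tab$defined & !is.na(tab$oem)
  if (scheme %in% c("timing_median", "earliest_k")) {
    ann <- !is.na(tab$t_rep)
    excl <- sum(!(def & ann))
    t_rep <- tab$t_rep
    if (scheme == "timing_median") {
      med <- stats::median(t_rep[ann])
      ga <- tab$oem[def & ann & t_rep < med]
      gb <- tab$oem[def & ann & t_rep >= med]
      gnames <- c("early", "late")
    } else {
      ga <- tab$oem[def & ann & t_rep < theta]
      gb <- tab$oem[def & ann & t_rep >= theta]
      gnames <- c(sprintf("t_rep<%g", theta), sprintf("t_rep>=%g", theta))
    }
  } else {
    ann <- tab$fkh_class %in% groups
    excl <- sum(!(def & ann))
    ga <- tab$oem[def & tab$fkh_class == groups[1]]
    gb <- tab$oem[def & tab$fkh_class == groups[2]]
    gnames <- groups
  }
  if (length(ga) < 2 || length(gb) < 2)
    stop("each group needs at least 2 defined OEM values")
  ht <- stats::t.test(ga, gb, var.equal = var_equal)
  out <- list(groups = stats::setNames(list(ga, gb), gnames),
              test = list(t = unname(ht$statistic),
                          df = unname(ht$parameter),
                          p = ht$p.value),
              n_excluded = excl, scheme = scheme)
  class(out) <- "oem_comparison"
  out
}

#' @export
print.oem_comparison <- function(x, ...) {
  gn <- names(x$groups)
  cat(sprintf("<oem_comparison> %s: %s (n=%d, mean %.3f) vs %s (n=%d, mean %.3f)\n",
              x$scheme, gn[1], length(x$groups[[1]]), mean(x$groups[[1]]),
              gn[2], length(x$groups[[2]]), mean(x$groups[[2]])))
  cat(sprintf("  unpaired t = %.3f, df = %.2f, p = %.4g (%d origins excluded)\n",
              x$test$t, x$test$df, x$test$p, x$n_excluded))
  invisible(x)
}

#' Replicate agreement between two OEM tables
#'
#' Pearson correlation of OEM values over origins defined in both tables.
#'
#' @param table_a,table_b Two `oem_table`s over the same origin set.
#' @return List with `r`, `n_used`, `n_dropped` and the paired `data`
#'   (name, oem_a, oem_b) for scatter plotting.
#' @export
replicate_correlation <- function(table_a, table_b) {
  if (!identical(table_a$name, table_b$name))
    stop("the two tables must cover the same origins in the same order")
  ok <- table_a$defined & table_b$defined &
    !is.na(table_a$oem) & !is.na(table_b$oem)
  if (sum(ok) < 3) stop("fewer than 3 jointly defined origins")
  a <- table_a$oem[ok]; b <- table_b$oem[ok]
  list(r = stats::cor(a, b), n_used = sum(ok), n_dropped = sum(!ok),
       data = data.frame(name = table_a$name[ok], oem_a = a, oem_b = b,
                         stringsAsFactors = FALSE))
}
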