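#' Replication-fork direction profile around oriented loci
#'
#' For each offset bin relative to a locus midpoint, pools Watson/Crick
#' fragment counts across loci and reports the rightward-fork fraction
#' `Crick / (Watson + Crick)` (Crick fragments derive from
#' rightward-moving forks). Offsets are transcription-oriented: for
#' minus-strand loci offsets are reflected and strands swapped before
#' aggregation, so positive offsets always point downstream of
#' transcription. Increased fork arrest at the loci appears as a drop in
#' the profile at or after offset 0.
#'
#' @param cov A `stranded_coverage` from [stranded_counts()]; its bin
#'   size must divide `bin`.
#' @param loci Data frame of oriented loci (`chrom`, `midpoint`,
#'   `strand`) as from [read_loci()] (non-empty).
#' @param window Half-width in bp.
#' @param bin Offset bin width in bp; must divide `window`.
#' @return A `direction_profile`: data frame with `offset` (bin left
#'   edge) and `value` (rightward-fork fraction, `NA` on zero counts);
#'   attribute `n_loci`.
#' @export
fork_direction_profile <- function(cov, loci, window = 5000, bin = 100) {
  if (is.null(loci) || !nrow(loci)) stop("empty locus list")
  if (!all(c("chrom", "midpoint", "strand") %in% names(loci)))
    stop("loci need chrom, midpoint and strand columns")
  if (window %% bin != 0) stop("bin must divide window")
  offs <- seq(-window, window - bin, by = bin)
  wat <- numeric(length(offs)); cri <- numeric(length(offs))
  for (i in seq_len(nrow(loci))) {
    ch <- loci$chrom[i]; m <- loci$midpoint[i]
    L <- chrom_length(cov$genome, ch)
    minus <- loci$strand[i] == "-"
    for (k in seq_along(offs)) {
      # genomic interval for transcription-oriented offset bin
      if (!minus) { a <- m + offs[k]; b <- a + bin }
      else { b <- m - offs[k]; a <- b - bin }
      if (b <= 0 || a >= L) next
      n <- flank_counts(cov, ch, max(0, a), min(L, b))
      if (!minus) {
        wat[k] <- wat[k] + n[["W"]]; cri[k] <- cri[k] + n[["C"]]
      } else {
        # reflected: genomic Watson (leftward) is downstream-moving
        wat[k] <- wat[k] + n[["C"]]; cri[k] <- cri[k] + n[["W"]]
      }
    }
  }
  tot <- wat + cri
  value <- ifelse(tot > 0, cri / tot, NA_real_)
  structure(data.frame(offset = offs, value = value,
                       watson = wat, crick = cri),
            n_loci = nrow(loci), class = c("direction_profile", "data.frame"))
}

#' @export
print.direction_profile <- function(x, ...) {
  cat(sprintf("<direction_profile> %d loci, offsets %d..%d bp\n",
              attr(x, "n_loci"), min(x$offset), max(x$offset)))
  invisible(x)
}

#' @export
plot.direction_profile <- function(x, ...) {
  graphics::plot(x$offset, x$value, type = "l", ylim = c(0, 1),
                 xlab = "offset from locus midpoint (transcription-oriented, bp)",
                 ylab = "rightward-fork fraction", ...)
  graphics::abline(v = 0, lty = 3); graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Stall score of a direction profile
#'
#' Mean rightward-fork fraction downstream of the locus midpoint
#' (offsets in `(0, flank]`) minus the mean upstream (`[-flank, 0)`).
#' Fork arrest at the locus removes downstream rightward coverage and
#' upstream leftward coverage, so a stalling signature is a negative
#' score; without stalling the score is ~0 by symmetry.
#'
#' @param profile A `direction_profile` covering at least `[-flank, flank]`.
#' @param flank Flank width in bp.
#' @return A single numeric score.
#' @export
stall_score <- function(profile, flank = 2000) {
  if (min(profile$offset) > -flank || max(profile$offset) < flank - 1)
    stop("profile does not cover +/-", flank, " bp")
  bin <- profile$offset[2] - profile$offset[1]
  mid <- profile$offset + bin / 2
  dn <- profile$value[mid > 0 & mid <= flank]
  up <- profile$value[mid >= -flank & mid < 0]
  dn <- dn[!is.na(dn)]; up <- up[!is.na(up)]
  if (!length(dn) || !length(up)) stop("all bins undefined in the flank range")
  mean(dn) - mean(up)
}

#' Filter loci to origin-distal ones
#'
#' Drops loci whose midpoint lies within `min_dist` of any origin
#' midpoint, the preselection used for fork-stalling analyses around
#' tRNA genes.
#'
#' @param loci Data frame with `chrom`, `midpoint`.
#' @param origins An [origin_table()].
#' @param min_dist Minimum distance in bp (default 10000).
#' @return The filtered loci data frame.
#' @export
origin_distal_loci <- function(loci, origins, min_dist = 10000) {
  keep <- vapply(seq_len(nrow(loci)), function(i) {
    o <- origins$midpoint[origins$chrom == loci$chrom[i]]
    !length(o) || min(abs(o - loci$midpoint[i])) >= min_dist
  }, logical(1))
  loci[keep, , drop = FALSE]
}
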