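#' Simulate one cell's replication program
#'
#' Draws per-origin competence and firing times, then resolves the whole
#' genome by earliest fork arrival: each position is replicated by the
#' first fork to reach it, competent origins reached before their firing
#' time are passively replicated, and fork direction flips only at fired
#' origins (divergence) and at collision or stall points (convergence).
#' Cells in which no origin fires anywhere are rejected and redrawn.
#'
#' @param config A [sim_config()].
#' @param cell_seed Optional integer seed for this cell's RNG substream;
#'   if `NULL` the current RNG state is used.
#' @return A `replication_program`: per chromosome a data frame of
#'   segments (`start`, `end`, `dir` with +1 = rightward fork,
#'   -1 = leftward, `NA` = never replicated; `fork_pos`, `fork_time`
#'   give the generating origin so replication time at `x` is
#'   `fork_time + |x - fork_pos| / fork_speed`), plus the fired-origin
#'   table.
#' @export
simulate_cell <- function(config, cell_seed = NULL) {
  if (!is.null(cell_seed)) set.seed(cell_seed)
  org <- config$origins
  p <- effective_competence(config)
  if (all(p <= 0)) stop("unreplicatable genome: all origin competences are 0")
  v <- config$fork_speed

  for (attempt in seq_len(10000L)) {
    comp <- stats::runif(nrow(org)) < p
    if (any(comp)) break
    if (attempt == 10000L) stop("unreplicatable genome: no origin fired in 10000 draws")
  }
  t_fire <- rep(NA_real_, nrow(org))
  t_fire[comp] <- truncated_normal(sum(comp), org$t_rep[comp], config$sigma_fire)

  segs <- vector("list", nrow(config$genome))
  names(segs) <- config$genome$chrom
  fired <- logical(nrow(org))
  use_events <- config$stall_prob > 0 && !is.null(config$stall_sites) &&
    nrow(config$stall_sites) > 0

  for (ci in seq_len(nrow(config$genome))) {
    ch <- config$genome$chrom[ci]
    L <- config$genome$length[ci]
    idx <- which(org$chrom == ch & comp)
    if (!length(idx)) {
      segs[[ci]] <- data.frame(start = 0, end = L, dir = NA_integer_,
                               fork_pos = NA_real_, fork_time = NA_real_)
      next
    }
    sites <- if (use_events) {
      ss <- config$stall_sites
      sort(ss$midpoint[ss$chrom == ch])
    } else numeric()
    if (length(sites)) {
      res <- replicate_chrom_events(L, org$midpoint[idx], t_fire[idx], v,
                                    sites, config$stall_prob)
    } else {
      res <- replicate_chrom_closed(L, org$midpoint[idx], t_fire[idx], v)
    }
    segs[[ci]] <- res$segments
    fired[idx[res$active]] <- TRUE
  }

  structure(list(segments = segs,
                 fired = data.frame(name = org$name, chrom = org$chrom,
                                    midpoint = org$midpoint,
                                    competent = comp, fire_time = t_fire,
                                    active = fired, stringsAsFactors = FALSE),
                 fork_speed = v, genome = config$genome),
            class = "replication_program")
}

#' @export
print.replication_program <- function(x, ...) {
  cat(sprintf("<replication_program> %d chromosome(s), %d/%d origins fired actively\n",
              length(x$segments), sum(x$fired$active), nrow(x$fired)))
  invisible(x)
}

truncated_normal <- function(n, mean, sd) {
  if (sd == 0) return(rep_len(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[(bad - 1L) %% length(mean) + 1L], sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

# Closed-form earliest-arrival program for one chromosome (no stalls).
# Valid because every fork moves at the same speed: replication time is
# min_j (t_j + |x - o_j| / v) over competent origins, and an origin fires
# actively iff its own time beats every other origin's arrival.
replicate_chrom_closed <- function(L, opos, otime, v) {
  n <- length(opos)
  o <- order(opos)
  opos <- opos[o]; otime <- otime[o]
  if (n == 1L) {
    active <- TRUE
  } else {
    # arrival of fork from j at origin i: t_j + |o_i - o_j|/v
    d <- abs(outer(opos, opos, "-")) / v
    arrm <- sweep(d, 2L, otime, "+")
    diag(arrm) <- Inf
    active <- otime < apply(arrm, 1L, min)
  }
  act <- which(active)
  ap <- opos[act]; at <- otime[act]
  k <- length(ap)
  # domain boundaries between consecutive active origins (collision points)
  if (k > 1L) {
    b <- (ap[-k] + ap[-1L]) / 2 + v * (at[-1L] - at[-k]) / 2
    b <- round(b)
  } else b <- numeric()
  lo <- c(0, b); hi <- c(b, L)
  start <- c(rbind(lo, ap)); end <- c(rbind(ap, hi))
  dir <- rep(c(-1L, 1L), k)
  fp <- rep(ap, each = 2L); ft <- rep(at, each = 2L)
  keep <- end > start
  res <- data.frame(start = start[keep], end = end[keep], dir = dir[keep],
                    fork_pos = fp[keep], fork_time = ft[keep])
  active_orig <- logical(n); active_orig[o[act]] <- TRUE
  # map back to input order
  list(segments = res, active = active_orig)
}

# Event-driven program for one chromosome with fork-arrest sites.
# Gaps are unreplicated intervals flanked by at most one rightward-moving
# fork on the left edge and one leftward-moving fork on the right edge;
# events (origin firing, fork-vs-stall-site encounter, fork collision,
# fork reaching a gap end) are processed in global time order.
replicate_chrom_events <- function(L, opos, otime, v, sites, s_prob) {
  n <- length(opos)
  ord <- order(opos)
  opos_s <- opos[ord]; otime_s <- otime[ord]
  pending <- rep(TRUE, n)            # indexes into sorted origins
  active <- logical(n)
  seg_start <- numeric(); seg_end <- numeric(); seg_dir <- integer()
  seg_fp <- numeric(); seg_ft <- numeric()
  emit <- function(a, b, dir, fp, ft) {
    if (b > a) {
      seg_start[length(seg_start) + 1L] <<- a
      seg_end[length(seg_end) + 1L] <<- b
      seg_dir[length(seg_dir) + 1L] <<- dir
      seg_fp[length(seg_fp) + 1L] <<- fp
      seg_ft[length(seg_ft) + 1L] <<- ft
    }
  }
  # a fork: c(p0, t0, from, ptr); ptr = index of last stall site tested
  gaps <- list(list(a = 0, b = L, lf = NULL, rf = NULL))

  arr_right <- function(f, x) f[2] + (x - f[1]) / v   # left-edge fork
  arr_left <- function(f, x) f[2] + (f[1] - x) / v    # right-edge fork

  repeat {
    best_t <- Inf; best <- NULL
    for (gi in seq_along(gaps)) {
      g <- gaps[[gi]]
      # origin firing
      po <- which(pending & opos_s > g$a & opos_s < g$b)
      for (oi in po) {
        aL <- if (is.null(g$lf)) Inf else arr_right(g$lf, opos_s[oi])
        aR <- if (is.null(g$rf)) Inf else arr_left(g$rf, opos_s[oi])
        if (otime_s[oi] < min(aL, aR) && otime_s[oi] < best_t) {
          best_t <- otime_s[oi]; best <- list(type = "fire", gi = gi, oi = oi)
        }
      }
      # left fork stall encounter / collision / gap end
      if (!is.null(g$lf)) {
        ns <- g$lf[4] + 1
        while (ns <= length(sites) && sites[ns] <= g$a) ns <- ns + 1
        if (ns <= length(sites) && sites[ns] < g$b) {
          tt <- arr_right(g$lf, sites[ns])
          if (tt < best_t) { best_t <- tt; best <- list(type = "stallL", gi = gi, ns = ns) }
        }
      }
      if (!is.null(g$rf)) {
        ns <- g$rf[4] - 1
        while (ns >= 1 && sites[ns] >= g$b) ns <- ns - 1
        if (ns >= 1 && sites[ns] > g$a) {
          tt <- arr_left(g$rf, sites[ns])
          if (tt < best_t) { best_t <- tt; best <- list(type = "stallR", gi = gi, ns = ns) }
        }
      }
      if (!is.null(g$lf) && !is.null(g$rf)) {
        x <- (g$lf[1] + g$rf[1]) / 2 + v * (g$rf[2] - g$lf[2]) / 2
        tt <- arr_right(g$lf, x)
        if (tt < best_t) { best_t <- tt; best <- list(type = "collide", gi = gi, x = x) }
      } else if (!is.null(g$lf)) {
        tt <- arr_right(g$lf, g$b)
        if (tt < best_t) { best_t <- tt; best <- list(type = "endL", gi = gi) }
      } else if (!is.null(g$rf)) {
        tt <- arr_left(g$rf, g$a)
        if (tt < best_t) { best_t <- tt; best <- list(type = "endR", gi = gi) }
      }
    }
    if (is.null(best)) break
    g <- gaps[[best$gi]]
    switch(best$type,
      fire = {
        oi <- best$oi; o <- opos_s[oi]; t0 <- otime_s[oi]
        pending[oi] <- FALSE; active[oi] <- TRUE
        # new leftward fork next tests the highest site strictly below o;
        # new rightward fork the lowest site strictly above o
        gaps[[best$gi]] <- list(a = g$a, b = o, lf = g$lf,
                                rf = c(o, t0, o, sum(sites < o) + 1))
        gaps[[length(gaps) + 1L]] <- list(a = o, b = g$b,
                                          lf = c(o, t0, o, sum(sites <= o)),
                                          rf = g$rf)
      },
      stallL = {
        sp <- sites[best$ns]
        f <- g$lf; f[4] <- best$ns
        if (stats::runif(1) < s_prob) {
          emit(f[3], sp, 1L, f[1], f[2])
          cov <- which(pending & opos_s >= g$a & opos_s < sp)
          pending[cov] <- FALSE
          gaps[[best$gi]] <- list(a = sp, b = g$b, lf = NULL, rf = g$rf)
        } else gaps[[best$gi]]$lf <- f
      },
      stallR = {
        sp <- sites[best$ns]
        f <- g$rf; f[4] <- best$ns
        if (stats::runif(1) < s_prob) {
          emit(sp, f[3], -1L, f[1], f[2])
          cov <- which(pending & opos_s > sp & opos_s <= g$b)
          pending[cov] <- FALSE
          gaps[[best$gi]] <- list(a = g$a, b = sp, lf = g$lf, rf = NULL)
        } else gaps[[best$gi]]$rf <- f
      },
      collide = {
        x <- round(best$x)
        emit(g$lf[3], x, 1L, g$lf[1], g$lf[2])
        emit(x, g$rf[3], -1L, g$rf[1], g$rf[2])
        cov <- which(pending & opos_s > g$a & opos_s < g$b)
        pending[cov] <- FALSE
        gaps[[best$gi]] <- NULL
      },
      endL = {
        emit(g$lf[3], g$b, 1L, g$lf[1], g$lf[2])
        cov <- which(pending & opos_s > g$a & opos_s < g$b)
        pending[cov] <- FALSE
        gaps[[best$gi]] <- NULL
      },
      endR = {
        emit(g$a, g$rf[3], -1L, g$rf[1], g$rf[2])
        cov <- which(pending & opos_s > g$a & opos_s < g$b)
        pending[cov] <- FALSE
        gaps[[best$gi]] <- NULL
      })
    gaps <- gaps[!vapply(gaps, is.null, TRUE)]
  }
  # remaining gaps can never be replicated
  if (length(gaps)) {
    for (g in gaps) {
      seg_start <- c(seg_start, g$a); seg_end <- c(seg_end, g$b)
      seg_dir <- c(seg_dir, NA_integer_)
      seg_fp <- c(seg_fp, NA_real_); seg_ft <- c(seg_ft, NA_real_)
    }
  }
  o2 <- order(seg_start)
  segments <- data.frame(start = seg_start[o2], end = seg_end[o2],
                         dir = seg_dir[o2], fork_pos = seg_fp[o2],
                         fork_time = seg_ft[o2])
  active_orig <- logical(n); active_orig[ord[which(active)]] <- TRUE
  list(segments = segments, active = active_orig)
}

#' Generate Okazaki fragments for one simulated cell
#'
#' Within each fork territory, Okazaki junction positions are a renewal
#' process with exponential spacings of mean
#' `priming_mean / pol_alpha_priming`; with probability `snap_prob` each
#' junction is relocated to the nearest nucleosome dyad plus
#' Normal(0, `snap_sd`) noise. Consecutive junctions delimit fragments
#' that tile the territory exactly. Fragments from leftward-fork
#' territories are Watson; rightward, Crick. Unreplicated territories
#' yield no fragments.
#'
#' @param program A `replication_program` from [simulate_cell()].
#' @param config The [sim_config()] used to generate it.
#' @return A list with integer vectors `chrom_idx`, `start`, `end` and a
#'   logical vector `watson` (internal compact form; see
#'   [simulate_okseq_library()] for the user-facing pooled set).
#' @export
fragments_from_cell <- function(program, config) {
  spacing <- effective_priming_mean(config)
  genome <- config$genome
  out_chrom <- integer(); out_start <- numeric(); out_end <- numeric()
  out_watson <- logical()
  for (ci in seq_along(program$segments)) {
    segs <- program$segments[[ci]]
    segs <- segs[!is.na(segs$dir), , drop = FALSE]
    if (!nrow(segs)) next
    dy <- if (!is.null(config$dyads)) {
      d <- config$dyads
      sort(d$pos[d$chrom == genome$chrom[ci]])
    } else numeric()
    for (si in seq_len(nrow(segs))) {
      a <- segs$start[si]; b <- segs$end[si]
      len <- b - a
      if (len < 1) next
      j <- draw_renewal(len, spacing)
      if (length(j) && config$snap_prob > 0 && length(dy)) {
        snap <- stats::runif(length(j)) < config$snap_prob
        if (any(snap)) {
          x <- a + j[snap]
          nd <- nearest_sorted(dy, x)
          x2 <- nd + if (config$snap_sd > 0)
            stats::rnorm(length(x), 0, config$snap_sd) else 0
          j[snap] <- x2 - a
        }
      }
      cuts <- sort(unique(round(c(0, j, len))))
      cuts <- cuts[cuts >= 0 & cuts <= len]
      if (length(cuts) < 2L || cuts[1] != 0 || cuts[length(cuts)] != len)
        cuts <- sort(unique(c(0, cuts[cuts > 0 & cuts < len], len)))
      fs <- a + cuts[-length(cuts)]
      fe <- a + cuts[-1L]
      nfr <- length(fs)
      out_chrom <- c(out_chrom, rep.int(ci, nfr))
      out_start <- c(out_start, fs)
      out_end <- c(out_end, fe)
      out_watson <- c(out_watson, rep.int(segs$dir[si] == -1L, nfr))
    }
  }
  list(chrom_idx = out_chrom, start = out_start, end = out_end,
       watson = out_watson)
}

# exponential renewal points strictly inside (0, len)
draw_renewal <- function(len, spacing) {
  n_exp <- len / spacing
  k <- ceiling(n_exp + 4 * sqrt(n_exp) + 10)
  x <- cumsum(stats::rexp(k, rate = 1 / spacing))
  while (x[length(x)] < len) {
    x <- c(x, x[length(x)] +
             cumsum(stats::rexp(max(8L, ceiling(k / 4)), rate = 1 / spacing)))
  }
  x[x < len]
}

# nearest value in sorted vector d for each x
nearest_sorted <- function(d, x) {
  i <- findInterval(x, d)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(d))
  ifelse(abs(x - d[lo]) <= abs(d[hi] - x), d[lo], d[hi])
}

# derive per-cell seeds (plus one extra stream) from the master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Simulate a pooled-cell OK-seq fragment library
#'
#' Runs [simulate_cell()] and [fragments_from_cell()] for `n_cells` cells
#' under per-cell RNG substreams derived from the master seed, pools the
#' fragments, and keeps each one independently with probability
#' `subsample_rate`. With `subsample_rate = 1` and fully competent
#' origins, Watson plus Crick base coverage equals `n_cells` at every
#' position (each position is lagging-strand exactly once per cell).
#'
#' @param config A [sim_config()].
#' @return An [ok_fragments()] set with attributes `truth` (per-origin
#'   data frame: `n_competent`, `n_active`, `efficiency` = fraction of
#'   cells in which the origin fired actively) and `n_cells`.
#' @export
simulate_okseq_library <- function(config) {
  org <- config$origins
  n <- config$n_cells
  truth_active <- integer(nrow(org))
  truth_comp <- integer(nrow(org))
  if (n == 0L) {
    frags <- ok_fragments(character(), numeric(), numeric(), character(),
                          config$genome)
  } else {
    seeds <- derive_seeds(config$seed, n)
    acc <- vector("list", n)
    for (k in seq_len(n)) {
      prog <- simulate_cell(config, cell_seed = seeds[k])
      truth_active <- truth_active + prog$fired$active
      truth_comp <- truth_comp + prog$fired$competent
      fr <- fragments_from_cell(prog, config)
      if (config$subsample_rate < 1 && length(fr$start)) {
        keep <- stats::runif(length(fr$start)) < config$subsample_rate
        fr <- lapply(fr, `[`, keep)
      }
      if (config$track_cells) fr$cell <- rep.int(k, length(fr$start))
      acc[[k]] <- fr
    }
    chrom_idx <- unlist(lapply(acc, `[[`, "chrom_idx"), use.names = FALSE)
    frags <- ok_fragments(
      config$genome$chrom[chrom_idx],
      unlist(lapply(acc, `[[`, "start"), use.names = FALSE),
      unlist(lapply(acc, `[[`, "end"), use.names = FALSE),
      ifelse(unlist(lapply(acc, `[[`, "watson"), use.names = FALSE),
             "Watson", "Crick"),
      config$genome,
      cell_id = if (config$track_cells)
        as.character(unlist(lapply(acc, `[[`, "cell"), use.names = FALSE))
      else NULL)
  }
  attr(frags, "truth") <- data.frame(
    name = org$name, chrom = org$chrom, midpoint = org$midpoint,
    n_cells = n, n_competent = truth_comp, n_active = truth_active,
    efficiency = if (n) truth_active / n else NA_real_,
    stringsAsFactors = FALSE)
  attr(frags, "n_cells") <- n
  frags
}

#' Ground-truth origin efficiencies of a simulated library
#'
#' @param frags An [ok_fragments()] set from [simulate_okseq_library()].
#' @return The per-origin truth table recorded during simulation.
#' @export
sim_truth <- function(frags) {
  tr <- attr(frags, "truth")
  if (is.null(tr)) stop("fragment set carries no simulation truth table")
  tr
}

#' Simulate an S-phase WGS pool with G1 control
#'
#' Each cell is frozen at a sampled time `t`; copy number at a position is
#' 2 if its replication time is `<= t`, else 1. Bin counts are Poisson
#' with mean `wgs_depth * mean copy` for the S pool and `wgs_depth` for
#' the G1 control.
#'
#' @param config A [sim_config()].
#' @param sampling_times Numeric vector of freeze times (recycled to
#'   `n_cells`), or `NULL` for Uniform(0, `s_phase_length`) per cell.
#' @return List with elements `s` and `g1` ([binned_counts()]) and
#'   `mean_copy` (the noise-free per-bin mean copy number, a
#'   [binned_counts()]).
#' @export
simulate_wgs_pool <- function(config, sampling_times = NULL) {
  n <- config$n_cells
  if (n < 1L) stop("n_cells must be >= 1 for a WGS pool")
  genome <- config$genome
  bin <- config$wgs_bin
  nb <- ceiling(genome$length / bin)
  seeds <- derive_seeds(config$seed, n + 2L)
  if (is.null(sampling_times)) {
    set.seed(seeds[n + 1L])
    times <- stats::runif(n, 0, config$s_phase_length)
  } else times <- rep_len(sampling_times, n)
  copy <- lapply(nb, function(m) rep(0, m))
  names(copy) <- genome$chrom
  v <- config$fork_speed
  for (k in seq_len(n)) {
    prog <- simulate_cell(config, cell_seed = seeds[k])
    t <- times[k]
    for (ci in seq_along(prog$segments)) {
      segs <- prog$segments[[ci]]
      vlen <- genome$length[ci]
      vv <- copy[[ci]]
      for (si in seq_len(nrow(segs))) {
        dir <- segs$dir[si]
        if (is.na(dir)) next
        a <- segs$start[si]; b <- segs$end[si]
        if (dir == 1L) {
          xf <- segs$fork_pos[si] + v * (t - segs$fork_time[si])
          lo <- a; hi <- min(b, xf)
        } else {
          xf <- segs$fork_pos[si] - v * (t - segs$fork_time[si])
          lo <- max(a, xf); hi <- b
        }
        if (hi > lo) vv <- add_bin_cover(vv, lo, hi, bin)
      }
      copy[[ci]] <- vv
    }
  }
  set.seed(seeds[n + 2L])
  depth <- config$wgs_depth
  s_counts <- lapply(seq_along(copy), function(ci) {
    mu <- depth * (1 + copy[[ci]] / n)
    stats::rpois(length(mu), mu)
  })
  g1_counts <- lapply(nb, function(m) stats::rpois(m, depth))
  names(s_counts) <- names(g1_counts) <- genome$chrom
  mean_copy <- lapply(copy, function(x) 1 + x / n)
  names(mean_copy) <- genome$chrom
  list(s = binned_counts(s_counts, genome, bin),
       g1 = binned_counts(g1_counts, genome, bin),
       mean_copy = binned_counts(mean_copy, genome, bin))
}

# add fractional bin coverage of [lo, hi) to vector vec (bins of width bin)
add_bin_cover <- function(vec, lo, hi, bin) {
  i0 <- floor(lo / bin) + 1L
  i1 <- ceiling(hi / bin)
  i1 <- min(i1, length(vec))
  if (i0 > length(vec)) return(vec)
  if (i0 == i1) {
    vec[i0] <- vec[i0] + (hi - lo) / bin
  } else {
    vec[i0] <- vec[i0] + (i0 * bin - lo) / bin
    vec[i1] <- vec[i1] + (hi - (i1 - 1) * bin) / bin
    if (i1 > i0 + 1L) {
      mid <- (i0 + 1L):(i1 - 1L)
      vec[mid] <- vec[mid] + 1
    }
  }
  vec
}

#' Replication time at given positions
#'
#' @param program A `replication_program`.
#' @param chrom Chromosome name.
#' @param pos Positions (bp).
#' @return Numeric vector of replication times in minutes (`Inf` for
#'   unreplicated positions); attribute `dir` gives fork direction
#'   (+1 rightward, -1 leftward).
#' @export
replication_time <- function(program, chrom, pos) {
  segs <- program$segments[[chrom]]
  if (is.null(segs)) stop("unknown chromosome: ", chrom)
  i <- findInterval(pos, segs$start)
  ok <- i >= 1 & pos < segs$end[pmax(i, 1L)]
  tt <- rep(Inf, length(pos)); dd <- rep(NA_integer_, length(pos))
  j <- which(ok & !is.na(segs$dir[i]))
  tt[j] <- segs$fork_time[i[j]] + abs(pos[j] - segs$fork_pos[i[j]]) / program$fork_speed
  dd[j] <- segs$dir[i[j]]
  attr(tt, "dir") <- dd
  tt
}
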