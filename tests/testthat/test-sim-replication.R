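test_that("single-origin program follows distance/speed arithmetic", {
  cfg <- single_origin_config(len = 100000, mid = 50000, v = 1000)
  prog <- simulate_cell(cfg, cell_seed = 1)
  tt <- replication_time(prog, "chrE", 20000)
  expect_equal(as.numeric(tt), 30)
  expect_equal(attr(tt, "dir"), -1L)
  segs <- prog$segments$chrE
  expect_equal(segs$start, c(0, 50000))
  expect_equal(segs$dir, c(-1L, 1L))
})

test_that("earliest-arrival program matches a brute-force grid oracle", {
  g <- genome_layout("chrE", 100000)
  opos <- c(25000, 60000, 75000)
  otime <- c(0, 9, 0)
  org <- origin_table("chrE", opos, c("a", "b", "c"), t_rep = otime,
                      true_competence = 1)
  cfg <- sim_config(g, org, fork_speed = 1000, sigma_fire = 0, snap_prob = 0,
                    seed = 1)
  prog <- simulate_cell(cfg, cell_seed = 1)
  grid <- seq(500, 99500, by = 500)
  got <- replication_time(prog, "chrE", grid)
  # oracle: minimise over competent origins directly
  arr <- sapply(seq_along(opos), function(j) otime[j] + abs(grid - opos[j]) / 1000)
  expect_equal(as.numeric(got), apply(arr, 1, min), tolerance = 1e-9)
  # origin b (fires at 9) is passively replicated: fork from a or c reaches
  # 60000 at min(0 + 35, 0 + 15) = 15 > 9 ... it is NOT overrun, so it fires
  expect_true(prog$fired$active[prog$fired$name == "b"])
  # classic two-origin collision: position 60000 between synchronised
  # origins at 25k/75k is replicated by the leftward fork at t = 15
  org2 <- origin_table("chrE", c(25000, 75000), c("a", "c"), t_rep = 0,
                       true_competence = 1)
  cfg2 <- sim_config(g, org2, fork_speed = 1000, sigma_fire = 0,
                     snap_prob = 0, seed = 1)
  p2 <- simulate_cell(cfg2, cell_seed = 1)
  t60 <- replication_time(p2, "chrE", 60000)
  expect_equal(as.numeric(t60), 15)
  expect_equal(attr(t60, "dir"), -1L)
})

test_that("passive suppression matches exhaustive competence enumeration on 3 origins", {
  g <- genome_layout("chrE", 120000)
  opos <- c(30000, 60000, 90000)
  otime <- c(10, 30, 12)          # middle origin usually passive
  v <- 1500
  # oracle: enumerate all 2^3 competence subsets; within a subset firing is
  # deterministic (sigma = 0), an origin fires iff no fork reaches it first
  subset_active <- function(S) {
    act <- logical(3)
    for (i in S) {
      others <- setdiff(S, i)
      arrivals <- if (length(others))
        otime[others] + abs(opos[others] - opos[i]) / v else Inf
      act[i] <- otime[i] < min(arrivals)
    }
    act
  }
  exact_eff <- function(p) {
    eff <- numeric(3); norm <- 0
    for (m in 1:7) {                 # nonempty subsets (rejection-conditioned)
      S <- which(bitwAnd(m, c(1, 2, 4)) > 0)
      pr <- prod(ifelse(1:3 %in% S, p, 1 - p))
      eff <- eff + pr * subset_active(S)
      norm <- norm + pr
    }
    eff / norm
  }
  p <- c(0.7, 0.8, 0.6)
  org <- origin_table("chrE", opos, c("a", "b", "c"), t_rep = otime,
                      true_competence = p)
  cfg <- sim_config(g, org, fork_speed = v, sigma_fire = 0, snap_prob = 0,
                    n_cells = 3000, subsample_rate = 1, priming_mean = 600,
                    seed = 4)
  eff_mc <- sim_truth(simulate_okseq_library(cfg))$efficiency
  expect_equal(eff_mc, exact_eff(p), tolerance = 0.03)
  # monotonicity (on the exact enumeration): raising a neighbour's
  # competence cannot raise another origin's efficiency
  for (j in 1:3) {
    lo <- p; hi <- p
    lo[j] <- 0.2; hi[j] <- 0.95
    e_lo <- exact_eff(lo); e_hi <- exact_eff(hi)
    expect_true(all(e_hi[-j] <= e_lo[-j] + 1e-12))
  }
})

test_that("an unreplicatable genome is rejected", {
  g <- genome_layout("chrE", 10000)
  org <- origin_table("chrE", 5000, "o", t_rep = 0, true_competence = 0)
  cfg <- sim_config(g, org, seed = 1)
  expect_error(simulate_cell(cfg), "unreplicatable")
})

test_that("fragments tile each cell's genome exactly once with territory strand", {
  g <- genome_layout(c("cA", "cB"), c(150000, 90000))
  org <- origin_table(c("cA", "cA", "cB"), c(40000, 110000, 45000),
                      c("a", "b", "c"), t_rep = c(10, 20, 15),
                      true_competence = 1)
  cfg <- sim_config(g, org, sigma_fire = 4, snap_prob = 0.5, snap_sd = 4,
                    dyads = rbind(regular_dyads(150000, "cA"),
                                  regular_dyads(90000, "cB")),
                    seed = 2)
  for (cell_seed in c(11, 12, 13)) {
    prog <- simulate_cell(cfg, cell_seed = cell_seed)
    fr <- fragments_from_cell(prog, cfg)
    for (ci in 1:2) {
      sel <- fr$chrom_idx == ci
      s <- fr$start[sel]; e <- fr$end[sel]
      o <- order(s)
      expect_equal(s[o][1], 0)
      expect_equal(e[o][length(e)], g$length[ci])
      expect_equal(s[o][-1], e[o][-length(e)])   # no gaps, no overlaps
    }
    # strand equals territory direction at the fragment midpoint
    mids <- (fr$start + fr$end) / 2
    for (ci in 1:2) {
      sel <- which(fr$chrom_idx == ci)
      tt <- replication_time(prog, g$chrom[ci], mids[sel])
      expect_true(all((attr(tt, "dir") == -1L) == fr$watson[sel]))
    }
  }
})

test_that("junction renewal has the configured mean spacing and scales with the priming knob", {
  l1 <- length_distribution(simulate_okseq_library(territory_config(seed = 5)))
  expect_equal(l1$mean, 150, tolerance = 0.02)
  l2 <- length_distribution(simulate_okseq_library(
    territory_config(seed = 6, pol_alpha_priming = 0.5)))
  expect_equal(l2$mean / l1$mean, 2, tolerance = 0.05)
})

test_that("snapped junctions land exactly on dyads when snap is certain and noiseless", {
  dy <- regular_dyads(150000)
  cfg <- territory_config(len = 150000, n_cells = 3, seed = 7,
                          snap_prob = 1, snap_sd = 0, dyads = dy)
  prog <- simulate_cell(cfg, cell_seed = 1)
  fr <- fragments_from_cell(prog, cfg)
  internal <- setdiff(unique(c(fr$start, fr$end)), c(0, 150000))
  expect_true(all(internal %in% dy$pos))
})

test_that("library simulation is deterministic under a fixed seed and conserves coverage", {
  cfg <- single_origin_config(len = 80000, mid = 40000, n_cells = 5, seed = 9)
  a <- simulate_okseq_library(cfg)
  b <- simulate_okseq_library(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_fragments(a, fa); write_fragments(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  # r = 1: every position is lagging-strand exactly once per cell
  cov <- stranded_counts(a, bin_size = 100, mode = "basecov")
  tot <- cov$watson$chrE + cov$crick$chrE
  expect_equal(tot, rep(5, length(tot)))
  # n_cells = 0 gives an empty set
  cfg0 <- single_origin_config(n_cells = 0)
  expect_equal(nrow(simulate_okseq_library(cfg0)), 0L)
})

test_that("fork arrest reroutes replication beyond the stall site", {
  g <- genome_layout("chrE", 100000)
  org <- origin_table("chrE", c(10000, 90000), c("a", "b"),
                      t_rep = c(0, 20), true_competence = 1)
  loci <- data.frame(chrom = "chrE", start = 49800, end = 50200,
                     name = "t1", strand = "+", midpoint = 50000,
                     stringsAsFactors = FALSE)
  cfg <- sim_config(g, org, fork_speed = 1000, sigma_fire = 0, snap_prob = 0,
                    stall_sites = loci, stall_prob = 1, seed = 1)
  prog <- simulate_cell(cfg, cell_seed = 1)
  # rightward fork from 10k arrests at 50k (t = 40); the region beyond is
  # replicated by the leftward fork from 90k (fires t = 20)
  t49 <- replication_time(prog, "chrE", 49000)
  t55 <- replication_time(prog, "chrE", 55000)
  expect_equal(as.numeric(t49), 39); expect_equal(attr(t49, "dir"), 1L)
  expect_equal(as.numeric(t55), 55); expect_equal(attr(t55, "dir"), -1L)
  # with stall_prob ~ 0 the event-driven program equals the closed form
  cfg_ev <- cfg; cfg_ev$stall_prob <- 1e-12
  cfg_cf <- cfg; cfg_cf$stall_prob <- 0
  expect_equal(simulate_cell(cfg_ev, cell_seed = 7)$segments,
               simulate_cell(cfg_cf, cell_seed = 7)$segments)
})

test_that("WGS pool matches the single-origin analytic copy profile", {
  cfg <- single_origin_config(len = 200000, mid = 100000, n_cells = 4000,
                              seed = 13, wgs_depth = 100)
  w <- simulate_wgs_pool(cfg)
  mc <- w$mean_copy$values$chrE
  d <- abs((seq_along(mc) - 0.5) * 100 - 100000)
  expected <- 1 + pmax(0, 1 - d / (1500 * 60))
  expect_lt(max(abs(mc - expected) / expected), 0.02)
  # all sampling times zero: S pool statistically identical to G1
  w0 <- simulate_wgs_pool(cfg, sampling_times = 0)
  expect_equal(mean(w0$s$values$chrE) / mean(w0$g1$values$chrE), 1,
               tolerance = 0.02)
  # determinism
  w2 <- simulate_wgs_pool(cfg)
  expect_identical(w$s$values, w2$s$values)
})
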