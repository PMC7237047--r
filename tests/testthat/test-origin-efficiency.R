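test_that("OEM reproduces its defining arithmetic and count floors", {
  g <- genome_layout("chrI", 100000)
  # hand-built pooled counts: 600 of 1000 cells fire (Watson left / Crick
  # right), 400 are passively replicated rightward (Crick on both flanks)
  mk <- function(n, start, strand) {
    s <- rep(seq(start, start + 9900, by = 100), length.out = n)
    ok_fragments("chrI", s, s + 80, rep(strand, n), g)
  }
  fr <- rbind(mk(600, 40000, "Watson"), mk(600, 50000, "Crick"),
              mk(400, 40000, "Crick"), mk(400, 50000, "Crick"))
  fr <- ok_fragments(fr$chrom, fr$start, fr$end, as.character(fr$strand), g)
  cov <- stranded_counts(fr, bin_size = 100)
  rec <- oem(cov, "chrI", 50000)
  expect_equal(rec$oem, 0.6)
  expect_equal(rec$oem,
               rec$w_l / (rec$w_l + rec$c_l) - rec$w_r / (rec$w_r + rec$c_r))
  # depth floor: below min_count the record is undefined, not noisy
  rec2 <- oem(cov, "chrI", 50000, min_count = 2000)
  expect_true(is.na(rec2$oem))
  expect_false(rec2$defined)
})

test_that("deterministic geometries give exact OEM values 1, 0.5 and 0", {
  g <- genome_layout("chrE", 200000)
  lib1 <- simulate_okseq_library(single_origin_config(len = 200000,
                                                      mid = 100000))
  cov1 <- stranded_counts(lib1, bin_size = 100, mode = "basecov")
  expect_equal(oem(cov1, "chrE", 100000, min_count = 1)$oem, 1)
  expect_equal(oem(cov1, "chrE", 30000, min_count = 1)$oem, 0)
  org2 <- origin_table("chrE", c(100000, 110000), c("a", "b"), t_rep = 0,
                       true_competence = 1)
  cfg2 <- sim_config(g, org2, sigma_fire = 0, snap_prob = 0, n_cells = 1,
                     seed = 2)
  cov2 <- stranded_counts(simulate_okseq_library(cfg2), bin_size = 100,
                          mode = "basecov")
  expect_equal(oem(cov2, "chrE", 100000, min_count = 1)$oem, 0.5)
})

test_that("OEM stays in [-1,1] and negates under genome reflection", {
  cfg <- sim_recovery_config(n_cells = 120, seed = 41)
  lib <- simulate_okseq_library(cfg)
  cov <- stranded_counts(lib, bin_size = 100)
  tab <- oem_table(cov, cfg$origins, min_count = 20)
  expect_true(all(abs(tab$oem[tab$defined]) <= 1))
  L <- cfg$genome$length
  # reflect coordinates only (keep strand labels): origins become
  # termination-like and the OEM changes sign
  refl <- ok_fragments(lib$chrom, L - lib$end, L - lib$start,
                       as.character(lib$strand), cfg$genome)
  covr <- stranded_counts(refl, bin_size = 100)
  for (i in c(3, 10, 17)) {
    m <- cfg$origins$midpoint[i]
    a <- oem(cov, "chrR", m, min_count = 20)
    b <- oem(covr, "chrR", L - m, min_count = 20)
    # midpoint rounding moves odd-length fragments by 1 bp under
    # reflection, so agreement is near-exact rather than bitwise
    if (a$defined && b$defined) expect_equal(b$oem, -a$oem, tolerance = 0.02)
  }
})

test_that("OEM is nondecreasing in an origin's own competence", {
  vals <- sapply(c(0.2, 0.5, 0.8), function(p) {
    comps <- rep(0.6, 20); comps[10] <- p
    cfg <- sim_recovery_config(n_cells = 500, seed = 51, competences = comps)
    lib <- simulate_okseq_library(cfg)
    cov <- stranded_counts(lib, bin_size = 100)
    oem(cov, "chrR", cfg$origins$midpoint[10])$oem
  })
  expect_true(all(diff(vals) > 0))
})

test_that("oem_table preserves order, flags shallow origins and summarises", {
  cfg <- sim_recovery_config(n_cells = 300, seed = 61)
  lib <- simulate_okseq_library(cfg)
  cov <- stranded_counts(lib, bin_size = 100)
  tab <- oem_table(cov, cfg$origins)
  expect_equal(nrow(tab), 20L)
  expect_equal(tab$name, cfg$origins$name)
  expect_true(all(tab$defined))
  s <- summary(tab)
  expect_equal(s[["n_defined"]], 20)
  expect_true(s[["min"]] <= s[["median"]] && s[["median"]] <= s[["max"]])
  # undefined records are excluded from summaries
  tab$defined[1:3] <- FALSE; tab$oem[1:3] <- NA_real_
  expect_equal(summary(tab)[["n_defined"]], 17)
  expect_error(oem_table(cov, cfg$origins[0, ]), "empty")
})

test_that("meta-origin profile is a step at a deterministic origin and reflects correctly", {
  cfg <- single_origin_config(len = 200000, mid = 100000, n_cells = 2, seed = 3)
  lib <- simulate_okseq_library(cfg)
  cov <- stranded_counts(lib, bin_size = 100)
  org <- cfg$origins
  prof <- meta_origin_profile(cov, org, window = 10000, bin = 500)
  expect_equal(prof$value[prof$offset < 0], rep(1, 20))
  expect_equal(prof$value[prof$offset >= 0], rep(0, 20))
  # normalize_max leaves a maximum of exactly 1
  profn <- meta_origin_profile(cov, org, window = 10000, bin = 500,
                               normalize_max = TRUE)
  expect_equal(max(profn$value, na.rm = TRUE), 1)
  # mirror image: value v maps to 1 - v on reflected offsets
  refl <- reflect_fragments(lib)
  covr <- stranded_counts(refl, bin_size = 100)
  orgr <- origin_table("chrE", 200000 - 100000, "o1", t_rep = 0,
                       true_competence = 1)
  profr <- meta_origin_profile(covr, orgr, window = 10000, bin = 500)
  expect_equal(profr$value, rev(1 - prof$value), tolerance = 1e-9)
  expect_error(meta_origin_profile(cov, org[0, ]), "origins")
})

test_that("group comparison matches the closed-form Welch t-test", {
  tab <- fake_oem_table(c(0.5, 0.6, 0.7, 0.5, 0.6, 0.7),
                        t_rep = c(10, 11, 12, 30, 31, 32))
  r <- split_and_compare(tab, scheme = "timing_median")
  expect_equal(r$test$t, 0)
  expect_equal(r$test$p, 1)
  # closed-form oracle for {1,2,3} vs {4,5,6}
  tab2 <- fake_oem_table(c(1, 2, 3, 4, 5, 6), t_rep = c(1, 1, 1, 9, 9, 9))
  r2 <- split_and_compare(tab2, scheme = "earliest_k", theta = 5)
  se <- sqrt(1 / 3 + 1 / 3)             # both variances are 1
  t_hand <- (2 - 5) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(r2$test$t, t_hand, tolerance = 1e-12)
  expect_equal(r2$test$df, df_hand, tolerance = 1e-12)
  expect_equal(r2$test$p, 2 * stats::pt(t_hand, df_hand), tolerance = 1e-12)
  expect_equal(r2$test$p, 0.0213, tolerance = 0.01)
  # fkh scheme partitions by class and excludes the rest
  tab3 <- fake_oem_table(c(0.8, 0.7, 0.2, 0.3, 0.5, 0.6),
                         fkh_class = c("activated", "activated", "repressed",
                                       "repressed", "independent", "unknown"))
  r3 <- split_and_compare(tab3, scheme = "fkh")
  expect_equal(lengths(r3$groups), c(activated = 2L, repressed = 2L))
  expect_equal(r3$n_excluded, 2L)
  expect_error(split_and_compare(fake_oem_table(c(1, 2), t_rep = c(1, 9)),
                                 scheme = "earliest_k", theta = 5),
               "at least 2")
})

test_that("the earliest-22-of-283 split produces groups of 22 and 261", {
  n <- 283
  t_rep <- c(seq(10, 17.9, length.out = 22), seq(18.5, 45, length.out = 261))
  set.seed(8)
  tab <- fake_oem_table(runif(n, 0.1, 0.9), t_rep = sample(t_rep))
  r <- split_and_compare(tab, scheme = "earliest_k", theta = 18)
  expect_equal(unname(lengths(r$groups)), c(22L, 261L))
})

test_that("replicate correlation handles identity, anti-order and undefined pairs", {
  tab <- fake_oem_table(seq(0.1, 0.9, length.out = 9))
  expect_equal(replicate_correlation(tab, tab)$r, 1)
  tab2 <- tab; tab2$oem <- rev(tab2$oem)
  expect_equal(replicate_correlation(tab, tab2)$r, -1)
  tab3 <- tab; tab3$defined[1:7] <- FALSE
  expect_error(replicate_correlation(tab, tab3), "fewer than 3")
  tab4 <- tab; tab4$defined[1] <- FALSE; tab4$oem[1] <- NA
  rc <- replicate_correlation(tab, tab4)
  expect_equal(rc$n_dropped, 1L)
  expect_equal(rc$n_used, 8L)
})

test_that("independent simulations of one configuration agree closely", {
  tabs <- lapply(c(71, 72), function(seed) {
    cfg <- sim_recovery_config(n_cells = 1000, seed = seed)
    lib <- simulate_okseq_library(cfg)
    oem_table(stranded_counts(lib, bin_size = 100), cfg$origins)
  })
  rc <- replicate_correlation(tabs[[1]], tabs[[2]])
  expect_equal(rc$n_used, 20L)
  expect_gte(rc$r, 0.95)
})
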