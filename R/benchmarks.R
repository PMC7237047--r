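#' Benchmark simulator configurations
#'
#' Ready-made [sim_config()]s for the package's standard verification
#' conditions. They are ordinary configurations — every knob can be
#' overridden downstream — but their geometry is chosen so that analytic
#' expectations hold:
#'
#' `sim_recovery_config()` is the efficiency-recovery condition: a single
#' 1.2 Mb chromosome with 20 origins spaced 60 kb apart (>= 20 kb of
#' clearance around every +/-10 kb OEM window), firing competences spread
#' over `[0.1, 0.95]` and mean firing times staggered through a
#' 12/24/36/48-minute cycle so that passive replication of any origin is
#' predominantly unidirectional and fork-convergence zones fall outside
#' the OEM windows. Under it the OEM tracks the true per-origin active
#' firing efficiency.
#'
#' `sim_stall_config()` is the fork-arrest condition: a 500 kb chromosome
#' with 10 fully competent origins 50 kb apart, firing times alternating
#' between 15 and 35 minutes, and 9 oriented loci placed midway between
#' origins, each carrying a stall site at its midpoint. The timing
#' alternation pushes every fork-convergence zone well away from the
#' loci, so without arrest each locus sits inside a uniform fork
#' territory and the direction profile around it is flat.
#'
#' @param n_cells Cells to simulate.
#' @param seed Master seed.
#' @param competences Length-20 vector of origin competences
#'   (recovery condition).
#' @param pol_alpha_firing,pol_alpha_priming Polymerase-alpha knobs
#'   passed through to [sim_config()].
#' @param subsample_rate Fragment-retention probability.
#' @param stall_prob Arrest probability at each locus (stall condition).
#' @return A [sim_config()].
#' @name benchmark_configs
NULL

#' @rdname benchmark_configs
#' @export
sim_recovery_config <- function(n_cells = 2000, seed = 1,
                                competences = seq(0.1, 0.95, length.out = 20),
                                pol_alpha_firing = 1, pol_alpha_priming = 1,
                                subsample_rate = 0.1) {
  stopifnot(length(competences) == 20)
  g <- genome_layout("chrR", 1200000)
  org <- origin_table("chrR", 30000 + 60000 * (0:19),
                      sprintf("o%02d", 1:20),
                      t_rep = rep(c(12, 24, 36, 48), 5),
                      true_competence = competences)
  sim_config(g, org, fork_speed = 1500, priming_mean = 150,
             pol_alpha_firing = pol_alpha_firing,
             pol_alpha_priming = pol_alpha_priming,
             sigma_fire = 5, snap_prob = 0, dyads = NULL,
             n_cells = n_cells, s_phase_length = 60,
             subsample_rate = subsample_rate, seed = seed)
}

#' @rdname benchmark_configs
#' @export
sim_stall_config <- function(stall_prob, n_cells = 2000, seed = 1,
                             subsample_rate = 0.2) {
  g <- genome_layout("chrT", 500000)
  org <- origin_table("chrT", 25000 + 50000 * (0:9),
                      sprintf("s%02d", 1:10),
                      t_rep = rep(c(15, 35), 5), true_competence = 1)
  loci <- data.frame(chrom = "chrT",
                     start = 50000 * (1:9) - 200,
                     end = 50000 * (1:9) + 200,
                     name = sprintf("tL%02d", 1:9),
                     strand = "+",
                     midpoint = 50000 * (1:9),
                     stringsAsFactors = FALSE)
  sim_config(g, org, fork_speed = 1500, priming_mean = 150,
             sigma_fire = 5, snap_prob = 0, dyads = NULL,
             stall_sites = loci, stall_prob = stall_prob,
             n_cells = n_cells, s_phase_length = 60,
             subsample_rate = subsample_rate, seed = seed)
}

#' Oriented loci of the stall benchmark
#' @return The locus table used by [sim_stall_config()].
#' @export
stall_benchmark_loci <- function() {
  sim_stall_config(stall_prob = 0, n_cells = 1)$stall_sites
}
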