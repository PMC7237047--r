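#' Replication-simulator configuration
#'
#' Full parameterisation of the stochastic whole-genome replication
#' simulator. Each simulated cell draws, per origin, a firing competence
#' Bernoulli(`true_competence * pol_alpha_firing`) and, for competent
#' origins, a firing time Normal(`t_rep`, `sigma_fire`) truncated at 0.
#' Forks move at constant speed `fork_speed` in both directions; every
#' position is replicated by the earliest-arriving fork, so origins reached
#' by a fork before their firing time are passively replicated and do not
#' fire. A fork hitting a stall site arrests there with probability
#' `stall_prob` (the region beyond is replicated by the opposing fork, if
#' any). Lagging-strand priming is a renewal process with mean spacing
#' `priming_mean / pol_alpha_priming`; each Okazaki junction is relocated
#' to the nearest nucleosome dyad plus Normal(0, `snap_sd`) noise with
#' probability `snap_prob` (requires `dyads`).
#'
#' The two `pol_alpha_*` knobs model polymerase-alpha availability
#' separately for the origin-firing arm (`pol_alpha_firing` scales every
#' competence) and the lagging-strand arm (`pol_alpha_priming` scales the
#' priming rate, so halving it doubles the mean inter-priming distance).
#' Setting only `pol_alpha_priming` below 1 emulates loss of
#' Ctf4-mediated recruitment, which perturbs Okazaki-fragment initiation
#' at polymerase levels that still support normal origin firing.
#'
#' @param genome A [genome_layout()].
#' @param origins An [origin_table()] with non-`NA` `true_competence`
#'   (firing probability per cell) and `t_rep` (mean firing time, minutes).
#' @param fork_speed Fork speed in bp/minute (> 0). Default 1500,
#'   a typical budding-yeast value.
#' @param priming_mean Mean inter-priming distance in bp at full
#'   polymerase-alpha level (> 0). Default 150 bp, giving
#'   nucleosome-sized fragments.
#' @param pol_alpha_priming,pol_alpha_firing Scalars in (0, 1] scaling the
#'   lagging-strand priming rate and the origin competences respectively.
#' @param sigma_fire Firing-time standard deviation in minutes (>= 0).
#' @param snap_prob Probability a junction snaps to the nearest dyad.
#' @param snap_sd Standard deviation (bp) of residual junction offset
#'   after snapping.
#' @param dyads Data frame (`chrom`, `pos`) of nucleosome dyad positions,
#'   or `NULL` to disable snapping.
#' @param stall_sites Data frame (`chrom`, `start`, `end`, `strand`,
#'   `midpoint`) of fork-stall loci (e.g. tRNA genes), or `NULL`. The
#'   stall position is the locus midpoint.
#' @param stall_prob Probability in `[0,1]` that a fork arrests on hitting
#'   a stall site.
#' @param n_cells Number of cells to simulate (>= 0).
#' @param s_phase_length S-phase length `T` in minutes; WGS sampling times
#'   default to Uniform(0, `T`).
#' @param subsample_rate Probability in (0, 1] of keeping each pooled
#'   fragment (library depth knob).
#' @param wgs_depth Expected G1 reads per `wgs_bin` bin in the simulated
#'   WGS pool.
#' @param wgs_bin WGS count bin size in bp (default 100).
#' @param seed Integer master seed; per-cell RNG substreams are derived
#'   from it so results do not depend on execution order.
#' @param track_cells Keep a per-fragment `cell_id` column (memory-heavy).
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(genome, origins,
                       fork_speed = 1500,
                       priming_mean = 150,
                       pol_alpha_priming = 1,
                       pol_alpha_firing = 1,
                       sigma_fire = 5,
                       snap_prob = 0.8,
                       snap_sd = 5,
                       dyads = NULL,
                       stall_sites = NULL,
                       stall_prob = 0,
                       n_cells = 1000,
                       s_phase_length = 60,
                       subsample_rate = 1,
                       wgs_depth = 50,
                       wgs_bin = 100,
                       seed = 1,
                       track_cells = FALSE) {
  stopifnot(inherits(genome, "genome_layout"), inherits(origins, "origin_table"))
  if (anyNA(origins$true_competence))
    stop("every origin needs a true_competence for simulation")
  if (anyNA(origins$t_rep))
    stop("every origin needs a t_rep (mean firing time) for simulation")
  if (!(fork_speed > 0)) stop("fork_speed must be > 0")
  if (!(priming_mean > 0)) stop("priming_mean must be > 0")
  for (p in c(pol_alpha_priming, pol_alpha_firing))
    if (!(p > 0 && p <= 1)) stop("pol_alpha knobs must be in (0,1]")
  for (p in c(snap_prob, stall_prob))
    if (p < 0 || p > 1) stop("probabilities must be in [0,1]")
  if (sigma_fire < 0) stop("sigma_fire must be >= 0")
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (!(subsample_rate > 0 && subsample_rate <= 1))
    stop("subsample_rate must be in (0,1]")
  if (!(s_phase_length > 0)) stop("s_phase_length must be > 0")
  len <- chrom_length(genome, origins$chrom)
  if (any(origins$midpoint < 0 | origins$midpoint >= len))
    stop("origin midpoint outside chromosome")
  if (!is.null(dyads) && nrow(dyads)) {
    stopifnot(all(c("chrom", "pos") %in% names(dyads)))
    dl <- chrom_length(genome, dyads$chrom)
    if (any(dyads$pos < 0 | dyads$pos >= dl)) stop("dyad position outside chromosome")
  }
  if (!is.null(stall_sites) && nrow(stall_sites)) {
    stopifnot(all(c("chrom", "midpoint") %in% names(stall_sites)))
  }
  structure(list(genome = genome, origins = origins, fork_speed = fork_speed,
                 priming_mean = priming_mean,
                 pol_alpha_priming = pol_alpha_priming,
                 pol_alpha_firing = pol_alpha_firing,
                 sigma_fire = sigma_fire, snap_prob = snap_prob,
                 snap_sd = snap_sd, dyads = dyads,
                 stall_sites = stall_sites, stall_prob = stall_prob,
                 n_cells = n_cells, s_phase_length = s_phase_length,
                 subsample_rate = subsample_rate, wgs_depth = wgs_depth,
                 wgs_bin = wgs_bin, seed = as.integer(seed),
                 track_cells = isTRUE(track_cells)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d origins / %d chromosome(s), %d cells\n",
    "  fork %g bp/min, priming mean %g bp (pol-alpha priming %g, firing %g)\n",
    "  snap %g (sd %g bp), stall %g at %d site(s), seed %d\n"),
    nrow(x$origins), nrow(x$genome), x$n_cells,
    x$fork_speed, x$priming_mean, x$pol_alpha_priming, x$pol_alpha_firing,
    x$snap_prob, x$snap_sd, x$stall_prob,
    if (is.null(x$stall_sites)) 0L else nrow(x$stall_sites), x$seed))
  invisible(x)
}

# effective per-origin firing competences
effective_competence <- function(config) {
  pmin(1, config$origins$true_competence * config$pol_alpha_firing)
}

# effective mean inter-priming distance
effective_priming_mean <- function(config) {
  config$priming_mean / config$pol_alpha_priming
}
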