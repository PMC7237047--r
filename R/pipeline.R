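#' Run the OK-seq analysis pipeline
#'
#' Orchestrates the analysis stages over real input files or a simulated
#' dataset and writes one artifact per stage plus a manifest that records
#' package version, seed, parameters and input/output checksums, so a
#' rerun with the same configuration is byte-identical.
#'
#' `config` is a list with elements:
#' * `out_dir` (required) — output directory, created if needed.
#' * `stages` — subset of `c("oem", "meta", "ends", "forkdir", "cnv")`
#'   (default: all stages whose inputs are present).
#' * `genome` — a [genome_layout()] or chromosome-sizes file path.
#' * `fragments` — an [ok_fragments()] set or BED6 path.
#' * `origins` — an [origin_table()] or TSV path.
#' * `dyads`, `exclusions` — data frames or BED3 paths.
#' * `loci` — data frame or BED6 path.
#' * `wgs_s`, `wgs_g1` — [binned_counts()] or bedGraph paths
#'   (with `wgs_bin`, default 100).
#' * `sim` — a [sim_config()]; if present, fragments and WGS counts are
#'   simulated (and written) instead of read.
#' * `params` — list of analysis parameters (`window`, `min_count`,
#'   `meta_bin`, `end_window`, `dir_window`, `dir_bin`, `span_fraction`,
#'   `smooth_bin`), all optional.
#' * `seed` — integer; overrides `sim$seed` when simulating.
#'
#' @param config Configuration list (see Details).
#' @return Invisibly, a named list of output file paths (including
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("configuration error: out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  par_get <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
  window <- par_get("window", 10000)
  min_count <- par_get("min_count", 50)
  meta_bin <- par_get("meta_bin", 100)
  cov_bin <- par_get("cov_bin", 100)
  end_window <- par_get("end_window", 200)
  dir_window <- par_get("dir_window", 5000)
  dir_bin <- par_get("dir_bin", 100)
  span_fraction <- par_get("span_fraction", 0.02)
  smooth_bin <- par_get("smooth_bin", 1000)
  wgs_bin <- par_get("wgs_bin", 100)

  inputs <- list()
  genome <- config$genome
  if (is.character(genome)) { inputs$genome <- genome; genome <- read_genome(genome) }
  load_tab <- function(x, reader, label) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) { inputs[[label]] <<- x; reader(x, genome) } else x
  }
  origins <- config$origins
  if (is.character(origins)) { inputs$origins <- origins
    origins <- read_origins(origins, genome) }
  dyads <- load_tab(config$dyads, read_dyads, "dyads")
  exclusions <- load_tab(config$exclusions, read_exclusions, "exclusions")
  loci <- load_tab(config$loci, read_loci, "loci")

  outputs <- list()
  frags <- NULL; wgs_s <- NULL; wgs_g1 <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    if (!is.null(config$seed)) sim$seed <- as.integer(config$seed)
    if (is.null(genome)) genome <- sim$genome
    if (is.null(origins)) origins <- sim$origins
    message("pipeline: simulating ", sim$n_cells, " cells (seed ", sim$seed, ")")
    frags <- simulate_okseq_library(sim)
    outputs$fragments <- file.path(out_dir, "fragments.bed")
    write_fragments(frags, outputs$fragments)
    outputs$truth <- file.path(out_dir, "truth.tsv")
    utils::write.table(sim_truth(frags), outputs$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    wgs <- simulate_wgs_pool(sim)
    wgs_s <- wgs$s; wgs_g1 <- wgs$g1
  } else {
    if (!is.null(config$fragments)) {
      frags <- if (is.character(config$fragments)) {
        inputs$fragments <- config$fragments
        read_fragments(config$fragments, genome)
      } else config$fragments
    }
    if (!is.null(config$wgs_s)) {
      wgs_s <- if (is.character(config$wgs_s)) {
        inputs$wgs_s <- config$wgs_s
        read_bedgraph(config$wgs_s, genome, wgs_bin)
      } else config$wgs_s
      wgs_g1 <- if (is.character(config$wgs_g1)) {
        inputs$wgs_g1 <- config$wgs_g1
        read_bedgraph(config$wgs_g1, genome, wgs_bin)
      } else config$wgs_g1
    }
  }

  stages <- config$stages
  if (is.null(stages)) {
    stages <- c(if (!is.null(frags) && !is.null(origins)) c("oem", "meta"),
                if (!is.null(frags) && !is.null(dyads)) "ends",
                if (!is.null(frags) && !is.null(loci)) "forkdir",
                if (!is.null(wgs_s) && !is.null(wgs_g1)) "cnv")
  }
  check <- function(stage, inputs_ok)
    if (!inputs_ok) stop("configuration error: stage '", stage,
                         "' is selected but its inputs are missing")

  cov <- NULL
  if (any(c("oem", "meta", "forkdir") %in% stages)) {
    check("oem/meta/forkdir", !is.null(frags))
    cov <- stranded_counts(frags, genome, bin_size = cov_bin)
  }
  if ("oem" %in% stages) {
    check("oem", !is.null(frags) && !is.null(origins))
    tab <- oem_table(cov, origins, window = window, min_count = min_count)
    message(sprintf("pipeline: oem — %d/%d origins defined",
                    sum(tab$defined), nrow(tab)))
    outputs$oem <- file.path(out_dir, "oem_table.tsv")
    write_oem_table(tab, outputs$oem)
  }
  if ("meta" %in% stages) {
    check("meta", !is.null(frags) && !is.null(origins))
    prof <- meta_origin_profile(cov, origins, window = window, bin = meta_bin,
                                normalize_max = TRUE)
    outputs$meta <- file.path(out_dir, "meta_profile.tsv")
    utils::write.table(as.data.frame(prof), outputs$meta, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("ends" %in% stages) {
    check("ends", !is.null(frags) && !is.null(dyads))
    for (which_end in c("five_prime", "three_prime")) {
      ends <- fragment_end_positions(frags, which_end)
      h <- dyad_offset_histogram(ends, dyads, window = end_window)
      f <- file.path(out_dir, sprintf("end_hist_%s.tsv",
                                      sub("_prime", "p", which_end)))
      utils::write.table(as.data.frame(h), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs[[paste0("ends_", which_end)]] <- f
    }
    ld <- length_distribution(frags)
    message(sprintf("pipeline: ends — mean fragment length %.1f bp", ld$mean))
  }
  if ("forkdir" %in% stages) {
    check("forkdir", !is.null(frags) && !is.null(loci))
    dp <- fork_direction_profile(cov, loci, window = dir_window, bin = dir_bin)
    outputs$forkdir <- file.path(out_dir, "direction_profile.tsv")
    utils::write.table(as.data.frame(dp), outputs$forkdir, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("cnv" %in% stages) {
    check("cnv", !is.null(wgs_s) && !is.null(wgs_g1))
    track <- normalize_track(wgs_s, wgs_g1, exclusions)
    track <- loess_smooth(track, span_fraction = span_fraction)
    outputs$cnv <- file.path(out_dir, "cn_track.bedgraph")
    write_bedgraph(track, outputs$cnv)
    if (!is.null(origins)) {
      mc <- meta_origin_coverage(track, origins, window = window,
                                 smooth_bin = smooth_bin)
      outputs$meta_coverage <- file.path(out_dir, "meta_coverage.tsv")
      utils::write.table(as.data.frame(mc), outputs$meta_coverage, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package = "okseqr",
    version = as.character(utils::packageVersion("okseqr")),
    seed = if (!is.null(config$seed)) as.integer(config$seed)
      else if (!is.null(config$sim)) config$sim$seed else NA,
    stages = as.list(stages),
    params = list(window = window, min_count = min_count, meta_bin = meta_bin,
                  cov_bin = cov_bin, end_window = end_window,
                  dir_window = dir_window, dir_bin = dir_bin,
                  span_fraction = span_fraction, smooth_bin = smooth_bin),
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  outputs$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, outputs$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outputs)
}

#' Generate an on-disk synthetic fixture dataset
#'
#' Simulates a two-chromosome genome (600 kb + 400 kb, 20 origins with
#' staggered firing times and competences spread over `[0.2, 0.9]`,
#' nucleosome dyads every 165 bp, an exclusion region per chromosome and
#' 9 oriented midway loci) under one of four presets and writes every
#' pipeline input plus ground truth:
#' * `baseline` — full polymerase-alpha level on both arms.
#' * `depleted` — both the firing and priming arms scaled by 0.5
#'   (global polymerase depletion: longer fragments and less efficient
#'   firing of every origin).
#' * `ctf4_like` — priming arm scaled by 0.5 with the firing arm intact
#'   (impaired lagging-strand initiation at normal origin firing).
#' * `stall` — baseline plus fork arrest (probability 0.6) at the loci.
#'
#' Presets differ only in these knob values.
#'
#' @param preset One of `"baseline"`, `"depleted"`, `"ctf4_like"`,
#'   `"stall"`.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_cells Cells to simulate (default 500).
#' @return Invisibly, list with the `sim_config` used and the written
#'   file paths.
#' @export
generate_fixture <- function(preset = c("baseline", "depleted", "ctf4_like",
                                        "stall"),
                             out_dir, seed = 1, n_cells = 500) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- fixture_sim_config(preset, seed = seed, n_cells = n_cells)
  genome <- sim$genome
  paths <- list(
    genome = file.path(out_dir, "genome.tsv"),
    origins = file.path(out_dir, "origins.tsv"),
    dyads = file.path(out_dir, "dyads.bed"),
    exclusions = file.path(out_dir, "exclusions.bed"),
    loci = file.path(out_dir, "loci.bed"),
    fragments = file.path(out_dir, "fragments.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    wgs_s = file.path(out_dir, "wgs_s.bedgraph"),
    wgs_g1 = file.path(out_dir, "wgs_g1.bedgraph"))
  utils::write.table(as.data.frame(genome), paths$genome, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_origins(sim$origins, paths$origins)
  dy <- sim$dyads
  writeLines(paste(dy$chrom, format_coord(dy$pos), format_coord(dy$pos + 1),
                   sep = "\t"), paths$dyads)
  ex <- fixture_exclusions()
  writeLines(paste(ex$chrom, format_coord(ex$start), format_coord(ex$end),
                   sep = "\t"), paths$exclusions)
  lo <- fixture_loci()
  writeLines(paste(lo$chrom, format_coord(lo$start), format_coord(lo$end),
                   lo$name, 0, lo$strand, sep = "\t"), paths$loci)
  frags <- simulate_okseq_library(sim)
  write_fragments(frags, paths$fragments)
  utils::write.table(sim_truth(frags), paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wgs <- simulate_wgs_pool(sim)
  write_bedgraph(wgs$s, paths$wgs_s)
  write_bedgraph(wgs$g1, paths$wgs_g1)
  invisible(list(sim = sim, paths = paths))
}

# fixture genome shared by all presets; origin spacing and the staggered
# firing-time cycle keep fork-convergence zones out of the OEM windows
fixture_genome <- function() {
  genome_layout(c("chrS1", "chrS2"), c(750000, 520000))
}

fixture_origins <- function() {
  pos1 <- 25000 + 60000 * (0:11)
  pos2 <- 25000 + 60000 * (0:7)
  chrom <- c(rep("chrS1", 12), rep("chrS2", 8))
  mid <- c(pos1, pos2)
  n <- length(mid)
  comp <- rep(c(0.9, 0.5, 0.7, 0.3, 0.8, 0.2, 0.6, 0.4), length.out = n)
  t_rep <- rep(c(12, 24, 36, 48), length.out = n)
  fkh <- rep(c("activated", "repressed", "independent"), length.out = n)
  origin_table(chrom, mid, sprintf("ORI%02d", seq_len(n)), t_rep = t_rep,
               fkh_class = fkh, true_competence = comp)
}

fixture_dyads <- function() {
  g <- fixture_genome()
  do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    data.frame(chrom = g$chrom[i],
               pos = seq(82, g$length[i] - 83, by = 165),
               stringsAsFactors = FALSE)))
}

fixture_exclusions <- function() {
  data.frame(chrom = c("chrS1", "chrS2"),
             start = c(350000, 250000), end = c(360000, 255000),
             stringsAsFactors = FALSE)
}

fixture_loci <- function() {
  mid <- 55000 + 60000 * (0:8)
  data.frame(chrom = "chrS1", start = mid - 200, end = mid + 200,
             name = sprintf("tL%02d", 1:9),
             strand = rep(c("+", "-"), length.out = 9),
             midpoint = mid, stringsAsFactors = FALSE)
}

#' Simulator configuration for a fixture preset
#'
#' The [sim_config()] behind [generate_fixture()], without touching disk.
#' See [generate_fixture()] for the preset definitions.
#'
#' @inheritParams generate_fixture
#' @param subsample_rate Fragment-retention probability.
#' @return A [sim_config()].
#' @export
fixture_sim_config <- function(preset, seed = 1, n_cells = 500,
                               subsample_rate = 0.5) {
  knobs <- switch(preset,
    baseline = list(priming = 1, firing = 1, stall = 0),
    depleted = list(priming = 0.5, firing = 0.5, stall = 0),
    ctf4_like = list(priming = 0.5, firing = 1, stall = 0),
    stall = list(priming = 1, firing = 1, stall = 0.6),
    stop("unknown preset: ", preset))
  sim_config(fixture_genome(), fixture_origins(),
             fork_speed = 1500, priming_mean = 150,
             pol_alpha_priming = knobs$priming,
             pol_alpha_firing = knobs$firing,
             sigma_fire = 5, snap_prob = 0.8, snap_sd = 5,
             dyads = fixture_dyads(),
             stall_sites = if (knobs$stall > 0) fixture_loci() else NULL,
             stall_prob = knobs$stall,
             n_cells = n_cells, s_phase_length = 60,
             subsample_rate = subsample_rate, wgs_depth = 50,
             wgs_bin = 100, seed = seed)
}
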