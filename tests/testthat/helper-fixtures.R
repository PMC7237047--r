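# Shared builders for small in-code fixtures. Everything is generated at
# test time; no binary data.

tiny_genome <- function(len = 200000, chrom = "chrE") genome_layout(chrom, len)

# deterministic single-origin configuration: p = 1, fires at t = 0
single_origin_config <- function(len = 200000, mid = len / 2, v = 1500,
                                 n_cells = 1, seed = 1, ...) {
  g <- tiny_genome(len)
  org <- origin_table("chrE", mid, "o1", t_rep = 0, true_competence = 1)
  sim_config(g, org, fork_speed = v, sigma_fire = 0, snap_prob = 0,
             n_cells = n_cells, seed = seed, ...)
}

# single-territory generator: one chromosome replicated by one rightward
# fork, used for renewal-process statistics
territory_config <- function(len = 300000, n_cells = 50, seed = 1,
                             pol_alpha_priming = 1, snap_prob = 0,
                             snap_sd = 0, dyads = NULL) {
  g <- genome_layout("chrF", len)
  org <- origin_table("chrF", 0, "o1", t_rep = 0, true_competence = 1)
  sim_config(g, org, sigma_fire = 0, priming_mean = 150,
             pol_alpha_priming = pol_alpha_priming,
             snap_prob = snap_prob, snap_sd = snap_sd, dyads = dyads,
             n_cells = n_cells, seed = seed)
}

regular_dyads <- function(len, chrom = "chrF", spacing = 165, phase = 82) {
  data.frame(chrom = chrom, pos = seq(phase, len - spacing, by = spacing),
             stringsAsFactors = FALSE)
}

# mirror a fragment set: reflect coordinates and swap strands, the exact
# symmetry under which Watson fraction maps to 1 - value
reflect_fragments <- function(frags) {
  g <- attr(frags, "genome")
  L <- g$length[match(frags$chrom, g$chrom)]
  ok_fragments(frags$chrom, L - frags$end, L - frags$start,
               ifelse(frags$strand == "Watson", "Crick", "Watson"), g)
}

# plain data frame shaped like an oem_table (for statistics-only tests)
fake_oem_table <- function(oem, t_rep = NA_real_, fkh_class = "unknown") {
  n <- length(oem)
  data.frame(name = sprintf("x%03d", seq_len(n)), oem = oem,
             defined = !is.na(oem),
             t_rep = rep_len(t_rep, n),
             fkh_class = rep_len(fkh_class, n),
             stringsAsFactors = FALSE)
}
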