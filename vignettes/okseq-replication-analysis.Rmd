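---
title: "Measuring replication-origin firing and lagging-strand priming from Okazaki-fragment and copy-number data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring replication-origin firing and lagging-strand priming from Okazaki-fragment and copy-number data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okseqr)
```

## The measurement problem

In a eukaryotic cell, S-phase replication initiates at many origins, each
of which fires in only a fraction of cells; the rest of the time the
origin is duplicated passively by a fork arriving from a neighbour.
Okazaki-fragment sequencing (OK-seq) turns this population heterogeneity
into a strand signal: unligated lagging-strand fragments are purified
from a pool of cells and sequenced strand-specifically. Because the
lagging strand of a *leftward*-moving fork is synthesised on the Watson
(reference plus) strand, the local fraction of Watson-mapping fragments
reads out the local fraction of leftward-moving forks, and an origin
appears as a sharp Watson-to-Crick transition at its midpoint.

`okseqr` implements the analysis stack for such data — strand-specific
coverage, the Origin Efficiency Metric, meta-origin profiles,
fragment-end phasing around nucleosome dyads, fork-direction profiles
around oriented loci, and G1-normalised S-phase copy-number tracks —
together with a stochastic whole-genome replication simulator that
produces OK-seq-like and WGS-like inputs with known ground truth. The
simulator is first-class, tested code: it is what makes every analysis
stage verifiable by parameter recovery and analytic limits, because real
libraries come with no per-origin truth attached.

## The Origin Efficiency Metric

For an origin with midpoint $m$ and flanks $L = [m - w, m)$,
$R = [m, m + w)$ with $w = 10$ kb,

$$\mathrm{OEM} = \frac{W_L}{W_L + C_L} - \frac{W_R}{W_R + C_R},$$

where $W$ and $C$ count Watson and Crick fragment midpoints. An origin
firing in every cell sends leftward forks left (Watson on the left
flank) and rightward forks right (Crick on the right flank), giving
OEM = 1; a locus replicated by passing forks has equal Watson fractions
on both flanks and OEM = 0; a pure termination zone gives −1. For an
origin firing actively in a fraction $f$ of cells whose passive
replication is unidirectional, both flank fractions shift by the same
passive term and the difference is exactly $f$ — the OEM is a proxy for
the *active firing efficiency*, and the package's acceptance suite
verifies the correspondence (Pearson r ≥ 0.95, mean absolute deviation
≤ 0.05) against simulator ground truth.

Choices the data do not dictate, fixed here explicitly:

* **Counting.** Midpoint counting (one fragment, one vote) is the
  default for all strand-fraction statistics; base-coverage mode is
  provided (`stranded_counts(mode = "basecov")`). Midpoint counting
  avoids over-weighting long fragments, which matters exactly in the
  depleted-polymerase regimes where fragments lengthen.
* **Depth floor.** A flank with fewer than `min_count = 50` fragments
  makes the OEM undefined (`NA`) rather than noisy; undefined records
  are excluded from summaries and flagged.
* **Flank convention.** Left flank `[m - w, m)`, right `[m, m + w)`,
  0-based half-open throughout; flanks truncated by a chromosome end
  use the available bins.
* **Group tests.** `split_and_compare()` defaults to the Welch
  (unequal-variance) unpaired t-test, with a pooled-variance option.
* **Replicates.** Replicate agreement is assessed on OEM values per
  origin (Pearson correlation over jointly defined origins); averaging
  across replicates averages OEMs rather than pooling fragments, with
  pooling available by simply concatenating fragment sets.

## The replication simulator

Each simulated cell draws, independently per origin $i$:

* competence: Bernoulli($p_i \cdot$ `pol_alpha_firing`), the chance the
  origin is licensed and able to fire in this cell;
* a firing time Normal($\mu_i$, $\sigma_{\mathrm{fire}}$) truncated at
  zero, with $\mu_i$ taken from the origin's `t_rep` (minutes).

Forks then move at a constant speed $v$ in both directions and every
position is replicated by the earliest-arriving fork. This is the
standard kinetic (earliest-arrival) model: because all forks share one
speed, the replication time of position $x$ is
$\min_j \left( t_j + |x - o_j| / v \right)$ over competent origins, an
origin reached by a fork before its own firing time is passively
replicated, and fork direction flips only at fired origins (divergence)
and at collision points (convergence). When fork-arrest sites are
present, the program is instead resolved by an event queue (origin
firings, fork–site encounters, collisions, chromosome ends) in global
time order; a fork hitting a site arrests terminally with probability
`stall_prob`, and the region beyond is replicated by the opposing fork
if one exists. A test asserts the event-driven and closed-form programs
agree exactly when arrest is impossible. Cells in which no origin fires
anywhere are rejected and redrawn — a conditioning step mirroring the
fact that every sampled genome did replicate. Arrest is modelled as
terminal, not a timed pause: the downstream assay detects polarity
change, which arrest produces; pausing would need a time-penalty
parameter the data cannot constrain.

On the lagging strand of each fork territory, Okazaki junctions are a
renewal process with exponential spacings of mean
`priming_mean / pol_alpha_priming`; each junction independently snaps to
the nearest nucleosome dyad plus Normal(0, `snap_sd`) noise with
probability `snap_prob`. Consecutive junctions delimit fragments that
tile the territory exactly — so with full retention the Watson plus
Crick base coverage equals the cell count at every position, a
conservation law the tests check bitwise. The two `pol_alpha_*` knobs
deliberately separate the two arms of polymerase-alpha function: the
firing arm scales every competence (global origin-efficiency loss under
depletion) and the priming arm scales the junction rate (fragment
lengthening). Setting only the priming knob below 1 reproduces the
phenotype of losing adaptor-mediated (Ctf4-type) polymerase recruitment:
longer fragments at unchanged origin firing. The simulator cannot
distinguish a reduced priming rate from reduced primer utilisation;
only the effective inter-priming distance is exposed.

### Default parameter choices

| parameter | default | units | rationale |
|---|---|---|---|
| `fork_speed` | 1500 | bp/min | typical budding-yeast fork rate |
| `priming_mean` | 150 | bp | gives nucleosome-sized (~165 bp mode) fragments |
| `sigma_fire` | 5 | min | firing-time dispersion comparable to timing-profile widths |
| `snap_prob` | 0.8 | — | strong but imperfect chromatin-coupled junction placement |
| `snap_sd` | 5 | bp | residual jitter of snapped junctions |
| `s_phase_length` | 60 | min | S-phase span for WGS sampling |
| `wgs_bin` | 100 | bp | copy-number bin size |
| OEM `window` | 10000 | bp | flank width of the efficiency metric |
| OEM `min_count` | 50 | fragments | depth floor below which OEM is undefined |
| `span_fraction` | 0.02 | of chrom bins | Loess window for copy-number smoothing |

Per-cell RNG substreams are derived from the master seed
(`sample.int` of one seed vector), so a run is reproducible
byte-for-byte and independent of the order in which cells are evaluated.

### Benchmark geometries

Two exported configurations fix the package's standard verification
conditions; their geometry is deliberate, chosen once, and the tests run
against it:

* `sim_recovery_config()` — one 1.2 Mb chromosome, 20 origins 60 kb
  apart with competences spread over [0.1, 0.95] and mean firing times
  cycling through 12/24/36/48 min. The spacing keeps ≥ 20 kb of
  clearance beyond each ±10 kb OEM window, and the staggered timing
  makes passive replication of any origin predominantly unidirectional
  so that fork-*convergence* zones (which carry negative OEM signal)
  fall outside the windows. With synchronous neighbours instead, an
  inefficient origin sits in a termination zone and its OEM is biased
  low by design of the metric, not by an implementation fault — the
  staggered geometry is what "isolated origins" must mean for the OEM
  to read out efficiency cleanly.
* `sim_stall_config()` — a 500 kb chromosome, 10 fully competent
  origins 50 kb apart with firing times alternating 15/35 min, and 9
  oriented loci midway between origins carrying the arrest sites. The
  alternation again moves convergence ~15 kb off the loci, so the
  fork-direction profile is flat there without arrest (stall score ~0)
  and any drop at the locus is attributable to arrest.

The fixture generator (`generate_fixture()`) uses a third, two-chromosome
layout with the same staggering plus dyads every 165 bp, one exclusion
region per chromosome, and presets (`baseline`, `depleted`, `ctf4_like`,
`stall`) that differ only in documented knob values.

## End phasing, fork direction, copy number

**End phasing.** Fragment 5′/3′ ends follow the strand convention
(Watson 5′ = `start`; Crick 5′ = `end − 1`). `dyad_offset_histogram()`
aggregates *all* (end, dyad) pairs within ±200 bp — metagene style, not
nearest-dyad assignment, matching standard practice. Both raw-count and
density normalisations are available. `phasing_ratio()` summarises
phasing strength as the mean count near offset 0 over the histogram-wide
mean (the uniform-background expectation); this stays finite even for
perfectly phased input, where a between-peak background estimate would
vanish.

**Fork direction.** `fork_direction_profile()` reports the
rightward-fork fraction `C/(W+C)` in transcription-oriented offset bins,
pooling counts across loci (the loci are few and individually shallow,
so pooled counts beat per-locus averaging). Minus-strand loci are
reflected and strand-swapped before aggregation. `stall_score()` is the
mean downstream minus mean upstream fraction over ±2 kb; arrest makes it
negative. Origin-distal preselection of loci is a helper
(`origin_distal_loci()`, default 10 kb), keeping list responsibility
with the caller.

**Copy number.** `normalize_track()` applies, in order: exclusion-list
masking → reads-per-million scaling per sample → division by each
sample's own median unmasked bin → S/G1 ratio, masking zero-G1 bins.
The order makes the ratio invariant to sequencing depth and idempotent;
the upstream description lists the median and G1/RPM normalisations
without an order, so the depth-invariant order is fixed here and
documented. `loess_smooth()` runs per chromosome (degree-1 local
regression, tricube weights, `surface = "direct"` so exactly linear
tracks are reproduced to machine precision) with a window of 2% of the
chromosome's bins by default, and leaves bins undefined where fewer
than 10 unmasked bins support the window. "Smoothed to 1 kb" in
meta-origin coverage means block-mean re-binning of the 100 bp ratio
bins, not a 1 kb Loess bandwidth; `meta_origin_coverage()` averages the
re-binned ratio across origins with equal weight, for all origins or a
`t_rep` threshold subset and its complement.

## What the generator does and does not emulate

The simulator reproduces the features the analyses actually consume:
strand polarity set by fork direction, passive-replication suppression,
priming-rate–dependent fragment length, nucleosome-phased junctions,
pan-S copy number with a G1 control, fork arrest at oriented sites, and
a library-depth subsampling knob. It does not model sequence (no
nucleotides, read errors or mappability structure), GC or PCR bias,
per-read duplicates, replisome biochemistry beyond the effective knobs,
or pausing-without-arrest. Passing tests therefore demonstrate that the
analysis stack measures what it claims on data whose generative model is
known — not that real libraries are free of the artefacts the generator
omits; the exclusion-list masking and depth floors are the hooks real
data would lean on. One open question upstream of the package is whether
a pipeline counts a read pair or a fragment as the unit; `okseqr`
operates on fragments throughout.

## Numerical and degenerate-input behaviour

* All coordinates are 0-based half-open; interval validation rejects
  `start >= end` and out-of-chromosome records with line numbers.
* Zero-count intervals give `NA` Watson fractions (undefined, never 0);
  OEM records below the depth floor are `NA` and excluded from
  summaries; profiles carry `NA` bins rather than zeros.
* Fragment tiling survives junction snapping because snapped junctions
  are clamped to their territory, de-duplicated and re-sorted before
  cutting; territories shorter than 1 bp yield no fragment.
* Fork-collision boundaries are rounded to integer base pairs once, in
  the replication program, so fragments of one cell always partition
  the chromosome exactly.
* Ties in firing/arrival times resolve in favour of passive replication
  (strict inequality for active firing), deterministically.
* With `stall_prob = 1` and no opposing fork the remaining territory is
  never replicated; such regions are recorded with infinite replication
  time and yield no fragments.

## Problem sizes used in the test suite

The shipped suite verifies analytic exactness on single-cell
deterministic programs, parameter recovery at 2,000 cells (OEM vs truth
over 20 origins), global-depletion monotonicity at 5,000 cells pairwise
across origins, length/phasing properties at ~10^5 fragments, copy-number
flattening on 300-cell mid-S pools and stall detection at 2,000 cells —
sizes at which the Monte-Carlo error is several-fold smaller than each
asserted margin, as chosen once from the binomial/Poisson error budgets
above.

## Known limitations

* The OEM reads active firing efficiency only where passive replication
  is locally unidirectional; origins inside broad termination zones are
  biased low (this is a property of the metric itself).
* Stall sites are point sites with terminal arrest; no pause-and-resume.
* The Loess span is a single per-chromosome fraction; chromosomes with
  very few bins fall back to undefined output rather than refusing.
* `simulate_wgs_pool()` freezes each cell at a sampled time rather than
  modelling continuous S-phase entry/exit kinetics; sampling-time lists
  are the hook for arbitrary population structures (e.g. arrested
  subpopulations).
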