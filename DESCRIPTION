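Package: okseqr
Title: Okazaki-Fragment Sequencing Analysis and Stochastic Replication Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled-cell Okazaki-fragment sequencing (OK-seq) and
    S-phase whole-genome-sequencing data from budding yeast and similar
    genomes: strand-specific fragment coverage, the Origin Efficiency Metric
    (Watson-strand bias in 10 kb flanks around replication origins),
    meta-origin strand profiles, fragment-end phasing around nucleosome
    dyads, replication-fork direction profiles around oriented loci such as
    tRNA genes, and G1-normalised Loess-smoothed copy-number tracks.
    Includes a stochastic whole-genome replication simulator (origin
    competence and firing times, constant fork speed, passive replication,
    lagging-strand priming as a renewal process with nucleosome-dyad
    junction snapping, fork arrest at stall sites) that generates OK-seq
    and WGS-like inputs with known ground truth, so every analysis stage is
    verifiable by parameter recovery and analytic limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
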