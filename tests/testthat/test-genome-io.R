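test_that("BED6 fragments map fields, strands and validate against the genome", {
  g <- genome_layout("chrI", 1000)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrI\t100\t250\tf1\t0\t+", f)
  fr <- read_fragments(f, g)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 100)
  expect_equal(fr$end, 250)
  expect_equal(as.character(fr$strand), "Watson")

  writeLines(character(), f)
  expect_equal(nrow(read_fragments(f, g)), 0L)

  writeLines(c("chrI\t10\t20\tf1\t0\t-", "chrI\t250\t100\tf2\t0\t+"), f)
  expect_error(read_fragments(f, g), "line 2")
  writeLines("chrI\t10\t20\tf1\t0", f)
  expect_error(read_fragments(f, g), "6 tab-separated")
  writeLines("chrI\t10\t20\tf1\t0\t*", f)
  expect_error(read_fragments(f, g), "strand")
  writeLines("chrX\t10\t20\tf1\t0\t+", f)
  expect_error(read_fragments(f, g), "unknown chromosome")
  writeLines("chrI\t900\t1100\tf1\t0\t+", f)
  expect_error(read_fragments(f, g), "invalid")
})

test_that("fragment write/read round trip is the identity on canonical order", {
  cfg <- single_origin_config(n_cells = 4, seed = 3)
  frags <- simulate_okseq_library(cfg)
  expect_gt(nrow(frags), 1000)
  f <- withr::local_tempfile(fileext = ".bed")
  write_fragments(frags, f)
  back <- read_fragments(f, cfg$genome)
  o <- order(frags$chrom, frags$start, frags$end, frags$strand)
  expect_equal(back$start, frags$start[o])
  expect_equal(back$end, frags$end[o])
  expect_equal(as.character(back$strand), as.character(frags$strand[o]))
  # Watson encodes as "+" in column 6
  first <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(first[6], if (back$strand[1] == "Watson") "+" else "-")
  # empty set round trip
  empty <- ok_fragments(character(), numeric(), numeric(), character(),
                        cfg$genome)
  write_fragments(empty, f)
  expect_equal(nrow(read_fragments(f, cfg$genome)), 0L)
})

test_that("coordinates are 0-based half-open: closed-coordinate conversion is lossless", {
  g <- genome_layout("chrI", 10000)
  set.seed(42)
  s <- sample(0:9000, 50)
  e <- pmin(s + sample(1:500, 50, replace = TRUE), 10000)
  # 1-based closed representation and back
  closed_start <- s + 1; closed_end <- e
  expect_equal(closed_start - 1, s)
  expect_equal(closed_end, e)
  expect_true(all(closed_end - closed_start + 1 == e - s))
  fr <- ok_fragments("chrI", s, e, "Watson", g)
  expect_true(all(fr$end > fr$start))
})

test_that("origin tables read, sort, validate and expose timing splits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tmidpoint\tname\tfkh_class",
               "chrII\t500\tb\tactivated",
               "chrI\t900\ta2\t",
               "chrI\t100\ta1\trepressed"), f)
  org <- read_origins(f)
  expect_equal(org$name, c("a1", "a2", "b"))        # sorted (chrom, midpoint)
  expect_equal(org$fkh_class[1], "repressed")
  expect_equal(org$fkh_class[2], "unknown")
  expect_true(all(is.na(org$t_rep)))

  writeLines(c("chrom\tmidpoint\tname", "chrI\t100\ta", "chrI\t200\ta"), f)
  expect_error(read_origins(f), "duplicate")
  writeLines(c("chrom\tmidpoint\tname", "chrI\t10.5\ta"), f)
  expect_error(read_origins(f), "integer")

  # synthetic genome-scale table: 283 origins, 22 of them early
  n <- 283
  t_rep <- c(seq(10, 17.9, length.out = 22), seq(18.5, 45, length.out = 261))
  big <- origin_table(rep("chrI", n), seq(5000, by = 5000, length.out = n),
                      sprintf("ARS%03d", 1:n), t_rep = t_rep)
  write_origins(big, f)
  back <- read_origins(f)
  expect_equal(nrow(back), 283L)
  expect_equal(sum(back$t_rep < 18), 22L)
  expect_equal(sum(back$t_rep >= 18), 261L)
})

test_that("BED3/BED6 readers validate and derive midpoints", {
  g <- genome_layout("chrI", 10000)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t100\t265", "chrI\t430\t431"), f)
  dy <- read_dyads(f, g)
  expect_equal(dy$pos, c(182, 430))
  ex <- read_exclusions(f, g)
  expect_equal(ex$end, c(265, 431))
  writeLines("chrI\t100\t90", f)
  expect_error(read_exclusions(f, g), "invalid")
  writeLines("chrI\t100\t300\ttA\t0\t-", f)
  lo <- read_loci(f, g)
  expect_equal(lo$midpoint, 200)
  expect_equal(lo$strand, "-")
})

test_that("bedGraph round trip preserves values and masked bins", {
  g <- genome_layout(c("c1", "c2"), c(1000, 550))
  v <- list(c1 = c(1, 2.5, NA, 4, 0, 6, 7, 8, 9, 10),
            c2 = c(NA, 1, 2, 3, 4, 5))
  bc <- binned_counts(v, g, 100)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(bc, f)
  back <- read_bedgraph(f, g, 100)
  expect_equal(back$values, v)
  expect_error(binned_counts(list(c1 = 1:3, c2 = 1:6), g, 100), "bins")
})
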