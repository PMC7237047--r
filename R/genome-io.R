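#' Genome layout
#'
#' A genome layout is the table of chromosome names and lengths that every
#' interval in the package is validated against. All coordinates in okseqr
#' are 0-based, half-open (BED convention).
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @return A `genome_layout` object (a data frame with columns `chrom`,
#'   `length`).
#' @examples
#' genome_layout(c("chrI", "chrII"), c(230218, 813184))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(is.na(length)) || any(length <= 0)) stop("chromosome lengths must be > 0")
  if (any(length != floor(length))) stop("chromosome lengths must be integers")
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp. No header.
#'
#' @param path Path to the file.
#' @return A [genome_layout()].
#' @export
read_genome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %s bp total\n",
              nrow(x), format(sum(x$length), big.mark = ",")))
  print.data.frame(x, ...)
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

# Validate 0-based half-open intervals against a genome; `where` names the
# offending input in error messages, `line` gives file line numbers if known.
validate_intervals <- function(chrom, start, end, genome, where = "interval",
                               line = NULL) {
  len <- chrom_length(genome, chrom)
  bad <- which(!(start >= 0 & start < end & end <= len))
  if (length(bad)) {
    b <- bad[1L]
    loc <- if (!is.null(line)) sprintf(" (line %d)", line[b]) else ""
    stop(sprintf("invalid %s%s: %s:[%s,%s) outside [0,%s) or start >= end",
                 where, loc, chrom[b], format(start[b]), format(end[b]),
                 format(len[b])))
  }
  invisible(TRUE)
}

#' Okazaki fragment set
#'
#' A set of stranded genomic intervals representing unligated Okazaki
#' fragments pooled over cells. Strand follows the package-wide convention:
#' Watson (reference plus strand) fragments derive from leftward-moving
#' replication forks; Crick fragments from rightward-moving forks.
#'
#' @param chrom,start,end Interval coordinates (0-based, half-open).
#' @param strand Character or factor, "Watson"/"Crick" (or BED "+"/"-").
#' @param genome A [genome_layout()] the fragments are validated against.
#' @param cell_id Optional per-fragment cell identifier.
#' @return An `ok_fragments` object (data frame with attribute `genome`).
#' @export
ok_fragments <- function(chrom, start, end, strand, genome, cell_id = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- as.character(strand)
  strand[strand == "+"] <- "Watson"
  strand[strand == "-"] <- "Crick"
  if (!all(strand %in% c("Watson", "Crick")))
    stop("strand must be 'Watson'/'Crick' (or '+'/'-')")
  if (length(chrom)) validate_intervals(chrom, start, end, genome, "fragment")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = factor(strand, levels = c("Watson", "Crick")),
                   stringsAsFactors = FALSE)
  if (!is.null(cell_id)) df$cell_id <- as.character(cell_id)
  structure(df, genome = genome, class = c("ok_fragments", "data.frame"))
}

#' @export
print.ok_fragments <- function(x, ...) {
  n <- nrow(x)
  nw <- sum(x$strand == "Watson")
  cat(sprintf("<ok_fragments> %s fragments (%s Watson / %s Crick)",
              format(n, big.mark = ","), format(nw, big.mark = ","),
              format(n - nw, big.mark = ",")))
  if (n) cat(sprintf(", median length %d bp", stats::median(x$end - x$start)))
  cat("\n")
  if (n) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read stranded Okazaki fragments from a BED6 file
#'
#' Six tab-separated columns (chrom, start, end, name, score, strand);
#' strand "+" maps to Watson, "-" to Crick. Every record is validated
#' against the genome; input order is preserved.
#'
#' @param path Path to the BED6 file.
#' @param genome A [genome_layout()].
#' @return An [ok_fragments()] set.
#' @export
read_fragments <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(ok_fragments(character(), numeric(), numeric(), character(), genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    b <- which(nf != 6L)[1L]
    stop(sprintf("parse error at line %d: expected 6 tab-separated fields, got %d",
                 b, nf[b]))
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    b <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("parse error at line %d: non-numeric coordinate", b))
  }
  if (!all(m[, 6L] %in% c("+", "-"))) {
    b <- which(!(m[, 6L] %in% c("+", "-")))[1L]
    stop(sprintf("parse error at line %d: strand must be '+' or '-', got '%s'",
                 b, m[b, 6L]))
  }
  validate_intervals(m[, 1L], start, end, genome, "fragment", line = seq_len(nrow(m)))
  ok_fragments(m[, 1L], start, end, m[, 6L], genome)
}

#' Write Okazaki fragments to a BED6 file
#'
#' Records are written in canonical order (chromosome, start, end, strand),
#' Watson as "+", Crick as "-", so that `read_fragments(write_fragments(x))`
#' reproduces `x` up to that ordering.
#'
#' @param frags An [ok_fragments()] set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  stopifnot(inherits(frags, "ok_fragments"))
  if (!nrow(frags)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  o <- order(frags$chrom, frags$start, frags$end, frags$strand)
  df <- frags[o, , drop = FALSE]
  bed <- data.frame(df$chrom, format_coord(df$start), format_coord(df$end),
                    paste0("f", seq_len(nrow(df))), 0L,
                    ifelse(df$strand == "Watson", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# avoid scientific notation in coordinate output
format_coord <- function(x) formatC(x, format = "d")

#' Replication origin table
#'
#' @param chrom,midpoint Origin location (midpoint in bp, 0-based).
#' @param name Unique origin names.
#' @param t_rep Optional replication timing in minutes after S-phase onset.
#' @param fkh_class Optional Forkhead class: "activated", "repressed",
#'   "independent" or "unknown".
#' @param true_competence Optional per-origin firing competence in `[0,1]`
#'   (simulation ground truth).
#' @param genome Optional [genome_layout()] for midpoint validation.
#' @return An `origin_table` (data frame sorted by chromosome, midpoint).
#' @export
origin_table <- function(chrom, midpoint, name, t_rep = NA_real_,
                         fkh_class = "unknown", true_competence = NA_real_,
                         genome = NULL) {
  chrom <- as.character(chrom)
  midpoint <- as.numeric(midpoint)
  name <- as.character(name)
  if (any(midpoint != floor(midpoint), na.rm = TRUE))
    stop("parse error: origin midpoint must be an integer")
  if (anyDuplicated(name)) stop("duplicate origin names")
  fkh_class <- as.character(fkh_class)
  fkh_class[is.na(fkh_class) | fkh_class == ""] <- "unknown"
  if (!all(fkh_class %in% c("activated", "repressed", "independent", "unknown")))
    stop("fkh_class must be activated/repressed/independent/unknown")
  tc <- as.numeric(true_competence)
  if (any(!is.na(tc) & (tc < 0 | tc > 1))) stop("true_competence must be in [0,1]")
  if (!is.null(genome)) {
    len <- chrom_length(genome, chrom)
    if (any(midpoint < 0 | midpoint >= len)) stop("origin midpoint outside chromosome")
  }
  df <- data.frame(chrom = chrom, midpoint = midpoint, name = name,
                   t_rep = as.numeric(rep_len(t_rep, length(name))),
                   fkh_class = rep_len(fkh_class, length(name)),
                   true_competence = rep_len(tc, length(name)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$midpoint), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("origin_table", "data.frame"))
}

#' @export
print.origin_table <- function(x, ...) {
  cat(sprintf("<origin_table> %d origins on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a replication-origin table (house TSV)
#'
#' Header row required. Required columns: `chrom` (alias `chromosome`),
#' `midpoint`, `name`. Optional: `t_rep` (minutes), `fkh_class`,
#' `true_competence`. Missing optional fields become `NA`/"unknown"; rows
#' are sorted by (chromosome, midpoint).
#'
#' @param path Path to the TSV file.
#' @param genome Optional [genome_layout()] for validation.
#' @return An [origin_table()].
#' @export
read_origins <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if ("chromosome" %in% names(df) && !("chrom" %in% names(df)))
    names(df)[names(df) == "chromosome"] <- "chrom"
  req <- c("chrom", "midpoint", "name")
  if (!all(req %in% names(df)))
    stop("origin table must have columns: ", paste(req, collapse = ", "))
  if (is.character(df$midpoint) || any(df$midpoint != floor(df$midpoint)))
    stop("parse error: origin midpoint must be an integer")
  origin_table(df$chrom, df$midpoint, df$name,
               t_rep = if ("t_rep" %in% names(df)) df$t_rep else NA_real_,
               fkh_class = if ("fkh_class" %in% names(df)) df$fkh_class else "unknown",
               true_competence = if ("true_competence" %in% names(df))
                 df$true_competence else NA_real_,
               genome = genome)
}

#' Write an origin table to TSV
#' @param origins An [origin_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_origins <- function(origins, path) {
  utils::write.table(as.data.frame(origins), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read single-position features (nucleosome dyads) from BED3
#'
#' Each record's position is the interval midpoint, `floor((start+end)/2)`.
#'
#' @param path Path to a BED3 file (no header).
#' @param genome A [genome_layout()].
#' @return Data frame with columns `chrom`, `pos`.
#' @export
read_dyads <- function(path, genome) {
  df <- read_bed3(path, genome)
  data.frame(chrom = df$chrom, pos = (df$start + df$end) %/% 2,
             stringsAsFactors = FALSE)
}

#' Read exclusion regions from BED3
#'
#' Intervals (0-based, half-open) masked out of copy-number analysis, the
#' analog of a poorly-mapped-region blacklist.
#'
#' @inheritParams read_dyads
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_exclusions <- function(path, genome) read_bed3(path, genome)

read_bed3 <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    b <- which(nf < 3L)[1L]
    stop(sprintf("parse error at line %d: expected >= 3 tab-separated fields", b))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    b <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("parse error at line %d: non-numeric coordinate", b))
  }
  validate_intervals(chrom, start, end, genome, "interval",
                     line = seq_along(chrom))
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Read oriented loci (tRNA genes, stall sites) from BED6
#'
#' @param path Path to a BED6 file (no header); strand column "+" or "-"
#'   gives the transcription direction.
#' @param genome A [genome_layout()].
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, `midpoint`.
#' @export
read_loci <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), strand = character(),
                      midpoint = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 6L)) {
    b <- which(lengths(fields) != 6L)[1L]
    stop(sprintf("parse error at line %d: expected 6 tab-separated fields", b))
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  start <- as.numeric(m[, 2L]); end <- as.numeric(m[, 3L])
  if (!all(m[, 6L] %in% c("+", "-"))) {
    b <- which(!(m[, 6L] %in% c("+", "-")))[1L]
    stop(sprintf("parse error at line %d: strand must be '+' or '-'", b))
  }
  validate_intervals(m[, 1L], start, end, genome, "locus",
                     line = seq_len(nrow(m)))
  data.frame(chrom = m[, 1L], start = start, end = end, name = m[, 4L],
             strand = m[, 6L], midpoint = (start + end) %/% 2,
             stringsAsFactors = FALSE)
}

#' Binned per-chromosome counts or values
#'
#' Container for a fixed-bin-size genome track (WGS read counts, coverage).
#' Bin `i` (1-based) covers `[(i-1)*bin_size, i*bin_size)`; the last bin of
#' each chromosome may be truncated by the chromosome end.
#'
#' @param values Named list (one numeric vector per chromosome).
#' @param genome A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(values, genome, bin_size) {
  stopifnot(is.list(values), bin_size >= 1)
  need <- ceiling(genome$length / bin_size)
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    v <- values[[ch]]
    if (is.null(v) || length(v) != need[i])
      stop(sprintf("values for %s must have %d bins", ch, need[i]))
  }
  structure(list(values = values[genome$chrom], genome = genome,
                 bin_size = bin_size),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> bin %d bp, %d chromosome(s), total %s\n",
              x$bin_size, nrow(x$genome),
              format(sum(unlist(x$values), na.rm = TRUE), big.mark = ",")))
  invisible(x)
}

#' Write a binned track as bedGraph
#'
#' `NA` bins (masked) are omitted from the output, as is conventional for
#' masked tracks.
#'
#' @param x A [binned_counts()] or `cn_track` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  vals <- if (inherits(x, "cn_track")) x$ratio else x$values
  bin <- x$bin_size
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in x$genome$chrom) {
    v <- vals[[ch]]
    keep <- which(!is.na(v))
    if (!length(keep)) next
    start <- (keep - 1) * bin
    end <- pmin(keep * bin, chrom_length(x$genome, ch))
    writeLines(paste(ch, format_coord(start), format_coord(end),
                     formatC(v[keep], format = "g", digits = 15),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a fixed-bin bedGraph into binned counts
#'
#' Every record must align to the stated bin grid. Bins absent from the
#' file become `NA` (masked).
#'
#' @param path Path to the bedGraph file.
#' @param genome A [genome_layout()].
#' @param bin_size Bin width in bp the file was written at.
#' @return A [binned_counts()] with `NA` for absent bins.
#' @export
read_bedgraph <- function(path, genome, bin_size) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  validate_intervals(df$chrom, df$start, df$end, genome, "bedGraph record")
  if (any(df$start %% bin_size != 0))
    stop("bedGraph records do not align to the bin grid")
  vals <- lapply(seq_len(nrow(genome)), function(i) {
    rep(NA_real_, ceiling(genome$length[i] / bin_size))
  })
  names(vals) <- genome$chrom
  idx <- df$start %/% bin_size + 1
  for (ch in unique(df$chrom)) {
    sel <- df$chrom == ch
    vals[[ch]][idx[sel]] <- df$value[sel]
  }
  binned_counts(vals, genome, bin_size)
}
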