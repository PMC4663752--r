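#' Nx statistic of an assembly
#'
#' Length of the sequence at which the cumulative sum of descending-sorted
#' lengths first reaches `x` percent of the total assembly length. `nx(l, 50)`
#' is the familiar N50.
#'
#' @param lengths Numeric vector of sequence lengths (bp), all positive.
#' @param x Percentage in (0, 100].
#' @return Length in bp.
#' @examples
#' nx(c(60, 30, 20), 50)  # 60
#' @export
nx <- function(lengths, x = 50) {
  check_that(length(lengths) > 0, "no sequences")
  check_that(all(lengths > 0), "lengths must be positive")
  check_that(x > 0 && x <= 100, "x must be in (0, 100]")
  l <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(l))
  l[which(cum >= x / 100 * cum[length(cum)])[1]]
}

#' NGx statistic of an assembly
#'
#' Like [nx()] but against an external genome-size denominator: the
#' last-counted sequence length when the cumulative descending-sorted sum
#' first reaches `x` percent of `genome_size`. Returns 0 when the assembly
#' total never reaches that point, so NG curves can be drawn to their
#' termination point.
#'
#' @param lengths Numeric vector of sequence lengths (bp).
#' @param genome_size Estimated genome size (bp), positive.
#' @param x Percentage (typically an integer 1..100).
#' @return Length in bp, or 0 if unreached.
#' @examples
#' ng(c(60, 30, 20), 100, 50)   # 60
#' ng(c(60, 30), 1000, 50)      # 0: assembly too small
#' @export
ng <- function(lengths, genome_size, x = 50) {
  check_that(length(lengths) > 0, "no sequences")
  check_that(genome_size > 0, "genome_size must be positive")
  l <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(l))
  i <- which(cum >= x / 100 * genome_size)
  if (length(i) == 0) return(0)
  l[i[1]]
}

#' NG curve (NG1..NG100)
#'
#' @inheritParams ng
#' @return Data frame with columns `x` (1..100) and `ng_bp`.
#' @export
ng_curve <- function(lengths, genome_size) {
  data.frame(x = 1:100,
             ng_bp = vapply(1:100, function(x) ng(lengths, genome_size, x),
                            numeric(1)))
}

#' Plot NG curves for one or more assemblies
#'
#' @param curves Named list of data frames from [ng_curve()].
#' @param log Use a log-scaled y axis (default `TRUE`).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted values.
#' @export
plot_ng <- function(curves, log = TRUE, ...) {
  if (is.data.frame(curves)) curves <- list(assembly = curves)
  m <- sapply(curves, function(d) d$ng_bp)
  m[m == 0] <- NA
  graphics::matplot(1:100, m, type = "l", lty = 1, lwd = 2,
                    log = if (log) "y" else "",
                    xlab = "NG(x)", ylab = "length (bp)", ...)
  graphics::legend("topright", legend = names(curves), lty = 1, lwd = 2,
                   col = seq_along(curves))
  invisible(m)
}

#' Assembly coverage of the estimated genome size
#'
#' Two reporting dialects are in circulation: `length` divides the raw
#' assembly total by the genome size; `nongap` first subtracts the N (gap)
#' characters. Published assembly tables use either without saying which, so
#' both are exposed and the caller must choose.
#'
#' @param seqs A [sequence_set()], or a list with elements `total_bp` and
#'   `n_count` when only summary numbers are available.
#' @param genome_size Estimated genome size (bp).
#' @param dialect `"length"` or `"nongap"`.
#' @return Percentage, rounded half-up to 1 decimal.
#' @examples
#' coverage_pct(list(total_bp = 524364527, n_count = 0), 540e6)  # 97.1
#' @export
coverage_pct <- function(seqs, genome_size, dialect = c("length", "nongap")) {
  dialect <- match.arg(dialect)
  check_that(genome_size > 0, "genome_size must be positive")
  if (is.list(seqs)) {
    total <- seqs$total_bp
    ncnt <- seqs$n_count
  } else {
    total <- sum(as.numeric(seq_lengths(seqs)))
    ncnt <- count_ns(seqs)
  }
  if (length(total) == 0 || total == 0) return(0)
  num <- if (dialect == "length") total else total - ncnt
  round_half_up(100 * num / genome_size, 1)
}

# Internal: total number of N characters in a set.
count_ns <- function(seqs) {
  s <- unclass(seqs)
  sum(nchar(s) - nchar(gsub("N", "", s, fixed = TRUE)))
}

#' Gap (N) fraction of an assembly
#'
#' @param seqs A [sequence_set()].
#' @return Percentage of N characters over total length (0 for an empty set).
#' @examples
#' gap_fraction(sequence_set(c(a = "ACGTNNNNAC")))  # 40
#' @export
gap_fraction <- function(seqs) {
  total <- sum(as.numeric(seq_lengths(seqs)))
  if (length(total) == 0 || total == 0) return(0)
  100 * count_ns(seqs) / total
}

#' Summary statistics of an assembly
#'
#' Computes the usual per-assembly length statistics. The mean is reported by
#' floor (integer) division, matching the convention of published assembly
#' tables; percentages are rounded half-up to 1 decimal.
#'
#' @param seqs A [sequence_set()].
#' @param genome_size Estimated genome size (bp).
#' @param dialect Coverage dialect, see [coverage_pct()].
#' @return An object of class `assembly_stats`: a list with fields
#'   `n_sequences`, `total_bp`, `mean_bp`, `max_bp`, `n50_bp`, `ng`
#'   (numeric vector of NG1..NG100), `ng50_bp`, `coverage_pct`, `gap_pct`.
#' @export
assembly_stats <- function(seqs, genome_size, dialect = "length") {
  check_that(length(seqs) > 0, "no sequences")
  len <- as.numeric(seq_lengths(seqs))
  ngv <- ng_curve(len, genome_size)$ng_bp
  structure(list(
    n_sequences = length(len),
    total_bp = sum(len),
    mean_bp = floor(sum(len) / length(len)),
    max_bp = max(len),
    n50_bp = nx(len, 50),
    ng = ngv,
    ng50_bp = ngv[50],
    coverage_pct = coverage_pct(seqs, genome_size, dialect),
    gap_pct = round_half_up(gap_fraction(seqs), 1)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("assembly statistics\n")
  cat("  sequences :", fmt(x$n_sequences), "\n")
  cat("  total (bp):", fmt(x$total_bp), "\n")
  cat("  mean (bp) :", fmt(x$mean_bp), "\n")
  cat("  max (bp)  :", fmt(x$max_bp), "\n")
  cat("  N50 (bp)  :", fmt(x$n50_bp), "\n")
  cat("  NG50 (bp) :", fmt(x$ng50_bp), "\n")
  cat("  coverage  :", x$coverage_pct, "%\n")
  cat("  gap       :", x$gap_pct, "%\n")
  invisible(x)
}

#' Scan sequence termini for telomeric repeats
#'
#' Counts occurrences of the telomere motif (plant-type `TTTAGGG` by default)
#' and of its reverse complement in each terminal window; a terminus is
#' called telomeric when either orientation reaches `min_copies`. At the left
#' (5') end of a chromosome the reverse complement (`CCCTAAA`) is the
#' expected orientation, but both are always checked.
#'
#' @param seq A single nucleotide string.
#' @param motif Telomere repeat unit.
#' @param terminal_window Window size at each end (bp). Sequences shorter
#'   than the window are scanned whole.
#' @param min_copies Minimum motif count to call a telomere.
#' @return Logical vector `c(left = , right = )`.
#' @export
telomere_scan <- function(seq, motif = "TTTAGGG", terminal_window = 1000L,
                          min_copies = 3L) {
  check_that(terminal_window >= nchar(motif) * min_copies,
             "terminal_window too small for min_copies motifs")
  seq <- toupper(seq)
  n <- nchar(seq)
  w <- min(terminal_window, n)
  left <- substr(seq, 1L, w)
  right <- substr(seq, n - w + 1L, n)
  rc <- revcomp(motif)
  cnt <- function(window, pat) {
    m <- gregexpr(pat, window, fixed = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  has <- function(window) {
    cnt(window, motif) >= min_copies || cnt(window, rc) >= min_copies
  }
  c(left = has(left), right = has(right))
}

#' Estimate genome size from a k-mer multiplicity histogram
#'
#' The haploid genome size is estimated as the total number of counted k-mers
#' (sum of multiplicity times distinct k-mer count) divided by the modal
#' (coverage-peak) multiplicity. Low-multiplicity entries, dominated by
#' sequencing errors, are excluded by `min_multiplicity` before locating the
#' peak.
#'
#' @param hist Data frame with columns `multiplicity` and `count`
#'   (distinct k-mers at that multiplicity), as written by common k-mer
#'   counters.
#' @param min_multiplicity Error-peak cutoff: entries with multiplicity below
#'   this value are ignored.
#' @return Estimated genome size in bp (bases).
#' @examples
#' h <- data.frame(multiplicity = 30, count = 1e6)
#' genome_size_from_kmers(h)  # 1e6
#' @export
genome_size_from_kmers <- function(hist, min_multiplicity = 4L) {
  check_that(all(c("multiplicity", "count") %in% names(hist)),
             "hist needs columns multiplicity, count")
  h <- hist[order(hist$multiplicity), , drop = FALSE]
  check_that(!is.unsorted(h$multiplicity, strictly = TRUE),
             "multiplicities must be unique")
  keep <- h$multiplicity >= min_multiplicity & h$count > 0
  if (!any(keep)) stop("cannot locate coverage peak", call. = FALSE)
  h <- h[keep, , drop = FALSE]
  peak <- h$multiplicity[which.max(h$count)]
  sum(as.numeric(h$multiplicity) * as.numeric(h$count)) / peak
}

#' Read a k-mer histogram from a 2-column TSV
#'
#' @param path File with two columns: multiplicity, distinct k-mer count
#'   (no header), the common k-mer counter output format.
#' @return Data frame with columns `multiplicity`, `count`.
#' @export
read_kmer_histogram <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t",
                  col.names = c("multiplicity", "count"))
  d
}
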