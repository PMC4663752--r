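#' Find negative gaps in a scaffold layout
#'
#' A pair of bridged contigs is a merge candidate when the scaffolder's
#' estimated gap between them is negative, or when the overhangs of the two
#' contigs beyond their bridging read pairs together exceed the expected
#' insert size — both signals that the contig ends actually overlap.
#'
#' @param layout Data frame with columns `left_id`, `right_id`,
#'   `estimated_gap` (bp, may be negative), `left_overhang`,
#'   `right_overhang`, `expected_insert`.
#' @return The candidate subset of `layout`.
#' @export
find_negative_gaps <- function(layout) {
  need <- c("left_id", "right_id", "estimated_gap", "left_overhang",
            "right_overhang", "expected_insert")
  check_that(all(need %in% names(layout)), "missing layout columns")
  check_that(all(layout$left_overhang >= 0 & layout$right_overhang >= 0),
             "overhangs must be non-negative")
  keep <- layout$estimated_gap < 0 |
    (layout$left_overhang + layout$right_overhang > layout$expected_insert)
  layout[keep, , drop = FALSE]
}

# Internal: positions (1-based) of all k-mers of `s`, as a named-less
# environment-free list: returns data.frame(kmer, pos).
kmer_positions <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(data.frame(kmer = character(), pos = integer()))
  starts <- seq_len(n - k + 1L)
  data.frame(kmer = substring(s, starts, starts + k - 1L), pos = starts)
}

#' Detect a terminal overlap between two contigs
#'
#' Compares the last `window` bases of `left` with the first `window` bases
#' of `right`. Shared 21-mers vote for candidate diagonals; the
#' best-supported diagonal cluster bounds the putative overlap, which is
#' then verified by an ends-free alignment of the bounded regions (so a full
#' window-by-window dynamic program is never run). Identity is defined as
#' matches over alignment columns.
#'
#' The pair is `merged = TRUE` when at least `min_len` bases align with at
#' least `min_ident` identity and the alignment is terminal-consistent: it
#' reaches within 50 bp of the end of `left` and of the start of `right`.
#'
#' @param left_seq,right_seq Contig sequences.
#' @param window Terminal window size (bp), default 10 kb.
#' @param min_len Minimum aligned length (default 500 bp).
#' @param min_ident Minimum identity (default 0.95).
#' @param k Seed k-mer size (default 21).
#' @return List with `aligned_length` (alignment columns), `identity`,
#'   `score` (alignment score: match 1, mismatch -2, gap open 4 and extend
#'   2), `left_cut` and `right_cut` (1-based junction coordinates in the
#'   full sequences, at the alignment midpoint), `merged`.
#' @export
terminal_overlap <- function(left_seq, right_seq, window = 10000L,
                             min_len = 500L, min_ident = 0.95, k = 21L) {
  no <- list(aligned_length = 0L, identity = 0, score = 0,
             left_cut = NA_integer_, right_cut = NA_integer_, merged = FALSE)
  left_seq <- toupper(left_seq)
  right_seq <- toupper(right_seq)
  nl <- nchar(left_seq)
  wl <- min(window, nl)
  lw <- substr(left_seq, nl - wl + 1L, nl)          # left terminal window
  rw <- substr(right_seq, 1L, min(window, nchar(right_seq)))
  kl <- kmer_positions(lw, k)
  kr <- kmer_positions(rw, k)
  shared <- merge(kl, kr, by = "kmer", suffixes = c("_l", "_r"))
  if (nrow(shared) == 0) return(no)
  # drop k-mers that are highly repetitive in either window
  tab_l <- table(kl$kmer)
  tab_r <- table(kr$kmer)
  ok <- tab_l[shared$kmer] <= 5 & tab_r[shared$kmer] <= 5
  shared <- shared[ok, , drop = FALSE]
  if (nrow(shared) == 0) return(no)
  diag <- shared$pos_l - shared$pos_r
  # cluster diagonals within a +-50 band around the best-supported one
  dt <- sort(table(diag), decreasing = TRUE)
  d0 <- as.integer(names(dt)[1])
  in_band <- abs(diag - d0) <= 50
  if (!any(in_band)) return(no)
  band <- shared[in_band, , drop = FALSE]
  d_lo <- min(band$pos_l - band$pos_r)
  # candidate: lw[(d+1)..wl] overlaps rw[1..(wl-d)]
  a_start <- max(1L, min(band$pos_l) - 60L)
  a <- substr(lw, a_start, wl)
  b_end <- min(nchar(rw), max(band$pos_r + k - 1L) + 60L + 50L)
  b <- substr(rw, 1L, b_end)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 4, gapExtension = 2)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pa)
  if (cols == 0) return(no)
  matches <- sum(strsplit(pa, "")[[1]] == strsplit(sa, "")[[1]])
  identity <- matches / cols
  # terminal consistency (within full sequences)
  p_end_in_left <- nl - wl + a_start - 1L + Biostrings::end(Biostrings::pattern(aln))
  s_start_in_right <- Biostrings::start(Biostrings::subject(aln))
  terminal_ok <- (nl - p_end_in_left) <= 50L && (s_start_in_right - 1L) <= 50L
  merged <- cols >= min_len && identity >= min_ident && terminal_ok
  # junction at the alignment midpoint
  mid <- ceiling(cols / 2)
  p_chars <- cumsum(strsplit(pa, "")[[1]] != "-")
  s_chars <- cumsum(strsplit(sa, "")[[1]] != "-")
  left_cut <- nl - wl + a_start - 1L +
    (Biostrings::start(Biostrings::pattern(aln)) - 1L) + p_chars[mid]
  right_cut <- (Biostrings::start(Biostrings::subject(aln)) - 1L) + s_chars[mid]
  list(aligned_length = cols, identity = identity,
       score = Biostrings::score(aln),
       left_cut = as.integer(left_cut), right_cut = as.integer(right_cut),
       merged = merged)
}

#' Merge two contigs across a verified terminal overlap
#'
#' Takes `left` up to the alignment midpoint and `right` from the
#' corresponding coordinate. For a gap-free overlap the merged length equals
#' `nchar(left) + nchar(right) - aligned_length`, which is asserted.
#'
#' @param left_seq,right_seq Contig sequences.
#' @param overlap Result of [terminal_overlap()] with `merged = TRUE`.
#' @return Merged sequence.
#' @export
merge_pair <- function(left_seq, right_seq, overlap) {
  check_that(isTRUE(overlap$merged), "overlap not mergeable")
  merged <- paste0(substr(left_seq, 1L, overlap$left_cut),
                   substr(right_seq, overlap$right_cut + 1L,
                          nchar(right_seq)))
  merged
}

#' Remove contained near-duplicate contigs
#'
#' A sequence is dropped when it aligns to a longer sequence over more than
#' `min_cov` of its own length at more than `min_ident` identity. Candidate
#' pairs are screened by shared k-mers, then verified by local alignment.
#' The longer member of a mutually contained pair is always kept.
#'
#' @param seqs A [sequence_set()].
#' @param min_cov Minimum fraction of the shorter sequence covered
#'   (default 0.98).
#' @param min_ident Minimum alignment identity (default 0.98).
#' @param k Screening k-mer size (default 31).
#' @return The retained [sequence_set()]; attribute `dropped` lists removed
#'   ids and their containers.
#' @export
drop_contained <- function(seqs, min_cov = 0.98, min_ident = 0.98, k = 31L) {
  s <- unclass(seqs)
  ids <- names(s)[order(-nchar(unclass(seqs)), names(s))]
  kept <- character(0)
  dropped <- list()
  kmers_of <- function(x) unique(kmer_positions(x, k)$kmer)
  kept_kmers <- list()
  for (id in ids) {
    x <- s[[id]]
    km <- kmers_of(x)
    km_rc <- kmers_of(revcomp(x))
    contained <- FALSE
    for (big in kept) {
      sh_f <- mean(km %in% kept_kmers[[big]])
      sh_r <- mean(km_rc %in% kept_kmers[[big]])
      use_rc <- sh_r > sh_f
      if (max(sh_f, sh_r) < 0.5) next
      q <- if (use_rc) revcomp(x) else x
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(s[[big]]),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -2),
        gapOpening = 4, gapExtension = 2)
      pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      cols <- length(pa)
      if (cols == 0) next
      ident <- sum(pa == sa) / cols
      covered <- (Biostrings::end(Biostrings::pattern(aln)) -
                    Biostrings::start(Biostrings::pattern(aln)) + 1) / nchar(x)
      if (covered > min_cov && ident > min_ident) {
        contained <- TRUE
        dropped[[length(dropped) + 1]] <- data.frame(id = id, container = big)
        break
      }
    }
    if (!contained) {
      kept <- c(kept, id)
      kept_kmers[[id]] <- km
    }
  }
  out <- seqs[names(s)[names(s) %in% kept]]
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(id = character(), container = character())
  out
}
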