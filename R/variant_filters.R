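#' Variant-filter configuration
#'
#' Houses every threshold used by the variant-level rules. Defaults follow
#' the error-correction and marker-design conventions of map-guided assembly
#' projects: a site must be covered by at least 10 reads whose base quality
#' is at least Q30; error correction requires an alternate-allele frequency
#' of at least 0.70 and marker design at least 0.90; strand bias is rejected
#' at Fisher p <= 0.01; marker flanks are 60 bp each side and selected
#' markers at least 100 kb apart; an indel is homopolymer-associated when the
#' local single-base run is at least 4 (more than three consecutive
#' nucleotides).
#'
#' @param min_depth,min_baseq,min_freq_error,min_freq_marker,strand_p,flank,min_spacing,homopolymer_min_run
#'   See description.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10L, min_baseq = 30L,
                          min_freq_error = 0.70, min_freq_marker = 0.90,
                          strand_p = 0.01, flank = 60L,
                          min_spacing = 100000L, homopolymer_min_run = 4L) {
  cfg <- list(min_depth = min_depth, min_baseq = min_baseq,
              min_freq_error = min_freq_error,
              min_freq_marker = min_freq_marker, strand_p = strand_p,
              flank = flank, min_spacing = min_spacing,
              homopolymer_min_run = homopolymer_min_run)
  check_that(all(unlist(cfg) > 0), "all thresholds must be positive")
  structure(cfg, class = "filter_config")
}

#' Two-sided Fisher exact test for strand bias
#'
#' Tests association between allele and strand in the 2x2 table of
#' per-strand allele counts. Two-sided in the standard convention: sum of the
#' probabilities of all tables (given margins) no more likely than the
#' observed one.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev Read counts.
#' @return p-value.
#' @examples
#' strand_bias_p(5, 5, 5, 5)    # 1: no association
#' strand_bias_p(10, 0, 0, 10)  # ~1.08e-5
#' @export
strand_bias_p <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  counts <- c(ref_fwd, ref_rev, alt_fwd, alt_rev)
  check_that(all(counts >= 0), "counts must be non-negative")
  check_that(sum(counts) > 0, "all-zero strand table")
  fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

# Internal: vectorised strand-bias p over a variant table.
strand_bias_p_vec <- function(v) {
  vapply(seq_len(nrow(v)), function(i) {
    strand_bias_p(v$ref_fwd[i], v$ref_rev[i], v$alt_fwd[i], v$alt_rev[i])
  }, numeric(1))
}

#' Read / write variant records as TSV
#'
#' Plain-TSV dialect of a site-level VCF: columns `scaffold`, `position`
#' (0-based), `ref`, `alt`, `depth_hq` (covering reads with base quality at
#' or above the configured floor), `alt_frequency` (over those reads),
#' `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`, `genotype`
#' (`hom_ref`/`het`/`hom_alt`).
#'
#' @param path File path.
#' @return Data frame of variant records; the writer returns `path`
#'   invisibly.
#' @export
read_variants <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(scaffold = "character", ref = "character",
                                 alt = "character", genotype = "character"))
  need <- c("scaffold", "position", "ref", "alt", "depth_hq", "alt_frequency",
            "ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "genotype")
  check_that(all(need %in% names(d)), "missing variant columns")
  d
}

#' @rdname read_variants
#' @param variants Variant data frame.
#' @export
write_variants <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select assembly-error sites for correction
#'
#' Keeps variant sites supported by at least `min_depth` high-quality reads,
#' an alternate-allele frequency of at least `min_freq_error`, and no strand
#' bias (Fisher p greater than `strand_p`). Boundaries are inclusive.
#'
#' @param variants Variant data frame (see [read_variants()]).
#' @param cfg A [filter_config()].
#' @return The selected subset, with a `p_strand` column added.
#' @export
select_error_sites <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0) return(cbind(variants, p_strand = numeric(0)))
  p <- strand_bias_p_vec(variants)
  keep <- variants$depth_hq >= cfg$min_depth &
    variants$alt_frequency >= cfg$min_freq_error &
    p > cfg$strand_p
  out <- variants[keep, , drop = FALSE]
  out$p_strand <- p[keep]
  out
}

#' Select candidate marker SNPs with flank screens
#'
#' Four-stage pipeline, each stage recorded in the audit log:
#' \enumerate{
#'   \item homozygous-alternate sites with `depth_hq >= min_depth`,
#'     `alt_frequency >= min_freq_marker` and Fisher strand p above
#'     `strand_p`;
#'   \item no other variant (in either parent) within the flank distance on
#'     either side;
#'   \item the 121-mer flank (SNP centred, 60 bp each side) occurs exactly
#'     once in the assembly — an exact-occurrence uniqueness screen;
#'   \item cross-parent flank fixity: no other-parent variant inside the
#'     flank (other-parent records inside a candidate's flank disqualify
#'     it), so the flanking sequence is fixed between parents.
#' }
#'
#' @param variants Variant records of the polymorphic parent.
#' @param assembly A [sequence_set()] giving the coordinate frame.
#' @param other_parent_variants Variant records of the second parent mapped
#'   to the same assembly (its non-reference calls mark unfixed flanks).
#' @param cfg A [filter_config()].
#' @return A [probe_set()] of candidates with extra columns `scaffold`,
#'   `position`; attribute `audit` holds the per-stage survivor counts.
#' @export
select_marker_snps <- function(variants, assembly, other_parent_variants,
                               cfg = filter_config()) {
  audit <- c(input = nrow(variants))
  p <- strand_bias_p_vec(variants)
  v <- variants[variants$genotype == "hom_alt" &
                  variants$depth_hq >= cfg$min_depth &
                  variants$alt_frequency >= cfg$min_freq_marker &
                  p > cfg$strand_p, , drop = FALSE]
  audit["quality"] <- nrow(v)

  all_sites <- rbind(variants[, c("scaffold", "position")],
                     other_parent_variants[, c("scaffold", "position")])
  clean_flank <- vapply(seq_len(nrow(v)), function(i) {
    near <- all_sites$scaffold == v$scaffold[i] &
      abs(all_sites$position - v$position[i]) <= cfg$flank &
      all_sites$position != v$position[i]
    !any(near)
  }, logical(1))
  v <- v[clean_flank, , drop = FALSE]
  audit["flank_clean"] <- nrow(v)

  seqs <- unclass(assembly)
  flank_seq <- vapply(seq_len(nrow(v)), function(i) {
    s <- seqs[[v$scaffold[i]]]
    p1 <- v$position[i] + 1L  # 1-based centre
    if (p1 - cfg$flank < 1 || p1 + cfg$flank > nchar(s)) return(NA_character_)
    substr(s, p1 - cfg$flank, p1 + cfg$flank)
  }, character(1))
  uniq <- vapply(seq_along(flank_seq), function(i) {
    fs <- flank_seq[i]
    if (is.na(fs)) return(FALSE)
    hits <- sum(vapply(seqs, function(s) {
      m <- gregexpr(fs, s, fixed = TRUE)[[1]]
      f <- if (m[1] == -1) 0L else length(m)
      m2 <- gregexpr(revcomp(fs), s, fixed = TRUE)[[1]]
      r <- if (m2[1] == -1) 0L else length(m2)
      f + r
    }, integer(1)))
    hits == 1L
  }, logical(1))
  v <- v[uniq, , drop = FALSE]
  flank_seq <- flank_seq[uniq]
  audit["unique_flank"] <- nrow(v)

  fixed <- vapply(seq_len(nrow(v)), function(i) {
    op <- other_parent_variants
    inside <- op$scaffold == v$scaffold[i] &
      abs(op$position - v$position[i]) <= cfg$flank
    !any(inside)
  }, logical(1))
  v <- v[fixed, , drop = FALSE]
  flank_seq <- flank_seq[fixed]
  audit["cross_parent_fixed"] <- nrow(v)

  probes <- data.frame(
    marker = sprintf("%s_%d", v$scaffold, v$position),
    seq = flank_seq, allele_a = substr(flank_seq, cfg$flank + 1, cfg$flank + 1),
    allele_b = v$alt, scaffold = v$scaffold, position = v$position)
  out <- probe_set(probes)
  attr(out, "audit") <- audit
  out
}

#' Thin marker candidates to a minimum spacing
#'
#' Greedy per-scaffold sweep in position order: a candidate is accepted when
#' it lies at least `min_spacing` from the last accepted one; among the
#' eligible candidates the one nearest the ideal even-grid position (the
#' last accepted position plus the spacing) is taken, which under exact
#' sweep order is the earliest eligible candidate. All pairwise gaps in the
#' output satisfy the spacing bound.
#'
#' @param candidates Data frame with columns `scaffold`, `position` (plus
#'   any others, carried through).
#' @param cfg A [filter_config()] (uses `min_spacing`).
#' @param per_scaffold_quota Optional cap on selections per scaffold.
#' @return The selected subset, in scaffold/position order.
#' @export
space_markers <- function(candidates, cfg = filter_config(),
                          per_scaffold_quota = NULL) {
  sel <- list()
  for (sc in unique(candidates$scaffold)) {
    d <- candidates[candidates$scaffold == sc, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    last <- -Inf
    taken <- 0L
    for (i in seq_len(nrow(d))) {
      if (!is.null(per_scaffold_quota) && taken >= per_scaffold_quota) break
      if (d$position[i] - last >= cfg$min_spacing) {
        sel[[length(sel) + 1]] <- d[i, , drop = FALSE]
        last <- d$position[i]
        taken <- taken + 1L
      }
    }
  }
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

#' Length of the homopolymer run touching a position
#'
#' Returns the length of the maximal single-base run touching `position`
#' (0-based). When `base` is given (e.g. the inserted or deleted base of an
#' indel), runs of that base touching the position from either side are
#' measured; otherwise the base at the position is used. A site is
#' homopolymer-associated when the run reaches
#' `filter_config()$homopolymer_min_run` (4, i.e. more than three
#' consecutive nucleotides).
#'
#' @param seq Nucleotide string.
#' @param position 0-based position.
#' @param base Optional base whose run is measured.
#' @return Integer run length.
#' @examples
#' homopolymer_run("ACGGGGT", 3)  # 4
#' @export
homopolymer_run <- function(seq, position, base = NULL) {
  seq <- toupper(seq)
  n <- nchar(seq)
  check_that(position >= 0 && position < n, "position outside sequence")
  p1 <- position + 1L
  ch <- function(i) substr(seq, i, i)
  run_at <- function(i, b) {
    if (i < 1 || i > n || ch(i) != b) return(0L)
    l <- i
    while (l > 1 && ch(l - 1) == b) l <- l - 1
    r <- i
    while (r < n && ch(r + 1) == b) r <- r + 1
    r - l + 1L
  }
  if (is.null(base)) base <- ch(p1)
  base <- toupper(base)
  max(run_at(p1, base), run_at(p1 - 1L, base), run_at(p1 + 1L, base))
}

#' Apply a set of edits to sequences, with coordinate remapping
#'
#' Edits (`scaffold`, `position` 0-based, `ref`, `alt`) are validated
#' against the current sequence content and applied right to left so earlier
#' coordinates stay valid. The returned coordinate map gives, per scaffold,
#' the cumulative offset in effect after each edited position, so downstream
#' positions can be translated with [remap_position()]. The reverse edit set
#' (in new coordinates) is also returned, so that applying it restores the
#' original sequences exactly.
#'
#' @param seqs A [sequence_set()].
#' @param edits Data frame with columns `scaffold`, `position`, `ref`,
#'   `alt`; non-overlapping.
#' @return List with `seqs` (edited [sequence_set()]), `coord_map` (data
#'   frame `scaffold`, `old_pos`, `shift`), and `reverse_edits`.
#' @export
apply_edits <- function(seqs, edits) {
  s <- unclass(seqs)
  if (nrow(edits) == 0)
    return(list(seqs = seqs,
                coord_map = data.frame(scaffold = character(),
                                       old_pos = numeric(), shift = numeric()),
                reverse_edits = edits))
  edits <- edits[order(edits$scaffold, edits$position), , drop = FALSE]
  # overlap check within scaffold
  for (sc in unique(edits$scaffold)) {
    e <- edits[edits$scaffold == sc, , drop = FALSE]
    ends <- e$position + nchar(e$ref)
    if (nrow(e) > 1)
      check_that(all(e$position[-1] >= ends[-length(ends)]),
                 paste0("overlapping edits on ", sc))
  }
  cmap <- list()
  rev_edits <- list()
  for (sc in unique(edits$scaffold)) {
    e <- edits[edits$scaffold == sc, , drop = FALSE]
    x <- s[[sc]]
    shifts <- cumsum(nchar(e$alt) - nchar(e$ref))
    for (i in rev(seq_len(nrow(e)))) {
      p1 <- e$position[i] + 1L
      ref <- e$ref[i]
      have <- substr(x, p1, p1 + nchar(ref) - 1L)
      if (have != toupper(ref))
        stop(sprintf("ref mismatch at %s:%d (have %s, expected %s)",
                     sc, e$position[i], have, ref), call. = FALSE)
      x <- paste0(substr(x, 1L, p1 - 1L), toupper(e$alt[i]),
                  substr(x, p1 + nchar(ref), nchar(x)))
    }
    s[[sc]] <- x
    cmap[[sc]] <- data.frame(scaffold = sc,
                             old_pos = e$position + nchar(e$ref),
                             shift = shifts)
    new_pos <- e$position + c(0, shifts[-length(shifts)])
    rev_edits[[sc]] <- data.frame(scaffold = sc, position = new_pos,
                                  ref = e$alt, alt = e$ref)
  }
  list(seqs = sequence_set(unlist(s), kind = seq_kind(seqs)),
       coord_map = do.call(rbind, c(cmap, list(make.row.names = FALSE))),
       reverse_edits = do.call(rbind, c(rev_edits,
                                        list(make.row.names = FALSE))))
}

#' Translate an old coordinate through an edit coordinate map
#'
#' @param coord_map From [apply_edits()].
#' @param scaffold Scaffold id.
#' @param position 0-based position in the pre-edit sequence (must not lie
#'   inside an edited interval).
#' @return 0-based position in the post-edit sequence.
#' @export
remap_position <- function(coord_map, scaffold, position) {
  m <- coord_map[coord_map$scaffold == scaffold, , drop = FALSE]
  if (nrow(m) == 0) return(position)
  i <- findInterval(position, m$old_pos)
  position + ifelse(i == 0, 0, m$shift[pmax(i, 1)])
}

#' Classify assembly/read discrepancies
#'
#' Substitution when `ref` and `alt` have equal length, insertion when the
#' alternate is longer, deletion otherwise; each indel is additionally
#' flagged homopolymer-associated via [homopolymer_run()] on the
#' inserted/deleted bases.
#'
#' @param edits Edit data frame (`scaffold`, `position`, `ref`, `alt`).
#' @param seqs A [sequence_set()] (coordinate frame of the edits).
#' @param cfg A [filter_config()].
#' @return List of tallies: `substitutions`, `insertions`, `deletions`,
#'   `homopolymer_indels`, plus the per-edit classification data frame.
#' @export
classify_discrepancies <- function(edits, seqs, cfg = filter_config()) {
  s <- unclass(seqs)
  n <- nrow(edits)
  kind <- character(n)
  hp <- logical(n)
  for (i in seq_len(n)) {
    lr <- nchar(edits$ref[i])
    la <- nchar(edits$alt[i])
    kind[i] <- if (la == lr) "substitution" else
      if (la > lr) "insertion" else "deletion"
    if (kind[i] != "substitution") {
      longer <- if (la > lr) edits$alt[i] else edits$ref[i]
      shorter <- if (la > lr) edits$ref[i] else edits$alt[i]
      changed <- substr(longer, nchar(shorter) + 1, nchar(longer))
      b <- substr(changed, 1, 1)
      run <- homopolymer_run(s[[edits$scaffold[i]]], edits$position[i], b)
      hp[i] <- run >= cfg$homopolymer_min_run
    }
  }
  list(substitutions = sum(kind == "substitution"),
       insertions = sum(kind == "insertion"),
       deletions = sum(kind == "deletion"),
       homopolymer_indels = sum(hp),
       detail = cbind(edits, kind = kind, homopolymer = hp))
}
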