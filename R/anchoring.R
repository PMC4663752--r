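#' Create a SNP probe set
#'
#' Each probe is a 121-mer with the SNP base at the centre (60 bp of flank on
#' each side). The stored sequence carries `allele_a` at the centre; the
#' `allele_b` variant is derived by substitution.
#'
#' @param probes Data frame with columns `marker`, `seq` (121-mer),
#'   `allele_a`, `allele_b`.
#' @return Validated `probe_set` data frame.
#' @export
probe_set <- function(probes) {
  need <- c("marker", "seq", "allele_a", "allele_b")
  check_that(all(need %in% names(probes)), "probe columns: marker, seq, allele_a, allele_b")
  probes$seq <- toupper(probes$seq)
  check_that(all(nchar(probes$seq) == 121), "probes must be 121-mers")
  check_that(all(substr(probes$seq, 61, 61) == toupper(probes$allele_a)),
             "probe centre must carry allele_a")
  check_that(all(toupper(probes$allele_a) != toupper(probes$allele_b)),
             "alleles must differ")
  check_that(!anyDuplicated(probes$marker), "marker ids must be unique")
  structure(probes, class = c("probe_set", "data.frame"))
}

#' Read / write probe sets as FASTA with allele annotations
#'
#' Headers have the form `>marker allele_a=G allele_b=T`.
#' @param path File path.
#' @return A [probe_set()]; the writer returns `path` invisibly.
#' @export
read_probes <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  marker <- sub("\\s.*$", "", hdr)
  getf <- function(key) sub(paste0(".*", key, "=([A-Za-z]).*"), "\\1", hdr)
  probe_set(data.frame(marker = marker, seq = as.character(x),
                       allele_a = getf("allele_a"), allele_b = getf("allele_b")))
}

#' @rdname read_probes
#' @param probes A [probe_set()].
#' @export
write_probes <- function(probes, path) {
  x <- Biostrings::DNAStringSet(probes$seq)
  names(x) <- sprintf("%s allele_a=%s allele_b=%s", probes$marker,
                      probes$allele_a, probes$allele_b)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Place SNP probes on scaffolds by exact match
#'
#' Both allele variants of each probe are searched exactly on both strands of
#' every scaffold. `n_hits` counts all occurrences genome-wide; a marker is
#' usable for anchoring only when it has exactly one, exact, hit
#' (`n_hits == 1 & identical`).
#'
#' @param probes A [probe_set()].
#' @param scaffolds A [sequence_set()].
#' @return Data frame with one row per probe: `marker`, `scaffold`,
#'   `position` (0-based offset of the SNP base on the scaffold's forward
#'   strand), `strand`, `n_hits`, `identical`, `usable`. Zero-hit probes are
#'   reported with `n_hits = 0` and `NA` coordinates; multi-hit probes carry
#'   the first hit's coordinates.
#' @export
place_probes <- function(probes, scaffolds) {
  pats <- c(probes$seq,
            vapply(seq_len(nrow(probes)), function(i) {
              s <- probes$seq[i]
              substr(s, 61, 61) <- toupper(probes$allele_b[i])
              s
            }, character(1)))
  idx <- rep(seq_len(nrow(probes)), 2)
  rc_pats <- revcomp(pats)
  pd_f <- Biostrings::PDict(pats)
  pd_r <- Biostrings::PDict(rc_pats)

  hits <- vector("list", 0)
  for (sc in names(scaffolds)) {
    subj <- Biostrings::DNAString(unclass(scaffolds)[[sc]])
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPDict(if (strand == "+") pd_f else pd_r, subj)
      st <- Biostrings::startIndex(m)
      for (k in which(lengths(st) > 0)) {
        for (s1 in st[[k]]) {
          hits[[length(hits) + 1]] <- data.frame(
            probe = idx[k], scaffold = sc,
            position = s1 - 1L + 60L,  # SNP base, 0-based (121-mer centre)
            strand = strand)
        }
      }
    }
  }
  hitdf <- if (length(hits)) do.call(rbind, hits) else
    data.frame(probe = integer(), scaffold = character(),
               position = integer(), strand = character())
  out <- data.frame(marker = probes$marker, scaffold = NA_character_,
                    position = NA_integer_, strand = NA_character_,
                    n_hits = 0L, identical = FALSE)
  for (i in seq_len(nrow(probes))) {
    h <- hitdf[hitdf$probe == i, , drop = FALSE]
    out$n_hits[i] <- nrow(h)
    if (nrow(h) > 0) {
      h <- h[order(h$scaffold, h$position), , drop = FALSE]
      out$scaffold[i] <- h$scaffold[1]
      out$position[i] <- h$position[1]
      out$strand[i] <- h$strand[1]
      out$identical[i] <- TRUE
    }
  }
  out$usable <- out$n_hits == 1L & out$identical
  out
}

# Internal: join usable placements with map rows.
placed_markers <- function(placements, map) {
  u <- placements[placements$usable, , drop = FALSE]
  i <- match(u$marker, map$marker)
  keep <- !is.na(i)
  data.frame(marker = u$marker[keep], scaffold = u$scaffold[keep],
             position = u$position[keep],
             lg = map$lg[i[keep]], cm = map$cm[i[keep]])
}

#' Detect contradictions between assembly and genetic map
#'
#' Per scaffold, two kinds of misassembly evidence are reported, at most one
#' record per scaffold per kind:
#' \itemize{
#'   \item `inter_lg_chimera`: usable markers from more than one linkage
#'     group placed on one scaffold;
#'   \item `order_conflict`: within one linkage group, the cM sequence of
#'     the markers in physical order (after collapsing runs of tied cM) is
#'     neither non-decreasing nor non-increasing.
#' }
#' The headline statistic is the number of contradicted scaffolds.
#'
#' @param placements Output of [place_probes()] (only usable markers are
#'   considered).
#' @param map A genetic map (columns `lg`, `marker`, `cm`).
#' @return Data frame with columns `scaffold`, `kind`, `n_markers`, `detail`
#'   and a list column `evidence` of per-marker data frames.
#' @export
detect_contradictions <- function(placements, map) {
  pm <- placed_markers(placements, map)
  recs <- list()
  for (sc in unique(pm$scaffold)) {
    d <- pm[pm$scaffold == sc, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    lgs <- unique(d$lg)
    if (length(lgs) > 1) {
      recs[[length(recs) + 1]] <- data.frame(
        scaffold = sc, kind = "inter_lg_chimera", n_markers = nrow(d),
        detail = paste(sort(lgs), collapse = ","))
      attr(recs[[length(recs)]], "evidence") <- d
      next
    }
    cm <- d$cm
    # collapse runs of tied cM: ties carry no order information
    cmc <- cm[c(TRUE, diff(cm) != 0)]
    if (length(cmc) >= 3) {
      dif <- diff(cmc)
      if (!all(dif >= 0) && !all(dif <= 0)) {
        recs[[length(recs) + 1]] <- data.frame(
          scaffold = sc, kind = "order_conflict", n_markers = nrow(d),
          detail = sprintf("non-monotone cM over %d informative positions",
                           length(cmc)))
        attr(recs[[length(recs)]], "evidence") <- d
      }
    }
  }
  if (length(recs) == 0)
    return(data.frame(scaffold = character(), kind = character(),
                      n_markers = integer(), detail = character(),
                      evidence = I(list())))
  ev <- lapply(recs, attr, "evidence")
  out <- do.call(rbind, recs)
  out$evidence <- I(ev)
  rownames(out) <- NULL
  out
}

#' Order and orient scaffolds along the genetic map
#'
#' Every scaffold carrying at least one usable marker is assigned to its
#' linkage group and ordered by the median cM of its markers (ties broken by
#' scaffold id). Orientation: when a scaffold has markers at two or more
#' distinct cM values (after rounding to 0.01 cM), the sign of the Kendall
#' rank correlation between physical position and cM decides (+ when
#' positive); otherwise a synteny hint is consulted; otherwise the
#' orientation is `"?"` (unknown; emitted as `+` downstream and flagged).
#'
#' Scaffolds with usable markers from more than one linkage group must be
#' resolved or excluded upstream (see [detect_contradictions()]): they raise
#' an error here.
#'
#' @param placements Output of [place_probes()].
#' @param map Genetic map (columns `lg`, `marker`, `cm`).
#' @param scaffold_lengths Named vector of scaffold lengths (bp), e.g.
#'   `seq_lengths(scaffolds)`.
#' @param synteny_hint Optional data frame (`scaffold`, `orientation`) used
#'   for scaffolds whose own markers cannot orient them.
#' @param bp_per_cm Physical bp per cM used for gap estimation; default
#'   `genome_size / total map length`.
#' @param genome_size Needed when `bp_per_cm` is not given.
#' @return An `anchor_plan`: data frame with columns `lg`, `rank`,
#'   `scaffold`, `orientation` (`+`, `-`, `?`), `median_cm`, `n_markers`,
#'   `gap_after` (bp of N to insert after this scaffold; `NA` for the last of
#'   each LG), with attributes `unanchored` (ids) and `bp_per_cm`.
#' @export
anchor <- function(placements, map, scaffold_lengths, synteny_hint = NULL,
                   bp_per_cm = NULL, genome_size = NULL) {
  pm <- placed_markers(placements, map)
  if (is.null(bp_per_cm)) {
    check_that(!is.null(genome_size),
               "give bp_per_cm or genome_size to derive it")
    total_cm <- sum(vapply(split(map$cm, map$lg), max, numeric(1)))
    bp_per_cm <- genome_size / total_cm
  }
  rows <- list()
  for (sc in unique(pm$scaffold)) {
    d <- pm[pm$scaffold == sc, , drop = FALSE]
    if (length(unique(d$lg)) > 1) stop("unresolved chimera: ", sc, call. = FALSE)
    cm_r <- round(d$cm, 2)  # "tightly linked" = one cM value at 0.01 precision
    ori <- "?"
    if (length(unique(cm_r)) >= 2) {
      tau <- suppressWarnings(cor(d$position, d$cm, method = "kendall"))
      if (!is.na(tau) && tau != 0) ori <- if (tau > 0) "+" else "-"
    }
    if (ori == "?" && !is.null(synteny_hint)) {
      j <- match(sc, synteny_hint$scaffold)
      if (!is.na(j)) ori <- synteny_hint$orientation[j]
    }
    rows[[length(rows) + 1]] <- data.frame(
      lg = d$lg[1], scaffold = sc, orientation = ori,
      median_cm = median(d$cm), n_markers = nrow(d))
  }
  plan <- do.call(rbind, rows)
  plan <- plan[order(plan$lg, plan$median_cm, plan$scaffold), , drop = FALSE]
  plan$rank <- unlist(lapply(split(seq_len(nrow(plan)), plan$lg), seq_along),
                      use.names = FALSE)
  # stable per-LG rank: recompute within groups in row order
  plan$rank <- stats::ave(seq_len(nrow(plan)), plan$lg, FUN = seq_along)
  plan$gap_after <- NA_real_
  for (lg in unique(plan$lg)) {
    i <- which(plan$lg == lg)
    if (length(i) < 2) next
    for (k in seq_len(length(i) - 1)) {
      plan$gap_after[i[k]] <- estimate_gap(
        plan$scaffold[i[k]], plan$orientation[i[k]],
        plan$scaffold[i[k + 1]], plan$orientation[i[k + 1]],
        pm, scaffold_lengths, bp_per_cm)
    }
  }
  plan <- plan[, c("lg", "rank", "scaffold", "orientation", "median_cm",
                   "n_markers", "gap_after")]
  rownames(plan) <- NULL
  structure(plan,
            unanchored = setdiff(names(scaffold_lengths), plan$scaffold),
            bp_per_cm = bp_per_cm,
            class = c("anchor_plan", "data.frame"))
}

#' Estimate the gap between two adjacent anchored scaffolds
#'
#' The gap is derived from the genetic interval between the two markers
#' nearest the junction: `(cM_right - cM_left) * bp_per_cm` minus the
#' physical overhang of each scaffold beyond its junction-side marker. A
#' positive estimate is clamped below at a 100 bp minimum gap; when the
#' markers are tied in cM or the computation is negative or undefined the
#' 1,000 bp sentinel gap is used.
#'
#' @param left,right Scaffold ids.
#' @param left_ori,right_ori Orientations (`+`, `-`, `?`; `?` treated as
#'   `+`).
#' @param pm Placed-marker table (internal format: `marker`, `scaffold`,
#'   `position`, `lg`, `cm`).
#' @param scaffold_lengths Named length vector.
#' @param bp_per_cm Physical bp per cM.
#' @return Gap size in bases.
#' @export
estimate_gap <- function(left, left_ori, right, right_ori, pm,
                         scaffold_lengths, bp_per_cm) {
  sentinel <- 1000
  oriented_pos <- function(sc, ori) {
    d <- pm[pm$scaffold == sc, , drop = FALSE]
    len <- scaffold_lengths[[sc]]
    pos <- if (identical(ori, "-")) len - 1 - d$position else d$position
    data.frame(pos = pos, cm = d$cm, len = len)
  }
  dl <- oriented_pos(left, left_ori)
  dr <- oriented_pos(right, right_ori)
  if (nrow(dl) == 0 || nrow(dr) == 0) return(sentinel)
  # marker nearest the junction: right end of left scaffold, left end of right
  il <- which.max(dl$pos)
  ir <- which.min(dr$pos)
  interval_cm <- dr$cm[ir] - dl$cm[il]
  if (is.na(interval_cm) || interval_cm <= 0) return(sentinel)
  overhang_l <- dl$len[1] - 1 - dl$pos[il]
  overhang_r <- dr$pos[ir]
  gap <- interval_cm * bp_per_cm - overhang_l - overhang_r
  if (is.na(gap) || gap < 0) return(sentinel)
  max(round(gap), 100)
}

#' Build pseudomolecule sequences and an AGP from an anchor plan
#'
#' Oriented scaffold sequences are concatenated with runs of N of the
#' estimated gap sizes; AGP v2.0 rows are emitted (`W` component rows with
#' 1-based inclusive coordinates; `N` gap rows). Unanchored scaffolds are
#' passed through unchanged as single-component objects.
#'
#' @param plan An [anchor()] plan.
#' @param scaffolds A [sequence_set()].
#' @param object_prefix Prefix for pseudomolecule names (default `""`: the
#'   LG label itself).
#' @return List with `pseudomolecules` (a [sequence_set()]) and `agp` (data
#'   frame in AGP column order). The AGP/FASTA length consistency is
#'   asserted on every build.
#' @export
build_pseudomolecules <- function(plan, scaffolds, object_prefix = "") {
  seqs <- unclass(scaffolds)
  agp <- list()
  out <- character(0)
  add_agp <- function(...) agp[[length(agp) + 1]] <<- data.frame(...)

  for (lg in unique(plan$lg)) {
    rows <- plan[plan$lg == lg, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    obj <- paste0(object_prefix, lg)
    parts <- character(0)
    pos <- 0L
    part_no <- 0L
    for (k in seq_len(nrow(rows))) {
      sc <- rows$scaffold[k]
      ori <- rows$orientation[k]
      s <- seqs[[sc]]
      emit_ori <- if (ori == "-") "-" else "+"
      if (ori == "-") s <- revcomp(s)
      part_no <- part_no + 1L
      add_agp(object = obj, object_beg = pos + 1L, object_end = pos + nchar(s),
              part_number = part_no, component_type = "W",
              component_id = sc, component_beg = 1L,
              component_end = nchar(s), orientation = emit_ori)
      parts <- c(parts, s)
      pos <- pos + nchar(s)
      g <- rows$gap_after[k]
      if (k < nrow(rows) && !is.na(g) && g > 0) {
        part_no <- part_no + 1L
        add_agp(object = obj, object_beg = pos + 1L, object_end = pos + g,
                part_number = part_no, component_type = "N",
                component_id = as.character(g), component_beg = "scaffold",
                component_end = "yes", orientation = "map")
        parts <- c(parts, strrep("N", g))
        pos <- pos + g
      }
    }
    out[[obj]] <- paste(parts, collapse = "")
  }
  for (sc in attr(plan, "unanchored")) {
    s <- seqs[[sc]]
    add_agp(object = sc, object_beg = 1L, object_end = nchar(s),
            part_number = 1L, component_type = "W", component_id = sc,
            component_beg = 1L, component_end = nchar(s), orientation = "+")
    out[[sc]] <- s
  }
  agp <- do.call(rbind, agp)
  names(agp) <- c("object", "object_beg", "object_end", "part_number",
                  "component_type", "component_id", "component_beg",
                  "component_end", "orientation")
  ps <- sequence_set(out, kind = "pseudomolecule")
  # AGP consistency assertion
  for (obj in names(out)) {
    a <- agp[agp$object == obj, , drop = FALSE]
    stopifnot(a$object_end[nrow(a)] == nchar(out[[obj]]))
  }
  list(pseudomolecules = ps, agp = agp)
}

#' Write / read AGP v2.0
#'
#' @param agp AGP data frame as produced by [build_pseudomolecules()].
#' @param path File path.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  writeLines("##agp-version\t2.0", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  colClasses = c("character", "integer", "integer", "integer",
                                 "character", "character", "character",
                                 "character", "character"))
  names(d) <- c("object", "object_beg", "object_end", "part_number",
                "component_type", "component_id", "component_beg",
                "component_end", "orientation")
  d
}

#' Rebuild object FASTA from an AGP and its component sequences
#'
#' @param agp AGP data frame.
#' @param components A [sequence_set()] holding every `W` component.
#' @return A [sequence_set()] of the reconstructed objects.
#' @export
agp_to_fasta <- function(agp, components) {
  seqs <- unclass(components)
  out <- character(0)
  for (obj in unique(agp$object)) {
    a <- agp[agp$object == obj, , drop = FALSE]
    a <- a[order(a$part_number), , drop = FALSE]
    parts <- vapply(seq_len(nrow(a)), function(i) {
      if (a$component_type[i] %in% c("N", "U")) {
        strrep("N", as.integer(a$component_id[i]))
      } else {
        s <- substr(seqs[[a$component_id[i]]],
                    as.integer(a$component_beg[i]),
                    as.integer(a$component_end[i]))
        if (a$orientation[i] == "-") revcomp(s) else s
      }
    }, character(1))
    out[[obj]] <- paste(parts, collapse = "")
  }
  sequence_set(out, kind = "pseudomolecule")
}

#' Relabel linkage groups from a reference marker table
#'
#' Each LG is renamed to the majority chromosome label among its markers in
#' the reference table (ties broken by the lexicographically smaller label).
#' LGs with no overlapping markers keep their provisional name with a
#' warning.
#'
#' @param plan An [anchor()] plan (or any data frame with an `lg` column).
#' @param map Genetic map providing the LG membership of each marker.
#' @param reference Data frame with columns `marker`, `chromosome`.
#' @return The plan with relabelled `lg`, plus attribute `lg_relabels`
#'   (named character vector old -> new).
#' @export
relabel_groups <- function(plan, map, reference) {
  check_that(nrow(reference) > 0, "reference table is empty")
  relab <- character(0)
  for (lg in unique(map$lg)) {
    mk <- map$marker[map$lg == lg]
    lab <- reference$chromosome[match(mk, reference$marker)]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) {
      warning("LG ", lg, " shares no markers with the reference; name kept")
      relab[lg] <- lg
    } else {
      t <- table(lab)
      best <- sort(names(t)[t == max(t)])[1]
      relab[lg] <- best
    }
  }
  plan$lg <- unname(relab[plan$lg])
  attr(plan, "lg_relabels") <- relab
  plan
}
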