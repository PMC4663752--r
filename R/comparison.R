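#' Gene-family size deltas between assemblies
#'
#' For each gene family and each non-reference assembly, the delta is the
#' family size in that assembly minus the size in the reference assembly.
#' Increased and reduced families are aggregated separately, together with
#' the gene totals gained and lost and the per-assembly singleton count (a
#' singleton is a gene whose family has size 1 and has members in exactly
#' one assembly).
#'
#' @param table Data frame with columns `gene`, `family`, `assembly`.
#' @param reference Reference assembly id.
#' @return Data frame with one row per assembly (including the reference,
#'   whose deltas are 0): `assembly`, `n_increased_families`,
#'   `n_reduced_families`, `genes_gained`, `genes_lost`, `n_singletons`.
#' @export
family_deltas <- function(table, reference) {
  check_that(all(c("gene", "family", "assembly") %in% names(table)),
             "columns gene, family, assembly required")
  check_that(reference %in% table$assembly, "reference assembly not in table")
  sizes <- as.data.frame(base::table(family = table$family,
                                     assembly = table$assembly),
                         responseName = "size")
  wide <- stats::reshape(sizes, idvar = "family", timevar = "assembly",
                         direction = "wide")
  names(wide) <- sub("^size\\.", "", names(wide))
  assemblies <- setdiff(names(wide), "family")
  # singleton: family of global size 1 (so one gene, one assembly)
  fam_tot <- rowSums(wide[, assemblies, drop = FALSE])
  single_fam <- wide$family[fam_tot == 1]
  singletons <- table[table$family %in% single_fam, , drop = FALSE]
  out <- lapply(assemblies, function(a) {
    delta <- wide[[a]] - wide[[reference]]
    data.frame(assembly = a,
               n_increased_families = sum(delta > 0),
               n_reduced_families = sum(delta < 0),
               genes_gained = sum(delta[delta > 0]),
               genes_lost = -sum(delta[delta < 0]),
               n_singletons = sum(singletons$assembly == a))
  })
  out <- do.call(rbind, out)
  out[order(out$assembly != reference, out$assembly), , drop = FALSE]
}

#' Fraction of core eukaryotic genes present
#'
#' @param present Number of CEGs found.
#' @param total Size of the CEG set (458 in the standard set).
#' @return Percentage, rounded half-up to 1 decimal.
#' @examples
#' ceg_fraction(446)  # 97.4
#' @export
ceg_fraction <- function(present, total = 458L) {
  check_that(present >= 0 && present <= total, "present must be in [0, total]")
  round_half_up(100 * present / total, 1)
}

#' Recombination-landscape tracks (cM/Mb and cM/gene)
#'
#' Tiles each linkage group's pseudomolecule into fixed windows and computes
#' the genetic span of each window by linear interpolation of cM between
#' flanking markers, the recombination rate `cm_per_mb`, and the
#' recombination per gene `cm_per_gene` (NA when a window has no genes).
#' Windows outside the marker span get `NA` tracks.
#'
#' @param map Genetic map (columns `lg`, `marker`, `cm`).
#' @param marker_positions Data frame `marker`, `lg`, `position` (bp on the
#'   pseudomolecule, 0-based).
#' @param genes Data frame `lg`, `start`, `end` (bp intervals of genes on
#'   the pseudomolecules).
#' @param lg_lengths Named vector of pseudomolecule lengths (bp).
#' @param window Window size in bp (default 1 Mb).
#' @return Data frame `lg`, `start`, `end`, `cm_span`, `gene_count`,
#'   `cm_per_mb`, `cm_per_gene`.
#' @export
recomb_tracks <- function(map, marker_positions, genes, lg_lengths,
                          window = 1000000L) {
  rows <- list()
  for (lg in names(lg_lengths)) {
    mk <- merge(marker_positions[marker_positions$lg == lg, , drop = FALSE],
                map[map$lg == lg, c("marker", "cm")], by = "marker")
    mk <- mk[order(mk$position), , drop = FALSE]
    len <- lg_lengths[[lg]]
    starts <- seq(0L, max(0L, len - 1L), by = window)
    cm_at <- function(bp) {
      if (nrow(mk) < 2) return(NA_real_)
      stats::approx(mk$position, mk$cm, xout = bp, rule = 1, ties = "ordered")$y
    }
    for (st in starts) {
      en <- min(st + window, len)
      c0 <- cm_at(st)
      c1 <- cm_at(en)
      span <- if (is.na(c0) || is.na(c1)) NA_real_ else c1 - c0
      gc <- if (nrow(genes)) sum(genes$lg == lg & genes$start < en &
                                   genes$end > st) else 0L
      rows[[length(rows) + 1]] <- data.frame(
        lg = lg, start = st, end = en, cm_span = span,
        gene_count = gc,
        cm_per_mb = span / ((en - st) / 1e6),
        cm_per_gene = if (gc > 0) span / gc else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mapping population size needed for a given cM/gene resolution
#'
#' One informative recombinant per gene interval among the 2n gametes of a
#' population of n plants requires `n = 100 / d` plants at a gene interval
#' of `d` cM.
#'
#' @param cm_per_gene Genetic interval per gene, in cM (positive).
#' @return Number of plants.
#' @examples
#' population_size_for(0.05)  # 2000
#' population_size_for(0.01)  # 10000
#' @export
population_size_for <- function(cm_per_gene) {
  check_that(all(cm_per_gene > 0), "cm_per_gene must be positive")
  100 / cm_per_gene
}

#' Read / write gene-family membership TSV (gene, family, assembly)
#' @param path File path.
#' @return Data frame; the writer returns `path` invisibly.
#' @export
read_family_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", colClasses = "character")
}

#' @rdname read_family_table
#' @param table Family table data frame.
#' @export
write_family_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
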