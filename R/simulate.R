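#' Configuration for the synthetic cross simulator
#'
#' The simulator emulates the study design of a map-guided legume assembly
#' project at a physically compressed scale: a diploid genome of a few
#' linkage groups with interspersed repeats and telomeric termini, SNP
#' markers planted at controlled spacing with unique flanks, an F2 cross
#' with Haldane (no-interference) crossovers plus genotyping error and
#' missing data, and a fragmented scaffold set carrying planted inter-LG
#' chimeras and within-scaffold inversions.
#'
#' Physical sizes are compressed (1 Mb linkage groups) but the genetic scale
#' is kept realistic: with the default `cm_per_mb = 50`, each 1 Mb group
#' spans ~50 cM, comparable to a real bean chromosome, and markers planted
#' every 100 kb are ~5 cM apart — resolvable separations for an F2 of a few
#' hundred plants.
#'
#' @param seed Integer seed; every generator is a deterministic function of
#'   the configuration including this seed.
#' @param n_lgs Number of linkage groups.
#' @param lg_size Linkage-group size (bp); scalar or vector of `n_lgs`.
#' @param repeat_fraction Fraction of each LG occupied by interspersed
#'   repeat copies from a small shared library (lengths 200-5,000 bp).
#' @param marker_spacing Target distance between planted markers (bp).
#' @param n_individuals F2 population size.
#' @param genotyping_error Probability a call is replaced by a random other
#'   code.
#' @param missing_rate Probability a call is missing.
#' @param n_scaffolds Number of scaffold pieces the genome is cut into.
#' @param chimera_rate Probability a scaffold piece is joined to a piece
#'   from a different LG.
#' @param inversion_rate Probability a scaffold receives an internal
#'   inversion spanning at least two distinct-cM markers.
#' @param cm_per_mb Genetic-to-physical rate (cM per Mb).
#' @param telomere_copies Telomere motif copies planted at each terminus.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_lgs = 2L, lg_size = 1000000L,
                       repeat_fraction = 0.15, marker_spacing = 100000L,
                       n_individuals = 500L, genotyping_error = 0.005,
                       missing_rate = 0.03, n_scaffolds = 24L,
                       chimera_rate = 0.0, inversion_rate = 0.0,
                       cm_per_mb = 50, telomere_copies = 30L) {
  cfg <- list(seed = as.integer(seed), n_lgs = n_lgs,
              lg_size = rep_len(lg_size, n_lgs),
              repeat_fraction = repeat_fraction,
              marker_spacing = marker_spacing,
              n_individuals = n_individuals,
              genotyping_error = genotyping_error,
              missing_rate = missing_rate, n_scaffolds = n_scaffolds,
              chimera_rate = chimera_rate, inversion_rate = inversion_rate,
              cm_per_mb = cm_per_mb, telomere_copies = telomere_copies)
  rates <- c(cfg$repeat_fraction, cfg$genotyping_error, cfg$missing_rate,
             cfg$chimera_rate, cfg$inversion_rate)
  check_that(all(rates >= 0 & rates <= 1), "rates must be in [0, 1]")
  check_that(all(cfg$lg_size > 0), "sizes must be positive")
  check_that(all(cfg$marker_spacing <= cfg$lg_size),
             "marker spacing exceeds LG size")
  structure(cfg, class = "sim_config")
}

# Internal: random DNA string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the founder genome with planted markers
#'
#' Builds each linkage group as random sequence with interspersed repeat
#' copies, telomere arrays at both termini (`TTTAGGG` on the right,
#' `CCCTAAA` on the left), and SNP markers every `marker_spacing` bp whose
#' 121-mer contexts are unique genome-wide (positions falling in repeats
#' are nudged until unique). Marker cM positions follow the linear
#' genetic-to-physical rate.
#'
#' @param cfg A [sim_config()].
#' @return A `truth_set` list: `genome` (a [sequence_set()]), `markers`
#'   (data frame `marker`, `lg`, `position`, `cm`, `allele_a`, `allele_b`),
#'   `probes` (a [probe_set()]), `cfg`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  motif <- "TTTAGGG"
  tel_r <- strrep(motif, cfg$telomere_copies)
  tel_l <- strrep(revcomp(motif), cfg$telomere_copies)
  # shared repeat library
  rep_lens <- c(200, 500, 1200, 2500, 5000)
  rep_lib <- vapply(rep_lens, random_dna, character(1))
  genome <- character(0)
  for (i in seq_len(cfg$n_lgs)) {
    size <- cfg$lg_size[i]
    target_rep <- round(cfg$repeat_fraction * size)
    parts <- character(0)
    rep_bp <- 0
    built <- 0
    while (built < size) {
      if (rep_bp < target_rep && stats::runif(1) < 0.5) {
        r <- sample(rep_lib, 1)
        parts <- c(parts, r)
        rep_bp <- rep_bp + nchar(r)
        built <- built + nchar(r)
      } else {
        chunk <- min(20000L, size - built)
        parts <- c(parts, random_dna(chunk))
        built <- built + chunk
      }
    }
    s <- substr(paste(parts, collapse = ""), 1, size)
    substr(s, 1, nchar(tel_l)) <- tel_l
    substr(s, size - nchar(tel_r) + 1, size) <- tel_r
    genome[[paste0("LG", i)]] <- s
  }
  gs <- sequence_set(genome, kind = "pseudomolecule")

  # plant markers with unique 121-mer contexts
  flank <- 60L
  markers <- list()
  occurs_once <- function(pat) {
    tot <- sum(vapply(genome, function(s) {
      m <- gregexpr(pat, s, fixed = TRUE)[[1]]
      a <- if (m[1] == -1) 0L else length(m)
      m2 <- gregexpr(revcomp(pat), s, fixed = TRUE)[[1]]
      b <- if (m2[1] == -1) 0L else length(m2)
      a + b
    }, integer(1)))
    tot == 1L
  }
  for (i in seq_len(cfg$n_lgs)) {
    lg <- paste0("LG", i)
    size <- cfg$lg_size[i]
    pos0 <- seq(cfg$marker_spacing %/% 2, size - flank - 1,
                by = cfg$marker_spacing)
    k <- 0L
    for (p in pos0) {
      # nudge out of repeats until the 121-mer context is unique
      p_try <- p
      ok <- FALSE
      for (shift in seq(0, 5000, by = 97)) {
        p_try <- p + shift
        if (p_try - flank < 0 || p_try + flank >= size) break
        ctx <- substr(genome[[lg]], p_try - flank + 1, p_try + flank + 1)
        if (occurs_once(ctx)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next
      k <- k + 1L
      a <- substr(genome[[lg]], p_try + 1, p_try + 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), a), 1)
      markers[[length(markers) + 1]] <- data.frame(
        marker = sprintf("%s_M%02d", lg, k), lg = lg, position = p_try,
        cm = p_try * cfg$cm_per_mb / 1e6, allele_a = a, allele_b = b)
    }
  }
  markers <- do.call(rbind, markers)
  probes <- probe_set(data.frame(
    marker = markers$marker,
    seq = vapply(seq_len(nrow(markers)), function(i) {
      substr(genome[[markers$lg[i]]], markers$position[i] - flank + 1,
             markers$position[i] + flank + 1)
    }, character(1)),
    allele_a = markers$allele_a, allele_b = markers$allele_b))
  structure(list(genome = gs, markers = markers, probes = probes, cfg = cfg),
            class = "truth_set")
}

#' Genetic map of the planted markers (the truth map)
#' @param truth A [simulate_genome()] truth set (or any object with a
#'   `markers` table).
#' @return Genetic map data frame (`lg`, `marker`, `cm`), cM restarting at 0
#'   per LG.
#' @export
truth_map <- function(truth) {
  m <- truth$markers
  m <- m[order(m$lg, m$cm), , drop = FALSE]
  cm0 <- stats::ave(m$cm, m$lg, FUN = function(x) x - min(x))
  structure(data.frame(lg = m$lg, marker = m$marker, cm = cm0),
            class = c("genetic_map", "data.frame"))
}

#' Simulate an F2 genotype matrix from the planted markers
#'
#' Each gamete per linkage group receives a Poisson number of crossovers
#' (mean = map length in Morgans; the Haldane no-interference model) at
#' uniform cM positions; the F2 genotype is the sum of two independent
#' gametes. Genotyping errors replace a call with a random different code;
#' missing data are planted as NA.
#'
#' @param truth A [simulate_genome()] truth set, or a data frame of marker
#'   truth with columns `marker`, `lg`, `cm`.
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] (`F2_###` individuals x markers).
#' @export
simulate_f2 <- function(truth, cfg) {
  set.seed(cfg$seed + 1L)
  mk <- if (is.data.frame(truth)) truth else truth$markers
  n <- cfg$n_individuals
  calls <- matrix(NA_character_, n, nrow(mk),
                  dimnames = list(sprintf("F2_%03d", seq_len(n)), mk$marker))
  for (lg in unique(mk$lg)) {
    sel <- which(mk$lg == lg)
    cm <- mk$cm[sel]
    cm <- cm - min(cm)
    span <- max(cm)
    gamete <- function() {
      nx <- stats::rpois(1, span / 100)
      xo <- sort(stats::runif(nx, 0, span))
      start <- sample(0:1, 1)
      if (nx == 0) return(rep(start, length(cm)))
      (start + vapply(cm, function(x) sum(xo <= x), numeric(1))) %% 2
    }
    for (ind in seq_len(n)) {
      dose <- gamete() + gamete()
      calls[ind, sel] <- c("AA", "AB", "BB")[dose + 1]
    }
  }
  err <- matrix(stats::runif(length(calls)) < cfg$genotyping_error,
                nrow(calls), ncol(calls))
  if (any(err)) {
    idx <- which(err)
    calls[idx] <- vapply(calls[idx], function(x)
      sample(setdiff(c("AA", "AB", "BB"), x), 1), character(1))
  }
  miss <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                 nrow(calls), ncol(calls))
  calls[miss] <- NA
  genotype_matrix(calls)
}

#' Fragment the genome into scaffolds with planted defects
#'
#' Cuts each linkage group at random points into `n_scaffolds` pieces
#' (allocated proportionally to LG length), then plants defects:
#' with probability `chimera_rate` a piece is joined to a marker-bearing
#' piece from a different LG (an inter-LG chimera), and with probability
#' `inversion_rate` a scaffold receives an internal reverse-complemented
#' segment spanning at least two distinct-cM markers while leaving at least
#' one marker outside the segment (so the defect is detectable in
#' principle). Each realized defect is logged exactly once. Finally each
#' scaffold is emitted on a random strand.
#'
#' @param truth A [simulate_genome()] truth set.
#' @param cfg A [sim_config()].
#' @return List with `scaffolds` (a [sequence_set()]), `defects` (data
#'   frame `scaffold`, `kind`), and `scaffold_truth` (data frame `scaffold`,
#'   `lg`, `start`, `end`, `strand` for defect-free scaffolds; coordinates
#'   are 0-based half-open in the source LG).
#' @export
fragment_assembly <- function(truth, cfg) {
  set.seed(cfg$seed + 2L)
  genome <- unclass(truth$genome)
  mk <- truth$markers
  sizes <- vapply(genome, nchar, numeric(1))
  n_pieces <- setNames(pmax(1, round(cfg$n_scaffolds * sizes / sum(sizes))),
                       names(sizes))
  pieces <- list()
  for (lg in names(genome)) {
    np <- n_pieces[[lg]]
    len <- sizes[[lg]]
    cand <- seq(20000L, len - 20000L)
    # keep cuts clear of marker flanks so planted probes stay placeable
    near_mk <- mk$position[mk$lg == lg]
    ok <- rep(TRUE, length(cand))
    for (pm in near_mk) ok[abs(cand - pm) <= 200L] <- FALSE
    cuts <- sort(sample(cand[ok], np - 1))
    bounds <- c(0L, cuts, len)
    for (j in seq_len(np)) {
      st <- bounds[j]
      en <- bounds[j + 1]
      pieces[[length(pieces) + 1]] <- list(
        lg = lg, start = st, end = en,
        seq = substr(genome[[lg]], st + 1, en),
        markers = mk$marker[mk$lg == lg & mk$position >= st &
                              mk$position < en])
    }
  }
  has_mk <- vapply(pieces, function(p) length(p$markers) > 0, logical(1))
  defects <- list()
  scaffolds <- character(0)
  struth <- list()
  used <- rep(FALSE, length(pieces))
  sc_id <- 0L
  for (i in seq_along(pieces)) {
    if (used[i]) next
    used[i] <- TRUE
    p <- pieces[[i]]
    sc_id <- sc_id + 1L
    id <- sprintf("scf%03d", sc_id)
    seqs <- p$seq
    kind <- NA_character_
    # inter-LG chimera: join a marker-bearing partner from another LG
    if (stats::runif(1) < cfg$chimera_rate && has_mk[i]) {
      partners <- which(!used & has_mk &
                          vapply(pieces, function(q) q$lg, character(1)) != p$lg)
      if (length(partners) > 0) {
        j <- if (length(partners) == 1) partners else sample(partners, 1)
        used[j] <- TRUE
        seqs <- paste0(seqs, pieces[[j]]$seq)
        kind <- "inter_lg_chimera"
      }
    }
    # internal inversion spanning >= 2 distinct-cM markers, >= 1 outside
    if (is.na(kind) && stats::runif(1) < cfg$inversion_rate &&
        length(p$markers) >= 3) {
      pos <- mk$position[match(p$markers, mk$marker)] - p$start
      cms <- mk$cm[match(p$markers, mk$marker)]
      ord <- order(pos)
      pos <- pos[ord]
      cms <- cms[ord]
      nm <- length(pos)
      # segment covering markers 2..(nm-1), keeping the first outside
      lo <- pos[2] - min(1000L, pos[2] - pos[1] - 1L)
      hi <- pos[nm - 1] + min(1000L, pos[nm] - pos[nm - 1] - 1L)
      if (length(unique(cms[2:(nm - 1)])) >= 2 && lo > 0 &&
          hi < nchar(seqs)) {
        seg <- substr(seqs, lo + 1, hi + 1)
        seqs <- paste0(substr(seqs, 1, lo), revcomp(seg),
                       substr(seqs, hi + 2, nchar(seqs)))
        kind <- "inversion"
      }
    }
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") seqs <- revcomp(seqs)
    scaffolds[[id]] <- seqs
    if (!is.na(kind)) {
      defects[[length(defects) + 1]] <- data.frame(scaffold = id, kind = kind)
    } else {
      struth[[length(struth) + 1]] <- data.frame(
        scaffold = id, lg = p$lg, start = p$start, end = p$end,
        strand = strand)
    }
  }
  list(scaffolds = sequence_set(scaffolds, kind = "scaffold"),
       defects = if (length(defects)) do.call(rbind, defects) else
         data.frame(scaffold = character(), kind = character()),
       scaffold_truth = if (length(struth)) do.call(rbind, struth) else
         data.frame(scaffold = character(), lg = character(),
                    start = integer(), end = integer(), strand = character()))
}

#' Simulate two-parent variant tables with planted filter decoys
#'
#' Plants `n_valid` marker-grade SNPs (homozygous alternate, deep, clean
#' flanks, balanced strands) on the truth genome, plus labelled decoy
#' classes violating one filter dimension each: `low_depth` (9 reads),
#' `low_freq` (0.5), `strand_bias` (all alternate reads on one strand),
#' `flank_near` (a second variant 40 bp away), `non_unique_flank` (inside a
#' repeat copy), `het` (heterozygous call), `cross_parent` (an other-parent
#' variant inside the flank).
#'
#' @param truth A [simulate_genome()] truth set.
#' @param cfg A [sim_config()].
#' @param n_valid Number of planted valid sites.
#' @param n_decoy Number of sites per decoy class.
#' @return List with `parent1` and `parent2` variant data frames (see
#'   [read_variants()]) and `labels` (data frame `scaffold`, `position`,
#'   `label`).
#' @export
simulate_variants <- function(truth, cfg, n_valid = 20L, n_decoy = 6L) {
  set.seed(cfg$seed + 3L)
  genome <- unclass(truth$genome)
  flank <- 60L
  base_at <- function(lg, p) substr(genome[[lg]], p + 1, p + 1)
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  # candidate positions: clear of planted markers and of each other
  taken <- truth$markers[, c("lg", "position")]
  pick_pos <- function(lg, need_unique_flank = TRUE) {
    len <- nchar(genome[[lg]])
    for (t in 1:200) {
      p <- sample(seq(flank + 1, len - flank - 2), 1)
      if (any(taken$lg == lg & abs(taken$position - p) <= 2 * flank + 1)) next
      ctx <- substr(genome[[lg]], p - flank + 1, p + flank + 1)
      if (grepl("N", ctx, fixed = TRUE)) next
      n_occ <- sum(vapply(genome, function(s) {
        m <- gregexpr(ctx, s, fixed = TRUE)[[1]]
        a <- if (m[1] == -1) 0L else length(m)
        m2 <- gregexpr(revcomp(ctx), s, fixed = TRUE)[[1]]
        a + if (m2[1] == -1) 0L else length(m2)
      }, integer(1)))
      if (need_unique_flank != (n_occ == 1L)) next
      taken <<- rbind(taken, data.frame(lg = lg, position = p))
      return(p)
    }
    stop("could not place a variant site")
  }
  rec <- function(lg, p, depth = 30L, freq = 0.97, biased = FALSE,
                  genotype = "hom_alt") {
    alt_n <- round(depth * freq)
    ref_n <- depth - alt_n
    if (biased) {
      alt_f <- alt_n; alt_r <- 0L; ref_f <- 0L; ref_r <- ref_n + 10L
    } else {
      alt_f <- alt_n %/% 2; alt_r <- alt_n - alt_f
      ref_f <- ref_n %/% 2; ref_r <- ref_n - ref_f
    }
    a <- base_at(lg, p)
    data.frame(scaffold = lg, position = p, ref = a, alt = other_base(a),
               depth_hq = depth, alt_frequency = freq, ref_fwd = ref_f,
               ref_rev = ref_r, alt_fwd = alt_f, alt_rev = alt_r,
               genotype = genotype)
  }
  p1 <- list()
  p2 <- list()
  labels <- list()
  add <- function(v, label) {
    p1[[length(p1) + 1]] <<- v
    labels[[length(labels) + 1]] <<- data.frame(
      scaffold = v$scaffold[1], position = v$position[1], label = label)
  }
  lgs <- names(genome)
  for (i in seq_len(n_valid)) {
    lg <- sample(lgs, 1)
    add(rec(lg, pick_pos(lg)), "valid")
  }
  for (i in seq_len(n_decoy)) {
    lg <- sample(lgs, 1)
    add(rec(lg, pick_pos(lg), depth = 9L), "low_depth")
    lg <- sample(lgs, 1)
    add(rec(lg, pick_pos(lg), freq = 0.5, genotype = "het"), "low_freq")
    lg <- sample(lgs, 1)
    add(rec(lg, pick_pos(lg), biased = TRUE), "strand_bias")
    # flank contamination: second parent-1 variant 40 bp away
    lg <- sample(lgs, 1)
    p <- pick_pos(lg)
    v <- rec(lg, p)
    add(v, "flank_near")
    p1[[length(p1) + 1]] <- rec(lg, p + 40L)
    labels[[length(labels) + 1]] <- data.frame(scaffold = lg,
                                               position = p + 40L,
                                               label = "flank_near")
    # non-unique flank: inside a repeat copy
    lg <- sample(lgs, 1)
    pr <- tryCatch(pick_pos(lg, need_unique_flank = FALSE),
                   error = function(e) NULL)
    if (!is.null(pr)) add(rec(lg, pr), "non_unique_flank")
    # cross-parent contamination
    lg <- sample(lgs, 1)
    p <- pick_pos(lg)
    add(rec(lg, p), "cross_parent")
    p2[[length(p2) + 1]] <- rec(lg, p + 25L)
  }
  list(parent1 = do.call(rbind, p1),
       parent2 = if (length(p2)) do.call(rbind, p2) else
         read_variants_empty(),
       labels = do.call(rbind, labels))
}

# Internal: empty variant frame with the right columns.
read_variants_empty <- function() {
  data.frame(scaffold = character(), position = integer(), ref = character(),
             alt = character(), depth_hq = integer(),
             alt_frequency = numeric(), ref_fwd = integer(),
             ref_rev = integer(), alt_fwd = integer(), alt_rev = integer(),
             genotype = character())
}

#' Simulate a k-mer multiplicity histogram from a known genome size
#'
#' Distinct k-mers (approximately one per genome position) receive Poisson
#' multiplicities at the given mean depth; an error peak of singleton
#' k-mers is added at multiplicity 1.
#'
#' @param genome_size True genome size (bp).
#' @param depth Mean k-mer depth.
#' @param error_kmers Number of error k-mers added at multiplicity 1.
#' @param seed Seed.
#' @return Histogram data frame (`multiplicity`, `count`).
#' @export
simulate_kmer_histogram <- function(genome_size, depth = 30,
                                    error_kmers = round(genome_size / 2),
                                    seed = 1L) {
  set.seed(seed)
  mult <- stats::rpois(genome_size, depth)
  tab <- table(mult[mult > 0])
  h <- data.frame(multiplicity = as.integer(names(tab)),
                  count = as.integer(tab))
  if (error_kmers > 0) {
    i <- match(1L, h$multiplicity)
    if (is.na(i)) {
      h <- rbind(data.frame(multiplicity = 1L, count = error_kmers), h)
    } else {
      h$count[i] <- h$count[i] + error_kmers
    }
  }
  h[order(h$multiplicity), , drop = FALSE]
}

#' Write every synthetic input to a directory
#'
#' Emits the genome FASTA, scaffold FASTA, truth map TSV, genotype TSV,
#' probe FASTA, the two parents' variant TSVs and the truth tables
#' (markers, defects, scaffold sources) as TSVs.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_all <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_genome(cfg)
  g <- simulate_f2(truth, cfg)
  frag <- fragment_assembly(truth, cfg)
  vars <- simulate_variants(truth, cfg)
  write_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_fasta(frag$scaffolds, file.path(dir, "scaffolds.fa"))
  write_genetic_map(truth_map(truth), file.path(dir, "map.tsv"))
  write_genotypes(g, file.path(dir, "genotypes.tsv"))
  write_probes(truth$probes, file.path(dir, "probes.fa"))
  write_variants(vars$parent1, file.path(dir, "variants_parent1.tsv"))
  write_variants(vars$parent2, file.path(dir, "variants_parent2.tsv"))
  write.table(truth$markers, file.path(dir, "truth_markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(frag$defects, file.path(dir, "truth_defects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(frag$scaffold_truth, file.path(dir, "truth_scaffolds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(truth = truth, genotypes = g, fragments = frag,
                 variants = vars))
}
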