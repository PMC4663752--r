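make_variant <- function(scaffold = "s1", position = 500L, ref = "A",
                         alt = "G", depth_hq = 30L, alt_frequency = 0.95,
                         ref_fwd = 1L, ref_rev = 1L, alt_fwd = 14L,
                         alt_rev = 14L, genotype = "hom_alt") {
  data.frame(scaffold = scaffold, position = position, ref = ref, alt = alt,
             depth_hq = depth_hq, alt_frequency = alt_frequency,
             ref_fwd = ref_fwd, ref_rev = ref_rev, alt_fwd = alt_fwd,
             alt_rev = alt_rev, genotype = genotype)
}

test_that("strand-bias p matches hypergeometric enumeration", {
  expect_equal(strand_bias_p(5, 5, 5, 5), 1.0)
  expect_equal(strand_bias_p(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-9)
  set.seed(401)
  for (rep in 1:50) {
    tab <- as.integer(sample(0:15, 4, replace = TRUE))
    if (sum(tab) == 0) tab[1] <- 1L
    expect_equal(strand_bias_p(tab[1], tab[2], tab[3], tab[4]),
                 fisher_enum_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
  expect_error(strand_bias_p(0, 0, 0, 0), "all-zero")
})

test_that("error-site selection applies inclusive boundaries", {
  v <- rbind(make_variant(position = 1L, depth_hq = 9L),        # depth fail
             make_variant(position = 200L, depth_hq = 10L,
                          alt_frequency = 0.70),                # both at bound
             make_variant(position = 400L, alt_frequency = 0.69),
             make_variant(position = 600L, ref_fwd = 0L, ref_rev = 12L,
                          alt_fwd = 18L, alt_rev = 0L),         # strand bias
             make_variant(position = 800L))
  sel <- select_error_sites(v)
  expect_setequal(sel$position, c(200L, 800L))
  # degenerate thresholds keep everything
  cfg0 <- filter_config(min_depth = 1L, min_freq_error = 1e-9,
                        strand_p = 1e-300)
  expect_equal(nrow(select_error_sites(v, cfg0)), nrow(v))
})

test_that("filters are monotone: tightening thresholds never grows the set", {
  set.seed(402)
  v <- do.call(rbind, lapply(1:200, function(i) {
    d <- sample(5:40, 1)
    af_n <- sample(seq(ceiling(d / 2), d), 1)
    fwd <- rbinom(1, af_n, runif(1, 0.1, 0.9))
    rfn <- d - af_n
    rfwd <- rbinom(1, rfn, 0.5)
    make_variant(position = i * 1000L, depth_hq = d,
                 alt_frequency = af_n / d, ref_fwd = rfwd,
                 ref_rev = rfn - rfwd, alt_fwd = fwd, alt_rev = af_n - fwd)
  }))
  base <- select_error_sites(v, filter_config())
  for (cfg in list(filter_config(min_depth = 20L),
                   filter_config(min_freq_error = 0.9),
                   filter_config(strand_p = 0.2))) {
    tight <- select_error_sites(v, cfg)
    expect_true(all(tight$position %in% base$position))
  }
})

test_that("marker SNP selection recovers exactly the planted valid set", {
  cfg <- sim_config(seed = 403, n_lgs = 2, lg_size = 300000)
  truth <- simulate_genome(cfg)
  vars <- simulate_variants(truth, cfg, n_valid = 12, n_decoy = 5)
  sel <- select_marker_snps(vars$parent1, truth$genome, vars$parent2)
  valid <- vars$labels[vars$labels$label == "valid", ]
  expect_setequal(paste(sel$scaffold, sel$position),
                  paste(valid$scaffold, valid$position))
  aud <- attr(sel, "audit")
  expect_equal(unname(aud["cross_parent_fixed"]), nrow(valid))
  expect_true(all(diff(aud) <= 0))  # each stage only removes
  # a SNP with a neighbour 40 bp away dies at the flank screen
  lab <- vars$labels
  near <- lab$position[lab$label == "flank_near"]
  expect_false(any(near %in% sel$position))
})

test_that("marker spacing: pairwise gaps respect the minimum", {
  cand <- data.frame(scaffold = "s1", position = seq(0, 990000, by = 10000))
  sel <- space_markers(cand)
  expect_true(all(diff(sel$position) >= 100000))
  expect_lte(nrow(sel), 10)
  # matches first-fit count
  first_fit <- 0L
  last <- -Inf
  for (p in cand$position) {
    if (p - last >= 100000) {
      first_fit <- first_fit + 1L
      last <- p
    }
  }
  expect_equal(nrow(sel), first_fit)
  # single candidate is kept; random sets keep the invariant
  expect_equal(nrow(space_markers(cand[3, , drop = FALSE])), 1)
  set.seed(404)
  for (rep in 1:10) {
    cand2 <- data.frame(scaffold = sample(c("a", "b"), 60, replace = TRUE),
                        position = sample(1:2000000, 60))
    sel2 <- space_markers(cand2)
    for (sc in unique(sel2$scaffold)) {
      p <- sort(sel2$position[sel2$scaffold == sc])
      if (length(p) > 1) expect_true(all(diff(p) >= 100000))
    }
  }
})

test_that("homopolymer run length matches a regex-scan oracle", {
  expect_equal(homopolymer_run("ACGGGGT", 2), 4)
  expect_equal(homopolymer_run("ACGGGGT", 5), 4)
  expect_equal(homopolymer_run("ACGT", 1), 1)
  # indel base adjacent to a run: the run of that base touching the site
  expect_equal(homopolymer_run("ACTTTTG", 1, base = "T"), 4)
  set.seed(405)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                      prob = c(4, 1, 1, 4)), collapse = "")
    p <- sample(0:59, 1)
    b <- substr(s, p + 1, p + 1)
    runs <- gregexpr(paste0(b, "+"), s)[[1]]
    len <- attr(runs, "match.length")
    hit <- which(runs <= p + 1 & runs + len - 1 >= p + 1)
    expect_equal(homopolymer_run(s, p), len[hit])
  }
})

test_that("edit application remaps coordinates and reverses exactly", {
  set.seed(406)
  base <- random_dna(5000)
  ss <- sequence_set(c(chr = base))
  # plant landmarks, then edits strictly between them
  landmarks <- seq(100, 4800, by = 500)
  lm_seq <- substring(base, landmarks + 1, landmarks + 20)
  pos <- sort(sample(setdiff(seq(150, 4700), as.vector(
    outer(landmarks, 0:25, `+`))), 40))
  pos <- pos[c(TRUE, diff(pos) > 10)]
  edits <- do.call(rbind, lapply(pos, function(p) {
    ref <- substr(base, p + 1, p + 1)
    type <- sample(c("sub", "ins", "del"), 1)
    if (type == "sub") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (type == "ins") {
      alt <- paste0(ref, random_dna(sample(1:4, 1)))
    } else {
      ref <- substr(base, p + 1, p + 1 + sample(1:3, 1))
      alt <- substr(ref, 1, 1)
    }
    data.frame(scaffold = "chr", position = p, ref = ref, alt = alt)
  }))
  res <- apply_edits(ss, edits)
  # length change equals sum of allele length differences
  expect_equal(nchar(unclass(res$seqs)[["chr"]]) - 5000,
               sum(nchar(edits$alt) - nchar(edits$ref)))
  # landmarks recoverable through the coordinate map
  new_pos <- remap_position(res$coord_map, "chr", landmarks)
  got <- substring(unclass(res$seqs)[["chr"]], new_pos + 1, new_pos + 20)
  expect_identical(got, lm_seq)
  # reverse edits restore the original byte-for-byte
  back <- apply_edits(res$seqs, res$reverse_edits)
  expect_identical(unclass(back$seqs)[["chr"]], base)
  # ref mismatch is reported with the site
  bad <- data.frame(scaffold = "chr", position = 0,
                    ref = if (substr(base, 1, 1) == "A") "C" else "A",
                    alt = "T")
  expect_error(apply_edits(ss, bad), "ref mismatch")
  # empty edit set is the identity
  none <- apply_edits(ss, edits[0, ])
  expect_identical(unclass(none$seqs)[["chr"]], base)
})

test_that("discrepancy classification tallies a planted composition", {
  set.seed(407)
  s <- paste0(random_dna(200), "GGGGG", random_dna(200))
  ss <- sequence_set(c(c1 = s))
  edits <- rbind(
    data.frame(scaffold = "c1", position = 10, ref = substr(s, 11, 11),
               alt = "T"),
    data.frame(scaffold = "c1", position = 50, ref = substr(s, 51, 51),
               alt = paste0(substr(s, 51, 51), "AC")),
    data.frame(scaffold = "c1", position = 201, ref = substr(s, 202, 203),
               alt = substr(s, 202, 202)),
    data.frame(scaffold = "c1", position = 200,
               ref = substr(s, 201, 201),
               alt = paste0(substr(s, 201, 201), "G")))  # homopolymer ins
  edits$alt[1] <- if (edits$ref[1] == "T") "A" else "T"
  cl <- classify_discrepancies(edits, ss)
  expect_equal(cl$substitutions, 1)
  expect_equal(cl$insertions, 2)
  expect_equal(cl$deletions, 1)
  expect_gte(cl$homopolymer_indels, 1)
  expect_equal(nrow(cl$detail), 4)
})

test_that("variant TSV round trip preserves records", {
  v <- rbind(make_variant(), make_variant(position = 700L, genotype = "het"))
  f <- tempfile(fileext = ".tsv")
  write_variants(v, f)
  back <- read_variants(f)
  expect_equal(back$position, v$position)
  expect_equal(back$alt_frequency, v$alt_frequency)
  unlink(f)
})
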