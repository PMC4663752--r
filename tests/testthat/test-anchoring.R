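# Shared small synthetic world for the anchoring tests.
anchor_world <- function(seed = 301) {
  cfg <- sim_config(seed = seed, n_lgs = 2, lg_size = 400000,
                    n_individuals = 100, n_scaffolds = 10)
  truth <- simulate_genome(cfg)
  frag <- fragment_assembly(truth, cfg)
  list(cfg = cfg, truth = truth, frag = frag, map = truth_map(truth))
}

test_that("planted probes are recovered exactly, duplicates flagged", {
  w <- anchor_world()
  pl <- place_probes(w$truth$probes, w$truth$genome)
  expect_true(all(pl$n_hits == 1))
  expect_true(all(pl$usable))
  # position: the SNP base itself (0-based) on the source LG
  i <- match(w$truth$markers$marker, pl$marker)
  expect_equal(pl$position[i], w$truth$markers$position)
  expect_equal(pl$scaffold[i], w$truth$markers$lg)
  # a probe planted twice becomes unusable with n_hits = 2
  g <- as.list(unclass(w$truth$genome))
  dup <- w$truth$probes[1, , drop = FALSE]
  g$LG1 <- paste0(g$LG1, dup$seq)
  g <- unlist(g)
  pl2 <- place_probes(probe_set(dup),
                      sequence_set(g, kind = "pseudomolecule"))
  expect_equal(pl2$n_hits, 2L)
  expect_false(pl2$usable)
  # an absent probe reports zero hits
  set.seed(999)
  fake <- dup
  fake$seq <- paste0(substr(random_dna(121), 1, 60), dup$allele_a,
                     substr(random_dna(121), 62, 121))
  fake$marker <- "absent"
  pl3 <- place_probes(probe_set(fake), w$truth$genome)
  expect_equal(pl3$n_hits, 0L)
})

test_that("hand-built cM sequences classify as monotone or conflicting", {
  mk_pl <- function(cms, sc = "s1") {
    data.frame(marker = paste0("m", seq_along(cms)), scaffold = sc,
               position = seq_along(cms) * 1000, strand = "+",
               n_hits = 1L, identical = TRUE, usable = TRUE)
  }
  mk_map <- function(cms) {
    data.frame(lg = "LG1", marker = paste0("m", seq_along(cms)), cm = cms)
  }
  expect_equal(nrow(detect_contradictions(mk_pl(c(3, 5, 9)),
                                          mk_map(c(3, 5, 9)))), 0)
  cc <- detect_contradictions(mk_pl(c(5, 3, 9)), mk_map(c(5, 3, 9)))
  expect_equal(cc$kind, "order_conflict")
  # decreasing is a valid (reverse-strand) monotone order
  expect_equal(nrow(detect_contradictions(mk_pl(c(9, 5, 3)),
                                          mk_map(c(9, 5, 3)))), 0)
  # ties collapse: (2, 2, 5) is monotone
  expect_equal(nrow(detect_contradictions(mk_pl(c(2, 2, 5)),
                                          mk_map(c(2, 2, 5)))), 0)
  # two LGs on one scaffold is a chimera record
  pl <- mk_pl(c(1, 2))
  map2 <- data.frame(lg = c("LG1", "LG2"), marker = c("m1", "m2"),
                     cm = c(1, 2))
  cc2 <- detect_contradictions(pl, map2)
  expect_equal(cc2$kind, "inter_lg_chimera")
})

test_that("planted chimeras and inversions are detected without false positives", {
  cfg <- sim_config(seed = 302, n_lgs = 2, lg_size = 1000000,
                    n_individuals = 50, n_scaffolds = 20,
                    chimera_rate = 0.3, inversion_rate = 0.3)
  truth <- simulate_genome(cfg)
  frag <- fragment_assembly(truth, cfg)
  expect_gt(nrow(frag$defects), 0)
  pl <- place_probes(truth$probes, frag$scaffolds)
  cc <- detect_contradictions(pl, truth_map(truth))
  planted_chimera <- frag$defects$scaffold[frag$defects$kind ==
                                             "inter_lg_chimera"]
  planted_inv <- frag$defects$scaffold[frag$defects$kind == "inversion"]
  expect_setequal(cc$scaffold[cc$kind == "inter_lg_chimera"], planted_chimera)
  expect_setequal(cc$scaffold[cc$kind == "order_conflict"], planted_inv)
  # clean fragmentation yields no records at all
  w <- anchor_world(seed = 303)
  pl0 <- place_probes(w$truth$probes, w$frag$scaffolds)
  expect_equal(nrow(detect_contradictions(pl0, w$map)), 0)
})

test_that("anchoring orders by median cM and orients by rank correlation", {
  # two-marker scaffold with decreasing cM along position: orientation -
  pl <- data.frame(marker = c("m1", "m2"), scaffold = "s1",
                   position = c(10000, 900000), strand = "+",
                   n_hits = 1L, identical = TRUE, usable = TRUE)
  map <- data.frame(lg = "LG1", marker = c("m1", "m2"), cm = c(4, 2))
  plan <- anchor(pl, map, c(s1 = 1000000), bp_per_cm = 1e5)
  expect_equal(plan$orientation, "-")
  # single-marker scaffold: unknown without a hint, hint wins when given
  pl1 <- pl[1, , drop = FALSE]
  plan1 <- anchor(pl1, map, c(s1 = 1000000), bp_per_cm = 1e5)
  expect_equal(plan1$orientation, "?")
  plan2 <- anchor(pl1, map, c(s1 = 1000000), bp_per_cm = 1e5,
                  synteny_hint = data.frame(scaffold = "s1",
                                            orientation = "-"))
  expect_equal(plan2$orientation, "-")
  # a chimeric scaffold reaching anchoring is an error
  map2 <- data.frame(lg = c("LG1", "LG2"), marker = c("m1", "m2"),
                     cm = c(4, 2))
  expect_error(anchor(pl, map2, c(s1 = 1000000), bp_per_cm = 1e5),
               "unresolved chimera")
})

test_that("synthetic anchoring recovers true scaffold order and orientation", {
  w <- anchor_world(seed = 304)
  pl <- place_probes(w$truth$probes, w$frag$scaffolds)
  plan <- anchor(pl, w$map, seq_lengths(w$frag$scaffolds),
                 genome_size = sum(w$cfg$lg_size))
  st <- w$frag$scaffold_truth
  for (lg in unique(plan$lg)) {
    p <- plan[plan$lg == lg, ]
    tr <- st[match(p$scaffold, st$scaffold), ]
    # order by median cM must equal true genomic order where anchored
    expect_false(is.unsorted(tr$start))
    # multi-marker scaffolds get the true orientation
    multi <- p$n_markers >= 2
    expect_true(all(p$orientation[multi] == tr$strand[multi]))
  }
})

test_that("gap estimation follows the marker-interval formula with sentinel", {
  # stated arithmetic: 0.5 cM * 900 kb/cM - 150 kb overhangs = 300 kb
  pm <- data.frame(marker = c("a", "b"), scaffold = c("L", "R"),
                   position = c(900000, 50000), lg = "LG1",
                   cm = c(10, 10.5))
  lens <- c(L = 1000000, R = 300000)
  g <- estimate_gap("L", "+", "R", "+", pm, lens, 900000)
  expect_equal(g, 0.5 * 900000 - (1000000 - 1 - 900000) - 50000)
  # tied markers: the 1,000 N sentinel
  pm2 <- pm
  pm2$cm <- c(10, 10)
  expect_equal(estimate_gap("L", "+", "R", "+", pm2, lens, 900000), 1000)
  # negative computation: sentinel
  pm3 <- pm
  pm3$cm <- c(10, 10.05)  # 45 kb of map distance, 149 kb of overhang
  expect_equal(estimate_gap("L", "+", "R", "+", pm3, lens, 900000), 1000)
  # small positive gap clamps to the 100 bp minimum
  pm4 <- pm
  pm4$position <- c(999950, 10)
  pm4$cm <- c(10, 10.0001)
  expect_equal(estimate_gap("L", "+", "R", "+", pm4, lens, 900000), 100)
})

test_that("pseudomolecule building is AGP-consistent and round-trips", {
  set.seed(305)
  scf <- sequence_set(c(s1 = random_dna(100), s2 = random_dna(200)))
  plan <- structure(
    data.frame(lg = "LG1", rank = 1:2, scaffold = c("s1", "s2"),
               orientation = c("+", "-"), median_cm = c(0, 1),
               n_markers = c(1, 1), gap_after = c(1000, NA)),
    unanchored = character(0), bp_per_cm = 1e6,
    class = c("anchor_plan", "data.frame"))
  built <- build_pseudomolecules(plan, scf)
  expect_equal(seq_lengths(built$pseudomolecules)[["LG1"]], 1300)
  # reverse-oriented component appears reverse-complemented, "-" in AGP
  s2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unclass(scf)[["s2"]])))
  expect_equal(substr(unclass(built$pseudomolecules)[["LG1"]], 1101, 1300),
               s2rc)
  expect_equal(built$agp$orientation[built$agp$component_id == "s2"], "-")
  # AGP + components reproduce the FASTA byte-for-byte, also through files
  f_agp <- tempfile(fileext = ".agp")
  write_agp(built$agp, f_agp)
  rebuilt <- agp_to_fasta(read_agp(f_agp), scf)
  expect_identical(unclass(rebuilt)[["LG1"]],
                   unclass(built$pseudomolecules)[["LG1"]])
  unlink(f_agp)
})

test_that("re-anchoring emitted pseudomolecules is clean: one component per LG", {
  w <- anchor_world(seed = 306)
  pl <- place_probes(w$truth$probes, w$frag$scaffolds)
  plan <- anchor(pl, w$map, seq_lengths(w$frag$scaffolds),
                 genome_size = sum(w$cfg$lg_size))
  built <- build_pseudomolecules(plan, w$frag$scaffolds)
  anchored_ids <- plan$lg
  ps <- built$pseudomolecules[unique(anchored_ids)]
  pl2 <- place_probes(w$truth$probes, ps)
  expect_equal(nrow(detect_contradictions(pl2, w$map)), 0)
  plan2 <- anchor(pl2, w$map, seq_lengths(ps),
                  genome_size = sum(w$cfg$lg_size))
  expect_equal(nrow(plan2), length(unique(plan$lg)))
  # sum of anchored lengths never exceeds the assembly total
  expect_lte(sum(seq_lengths(w$frag$scaffolds)[plan$scaffold]),
             sum(seq_lengths(w$frag$scaffolds)))
})

test_that("LG relabelling follows the majority reference vote", {
  map <- data.frame(lg = rep(c("LG1", "LG2"), c(3, 2)),
                    marker = paste0("m", 1:5), cm = c(0, 1, 2, 0, 1))
  plan <- data.frame(lg = c("LG1", "LG2"), scaffold = c("s1", "s2"))
  ref <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                    chromosome = c("chr2", "chr2", "chr7", "chr5"))
  out <- relabel_groups(plan, map, ref)
  expect_equal(out$lg, c("chr2", "chr5"))
  # no overlap: name kept with a warning
  ref2 <- data.frame(marker = "zzz", chromosome = "chr1")
  w <- capture_warnings(out2 <- relabel_groups(plan, map, ref2))
  expect_length(w, 2)
  expect_match(w, "no markers", all = TRUE)
  expect_equal(out2$lg, c("LG1", "LG2"))
})
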