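# Independent oracles used by the test suite. These deliberately use the
# most literal algorithm available (linear scans, full enumeration, full
# dynamic programming) and share no code with the implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Literal cumulative-scan Nx: walk descending lengths until x% of total.
brute_nx <- function(lengths, x) {
  l <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * sum(l)
  acc <- 0
  for (v in l) {
    acc <- acc + v
    if (acc >= target) return(v)
  }
  stop("unreachable")
}

# Literal cumulative-scan NGx against an external genome size.
brute_ng <- function(lengths, genome_size, x) {
  l <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * genome_size
  acc <- 0
  for (v in l) {
    acc <- acc + v
    if (acc >= target) return(v)
  }
  0
}

# Two-sided Fisher exact p by hypergeometric enumeration: condition on the
# margins, sum the probabilities of every table no more likely than the
# observed one (with the standard relative tolerance for ties).
fisher_enum_p <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  m <- ref_fwd + ref_rev          # ref total
  n <- alt_fwd + alt_rev          # alt total
  k <- ref_fwd + alt_fwd          # fwd total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(ref_fwd, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Full affine-gap Smith-Waterman on small sequences, with a state-based
# traceback. Scoring matches the package's overlap aligner: match 1,
# mismatch -2, gap of length L costs gap_open + L * gap_ext. Returns the
# best local alignment's score, column count and identity.
sw_local <- function(a, b, match = 1, mismatch = -2, gap_open = 4,
                     gap_ext = 2) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # alignment ends with gap in a
  F <- matrix(NEG, n + 1, m + 1)   # alignment ends with gap in b
  # pointers: for H, 0 = stop, 1 = diag from H, 2 = take F, 3 = take E;
  # for E/F, TRUE = opened here (came from H), FALSE = extended.
  pH <- matrix(0L, n + 1, m + 1)
  pE <- matrix(FALSE, n + 1, m + 1)
  pF <- matrix(FALSE, n + 1, m + 1)
  best <- 0
  bi <- bj <- 1L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      open_e <- H[i, j - 1] - gap_open - gap_ext
      ext_e <- E[i, j - 1] - gap_ext
      E[i, j] <- max(open_e, ext_e)
      pE[i, j] <- open_e >= ext_e
      open_f <- H[i - 1, j] - gap_open - gap_ext
      ext_f <- F[i - 1, j] - gap_ext
      F[i, j] <- max(open_f, ext_f)
      pF[i, j] <- open_f >= ext_f
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      d <- H[i - 1, j - 1] + s
      h <- max(0, d, E[i, j], F[i, j])
      H[i, j] <- h
      pH[i, j] <- if (h == 0) 0L else if (h == d) 1L else
        if (h == F[i, j]) 2L else 3L
      if (h > best) {
        best <- h
        bi <- i
        bj <- j
      }
    }
  }
  i <- bi
  j <- bj
  cols <- 0L
  matches <- 0L
  state <- "H"
  repeat {
    if (state == "H") {
      p <- pH[i, j]
      if (p == 0L) break
      if (p == 1L) {
        cols <- cols + 1L
        if (av[i - 1] == bv[j - 1]) matches <- matches + 1L
        i <- i - 1
        j <- j - 1
      } else if (p == 2L) state <- "F" else state <- "E"
    } else if (state == "F") {
      cols <- cols + 1L
      opened <- pF[i, j]
      i <- i - 1
      if (opened) state <- "H"
    } else {
      cols <- cols + 1L
      opened <- pE[i, j]
      j <- j - 1
      if (opened) state <- "H"
    }
  }
  list(score = best, columns = cols, matches = matches,
       identity = if (cols > 0) matches / cols else 0)
}

# Exhaustive-permutation optimum of the adjacent-r sum objective used by
# marker ordering (feasible for <= 8 markers).
brute_order_cost <- function(markers, rmat) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- c(out, lapply(rest, function(p) c(v[i], p)))
    }
    out
  }
  cost <- function(ord) {
    rr <- rmat[cbind(ord[-length(ord)], ord[-1])]
    rr[is.na(rr)] <- 0.5
    sum(rr)
  }
  min(vapply(perms(markers), cost, numeric(1)))
}

# Minimal two-marker F2 simulator, independent of the package's own
# simulator: each gamete recombines between the two loci with probability r.
sim_f2_pair <- function(n, r) {
  g1a <- rbinom(n, 1, 0.5)
  g1b <- (g1a + rbinom(n, 1, r)) %% 2
  g2a <- rbinom(n, 1, 0.5)
  g2b <- (g2a + rbinom(n, 1, r)) %% 2
  codes <- c("AA", "AB", "BB")
  list(a = codes[g1a + g2a + 1], b = codes[g1b + g2b + 1])
}

# Kendall rank correlation between an estimated and a true order (ids).
kendall_order_tau <- function(est, truth) {
  r1 <- match(est, truth)
  cor(seq_along(est), r1, method = "kendall")
}
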