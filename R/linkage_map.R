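#' Create an F2 genotype matrix
#'
#' Calls are coded `"AA"`, `"AB"`, `"BB"` or `NA`, rows are individuals,
#' columns are markers (the layout of the genotype TSV interchange format).
#'
#' @param calls Character matrix with row and column names.
#' @return A validated `genotype_matrix` (character matrix).
#' @export
genotype_matrix <- function(calls) {
  check_that(is.matrix(calls), "calls must be a matrix")
  check_that(!is.null(rownames(calls)) && !is.null(colnames(calls)),
             "individual and marker ids required")
  ok <- is.na(calls) | calls %in% c("AA", "AB", "BB")
  check_that(all(ok), "genotype codes restricted to AA/AB/BB/NA")
  structure(calls, class = c("genotype_matrix", class(unclass(calls))))
}

#' Read / write an F2 genotype matrix as TSV
#'
#' Rows are individuals, columns markers; missing calls are `NA`.
#' @param path File path.
#' @return [genotype_matrix()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_genotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  na.strings = "NA", colClasses = "character",
                  check.names = FALSE)
  m <- as.matrix(d)
  m[m == "NA" | m == ""] <- NA
  genotype_matrix(m)
}

#' @rdname read_genotypes
#' @param g A [genotype_matrix()].
#' @export
write_genotypes <- function(g, path) {
  d <- data.frame(individual = rownames(g), unclass(g), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove individuals and markers with excess missing data
#'
#' Iteratively drops whichever row (individual) or column (marker) currently
#' has the highest missing fraction above `max_missing`, re-evaluating after
#' each removal, until every row and column satisfies the bound. Considering
#' rows and columns jointly and removing the worst offender first removes as
#' little data as a greedy rule can.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Maximum tolerated NA fraction per individual and per
#'   marker (default 0.10).
#' @return Filtered [genotype_matrix()].
#' @export
filter_missing <- function(g, max_missing = 0.10) {
  m <- unclass(g)
  repeat {
    if (nrow(m) == 0 || ncol(m) == 0)
      stop("no data after filtering", call. = FALSE)
    rfrac <- rowMeans(is.na(m))
    cfrac <- colMeans(is.na(m))
    worst_r <- which.max(rfrac)
    worst_c <- which.max(cfrac)
    if (rfrac[worst_r] <= max_missing && cfrac[worst_c] <= max_missing) break
    if (rfrac[worst_r] >= cfrac[worst_c]) {
      m <- m[-worst_r, , drop = FALSE]
    } else {
      m <- m[, -worst_c, drop = FALSE]
    }
  }
  genotype_matrix(m)
}

# Internal: map genotype codes to counts of the B allele (0/1/2), NA kept.
geno_to_dose <- function(x) {
  d <- match(x, c("AA", "AB", "BB")) - 1L
  d
}

#' Estimate the recombination fraction between two F2 markers
#'
#' Maximum-likelihood estimation by EM over the nine joint-genotype classes
#' of two codominant markers in an F2 population. The double-heterozygote
#' class mixes zero- and two-recombinant gamete configurations; the E step
#' distributes it according to the current estimate. Both linkage phases
#' (coupling and repulsion) are fitted and the more likely one is kept. The
#' LOD score is the log10 likelihood ratio against r = 0.5.
#'
#' @param a,b Character vectors of calls (`AA`/`AB`/`BB`/`NA`) for the two
#'   markers, same individuals in the same order.
#' @param min_informative Minimum number of individuals with both calls
#'   present (default 20).
#' @param tol Absolute EM convergence tolerance on r.
#' @param max_iter Maximum EM iterations.
#' @return List with `r` (in [0, 0.5]), `lod`, `n_informative`, `phase`
#'   (`"coupling"` or `"repulsion"`).
#' @export
estimate_rf <- function(a, b, min_informative = 20L, tol = 1e-8,
                        max_iter = 1000L) {
  da <- geno_to_dose(a)
  db <- geno_to_dose(b)
  keep <- !is.na(da) & !is.na(db)
  n <- sum(keep)
  if (n < min_informative) stop("uninformative pair", call. = FALSE)
  # counts n[i+1, j+1] of (dose a = i, dose b = j)
  cnt <- matrix(0, 3, 3)
  tb <- table(factor(da[keep], levels = 0:2), factor(db[keep], levels = 0:2))
  cnt[] <- as.numeric(tb)

  fit_phase <- function(cnt) {
    # class probabilities for phase AB/ab; recombinant-gamete counts per class
    # (dose pairs): corners 0 rec or 2 rec, edges 1 rec, centre mixed.
    r <- 0.25
    for (it in seq_len(max_iter)) {
      # E: expected recombinant gametes
      p_par <- (1 - r)^2
      p_rec <- r^2
      e_dhet <- if (p_par + p_rec > 0) 2 * p_rec / (p_par + p_rec) else 0
      rec <- cnt[1, 1] * 0 + cnt[3, 3] * 0 +          # ab/ab, AB/AB
        cnt[1, 3] * 2 + cnt[3, 1] * 2 +               # aB/aB, Ab/Ab
        (cnt[1, 2] + cnt[2, 1] + cnt[2, 3] + cnt[3, 2]) * 1 +
        cnt[2, 2] * e_dhet
      r_new <- rec / (2 * n)
      if (abs(r_new - r) < tol) {
        r <- r_new
        break
      }
      r <- r_new
    }
    r <- min(max(r, 0), 0.5)
    list(r = r, ll = f2_loglik(cnt, r))
  }

  fit_c <- fit_phase(cnt)
  # repulsion = coupling after flipping one marker's dose
  cnt_r <- cnt[, 3:1]
  fit_r <- fit_phase(cnt_r)
  if (fit_c$ll >= fit_r$ll) {
    r <- fit_c$r; ll <- fit_c$ll; phase <- "coupling"
    ll0 <- f2_loglik(cnt, 0.5)
  } else {
    r <- fit_r$r; ll <- fit_r$ll; phase <- "repulsion"
    ll0 <- f2_loglik(cnt_r, 0.5)
  }
  lod <- max(0, (ll - ll0) / log(10))
  list(r = r, lod = lod, n_informative = n, phase = phase)
}

# Internal: F2 joint-genotype log-likelihood at recombination fraction r,
# phase AB/ab, for a 3x3 count matrix (rows dose a, cols dose b).
f2_loglik <- function(cnt, r) {
  g <- c(AB = (1 - r) / 2, ab = (1 - r) / 2, Ab = r / 2, aB = r / 2)
  # genotype probability: sum over ordered gamete pairs
  p <- matrix(0, 3, 3)
  doses <- list(AB = c(1, 1), ab = c(0, 0), Ab = c(1, 0), aB = c(0, 1))
  for (g1 in names(g)) for (g2 in names(g)) {
    d <- doses[[g1]] + doses[[g2]]
    p[d[1] + 1, d[2] + 1] <- p[d[1] + 1, d[2] + 1] + g[[g1]] * g[[g2]]
  }
  keep <- cnt > 0
  sum(cnt[keep] * log(p[keep]))
}

#' Map functions: recombination fraction to centimorgans
#'
#' Haldane assumes no crossover interference, `d = -50 ln(1 - 2r)`;
#' Kosambi models partial interference, `d = 25 ln((1 + 2r) / (1 - 2r))`.
#'
#' @param r Recombination fraction(s) in [0, 0.5).
#' @return Distance(s) in centimorgans.
#' @examples
#' haldane_cm(0.2)  # 25.54
#' kosambi_cm(0.2)  # 21.18
#' @export
haldane_cm <- function(r) {
  check_that(all(r >= 0 & r < 0.5), "unlinked")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @export
kosambi_cm <- function(r) {
  check_that(all(r >= 0 & r < 0.5), "unlinked")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Pairwise recombination fractions for all marker pairs
#'
#' @param g A [genotype_matrix()].
#' @param min_informative Passed to [estimate_rf()]; pairs with fewer joint
#'   calls get `r = NA`.
#' @return List of two matrices, `r` and `lod` (markers x markers).
#' @export
rf_matrix <- function(g, min_informative = 20L) {
  m <- unclass(g)
  p <- ncol(m)
  rmat <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  lmat <- rmat
  diag(rmat) <- 0
  diag(lmat) <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      est <- tryCatch(estimate_rf(m[, i], m[, j], min_informative),
                      error = function(e) NULL)
      if (!is.null(est)) {
        rmat[i, j] <- rmat[j, i] <- est$r
        lmat[i, j] <- lmat[j, i] <- est$lod
      }
    }
  }
  list(r = rmat, lod = lmat)
}

#' Group markers into linkage groups
#'
#' Builds a graph with an edge between two markers when their pairwise LOD is
#' at least `lod_min` and the recombination fraction at most `r_max`, and
#' returns its connected components. Singletons are reported separately.
#'
#' @param rf Result of [rf_matrix()].
#' @param lod_min Minimum LOD for linkage (default 3).
#' @param r_max Maximum recombination fraction for linkage (default 0.35).
#' @return List with `groups` (list of character vectors, largest first) and
#'   `singletons` (character vector).
#' @export
group_markers <- function(rf, lod_min = 3.0, r_max = 0.35) {
  adj <- !is.na(rf$r) & rf$r <= r_max & rf$lod >= lod_min
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  ids <- rownames(rf$r)
  groups <- split(ids, comp$membership)
  sizes <- lengths(groups)
  singles <- sort(unlist(groups[sizes == 1], use.names = FALSE))
  groups <- groups[sizes > 1]
  groups <- groups[order(-lengths(groups),
                         vapply(groups, min, character(1)))]
  names(groups) <- NULL
  list(groups = lapply(groups, sort), singletons = singles)
}

# Internal: sum of adjacent r along an order (NA treated as 0.5).
order_cost <- function(ord, rmat) {
  rr <- rmat[cbind(ord[-length(ord)], ord[-1])]
  rr[is.na(rr)] <- 0.5
  sum(rr)
}

#' Order the markers of one linkage group
#'
#' Seriation by greedy nearest-neighbour chaining on the recombination
#' fraction, refined by 2-opt moves that minimise the sum of adjacent r (a
#' travelling-salesman-path objective). The orientation of the whole order is
#' arbitrary; for determinism the end with the lexicographically smaller
#' marker id comes first.
#'
#' @param markers Character vector of marker ids (size >= 2).
#' @param rf Result of [rf_matrix()] covering these markers.
#' @return Character vector: the ordered marker ids.
#' @export
order_markers <- function(markers, rf) {
  check_that(length(markers) >= 2, "need at least 2 markers")
  markers <- sort(markers)
  if (length(markers) == 2) return(markers)
  rmat <- rf$r[markers, markers]
  rmat[is.na(rmat)] <- 0.5
  # greedy chain: start from the globally closest pair, extend at both ends
  d <- rmat
  diag(d) <- Inf
  st <- arrayInd(which.min(d), dim(d))
  path <- markers[st[1, ]]
  left <- setdiff(markers, path)
  while (length(left) > 0) {
    head_d <- d[path[1], left]
    tail_d <- d[path[length(path)], left]
    if (min(head_d) <= min(tail_d)) {
      nxt <- left[which.min(head_d)]
      path <- c(nxt, path)
    } else {
      nxt <- left[which.min(tail_d)]
      path <- c(path, nxt)
    }
    left <- setdiff(left, nxt)
  }
  # 2-opt refinement
  improved <- TRUE
  n <- length(path)
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cand <- path
        cand[i:j] <- rev(cand[i:j])
        if (order_cost(cand, rmat) < order_cost(path, rmat) - 1e-12) {
          path <- cand
          improved <- TRUE
        }
      }
    }
  }
  if (path[length(path)] < path[1]) path <- rev(path)
  path
}

#' Cumulative map distances along an ordered group
#'
#' @param order Ordered marker ids (from [order_markers()]).
#' @param rf Result of [rf_matrix()].
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return Data frame with columns `marker` and `cm`; the first marker is at
#'   0 cM.
#' @export
map_distances <- function(order, rf, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  f <- if (map_function == "kosambi") kosambi_cm else haldane_cm
  if (length(order) == 1) return(data.frame(marker = order, cm = 0))
  radj <- rf$r[cbind(order[-length(order)], order[-1])]
  if (any(is.na(radj) | radj >= 0.5)) stop("break group", call. = FALSE)
  data.frame(marker = order, cm = c(0, cumsum(f(radj))))
}

#' Build a genetic map from an F2 genotype matrix
#'
#' Full pipeline: missing-data filtering, pairwise recombination fractions,
#' linkage grouping, per-group ordering and cumulative distances. Linkage
#' groups are labelled `LG1`, `LG2`, ... in decreasing size order.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Missing-data bound, see [filter_missing()].
#' @param lod_min,r_max Grouping thresholds, see [group_markers()].
#' @param map_function See [map_distances()].
#' @param min_informative See [estimate_rf()].
#' @return A `genetic_map`: data frame with columns `lg`, `marker`, `cm`,
#'   with attribute `singletons`.
#' @export
build_map <- function(g, max_missing = 0.10, lod_min = 3.0, r_max = 0.35,
                      map_function = "kosambi", min_informative = 20L) {
  g <- filter_missing(g, max_missing)
  rf <- rf_matrix(g, min_informative)
  grp <- group_markers(rf, lod_min, r_max)
  rows <- lapply(seq_along(grp$groups), function(i) {
    ord <- order_markers(grp$groups[[i]], rf)
    d <- map_distances(ord, rf, map_function)
    cbind(lg = paste0("LG", i), d)
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  structure(map, singletons = grp$singletons, class = c("genetic_map",
                                                        "data.frame"))
}

#' Read / write a genetic map TSV (columns lg, marker, cm)
#' @param path File path.
#' @return The map data frame; the writer returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "character", "numeric"))
  check_that(all(c("lg", "marker", "cm") %in% names(d)),
             "map TSV needs columns lg, marker, cm")
  check_that(!anyDuplicated(d$marker), "marker ids must be unique across LGs")
  structure(d, class = c("genetic_map", "data.frame"))
}

#' @rdname read_genetic_map
#' @param map A genetic map data frame.
#' @export
write_genetic_map <- function(map, path) {
  write.table(map[, c("lg", "marker", "cm")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average adjacent-marker distance of a map
#' @param map A genetic map (columns `lg`, `marker`, `cm`).
#' @return Mean adjacent-marker interval in cM over all LGs.
#' @export
mean_marker_distance <- function(map) {
  iv <- unlist(lapply(split(map$cm, map$lg), function(cm) diff(sort(cm))))
  mean(iv)
}
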