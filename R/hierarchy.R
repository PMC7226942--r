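# Hierarchy of the directed TF network.  The raw hierarchy score of a level
# assignment is the mean edge-direction sign (an edge pointing from a lower
# level number to a higher one counts +1: level 1 is the top).  The corrected
# score standardizes the raw score against random permutations of the level
# labels across nodes (preserving level sizes).  Simulated annealing searches
# level assignments for each candidate level count L in 2..8 and the L with
# the best corrected score wins.

#' Annealing configuration for hierarchy inference
#'
#' @param restarts independent annealing restarts per level count.
#' @param steps_per_node proposed moves per node per restart.
#' @param T0 initial temperature.
#' @param alpha geometric cooling factor per step, in (0, 1).
#' @param permutations permutations for the corrected-score null.
#' @param seed RNG seed.
#' @return a list of class `anneal_config`.
#' @export
annealConfig <- function(restarts = 10L, steps_per_node = 200L, T0 = 1.0,
                         alpha = 0.995, permutations = 1000L, seed = 1L) {
  stopifnot(restarts >= 1, steps_per_node >= 1, T0 > 0, alpha > 0, alpha < 1,
            permutations >= 10)
  structure(list(restarts = as.integer(restarts),
                 steps_per_node = as.integer(steps_per_node), T0 = T0,
                 alpha = alpha, permutations = as.integer(permutations),
                 seed = seed),
            class = "anneal_config")
}

.rawHS <- function(ei, ej, lv) mean(sign(lv[ej] - lv[ei]))

# Sampled permutation null (mean, sd) of the raw score for a given per-level
# size profile on a fixed edge list.
.permNull <- function(ei, ej, sizes, R) {
  labels <- rep.int(seq_along(sizes), sizes)
  hs <- vapply(seq_len(R), function(r) {
    lv <- sample(labels)
    .rawHS(ei, ej, lv)
  }, numeric(1))
  c(mean = mean(hs), sd = max(sd(hs), 1e-9))
}

# Structural pair counts of the directed edge list, needed for the exact
# permutation variance; independent of the level assignment.
.edgePairCounts <- function(ei, ej) {
  nE <- length(ei)
  nodes <- max(c(ei, ej))
  outd <- tabulate(ei, nodes)
  ind <- tabulate(ej, nodes)
  key <- paste(ei, ej)
  rkey <- paste(ej, ei)
  m2 <- sum(key %in% rkey) / 2            # unordered 2-cycle pairs
  S_tt <- sum(choose(outd, 2))
  S_hh <- sum(choose(ind, 2))
  S_ht <- sum(outd * ind)
  P <- choose(nE, 2)
  list(nE = nE, S_tt = S_tt, S_hh = S_hh,
       S_ht = S_ht - 2 * m2, m2 = m2,
       N_disj = P - S_tt - S_hh - (S_ht - 2 * m2) - m2)
}

# Exact sd of the raw hierarchy score under uniformly random permutations of
# the level labels (mean is exactly 0 by exchangeability).  Needs the
# three- and four-node sign moments of the label multiset.
.exactNullSd <- function(counts, sizes) {
  n <- sum(sizes)
  L <- length(sizes)
  lv <- seq_len(L)
  if (n < 2) return(1e-9)
  q <- 1 - sum(sizes * (sizes - 1)) / (n * (n - 1))
  T_tt <- 0
  if (n >= 3) {
    for (i in lv) for (j in lv) for (k in lv) {
      cnt <- sizes[i] * (sizes[j] - (j == i)) *
        (sizes[k] - (k == i) - (k == j))
      if (cnt > 0) T_tt <- T_tt + cnt * sign(j - i) * sign(k - i)
    }
    T_tt <- T_tt / (n * (n - 1) * (n - 2))
  }
  D <- 0
  if (n >= 4 && counts$N_disj > 0) {
    for (i in lv) for (j in lv) for (k in lv) for (l in lv) {
      cnt <- sizes[i] * (sizes[j] - (j == i)) *
        (sizes[k] - (k == i) - (k == j)) *
        (sizes[l] - (l == i) - (l == j) - (l == k))
      if (cnt != 0) D <- D + cnt * sign(j - i) * sign(l - k)
    }
    D <- D / (n * (n - 1) * (n - 2) * (n - 3))
  }
  v <- counts$nE * q +
    2 * ((counts$S_tt + counts$S_hh) * T_tt - counts$S_ht * T_tt -
         counts$m2 * q + counts$N_disj * D)
  max(sqrt(max(v, 0)) / counts$nE, 1e-9)
}

#' Hierarchy score of a level assignment
#'
#' @param directed data.frame with columns `from`, `to` (or a [TFNetwork]).
#' @param levels named integer vector, node -> level (1 = top).
#' @param corrected if `TRUE`, return the permutation z-score; otherwise the
#'   raw mean edge-direction sign.
#' @param method `"exact"` standardizes with the combinatorially exact
#'   moments of the permutation null (its mean is 0 by exchangeability);
#'   `"sampled"` estimates them from `R` random label permutations.
#' @param R number of label permutations for `method = "sampled"`.
#' @param seed RNG seed for the sampled permutations.
#' @return the (corrected) hierarchy score.
#' @export
hierarchyScore <- function(directed, levels, corrected = FALSE,
                           method = c("exact", "sampled"), R = 1000L,
                           seed = 1L) {
  if (is(directed, "TFNetwork")) directed <- directedEdges(directed)
  if (!nrow(directed)) stopf("empty directed edge set")
  method <- match.arg(method)
  nodes <- names(levels)
  if (!all(c(directed$from, directed$to) %in% nodes))
    stopf("levels must be defined for every edge endpoint")
  ei <- match(directed$from, nodes)
  ej <- match(directed$to, nodes)
  lv <- as.integer(levels)
  hs <- .rawHS(ei, ej, lv)
  if (!corrected) return(hs)
  sizes <- tabulate(lv, nbins = max(lv))
  if (method == "exact") {
    counts <- .edgePairCounts(ei, ej)
    return(hs / .exactNullSd(counts, sizes))
  }
  null <- withSeed(seed, .permNull(ei, ej, sizes, R))
  unname((hs - null["mean"]) / null["sd"])
}

.annealOnce <- function(ei, ej, nNodes, L, cfg, adj, counts) {
  # returns list(levels, z); exact null sd cached per size profile
  cache <- new.env(parent = emptyenv())
  sdFor <- function(sizes) {
    key <- paste(sizes, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- .exactNullSd(counts, sizes)
    cache[[key]]
  }
  # init: every level non-empty
  lv <- integer(nNodes)
  seedNodes <- sample.int(nNodes, L)
  lv[seedNodes] <- seq_len(L)
  rest <- setdiff(seq_len(nNodes), seedNodes)
  if (length(rest)) lv[rest] <- sample.int(L, length(rest), replace = TRUE)
  sizes <- tabulate(lv, nbins = L)
  hsum <- sum(sign(lv[ej] - lv[ei]))
  nE <- length(ei)
  z <- hsum / nE / sdFor(sizes)
  best_lv <- lv; best_z <- z
  Tt <- cfg$T0
  nsteps <- cfg$steps_per_node * nNodes
  for (s in seq_len(nsteps)) {
    v <- sample.int(nNodes, 1L)
    if (sizes[lv[v]] <= 1L) { Tt <- Tt * cfg$alpha; next }
    newl <- sample.int(L, 1L)
    if (newl == lv[v]) { Tt <- Tt * cfg$alpha; next }
    inc <- adj[[v]]
    old_contrib <- sum(sign(lv[ej[inc]] - lv[ei[inc]]))
    oldl <- lv[v]
    lv[v] <- newl
    new_contrib <- sum(sign(lv[ej[inc]] - lv[ei[inc]]))
    hsum2 <- hsum + new_contrib - old_contrib
    sizes2 <- sizes
    sizes2[oldl] <- sizes2[oldl] - 1L
    sizes2[newl] <- sizes2[newl] + 1L
    z2 <- hsum2 / nE / sdFor(sizes2)
    if (z2 >= z || runif(1) < exp((z2 - z) / Tt)) {
      hsum <- hsum2; sizes <- sizes2; z <- z2
      if (z > best_z) { best_z <- z; best_lv <- lv }
    } else {
      lv[v] <- oldl
    }
    Tt <- Tt * cfg$alpha
  }
  list(levels = best_lv, z = unname(best_z))
}

#' Fit a hierarchical level assignment to the directed TF network
#'
#' For each candidate level count, runs several independent simulated
#' annealing restarts (single-node relocation moves, Metropolis acceptance on
#' the corrected-score change, geometric cooling) and keeps the level count
#' with the highest best corrected score.  Level assignment uncertainty is
#' summarized by each node's level frequency across the winning restarts; the
#' reported assignment is the per-node modal level.
#'
#' @param network a [TFNetwork] (its directed overlay is used) or a
#'   data.frame with columns `from`, `to`.
#' @param Lrange candidate level counts (default `2:8`).
#' @param cfg an [annealConfig()].
#' @return a [HierarchyFit].
#' @export
fitHierarchy <- function(network, Lrange = 2:8, cfg = annealConfig()) {
  directed <- if (is(network, "TFNetwork")) directedEdges(network) else network
  if (!nrow(directed)) stopf("network has no directed edges")
  nodes <- sort(unique(c(directed$from, directed$to)))
  ei <- match(directed$from, nodes)
  ej <- match(directed$to, nodes)
  nNodes <- length(nodes)
  nE <- length(ei)
  adj <- lapply(seq_len(nNodes), function(v) which(ei == v | ej == v))
  counts <- .edgePairCounts(ei, ej)
  Lrange <- Lrange[Lrange <= nNodes]
  results <- list()
  for (L in Lrange) {
    runs <- lapply(seq_len(cfg$restarts), function(r) {
      withSeed(childSeed(cfg$seed, L * 1000 + r),
               .annealOnce(ei, ej, nNodes, L, cfg, adj, counts))
    })
    zs <- vapply(runs, `[[`, 0, "z")
    results[[as.character(L)]] <- list(runs = runs, zs = zs,
                                       best = max(zs))
  }
  scoresByL <- vapply(results, `[[`, 0, "best")
  Lbest <- Lrange[which.max(scoresByL)]
  sel <- results[[as.character(Lbest)]]
  freq <- matrix(0, nNodes, Lbest,
                 dimnames = list(nodes, paste0("level", seq_len(Lbest))))
  for (r in sel$runs) {
    freq[cbind(seq_len(nNodes), r$levels)] <-
      freq[cbind(seq_len(nNodes), r$levels)] + 1
  }
  freq <- freq / cfg$restarts
  modal <- max.col(freq, ties.method = "first")
  names(modal) <- nodes
  new("HierarchyFit", levels = setNames(as.integer(modal), nodes),
      L = as.integer(Lbest), correctedScore = max(sel$zs),
      levelProbabilities = freq,
      scoresByL = setNames(scoresByL, names(results)))
}

#' Link ratios between and within hierarchy levels
#'
#' Entry (i, j) is the number of undirected network edges between levels i
#' and j divided by the largest theoretical number of such links
#' (`n_i * n_j` off-diagonal, `n_i (n_i - 1) / 2` within a level).  Levels
#' with fewer than 2 nodes get a within-level ratio of 0, flagged in the
#' `degenerate` attribute.
#'
#' @param network a [TFNetwork].
#' @param fit a [HierarchyFit].
#' @return L-by-L matrix of link ratios.
#' @export
levelLinkRatios <- function(network, fit) {
  lv <- hierarchyLevels(fit)
  L <- fit@L
  edges <- networkEdges(network)
  edges <- edges[edges$a %in% names(lv) & edges$b %in% names(lv), , drop = FALSE]
  sizes <- tabulate(lv, nbins = L)
  obs <- matrix(0, L, L)
  for (k in seq_len(nrow(edges))) {
    i <- lv[[edges$a[k]]]; j <- lv[[edges$b[k]]]
    obs[i, j] <- obs[i, j] + 1
    if (i != j) obs[j, i] <- obs[j, i] + 1
  }
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1) / 2
  ratio <- matrix(0, L, L, dimnames = list(paste0("L", seq_len(L)),
                                           paste0("L", seq_len(L))))
  ok <- denom > 0
  ratio[ok] <- obs[ok] / denom[ok]
  attr(ratio, "degenerate") <- which(sizes < 2)
  ratio
}
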