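# Motif occupancy of loop anchors: exact-null PWM scanning (log-odds scores
# with a dynamic-programming p-value over the discretized score distribution
# under the background model), rank-based promoter enrichment (minimal
# hypergeometric over affinity cutoffs), TF list assembly, and cross-cell
# threshold optimization by Jaccard-curve inflection.

#' Scan configuration for PWM matching
#'
#' @param p_threshold per-site p-value cutoff (default 1e-10).
#' @param pseudocount additive mass per matrix cell, distributed by the
#'   background (default 0.1).
#' @param background base frequencies over A, C, G, T (must sum to 1).
#' @param score_bin discretization step, in bits, for the exact p-value DP
#'   (default 1e-3; the induced score error is bounded by width * score_bin).
#' @return a validated list of class `scan_config`.
#' @export
scanConfig <- function(p_threshold = 1e-10, pseudocount = 0.1,
                       background = rep(0.25, 4), score_bin = 1e-3) {
  stopifnot(p_threshold > 0, p_threshold < 1, pseudocount >= 0,
            length(background) == 4, abs(sum(background) - 1) < 1e-6,
            score_bin > 0)
  if (any(background <= 0)) stopf("background frequencies must be positive")
  structure(list(p_threshold = p_threshold, pseudocount = pseudocount,
                 background = background, score_bin = score_bin),
            class = "scan_config")
}

# Integer-binned log-odds matrix and exact null tail probabilities.
.pwmTables <- function(pwm, cfg) {
  bg <- cfg$background
  pm <- sweep(pwm$matrix + cfg$pseudocount * rep(bg, each = nrow(pwm$matrix)),
              1, 1 + cfg$pseudocount, "/")
  lo <- log2(sweep(pm, 2, bg, "/"))       # width x 4, bits
  k <- round(lo / cfg$score_bin)          # integer bins
  w <- nrow(k)
  kmin <- sum(apply(k, 1, min)); kmax <- sum(apply(k, 1, max))
  dist <- numeric(kmax - kmin + 1)
  # DP over positions: distribution of the binned score under the background
  cur_min <- 0L
  cur <- 1
  for (j in seq_len(w)) {
    kj <- k[j, ]
    new_min <- cur_min + min(kj)
    new_max <- cur_min + length(cur) - 1L + max(kj)
    new <- numeric(new_max - new_min + 1)
    for (b in 1:4) {
      off <- cur_min + kj[b] - new_min
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg[b] * cur
    }
    cur <- new
    cur_min <- new_min
  }
  tail <- rev(cumsum(rev(cur)))           # P(K >= kmin + i - 1)
  list(k = k, lo = lo, kmin = cur_min, tail = pmin(tail, 1))
}

.revcompPWMk <- function(k) {
  # reverse position order, swap A<->T and C<->G columns
  k[rev(seq_len(nrow(k))), c(4, 3, 2, 1), drop = FALSE]
}

.seqCodes <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  c(A = 1L, C = 2L, G = 3L, `T` = 4L)[v]
}

# Binned window scores along one coded sequence for one strand's k matrix.
.windowScores <- function(codes, k) {
  w <- nrow(k)
  n <- length(codes) - w + 1L
  if (n < 1L) return(integer(0))
  sc <- integer(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    sc <- sc + k[j, cj]
  }
  sc[!ok] <- NA_integer_
  sc
}

#' Scan sequences with a PWM using exact null p-values
#'
#' Scores every window on both strands with log-odds bits against the
#' background; the p-value of a window is the exact probability, under the
#' background model, of a binned score at least as large (computed by dynamic
#' programming over the discretized per-position score distribution).
#' Windows containing `N` are skipped.
#'
#' @param seqs named character vector (or `DNAStringSet`) of sequences.
#' @param pwm a PWM record (see [readPWMs()]).
#' @param cfg a [scanConfig()].
#' @return data.frame of occurrences with `pvalue <= p_threshold`: columns
#'   `motif_id`, `tf_name`, `anchor`, `position`, `strand`, `score` (bits),
#'   `pvalue`.
#' @export
scanPWM <- function(seqs, pwm, cfg = scanConfig()) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  tab <- .pwmTables(pwm, cfg)
  krc <- .revcompPWMk(tab$k)
  res <- list()
  for (nm in names(seqs)) {
    codes <- .seqCodes(seqs[[nm]])
    for (strand in c("+", "-")) {
      km <- if (strand == "+") tab$k else krc
      sc <- .windowScores(codes, km)
      if (!length(sc)) next
      pv <- rep(NA_real_, length(sc))
      valid <- !is.na(sc)
      pv[valid] <- tab$tail[pmax(1L, sc[valid] - tab$kmin + 1L)]
      pv[valid & sc > tab$kmin + length(tab$tail) - 1L] <- 0
      hit <- which(valid & pv <= cfg$p_threshold)
      if (length(hit)) {
        res[[length(res) + 1L]] <- data.frame(
          motif_id = pwm$motif_id, tf_name = pwm$tf_name, anchor = nm,
          position = hit, strand = strand,
          score = sc[hit] * cfg$score_bin, pvalue = pv[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(motif_id = character(), tf_name = character(),
                      anchor = character(), position = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

# Best window score (bits, any strand) per sequence for one PWM; -Inf when no
# valid window.
.bestScores <- function(seqs, pwm, cfg) {
  tab <- .pwmTables(pwm, cfg)
  krc <- .revcompPWMk(tab$k)
  vapply(seqs, function(s) {
    codes <- .seqCodes(s)
    sc <- c(.windowScores(codes, tab$k), .windowScores(codes, krc))
    sc <- sc[!is.na(sc)]
    if (!length(sc)) -Inf else max(sc) * cfg$score_bin
  }, numeric(1))
}

#' Minimal hypergeometric rank enrichment
#'
#' Ranks items by decreasing affinity (ties broken by name) and, at every
#' cutoff k, tests whether the positives are over-represented among the top
#' k with a hypergeometric tail; returns the minimum p over all cutoffs.
#'
#' @param affinity named numeric vector of affinities.
#' @param positives character vector, a subset of `names(affinity)`.
#' @return the minimal hypergeometric tail probability over cutoffs.
#' @export
rankEnrichment <- function(affinity, positives) {
  if (!all(positives %in% names(affinity)))
    stopf("positives must be a subset of the ranked items")
  N <- length(affinity)
  K <- length(positives)
  if (K == 0L) return(1)
  ord <- order(-affinity, names(affinity))
  member <- names(affinity)[ord] %in% positives
  x <- cumsum(member)
  k <- seq_len(N)
  min(phyper(x - 1, K, N - K, k, lower.tail = FALSE))
}

.anchorTable <- function(epLoops) {
  st <- anchorStates(epLoops)
  enhA <- .hasClass(st$A, "Enhancer"); enhB <- .hasClass(st$B, "Enhancer")
  promA <- .hasClass(st$A, c("Promoter", "TSS"))
  promB <- .hasClass(st$B, c("Promoter", "TSS"))
  n <- length(epLoops)
  data.frame(
    loop = rep(seq_len(n), 2L),
    side = rep(c("A", "B"), each = n),
    anchor = c(paste0("L", seq_len(n), "_A"), paste0("L", seq_len(n), "_B")),
    enhancer = c(enhA, enhB), promoter = c(promA, promB),
    stringsAsFactors = FALSE)
}

.anchorSeqs <- function(epLoops, genome) {
  pull <- function(gr) {
    chrom <- as.character(seqnames(gr))
    missing <- setdiff(unique(chrom), names(genome))
    if (length(missing)) stopf("genome lacks chromosome %s", missing[1])
    vapply(seq_along(gr), function(i)
      as.character(Biostrings::subseq(genome[[chrom[i]]], start(gr)[i],
                                      end(gr)[i])), "")
  }
  n <- length(epLoops)
  setNames(c(pull(anchorsA(epLoops)), pull(anchorsB(epLoops))),
           c(paste0("L", seq_len(n), "_A"), paste0("L", seq_len(n), "_B")))
}

#' Determine enhancer and promoter TF lists from EP loop anchors
#'
#' A TF is in list A (enhancer side) when at least one of its motifs has a
#' significant occurrence in an enhancer-class anchor.  On the promoter side
#' a TF is in list B when its significant promoter anchors are enriched at
#' the top of the per-anchor best-score ranking (minimal hypergeometric p
#' below `enrichAlpha`, or significant in every promoter anchor).  The final
#' TF list is the intersection of A and B.
#'
#' @param epLoops an annotated enhancer-promoter [LoopSet] (see
#'   [filterEPLoops()]).
#' @param genome a `DNAStringSet` (chromosome sequences).
#' @param pwms PWM records from [readPWMs()].
#' @param cfg a [scanConfig()].
#' @param enrichAlpha promoter-enrichment cutoff (default 0.05).
#' @return list with `list_A`, `list_B`, `final` (sorted TF names),
#'   `occurrences` (per-anchor occurrence table over all anchors) and
#'   `anchors` (anchor classification table).
#' @export
buildTFLists <- function(epLoops, genome, pwms, cfg = scanConfig(),
                         enrichAlpha = 0.05) {
  if (length(epLoops) == 0L) stopf("no enhancer-promoter loops to scan")
  anchors <- .anchorTable(epLoops)
  seqs <- .anchorSeqs(epLoops, genome)
  occ_list <- lapply(pwms, function(p) scanPWM(seqs, p, cfg))
  occ <- if (length(occ_list))
    do.call(rbind, c(occ_list, list(make.row.names = FALSE)))
  else data.frame(motif_id = character(), tf_name = character(),
                  anchor = character(), position = integer(),
                  strand = character(), score = numeric(),
                  pvalue = numeric(), stringsAsFactors = FALSE)
  tfs <- unique(vapply(pwms, `[[`, "", "tf_name"))
  enh_anchors <- anchors$anchor[anchors$enhancer]
  prom_anchors <- anchors$anchor[anchors$promoter]
  listA <- sort(unique(occ$tf_name[occ$anchor %in% enh_anchors]))
  listB <- character()
  for (tf in tfs) {
    pos <- unique(occ$anchor[occ$tf_name == tf & occ$anchor %in% prom_anchors])
    if (!length(pos)) next
    if (length(pos) == length(prom_anchors)) { listB <- c(listB, tf); next }
    pw_tf <- pwms[vapply(pwms, `[[`, "", "tf_name") == tf]
    best <- do.call(pmax, lapply(pw_tf, function(p)
      .bestScores(seqs[prom_anchors], p, cfg)))
    names(best) <- prom_anchors
    if (rankEnrichment(best, pos) < enrichAlpha) listB <- c(listB, tf)
  }
  listB <- sort(listB)
  list(list_A = listA, list_B = listB, final = sort(intersect(listA, listB)),
       occurrences = occ, anchors = anchors)
}

#' Optimize the scan p-value threshold across cell lines
#'
#' For each grid threshold, computes the mean pairwise Jaccard similarity of
#' the per-cell final TF sets, then picks the interior grid point with the
#' largest absolute discrete second difference of the Jaccard curve (the
#' inflection).  A flat curve falls back to `1e-10`.
#'
#' @param perCellTFLists named list: cell -> named list mapping threshold
#'   (as character of the numeric value) -> character vector of TFs.
#' @param grid descending vector of candidate thresholds (default
#'   `10^-(7:13)`).
#' @return the chosen threshold.
#' @export
optimizeThreshold <- function(perCellTFLists, grid = 10^-(7:13)) {
  if (length(grid) < 3L) stopf("threshold grid needs at least 3 points")
  if (length(perCellTFLists) < 2L) stopf("need TF lists for >= 2 cell lines")
  cells <- names(perCellTFLists)
  jac <- vapply(seq_along(grid), function(gi) {
    key <- format(grid[gi], scientific = TRUE)
    sets <- lapply(perCellTFLists, function(m) {
      kk <- format(as.numeric(names(m)), scientific = TRUE)
      m[[match(key, kk)]]
    })
    pairs <- utils::combn(length(cells), 2)
    mean(apply(pairs, 2, function(pr) {
      u <- union(sets[[pr[1]]], sets[[pr[2]]])
      if (!length(u)) return(1)
      length(intersect(sets[[pr[1]]], sets[[pr[2]]])) / length(u)
    }))
  }, numeric(1))
  d2 <- abs(jac[-c(1, 2)] - 2 * jac[-c(1, length(jac))] +
            jac[-c(length(jac) - 1, length(jac))])
  if (all(d2 < 1e-12)) return(1e-10)
  grid[which.max(d2) + 1L]
}
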