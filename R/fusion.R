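# The 3D view (PPI adjacency restricted to anchor-occupying TFs) and its
# fusion with the 1D co-localization matrix by similarity network fusion:
# cross-diffusion of two row-stochastic kernels through each other's
# K-nearest-neighbour backbone.

#' Fusion configuration
#'
#' @param K neighbourhood size for the local kernel; `NULL` picks
#'   `max(2, floor(n/10))` at fusion time.
#' @param t number of cross-diffusion iterations (default 20).
#' @param eps floor added to off-diagonal affinities so isolated rows stay
#'   stochastic (default 1e-3).
#' @param binarize_rule `"mean_offdiag"` or `"quantile"`.
#' @param binarize_q quantile used when `binarize_rule = "quantile"`.
#' @return a list of class `fusion_config`.
#' @export
fusionConfig <- function(K = NULL, t = 20L, eps = 1e-3,
                         binarize_rule = c("mean_offdiag", "quantile"),
                         binarize_q = 0.5) {
  stopifnot(is.null(K) || K >= 2, t >= 1, eps >= 0)
  structure(list(K = K, t = as.integer(t), eps = eps,
                 binarize_rule = match.arg(binarize_rule),
                 binarize_q = binarize_q),
            class = "fusion_config")
}

#' Build the binary 3D TF adjacency from PPI evidence
#'
#' An edge is kept iff both proteins are in the final TF list, the pair has a
#' STRING record with score strictly above 400, and a BioGRID record with
#' experimental evidence (intersection of both databases).
#'
#' @param finalTFs character vector of TF names (see [buildTFLists()]).
#' @param edges PPI edge table from [readEdgeTable()].
#' @param minScore STRING score cutoff, strict (default 400).
#' @return symmetric 0/1 matrix over `finalTFs`.
#' @export
build3DMatrix <- function(finalTFs, edges, minScore = 400) {
  if (!length(finalTFs)) stopf("empty final TF list")
  stringOK <- edges$source == "string_db" & !is.na(edges$score) &
    edges$score > minScore
  biogridOK <- edges$source == "biogrid" & !is.na(edges$evidence) &
    grepl("experimental", edges$evidence, ignore.case = TRUE)
  keyS <- unique(pairKey(edges$protein_a[stringOK], edges$protein_b[stringOK]))
  keyB <- unique(pairKey(edges$protein_a[biogridOK], edges$protein_b[biogridOK]))
  shared <- intersect(keyS, keyB)
  A <- matrix(0, length(finalTFs), length(finalTFs),
              dimnames = list(finalTFs, finalTFs))
  if (length(shared)) {
    parts <- do.call(rbind, strsplit(shared, "\t", fixed = TRUE))
    keep <- parts[, 1] %in% finalTFs & parts[, 2] %in% finalTFs
    for (i in which(keep)) {
      A[parts[i, 1], parts[i, 2]] <- 1
      A[parts[i, 2], parts[i, 1]] <- 1
    }
  }
  A
}

# Full transition kernel: off-diagonal mass 1/2 split proportionally, 1/2 on
# the diagonal (keeps updates well-conditioned); symmetrized before use.
.fullKernel <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# Row-normalized K-nearest-neighbour local kernel.  Neighbourhoods are
# value-defined (every entry tied with the K-th largest is kept) so the
# kernel is equivariant under node relabeling even with tied affinities.
.localKernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    wi <- W[i, ]
    wi[i] <- -Inf
    thr <- sort(wi, decreasing = TRUE)[K]
    nb <- which(wi >= thr)
    S[i, nb] <- W[i, nb]
  }
  rs <- rowSums(S)
  rs[rs == 0] <- 1
  S / rs
}

#' Fuse the 1D and 3D matrices by similarity network fusion
#'
#' The asymmetric 1D matrix is symmetrized by the arithmetic mean of
#' `s(a->b)` and `s(b->a)`; both affinity matrices get an off-diagonal
#' `eps` floor; each is converted to a full transition kernel and a
#' row-normalized K-NN local kernel; the two full kernels are then diffused
#' through each other's local kernel (`P1 <- S1 P2 S1'`, `P2 <- S2 P1 S2'`,
#' simultaneous update, symmetrize and renormalize each iteration) for `t`
#' iterations; the fused matrix is the average of the two diffused kernels,
#' re-symmetrized.
#'
#' @param m1d a [TFSimilarityMatrix] (or a symmetric affinity matrix).
#' @param m3d symmetric adjacency/affinity matrix with dimnames.
#' @param cfg a [fusionConfig()].
#' @return list with `fused` (symmetric non-negative matrix over the shared
#'   TFs) and `trajectory` (per-iteration symmetry/negativity audit).
#' @export
snfFuse <- function(m1d, m3d, cfg = fusionConfig()) {
  W1 <- if (is(m1d, "TFSimilarityMatrix")) {
    v <- similarityValues(m1d)
    diag(v) <- 0
    (v + t(v)) / 2
  } else (m1d + t(m1d)) / 2
  W2 <- (m3d + t(m3d)) / 2
  shared <- intersect(rownames(W1), rownames(W2))
  if (length(shared) < 3L) stopf("fewer than 3 TFs shared by the 1D and 3D matrices")
  W1 <- W1[shared, shared]
  W2 <- W2[shared, shared]
  if (any(!is.finite(W1)) || any(!is.finite(W2)))
    stopf("non-finite affinities")
  n <- length(shared)
  K <- if (is.null(cfg$K)) max(2L, n %/% 10L) else as.integer(cfg$K)
  if (n < K + 1L) stopf("need more TFs (%d) than neighbours K=%d", n, K)
  off <- matrix(cfg$eps, n, n); diag(off) <- 0
  W1 <- W1 + off; W2 <- W2 + off
  P1 <- .fullKernel(W1); P2 <- .fullKernel(W2)
  P1 <- (P1 + t(P1)) / 2; P2 <- (P2 + t(P2)) / 2
  S1 <- .localKernel(W1, K); S2 <- .localKernel(W2, K)
  audit <- data.frame(iter = integer(), symmetric = logical(),
                      nonneg = logical())
  for (it in seq_len(cfg$t)) {
    P1n <- S1 %*% P2 %*% t(S1)
    P2n <- S2 %*% P1 %*% t(S2)
    P1 <- (P1n + t(P1n)) / 2
    P2 <- (P2n + t(P2n)) / 2
    audit <- rbind(audit, data.frame(
      iter = it,
      symmetric = max(abs(P1 - t(P1)), abs(P2 - t(P2))) < 1e-10,
      nonneg = min(P1, P2) >= 0))
  }
  fused <- (P1 + P2) / 2
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(shared, shared)
  list(fused = fused, trajectory = audit)
}

#' Binarize the fused matrix and attach the directed overlay
#'
#' Undirected edges are pairs whose fused weight is strictly above the rule
#' threshold (mean off-diagonal weight by default).  The directed overlay
#' keeps, among those edges, the directions derived from 1D asymmetry; TFs
#' with no directed incident pair are absent from the directed view.
#'
#' @param fused symmetric fused weight matrix.
#' @param directed data.frame of directed pairs from [deriveDirections()].
#' @param cfg a [fusionConfig()].
#' @return a [TFNetwork].
#' @export
binarizeAndOrient <- function(fused, directed, cfg = fusionConfig()) {
  tfs <- rownames(fused)
  off <- fused[row(fused) != col(fused)]
  thr <- if (cfg$binarize_rule == "mean_offdiag") mean(off)
         else quantile(off, cfg$binarize_q, names = FALSE)
  n <- length(tfs)
  ij <- which(upper.tri(fused) & fused > thr, arr.ind = TRUE)
  if (!nrow(ij)) warnf("degenerate fused weights: no edge above threshold")
  edges <- data.frame(a = tfs[ij[, 1]], b = tfs[ij[, 2]],
                      weight = fused[ij], stringsAsFactors = FALSE)
  ekey <- pairKey(edges$a, edges$b)
  dkeep <- directed[directed$from %in% tfs & directed$to %in% tfs, , drop = FALSE]
  dkeep <- dkeep[pairKey(dkeep$from, dkeep$to) %in% ekey, , drop = FALSE]
  rownames(dkeep) <- NULL
  new("TFNetwork", tfNames = tfs, fusedWeights = fused, edges = edges,
      directedEdges = dkeep)
}
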