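# Independent oracles and shared fixtures, implemented without touching the
# package's own code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Brute-force placement p-value: enumerate every start position of a width-w
# interval inside [1, L] and count placements at distance <= the query's.
oraclePlacementP <- function(qs, qe, rs, re, L) {
  w <- qe - qs + 1
  gap <- function(x) {
    if (!length(rs)) return(Inf)
    min(pmax(0, pmax(rs - x - w, x - re - 1)))
  }
  xs <- seq_len(L - w + 1)
  d <- vapply(xs, gap, numeric(1))
  mean(d <= gap(qs))
}

# Exhaustive k-mer score distribution for a PWM under a uniform background,
# using the same pseudocount convention as the scanner.
oracleKmerScores <- function(mat, pseudocount = 0.1, bg = rep(0.25, 4)) {
  w <- nrow(mat)
  pm <- (mat + pseudocount * matrix(bg, w, 4, byrow = TRUE)) / (1 + pseudocount)
  lo <- log2(pm / matrix(bg, w, 4, byrow = TRUE))
  kmers <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(kmers, 1, function(k) sum(lo[cbind(seq_len(w), k)]))
  list(lo = lo, scores = scores, prob = rep(prod(bg)^0, nrow(kmers)) *
         apply(kmers, 1, function(k) prod(bg[k])))
}

# Brute-force maximal clique enumeration over all vertex subsets.
oracleMaxCliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  for (m in seq_len(2^n) - 1L) {
    v <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0)
    if (length(v) < 1L) next
    if (length(v) > 1L) {
      sub <- adj[v, v, drop = FALSE]
      if (!all(sub[upper.tri(sub)])) next
    }
    cliques[[length(cliques) + 1L]] <- v
  }
  # keep maximal only
  keep <- vapply(cliques, function(a)
    !any(vapply(cliques, function(b)
      length(b) > length(a) && all(a %in% b), logical(1))), logical(1))
  cliques[keep]
}

# Weight matrix for two unit triangles joined by one bridge edge (c-d).
twoTriangleGraph <- function() {
  W <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  e <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  for (k in seq_len(nrow(e))) {
    W[e[k, 1], e[k, 2]] <- 1
    W[e[k, 2], e[k, 1]] <- 1
  }
  W
}

# Literal implementation of the two SNF update equations (full kernel,
# K-NN local kernel, cross-diffusion, symmetrize, average).
oracleSNF <- function(W1, W2, K, t, eps = 1e-3) {
  n <- nrow(W1)
  off <- matrix(eps, n, n); diag(off) <- 0
  A1 <- (W1 + t(W1)) / 2 + off
  A2 <- (W2 + t(W2)) / 2 + off
  fullK <- function(W) {
    P <- W; diag(P) <- 0
    rs <- rowSums(P); rs[rs == 0] <- 1
    P <- P / (2 * rs); diag(P) <- 0.5
    (P + t(P)) / 2
  }
  locK <- function(W, K) {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      w <- W[i, ]; w[i] <- -Inf
      thr <- sort(w, decreasing = TRUE)[K]
      nb <- which(w >= thr)
      S[i, nb] <- W[i, nb]
    }
    S / rowSums(S)
  }
  P1 <- fullK(A1); P2 <- fullK(A2)
  S1 <- locK(A1, K); S2 <- locK(A2, K)
  for (it in seq_len(t)) {
    P1n <- S1 %*% P2 %*% t(S1)
    P2n <- S2 %*% P1 %*% t(S2)
    P1 <- (P1n + t(P1n)) / 2
    P2 <- (P2n + t(P2n)) / 2
  }
  f <- (P1 + P2) / 2
  (f + t(f)) / 2
}

# Parse an in-memory PPI table through the package's file reader.
readEdgeTableFromFrame <- function(df) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(readEdgeTable(f))
}

# Coordinate keys for loops, computed from accessors only.
.loopKeysForTest <- function(ls) {
  a <- anchorsA(ls); b <- anchorsB(ls)
  paste(seqnames(a), start(a), end(a), seqnames(b), start(b), end(b),
        sep = ":")
}

# A small landscape configuration used by motif/pipeline unit tests.
smallFixtureConfig <- function(seed = 1) {
  fixtureConfig(seed = seed, n_chroms = 2L, chrom_len = 200000L, n_tfs = 6L,
                n_loops = 16L, fraction_ep = 0.75,
                planted_levels = c(2L, 2L, 2L),
                planted_communities = list(sprintf("TF%02d", 1:3),
                                           sprintf("TF%02d", 4:6)),
                planted_cliques = list(sprintf("TF%02d", 1:3),
                                       sprintf("TF%02d", 4:6)),
                colocal_pairs = list(sprintf("TF%02d", 1:2)),
                n_sim_cliques = 6L, n_genes = 30L,
                planted_biclusters = list(list(cliques = 1:2, genes = 1:8),
                                          list(cliques = 4:5, genes = 15:24)))
}
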