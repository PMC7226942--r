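# Biclustering of the binary clique-by-gene regulation matrix with a sparse
# multiplicative factor model X ~ loadings %*% factors fitted by alternating
# proximal-gradient sweeps (soft-threshold shrinkage on both sides), and
# extraction of the superclique / gene-group bipartite graph.

#' Build the binary clique-by-gene regulation matrix
#'
#' @param cliques list of cliques (rows, in order).
#' @param geneSets list parallel to `cliques` of regulated-gene vectors.
#' @param geneUniverse character vector of all gene names (columns); must
#'   cover every regulated gene and contain no duplicates.
#' @return binary matrix, cliques in rows (named by clique key), genes in
#'   columns; all-zero columns are retained.
#' @export
buildCliqueGeneMatrix <- function(cliques, geneSets, geneUniverse) {
  if (anyDuplicated(geneUniverse)) stopf("duplicate gene names in universe")
  extra <- setdiff(unique(unlist(geneSets)), geneUniverse)
  if (length(extra)) stopf("regulated gene %s absent from universe", extra[1])
  M <- matrix(0L, length(cliques), length(geneUniverse),
              dimnames = list(vapply(cliques, .cliqueKey, ""), geneUniverse))
  for (i in seq_along(geneSets))
    M[i, geneSets[[i]]] <- 1L
  M
}

.softThreshold <- function(x, tau) sign(x) * pmax(abs(x) - tau, 0)

#' Fit the sparse factor bicluster model
#'
#' Fits `X ~ L %*% Z` with an L1 penalty on both `L` (loadings, clique
#' side) and `Z` (factors, gene side) by alternating proximal-gradient
#' updates; the penalized loss
#' `0.5 ||X - L Z||_F^2 + sparseness (|L|_1 + |Z|_1)` is non-increasing over
#' sweeps.  Initialization is the truncated SVD, so fits are fully
#' deterministic; the seed is recorded for provenance.  The matrix is fitted
#' uncentered: disjoint biclusters of a 0/1 incidence matrix are orthogonal
#' and separate exactly in the factor basis, whereas column centering adds a
#' shared background component that mixes them.
#'
#' @param X cliques-by-genes matrix (binary or real).
#' @param nFactors number of biclusters to fit (default 10).
#' @param maxIter maximum sweeps (default 10000).
#' @param sparseness L1 penalty weight (default 0.01).
#' @param seed RNG seed for the jitter.
#' @param tol relative loss-change convergence tolerance (default 1e-6).
#' @return a [BiclusterFit].
#' @export
fitBiclusters <- function(X, nFactors = 10L, maxIter = 10000L,
                          sparseness = 0.01, seed = 1L, tol = 1e-6) {
  if (!length(X)) stopf("empty matrix")
  nFactors <- as.integer(nFactors)
  if (nFactors > min(dim(X)))
    stopf("nFactors (%d) exceeds the smaller matrix dimension (%d)",
          nFactors, min(dim(X)))
  Xc <- X
  if (all(Xc == 0)) {
    L <- matrix(0, nrow(X), nFactors)
    Z <- matrix(0, nFactors, ncol(X))
    return(new("BiclusterFit", loadings = L, factors = Z,
               nFactors = nFactors, iterations = 1L, seed = as.numeric(seed),
               loss = 0))
  }
  sv <- svd(Xc, nu = nFactors, nv = nFactors)
  d <- sqrt(sv$d[seq_len(nFactors)])
  L <- sv$u %*% diag(d, nFactors)
  Z <- diag(d, nFactors) %*% t(sv$v)
  if (nFactors >= 2L) {
    # rotate the subspace toward sparse, block-aligned loadings in case
    # overlapping biclusters of similar energy mix in the SVD basis
    vr <- stats::varimax(L, normalize = FALSE)
    L <- L %*% vr$rotmat
    Z <- t(vr$rotmat) %*% Z
  }
  lossFun <- function(L, Z) {
    0.5 * sum((Xc - L %*% Z)^2) + sparseness * (sum(abs(L)) + sum(abs(Z)))
  }
  loss <- lossFun(L, Z)
  trace <- loss
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    # proximal gradient on L with Lipschitz step 1/||Z Z'||
    ZZt <- Z %*% t(Z)
    stepL <- 1 / max(sum(diag(ZZt)), 1e-12)
    G <- (L %*% Z - Xc) %*% t(Z)
    L <- .softThreshold(L - stepL * G, stepL * sparseness)
    LtL <- t(L) %*% L
    stepZ <- 1 / max(sum(diag(LtL)), 1e-12)
    G <- t(L) %*% (L %*% Z - Xc)
    Z <- .softThreshold(Z - stepZ * G, stepZ * sparseness)
    new_loss <- lossFun(L, Z)
    trace <- c(trace, new_loss)
    if (abs(loss - new_loss) < tol * max(loss, 1e-12)) { loss <- new_loss; break }
    loss <- new_loss
  }
  rownames(L) <- rownames(X)
  colnames(Z) <- colnames(X)
  new("BiclusterFit", loadings = L, factors = Z, nFactors = nFactors,
      iterations = it, seed = as.numeric(seed), loss = trace)
}

.membership <- function(v, q) {
  a <- abs(v)
  m <- max(a)
  if (m <= 1e-9) return(integer(0))
  thr <- max(quantile(a, q, names = FALSE), 0.5 * m)
  which(a >= thr - 1e-12)
}

#' Extract the superclique / gene-group bipartite graph
#'
#' Per factor, the superclique is the set of cliques with loading magnitude
#' above the membership threshold (the `membershipQuantile` quantile, floored
#' at half the factor's maximum so near-zero factors stay empty); gene
#' groups likewise on the gene side.  Edge weight between superclique `S_i`
#' and gene group `G_j` is the number of regulated (clique, gene) pairs
#' between them in the input matrix; zero-weight edges and empty groups are
#' dropped.
#'
#' @param fit a [BiclusterFit].
#' @param X the clique-by-gene matrix the model was fitted to.
#' @param membershipQuantile per-factor membership quantile (default 0.9).
#' @return list with `supercliques` (list of clique-index vectors),
#'   `gene_groups` (list of gene-index vectors) and `edges` (data.frame
#'   `superclique`, `gene_group`, `weight`).
#' @export
extractSupercliqueGraph <- function(fit, X, membershipQuantile = 0.9) {
  L <- biclusterLoadings(fit)
  Z <- biclusterFactors(fit)
  S <- lapply(seq_len(ncol(L)), function(f) .membership(L[, f],
                                                        membershipQuantile))
  G <- lapply(seq_len(nrow(Z)), function(f) .membership(Z[f, ],
                                                        membershipQuantile))
  keepS <- which(lengths(S) > 0)
  keepG <- which(lengths(G) > 0)
  edges <- data.frame(superclique = integer(), gene_group = integer(),
                      weight = numeric())
  for (i in keepS) for (j in keepG) {
    w <- sum(X[S[[i]], G[[j]], drop = FALSE])
    if (w >= 1)
      edges <- rbind(edges, data.frame(superclique = i, gene_group = j,
                                       weight = w))
  }
  list(supercliques = S[keepS], gene_groups = G[keepG], edges = edges,
       superclique_ids = keepS, gene_group_ids = keepG)
}
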