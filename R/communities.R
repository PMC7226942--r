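# Overlapping community detection on the fused TF network, by greedy growth
# of the cohesiveness objective f(V) = w_in / (w_in + w_bound + penalty |V|)
# from unused seeds, followed by overlap merging and density filtering.

.asWeightMatrix <- function(x) {
  if (is(x, "TFNetwork")) {
    tfs <- tfNames(x)
    W <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
    e <- networkEdges(x)
    if (nrow(e)) {
      W[cbind(e$a, e$b)] <- e$weight
      W[cbind(e$b, e$a)] <- e$weight
    }
    W
  } else {
    stopifnot(is.matrix(x), nrow(x) == ncol(x))
    if (is.null(rownames(x)))
      dimnames(x) <- list(paste0("n", seq_len(nrow(x))),
                          paste0("n", seq_len(nrow(x))))
    x
  }
}

#' Cohesiveness of a node subset
#'
#' `f(V) = w_in / (w_in + w_bound + penalty * |V|)` where `w_in` is the total
#' weight of edges inside `V` and `w_bound` the total weight of edges with
#' exactly one endpoint in `V`.
#'
#' @param graph a [TFNetwork] or symmetric weight matrix.
#' @param subset node names (or indices) of `V`.
#' @param penalty per-node penalty (default 2).
#' @return the cohesiveness score.
#' @export
cohesiveness <- function(graph, subset, penalty = 2) {
  W <- .asWeightMatrix(graph)
  if (is.character(subset)) {
    missing <- setdiff(subset, rownames(W))
    if (length(missing)) stopf("node not in graph: %s", missing[1])
    subset <- match(subset, rownames(W))
  }
  if (!length(subset)) stopf("subset must be non-empty")
  inV <- seq_len(nrow(W)) %in% subset
  w_in <- sum(W[inV, inV, drop = FALSE]) / 2
  w_bound <- sum(W[inV, !inV, drop = FALSE])
  denom <- w_in + w_bound + penalty * sum(inV)
  if (denom == 0) 0 else w_in / denom
}

.growSeed <- function(W, seed, penalty) {
  n <- nrow(W)
  inV <- rep(FALSE, n)
  inV[seed] <- TRUE
  repeat {
    cur <- cohesiveness(W, which(inV), penalty)
    boundary <- which(!inV & colSums(W[inV, , drop = FALSE] > 0) > 0)
    removable <- which(inV)
    best_gain <- 0; best_action <- NULL
    for (v in boundary) {
      inV[v] <- TRUE
      f <- cohesiveness(W, which(inV), penalty)
      inV[v] <- FALSE
      if (f - cur > best_gain + 1e-12) { best_gain <- f - cur; best_action <- c(1L, v) }
    }
    if (sum(inV) > 1L) {
      for (v in removable) {
        inV[v] <- FALSE
        f <- cohesiveness(W, which(inV), penalty)
        inV[v] <- TRUE
        if (f - cur > best_gain + 1e-12) { best_gain <- f - cur; best_action <- c(-1L, v) }
      }
    }
    if (is.null(best_action)) break
    inV[best_action[2]] <- best_action[1] > 0
  }
  which(inV)
}

#' Detect overlapping communities by cohesiveness-greedy growth
#'
#' Seeds are taken in order of decreasing (weighted) degree among nodes not
#' yet covered by a grown set.  Each seed grows by the single add/remove step
#' that most increases cohesiveness until no step improves it.  Grown sets
#' with overlap score `|A
#' intersect B|^2 / (|A| |B|) >= mergeOverlap` are merged (transitively), and
#' merged sets failing the size or edge-density floor are discarded.  Nodes
#' may belong to several communities.
#'
#' @param graph a [TFNetwork] or symmetric weight matrix.
#' @param penalty cohesiveness penalty (default 2).
#' @param mergeOverlap overlap-score threshold for merging (default 0.8).
#' @param minSize minimal community size (default 3).
#' @param minDensity minimal edge density (default 0.5).
#' @return list of communities, each a list with `members` (node names) and
#'   `cohesiveness`.
#' @export
findCommunities <- function(graph, penalty = 2, mergeOverlap = 0.8,
                            minSize = 3L, minDensity = 0.5) {
  W <- .asWeightMatrix(graph)
  n <- nrow(W)
  if (!n) return(list())
  deg <- rowSums(W)
  used <- rep(FALSE, n)
  grown <- list()
  for (seed in order(-deg, rownames(W))) {
    if (used[seed]) next
    V <- .growSeed(W, seed, penalty)
    used[V] <- TRUE
    grown[[length(grown) + 1L]] <- V
  }
  grown <- unique(lapply(grown, sort))
  # transitive merge of highly overlapping sets
  if (length(grown) > 1L) {
    repeat {
      merged <- FALSE
      for (i in seq_along(grown)) {
        for (j in seq_along(grown)) {
          if (j <= i) next
          ov <- length(intersect(grown[[i]], grown[[j]]))^2 /
            (length(grown[[i]]) * length(grown[[j]]))
          if (ov >= mergeOverlap) {
            grown[[i]] <- sort(union(grown[[i]], grown[[j]]))
            grown[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  out <- list()
  for (V in grown) {
    k <- length(V)
    if (k < minSize) next
    m <- sum(W[V, V] > 0) / 2
    if (m / (k * (k - 1) / 2) < minDensity) next
    out[[length(out) + 1L]] <- list(
      members = rownames(W)[V],
      cohesiveness = cohesiveness(W, V, penalty))
  }
  out
}
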