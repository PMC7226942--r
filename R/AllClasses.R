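#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   findOverlaps granges
#' @importFrom IRanges IRanges CharacterList
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

#' LoopSet: a set of chromatin loops for one cell line
#'
#' A `LoopSet` stores paired loop anchors as two parallel [GRanges] objects,
#' a per-loop inter-ligation tag count, and (once annotated) the chromatin
#' state labels overlapping each anchor.  Intra-chromosomal loops are kept in
#' canonical orientation (`anchorA` not after `anchorB` in genome order) so
#' that merging contact lists is order-insensitive.
#'
#' @slot cellLine single cell-line name.
#' @slot anchorA,anchorB parallel `GRanges` of loop anchors.
#' @slot tags integer vector of tag counts (evidence), one per loop.
#' @slot statesA,statesB `CharacterList` of chromatin-state labels per anchor
#'   (empty until [annotateAnchors()] is run).
#' @export
setClass("LoopSet",
  representation(
    cellLine = "character",
    anchorA = "GRanges",
    anchorB = "GRanges",
    tags = "integer",
    statesA = "CharacterList",
    statesB = "CharacterList"
  )
)

setValidity("LoopSet", function(object) {
  n <- length(object@anchorA)
  msgs <- character()
  if (length(object@cellLine) != 1L) msgs <- c(msgs, "cellLine must be a single string")
  if (length(object@anchorB) != n || length(object@tags) != n ||
      length(object@statesA) != n || length(object@statesB) != n)
    msgs <- c(msgs, "anchorA, anchorB, tags, statesA, statesB must be parallel")
  if (n > 0 && any(object@tags < 0L)) msgs <- c(msgs, "tags must be non-negative")
  if (n > 0) {
    same <- as.character(seqnames(object@anchorA)) ==
      as.character(seqnames(object@anchorB))
    bad <- same & (start(object@anchorA) > start(object@anchorB) |
      (start(object@anchorA) == start(object@anchorB) &
       end(object@anchorA) > end(object@anchorB)))
    if (any(bad)) msgs <- c(msgs, "intra-chromosomal loops must be in canonical orientation")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a LoopSet
#'
#' Anchors are put into canonical orientation automatically.
#'
#' @param cellLine cell-line name.
#' @param anchorA,anchorB `GRanges` of equal length.
#' @param tags integer tag counts (default all 0).
#' @param statesA,statesB optional `CharacterList` of state labels.
#' @return a `LoopSet`.
#' @export
LoopSet <- function(cellLine, anchorA, anchorB, tags = integer(length(anchorA)),
                    statesA = NULL, statesB = NULL) {
  n <- length(anchorA)
  if (is.null(statesA)) statesA <- CharacterList(rep(list(character()), n))
  if (is.null(statesB)) statesB <- CharacterList(rep(list(character()), n))
  same <- as.character(seqnames(anchorA)) == as.character(seqnames(anchorB))
  swap <- same & (start(anchorA) > start(anchorB) |
    (start(anchorA) == start(anchorB) & end(anchorA) > end(anchorB)))
  if (any(swap)) {
    tmpA <- anchorA[swap]; anchorA[swap] <- anchorB[swap]; anchorB[swap] <- tmpA
    tmpS <- statesA[swap]; statesA[swap] <- statesB[swap]; statesB[swap] <- tmpS
  }
  new("LoopSet", cellLine = cellLine, anchorA = anchorA, anchorB = anchorB,
      tags = as.integer(tags), statesA = statesA, statesB = statesB)
}

#' @describeIn LoopSet-class number of loops
#' @param x a `LoopSet`.
#' @export
setMethod("length", "LoopSet", function(x) length(x@anchorA))

#' Subset a LoopSet
#' @param x a `LoopSet`; @param i index; @param j,drop,... ignored.
#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
  new("LoopSet", cellLine = x@cellLine, anchorA = x@anchorA[i],
      anchorB = x@anchorB[i], tags = x@tags[i],
      statesA = x@statesA[i], statesB = x@statesB[i])
})

setMethod("show", "LoopSet", function(object) {
  cat(sprintf("LoopSet for %s with %d loop(s)\n", object@cellLine, length(object)))
  if (length(object)) {
    cat(sprintf("  tags: min %d, max %d; %d annotated anchor pair(s)\n",
                min(object@tags), max(object@tags),
                sum(lengths(object@statesA) + lengths(object@statesB) > 0)))
  }
})

#' @rdname LoopSet-accessors
#' @param x a `LoopSet`.
#' @return `cellLine`: the cell-line name; `anchorsA`/`anchorsB`: `GRanges`;
#'   `loopTags`: integer tag counts; `anchorStates`: list with elements `A`
#'   and `B` (`CharacterList`s of state labels).
#' @export
cellLine <- function(x) x@cellLine
#' @rdname LoopSet-accessors
#' @export
anchorsA <- function(x) x@anchorA
#' @rdname LoopSet-accessors
#' @export
anchorsB <- function(x) x@anchorB
#' @rdname LoopSet-accessors
#' @export
loopTags <- function(x) x@tags
#' @rdname LoopSet-accessors
#' @export
anchorStates <- function(x) list(A = x@statesA, B = x@statesB)

#' TFSimilarityMatrix: asymmetric TF-by-TF co-localization similarities
#'
#' Entry `[a, b]` is the fraction of TF `a`'s peaks whose placement p-value
#' against TF `b`'s peaks falls below `alpha` (query TF in rows, reference TF
#' in columns).  The diagonal is `NA`.
#'
#' @slot tfNames TF names, in matrix order.
#' @slot values numeric matrix in `[0, 1]` with `NA` diagonal.
#' @slot alpha per-peak significance cutoff used to build the matrix.
#' @export
setClass("TFSimilarityMatrix",
  representation(tfNames = "character", values = "matrix", alpha = "numeric"))

setValidity("TFSimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (nrow(v) != length(object@tfNames)) msgs <- c(msgs, "tfNames length mismatch")
  off <- v[row(v) != col(v)]
  if (length(off) && (any(is.na(off)) || any(off < 0 | off > 1)))
    msgs <- c(msgs, "off-diagonal similarities must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TFSimilarityMatrix-class construct from a matrix
#' @param values square numeric matrix with TF dimnames.
#' @param alpha significance cutoff recorded with the matrix.
#' @export
TFSimilarityMatrix <- function(values, alpha = 0.05) {
  tf <- rownames(values)
  if (is.null(tf)) stopf("similarity matrix needs TF dimnames")
  diag(values) <- NA_real_
  new("TFSimilarityMatrix", tfNames = tf, values = values, alpha = alpha)
}

setMethod("show", "TFSimilarityMatrix", function(object) {
  n <- length(object@tfNames)
  cat(sprintf("TFSimilarityMatrix: %d TFs (%d ordered pairs), alpha = %g\n",
              n, n * (n - 1L), object@alpha))
})

#' @rdname TFSimilarityMatrix-class
#' @param x a `TFSimilarityMatrix` (or `TFNetwork` for `tfNames`).
#' @export
similarityValues <- function(x) x@values

#' TF names of a network-like object
#' @param x a `TFSimilarityMatrix`, `TFNetwork` or `HierarchyFit`.
#' @export
tfNames <- function(x) x@tfNames

#' TFNetwork: the fused TF network
#'
#' Holds the symmetric fused weight matrix from similarity network fusion,
#' the binarized undirected edge list, and the directed-edge overlay carried
#' over from the asymmetry of the 1D similarity matrix.
#'
#' @slot tfNames TF names.
#' @slot fusedWeights symmetric non-negative matrix.
#' @slot edges data.frame with columns `a`, `b`, `weight` (undirected, a < b).
#' @slot directedEdges data.frame with columns `from`, `to`.
#' @export
setClass("TFNetwork",
  representation(tfNames = "character", fusedWeights = "matrix",
                 edges = "data.frame", directedEdges = "data.frame"))

setValidity("TFNetwork", function(object) {
  w <- object@fusedWeights
  msgs <- character()
  if (nrow(w) != ncol(w) || nrow(w) != length(object@tfNames))
    msgs <- c(msgs, "fusedWeights must be square over tfNames")
  if (length(w) && (any(!is.finite(w)) || any(w < 0)))
    msgs <- c(msgs, "fusedWeights must be finite and non-negative")
  if (length(w) && max(abs(w - t(w))) > 1e-8)
    msgs <- c(msgs, "fusedWeights must be symmetric")
  if (nrow(object@directedEdges)) {
    key <- pairKey(object@directedEdges$from, object@directedEdges$to)
    ekey <- pairKey(object@edges$a, object@edges$b)
    if (!all(key %in% ekey))
      msgs <- c(msgs, "directedEdges must be a subset of undirected edges")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TFNetwork", function(object) {
  cat(sprintf("TFNetwork: %d TFs, %d undirected edge(s), %d directed edge(s)\n",
              length(object@tfNames), nrow(object@edges),
              nrow(object@directedEdges)))
})

#' @rdname TFNetwork-class
#' @param x a `TFNetwork`.
#' @return `networkEdges`: undirected edge data.frame; `directedEdges`:
#'   directed overlay data.frame; `fusedWeights`: the fused weight matrix.
#' @export
networkEdges <- function(x) x@edges
#' @rdname TFNetwork-class
#' @export
directedEdges <- function(x) x@directedEdges
#' @rdname TFNetwork-class
#' @export
fusedWeights <- function(x) x@fusedWeights

#' HierarchyFit: inferred hierarchy of the directed TF network
#'
#' @slot levels named integer vector, TF -> level (1 = top).
#' @slot L selected number of levels.
#' @slot correctedScore permutation-corrected hierarchy score of the best state.
#' @slot levelProbabilities TF-by-level matrix of level frequencies across
#'   annealing restarts (rows sum to 1).
#' @slot scoresByL best corrected score for each candidate level count.
#' @export
setClass("HierarchyFit",
  representation(levels = "integer", L = "integer", correctedScore = "numeric",
                 levelProbabilities = "matrix", scoresByL = "numeric"))

setMethod("show", "HierarchyFit", function(object) {
  cat(sprintf("HierarchyFit: %d TFs in %d levels (corrected score %.3f)\n",
              length(object@levels), object@L, object@correctedScore))
  print(table(factor(object@levels, levels = seq_len(object@L))))
})

#' @rdname HierarchyFit-class
#' @param x a `HierarchyFit`.
#' @return `hierarchyLevels`: named integer vector of modal levels;
#'   `levelProbabilities`: restart-frequency matrix.
#' @export
hierarchyLevels <- function(x) x@levels
#' @rdname HierarchyFit-class
#' @export
levelProbabilities <- function(x) x@levelProbabilities

#' BiclusterFit: sparse factor model of the clique-by-gene matrix
#'
#' Factorizes the binary regulation matrix as `X ~ loadings %*% factors`,
#' with soft-threshold sparsity on both sides.
#'
#' @slot loadings cliques-by-F matrix.
#' @slot factors F-by-genes matrix.
#' @slot nFactors number of factors fitted.
#' @slot iterations sweeps actually run.
#' @slot seed seed recorded for provenance (the fit is deterministic).
#' @slot loss penalized loss per sweep (non-increasing).
#' @export
setClass("BiclusterFit",
  representation(loadings = "matrix", factors = "matrix", nFactors = "integer",
                 iterations = "integer", seed = "numeric", loss = "numeric"))

setMethod("show", "BiclusterFit", function(object) {
  cat(sprintf("BiclusterFit: %d x %d matrix, %d factors, %d sweep(s)\n",
              nrow(object@loadings), ncol(object@factors), object@nFactors,
              object@iterations))
})

#' @rdname BiclusterFit-class
#' @param x a `BiclusterFit`.
#' @return `biclusterLoadings`: clique-side matrix; `biclusterFactors`:
#'   gene-side matrix.
#' @export
biclusterLoadings <- function(x) x@loadings
#' @rdname BiclusterFit-class
#' @export
biclusterFactors <- function(x) x@factors
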