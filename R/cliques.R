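# Maximal clique enumeration (Bron-Kerbosch with pivoting), clique mapping
# onto hierarchy levels and communities, cross-cell-line clique comparison,
# regulated-gene assignment, pattern classification, and expression
# coherence of clique co-membership.

.bronKerbosch <- function(adj) {
  # adj: logical adjacency matrix; returns list of integer vectors
  out <- list()
  bk <- function(Rset, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- Rset
      return(invisible())
    }
    # pivot: vertex of P union X maximizing neighbours in P
    cand <- c(P, X)
    u <- cand[which.max(vapply(cand, function(v) sum(adj[v, P]), 0L))]
    for (v in P[!adj[u, P]]) {
      nv <- which(adj[v, ])
      bk(c(Rset, v), intersect(P, nv), intersect(X, nv))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(nrow(adj)), integer(0))
  out
}

#' Enumerate maximal cliques of the TF network
#'
#' Bron-Kerbosch with pivoting over the undirected edge view, filtered to the
#' configured size range and sorted by size then lexicographic member order.
#'
#' @param graph a [TFNetwork] or symmetric weight matrix (non-zero = edge).
#' @param minSize,maxSize clique size bounds (defaults 3 and 10).
#' @param cellLine optional cell-line tag attached to each clique.
#' @return list of cliques, each a list with `members` (sorted TF names) and
#'   `cell_line`.
#' @export
maximalCliques <- function(graph, minSize = 3L, maxSize = 10L,
                           cellLine = NA_character_) {
  W <- .asWeightMatrix(graph)
  adj <- W > 0
  diag(adj) <- FALSE
  cl <- .bronKerbosch(adj)
  cl <- cl[lengths(cl) >= minSize & lengths(cl) <= maxSize]
  members <- lapply(cl, function(v) sort(rownames(W)[v]))
  ord <- order(lengths(members),
               vapply(members, paste, "", collapse = "|"))
  lapply(members[ord], function(m) list(members = m, cell_line = cellLine))
}

#' Map cliques to hierarchy levels and communities
#'
#' @param cliques list of cliques from [maximalCliques()].
#' @param fit a [HierarchyFit].
#' @param communities list of communities from [findCommunities()].
#' @return data.frame with per-clique `size`, `levels_spanned` (number of
#'   distinct levels among members) and `communities_touched` (number of
#'   communities containing at least one member).
#' @export
mapCliqueSpans <- function(cliques, fit, communities) {
  lv <- hierarchyLevels(fit)
  data.frame(
    clique = vapply(cliques, function(c) paste(c$members, collapse = ","), ""),
    size = lengths(lapply(cliques, `[[`, "members")),
    levels_spanned = vapply(cliques, function(c) {
      missing <- setdiff(c$members, names(lv))
      if (length(missing)) stopf("clique member %s missing from hierarchy",
                                 missing[1])
      length(unique(lv[c$members]))
    }, 0L),
    communities_touched = vapply(cliques, function(c)
      sum(vapply(communities, function(cm)
        length(intersect(cm$members, c$members)) > 0, logical(1))), 0L),
    stringsAsFactors = FALSE)
}

.cliqueKey <- function(c) paste(sort(c$members), collapse = ",")

#' Partition cliques across cell lines (Venn regions)
#'
#' Clique identity is exact TF-member-set equality.  Every distinct clique is
#' assigned to exactly one region: the set of cell lines it occurs in.
#'
#' @param perCellCliques named list: cell line -> list of cliques.
#' @return list with `regions` (named counts, region = cells joined by `+`),
#'   `shared_by_all` and per-cell `specific` counts.
#' @export
compareCliquesAcrossCells <- function(perCellCliques) {
  if (length(perCellCliques) < 2L) stopf("need cliques for >= 2 cell lines")
  cells <- names(perCellCliques)
  keysets <- lapply(perCellCliques, function(cl)
    unique(vapply(cl, .cliqueKey, "")))
  allkeys <- unique(unlist(keysets))
  membership <- vapply(allkeys, function(k)
    paste(cells[vapply(keysets, function(ks) k %in% ks, logical(1))],
          collapse = "+"), "")
  regions <- table(membership)
  specific <- setNames(vapply(cells, function(cl)
    sum(membership == cl), 0L), cells)
  list(regions = as.list(regions),
       shared_by_all = sum(membership == paste(cells, collapse = "+")),
       specific = as.list(specific))
}

#' Genes regulated by a clique
#'
#' A gene is regulated by a clique when some enhancer-promoter loop has a
#' promoter-class anchor overlapping the gene's TSS and every clique TF has
#' at least one motif occurrence in that loop's promoter or enhancer anchor.
#'
#' @param clique a clique (list with `members`) or character vector of TFs.
#' @param epLoops the annotated EP [LoopSet] the occurrences were computed on.
#' @param occurrences occurrence table from [buildTFLists()].
#' @param tss `GRanges` of TSS positions with gene names in the `label`
#'   column.
#' @return sorted character vector of regulated gene names.
#' @export
regulatedGenes <- function(clique, epLoops, occurrences, tss) {
  members <- if (is.list(clique)) clique$members else clique
  if (!length(tss)) stopf("empty TSS annotation")
  if (is.null(tss$label)) stopf("TSS annotation lacks gene names in label")
  anchors <- .anchorTable(epLoops)
  genes <- character()
  hitsA <- findOverlaps(anchorsA(epLoops), tss, ignore.strand = TRUE)
  hitsB <- findOverlaps(anchorsB(epLoops), tss, ignore.strand = TRUE)
  tssByLoop <- function(hits) split(tss$label[subjectHits(hits)],
                                    queryHits(hits))
  tssA <- tssByLoop(hitsA); tssB <- tssByLoop(hitsB)
  for (i in seq_len(length(epLoops))) {
    ai <- anchors[anchors$loop == i & anchors$side == "A", ]
    bi <- anchors[anchors$loop == i & anchors$side == "B", ]
    occTF <- unique(occurrences$tf_name[occurrences$anchor %in%
                                          c(ai$anchor, bi$anchor)])
    if (!all(members %in% occTF)) next
    # orientations: promoter anchor must overlap a TSS
    if (ai$enhancer && bi$promoter) {
      g <- tssB[[as.character(i)]]
      if (!is.null(g)) genes <- c(genes, g)
    }
    if (bi$enhancer && ai$promoter) {
      g <- tssA[[as.character(i)]]
      if (!is.null(g)) genes <- c(genes, g)
    }
  }
  sort(unique(genes))
}

#' Classify shared-clique patterns across cell lines
#'
#' For each pair of cell lines and each clique pairing: identical member
#' sets with regulated-gene Jaccard at least `geneJaccard` are
#' "same-clique-same-genes"; identical member sets below it are
#' "same-clique-different-genes"; non-identical member sets sharing at least
#' `minSharedTFs` TFs are "partial-TF-sharing".
#'
#' @param perCellCliques named list: cell -> list of cliques.
#' @param perCellGenes named list: cell -> named list mapping clique key
#'   (comma-joined sorted members) -> character vector of regulated genes.
#' @param geneJaccard Jaccard cutoff for "nearly the same genes" (default 0.9).
#' @param minSharedTFs minimum shared TFs for partial sharing (default 3).
#' @return data.frame with columns `cell_a`, `cell_b`, `clique_a`,
#'   `clique_b`, `pattern`.
#' @export
classifyCliquePatterns <- function(perCellCliques, perCellGenes,
                                   geneJaccard = 0.9, minSharedTFs = 3L) {
  cells <- names(perCellCliques)
  if (length(cells) < 2L) stopf("need >= 2 cell lines")
  rows <- list()
  for (i in seq_along(cells)) for (j in seq_along(cells)) {
    if (j <= i) next
    ca <- perCellCliques[[i]]; cb <- perCellCliques[[j]]
    for (a in ca) for (b in cb) {
      ka <- .cliqueKey(a); kb <- .cliqueKey(b)
      shared <- length(intersect(a$members, b$members))
      if (ka == kb) {
        ga <- perCellGenes[[i]][[ka]]; gb <- perCellGenes[[j]][[kb]]
        u <- union(ga, gb)
        jac <- if (!length(u)) 1 else length(intersect(ga, gb)) / length(u)
        pattern <- if (jac >= geneJaccard) "same-clique-same-genes"
                   else "same-clique-different-genes"
      } else if (shared >= minSharedTFs) {
        pattern <- "partial-TF-sharing"
      } else next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_a = cells[i], cell_b = cells[j], clique_a = ka, clique_b = kb,
        pattern = pattern, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cell_a = character(), cell_b = character(),
                      clique_a = character(), clique_b = character(),
                      pattern = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Expression coherence of clique co-membership
#'
#' Computes Spearman rank correlations of expression for every TF pair that
#' co-occurs in at least one clique ("within") and every TF pair that never
#' does ("between"), then tests within > between with a one-sided Wilcoxon
#' rank-sum test (exact for small samples without ties, tie-corrected normal
#' approximation otherwise).  The pair universe is every row of the
#' expression table.  TFs with constant expression are excluded with a
#' warning.
#'
#' @param cliques list of cliques.
#' @param expression genes-by-samples matrix with TF rows (one per network
#'   TF).
#' @return list with `within`, `between` (correlation vectors) and
#'   `wilcoxon_p`.
#' @export
expressionCoherence <- function(cliques, expression) {
  members <- sort(unique(unlist(lapply(cliques, `[[`, "members"))))
  missing <- setdiff(members, rownames(expression))
  if (length(missing)) stopf("TF %s missing from expression table", missing[1])
  tfs <- rownames(expression)
  if (ncol(expression) < 3L) stopf("need >= 3 expression samples")
  const <- tfs[apply(expression[tfs, , drop = FALSE], 1, function(x)
    length(unique(x)) == 1L)]
  if (length(const)) {
    warnf("excluding %d TF(s) with constant expression", length(const))
    tfs <- setdiff(tfs, const)
  }
  co <- outer(tfs, tfs, Vectorize(function(a, b)
    any(vapply(cliques, function(c)
      all(c(a, b) %in% c$members), logical(1)))))
  within <- numeric(); between <- numeric()
  for (i in seq_along(tfs)) for (j in seq_along(tfs)) {
    if (j <= i) next
    rho <- cor(expression[tfs[i], ], expression[tfs[j], ],
               method = "spearman")
    if (co[i, j]) within <- c(within, rho) else between <- c(between, rho)
  }
  p <- if (length(within) && length(between))
    suppressWarnings(wilcox.test(within, between,
                                 alternative = "greater")$p.value)
  else NA_real_
  list(within = within, between = between, wilcoxon_p = p)
}
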