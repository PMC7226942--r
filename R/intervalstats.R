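# Asymmetric 1D TF x TF co-localization similarity.
#
# For a query peak q and a reference peak set R on the same chromosome, the
# significance of proximity is the fraction of all possible placements of an
# interval of |q|'s length inside the domain whose distance to R is at most
# the observed distance of q.  Small p means q sits unusually close to R.
# The per-TF similarity s(a -> b) is the fraction of a's peaks with p < alpha
# against b's peaks.  The matrix is asymmetric because each TF is the query
# set exactly once against every other TF as reference.

# Distance between a placement [x, x+w-1] and a reference [rs, re] (1-based
# closed): max(0, rs - x - w, x - re - 1).  Overlapping or adjacent = 0.

.gapToRefs <- function(qs, qe, rs, re) {
  # min gap from a single query [qs, qe] to refs sorted by rs; Inf if none
  if (!length(rs)) return(Inf)
  cre <- cummax(re)
  idx <- findInterval(qe, rs)
  gl <- if (idx >= 1L) qs - cre[idx] - 1 else Inf
  gr <- if (idx < length(rs)) rs[idx + 1L] - qe - 1 else Inf
  max(0, min(gl, gr))
}

# Count placements of width w with distance <= d to refs, restricted to
# positions where the placement fits inside one domain segment.
.placementCount <- function(w, d, rs, re, seg_lo, seg_hi) {
  lo <- rs - w - d
  hi <- re + d + 1
  # union of [lo, hi] (lo is sorted because rs is)
  chi <- cummax(hi)
  brk <- which(lo[-1] > chi[-length(chi)] + 0)
  ustart <- lo[c(1L, brk + 1L)]
  uend <- chi[c(brk, length(chi))]
  # valid start positions in segment s: [seg_lo, seg_hi - w + 1]
  vhi <- seg_hi - w + 1
  total <- 0
  for (k in seq_along(seg_lo)) {
    if (vhi[k] < seg_lo[k]) next
    ov <- pmin(uend, vhi[k]) - pmax(ustart, seg_lo[k]) + 1
    total <- total + sum(ov[ov > 0])
  }
  total
}

# p-values for queries (qs, qe parallel vectors) on one chromosome against
# refs (rs, re sorted by rs) within domain segments (seg_lo, seg_hi).
.placementPvalues <- function(qs, qe, rs, re, seg_lo, seg_hi) {
  w <- qe - qs + 1
  p <- numeric(length(qs))
  seg_len <- seg_hi - seg_lo + 1
  for (i in seq_along(qs)) {
    Ti <- sum(pmax(0L, seg_len - w[i] + 1))
    if (Ti <= 0)
      stopf("query of width %d longer than every domain segment", w[i])
    if (!length(rs)) { p[i] <- 1; next }
    d <- .gapToRefs(qs[i], qe[i], rs, re)
    if (!is.finite(d)) { p[i] <- 1; next }
    p[i] <- .placementCount(w[i], d, rs, re, seg_lo, seg_hi) / Ti
  }
  p
}

.splitByChrom <- function(gr) {
  chrom <- as.character(seqnames(gr))
  s <- start(gr); e <- end(gr)
  out <- list()
  for (ch in unique(chrom)) {
    k <- chrom == ch
    o <- order(s[k], e[k])
    out[[ch]] <- list(s = s[k][o], e = e[k][o])
  }
  out
}

#' Distance from a query interval to the nearest reference interval
#'
#' Zero if the query overlaps (or directly abuts) any reference on its
#' chromosome, otherwise the minimal base gap; `Inf` when the chromosome has
#' no references.
#'
#' @param q a `GRanges` of query intervals.
#' @param refs a `GRanges` of reference intervals.
#' @return numeric vector of distances, one per query.
#' @export
intervalDistance <- function(q, refs) {
  byc <- .splitByChrom(refs)
  chrom <- as.character(seqnames(q))
  vapply(seq_along(q), function(i) {
    r <- byc[[chrom[i]]]
    if (is.null(r)) return(Inf)
    .gapToRefs(start(q)[i], end(q)[i], r$s, r$e)
  }, numeric(1))
}

.domainSegments <- function(domain, peaksets = NULL) {
  if (is.null(domain)) {
    # default: full chromosome extents implied by the peak sets
    allp <- do.call(c, lapply(unname(peaksets), granges))
    chrom <- as.character(seqnames(allp))
    segs <- lapply(split(end(allp), chrom), function(e) {
      list(lo = 1L, hi = max(e))
    })
    return(segs)
  }
  red <- IRanges::reduce(granges(domain), ignore.strand = TRUE)
  chrom <- as.character(seqnames(red))
  out <- list()
  for (ch in unique(chrom)) {
    k <- chrom == ch
    out[[ch]] <- list(lo = start(red)[k], hi = end(red)[k])
  }
  out
}

#' Placement p-value of a query interval against a reference set
#'
#' The p-value is the fraction of start positions inside the domain at which
#' an interval of the query's width lies at distance no greater than the
#' query's observed distance to the reference set.  Queries on chromosomes
#' with no references get p = 1.
#'
#' @param q a `GRanges` of query intervals.
#' @param refs a `GRanges` of reference intervals.
#' @param domain a `GRanges` of domain segments; `NULL` uses the full
#'   chromosome extents implied by `refs` and `q`.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
intervalstatsPvalue <- function(q, refs, domain = NULL) {
  segs <- .domainSegments(domain, list(q = q, refs = refs))
  byc <- .splitByChrom(refs)
  chrom <- as.character(seqnames(q))
  out <- numeric(length(q))
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    sg <- segs[[ch]]
    if (is.null(sg)) stopf("domain does not cover chromosome %s", ch)
    r <- byc[[ch]]
    out[k] <- .placementPvalues(start(q)[k], end(q)[k],
                                if (is.null(r)) integer() else r$s,
                                if (is.null(r)) integer() else r$e,
                                sg$lo, sg$hi)
  }
  out
}

#' Build the asymmetric 1D TF similarity matrix
#'
#' For every ordered TF pair (a, b), computes the fraction of a's peaks whose
#' placement p-value against b's peaks is below `alpha`.  Each TF is the
#' query set exactly once against each other TF as reference.
#'
#' @param peaksets named list of `GRanges`, one peak set per TF.
#' @param domain optional `GRanges` restricting valid placements; `NULL`
#'   uses full chromosome extents implied by the peaks.
#' @param alpha per-peak significance cutoff (default 0.05, strict `<`).
#' @return a [TFSimilarityMatrix].
#' @export
build1DMatrix <- function(peaksets, domain = NULL, alpha = 0.05) {
  if (length(peaksets) < 2L) stopf("need at least 2 peak sets")
  if (is.null(names(peaksets)) || anyDuplicated(names(peaksets)))
    stopf("peaksets must be uniquely named by TF")
  empty <- names(peaksets)[lengths(peaksets) == 0]
  if (length(empty)) stopf("empty peak set for TF %s", empty[1])
  tfs <- names(peaksets)
  n <- length(tfs)
  segs <- .domainSegments(domain, peaksets)
  byc <- lapply(peaksets, .splitByChrom)
  # precompute query tuples per TF per chromosome
  S <- matrix(NA_real_, n, n, dimnames = list(tfs, tfs))
  for (a in seq_len(n)) {
    qa <- byc[[a]]
    nq_total <- sum(vapply(qa, function(z) length(z$s), 0L))
    for (b in seq_len(n)) {
      if (a == b) next
      rb <- byc[[b]]
      sig <- 0L
      for (ch in names(qa)) {
        sg <- segs[[ch]]
        if (is.null(sg)) stopf("domain does not cover chromosome %s", ch)
        r <- rb[[ch]]
        p <- .placementPvalues(qa[[ch]]$s, qa[[ch]]$e,
                               if (is.null(r)) integer() else r$s,
                               if (is.null(r)) integer() else r$e,
                               sg$lo, sg$hi)
        sig <- sig + sum(p < alpha)
      }
      S[a, b] <- sig / nq_total
    }
  }
  TFSimilarityMatrix(S, alpha = alpha)
}

#' Derive directed TF pairs from 1D matrix asymmetry
#'
#' Emits `a -> b` when `s(a -> b) > s(b -> a)`; pairs with exactly equal
#' similarities carry no direction and are omitted.
#'
#' @param S a [TFSimilarityMatrix].
#' @return data.frame with columns `from`, `to`.
#' @export
deriveDirections <- function(S) {
  v <- similarityValues(S)
  tfs <- tfNames(S)
  n <- length(tfs)
  from <- character(); to <- character()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (v[i, j] > v[j, i]) { from <- c(from, tfs[i]); to <- c(to, tfs[j]) }
      else if (v[j, i] > v[i, j]) { from <- c(from, tfs[j]); to <- c(to, tfs[i]) }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}
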