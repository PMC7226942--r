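# Turning raw contact lists into a cell's final enhancer-promoter loop set:
# state annotation of anchors, the tag-count / concurrent-annotation filter,
# and merging of contact lists from different antibodies.

#' Annotate loop anchors with chromatin-state labels
#'
#' Each anchor receives the set of labels of all state segments overlapping
#' it by at least one base.  Anchors on chromosomes absent from the state
#' segmentation get an empty label set (with one warning per call).
#'
#' @param loops a [LoopSet].
#' @param states `GRanges` with a `label` metadata column (e.g. from a BED4
#'   chromHMM segmentation).
#' @return the annotated `LoopSet`.
#' @export
annotateAnchors <- function(loops, states) {
  if (is.null(states$label)) stopf("state segmentation lacks a label column")
  lab <- function(anchors) {
    # seqlevel mismatches are handled by the explicit warning below
    hits <- suppressWarnings(findOverlaps(anchors, states,
                                          ignore.strand = TRUE))
    out <- rep(list(character()), length(anchors))
    if (length(hits)) {
      sp <- split(states$label[subjectHits(hits)], queryHits(hits))
      out[as.integer(names(sp))] <- lapply(sp, function(x) unique(sort(x)))
    }
    out
  }
  chroms <- unique(as.character(seqnames(states)))
  missing <- setdiff(unique(c(as.character(seqnames(anchorsA(loops))),
                              as.character(seqnames(anchorsB(loops))))), chroms)
  if (length(missing))
    warnf("no state annotation for chromosome(s): %s",
          paste(missing, collapse = ", "))
  loops@statesA <- CharacterList(lab(anchorsA(loops)))
  loops@statesB <- CharacterList(lab(anchorsB(loops)))
  loops
}

.hasClass <- function(states, classes) {
  vapply(as.list(states), function(s)
    any(vapply(classes, function(cl) any(grepl(cl, s, ignore.case = TRUE)),
               logical(1))), logical(1))
}

#' Filter to enhancer-promoter loops with sufficient tag support
#'
#' Keeps a loop iff its tag count exceeds `minTags` (strictly) and one anchor
#' carries an enhancer-class label while the other carries a promoter-class
#' label (either orientation).  Class membership is by case-insensitive
#' substring match against the configured vocabularies, since chromatin-state
#' names differ between segmentations.
#'
#' @param loops an annotated [LoopSet].
#' @param minTags keep loops with `tags > minTags` (default 5).
#' @param enhancerClasses,promoterClasses label substrings defining the
#'   enhancer and promoter state classes.
#' @return the filtered `LoopSet`.
#' @export
filterEPLoops <- function(loops, minTags = 5L,
                          enhancerClasses = c("Enhancer"),
                          promoterClasses = c("Promoter", "TSS")) {
  st <- anchorStates(loops)
  enhA <- .hasClass(st$A, enhancerClasses)
  enhB <- .hasClass(st$B, enhancerClasses)
  promA <- .hasClass(st$A, promoterClasses)
  promB <- .hasClass(st$B, promoterClasses)
  keep <- loopTags(loops) > minTags & ((enhA & promB) | (enhB & promA))
  loops[keep]
}

.loopKeys <- function(loops) {
  a <- anchorsA(loops); b <- anchorsB(loops)
  paste(as.character(seqnames(a)), start(a), end(a),
        as.character(seqnames(b)), start(b), end(b), sep = ":")
}

#' Merge contact lists from multiple antibodies
#'
#' Loops with identical anchor coordinate pairs are collapsed to a single
#' record whose tag count is the sum of the merged tags and whose state label
#' sets are unioned.  All inputs must come from the same cell line.
#'
#' @param ... two or more [LoopSet] objects (or a single list of them).
#' @return the merged `LoopSet`.
#' @export
mergeContacts <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "LoopSet"))
    sets <- sets[[1]]
  cells <- unique(vapply(sets, cellLine, ""))
  if (length(cells) != 1L)
    stopf("cannot merge loop sets from different cell lines: %s",
          paste(cells, collapse = ", "))
  aA <- do.call(c, lapply(sets, anchorsA))
  aB <- do.call(c, lapply(sets, anchorsB))
  tags <- do.call(c, lapply(sets, loopTags))
  stA <- do.call(c, lapply(sets, function(s) as.list(anchorStates(s)$A)))
  stB <- do.call(c, lapply(sets, function(s) as.list(anchorStates(s)$B)))
  pooled <- LoopSet(cells, aA, aB, tags, CharacterList(stA), CharacterList(stB))
  key <- .loopKeys(pooled)
  grp <- split(seq_along(key), key)
  first <- vapply(grp, `[[`, 0L, 1L)
  ord <- sort(first)  # preserve first-appearance order
  idx <- match(key[ord], names(grp))
  out <- pooled[ord]
  out@tags <- unname(vapply(grp[idx], function(g) sum(pooled@tags[g]), 0L))
  out@statesA <- CharacterList(lapply(grp[idx], function(g)
    unique(sort(unlist(as.list(pooled@statesA[g]))))))
  out@statesB <- CharacterList(lapply(grp[idx], function(g)
    unique(sort(unlist(as.list(pooled@statesB[g]))))))
  validObject(out)
  out
}
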