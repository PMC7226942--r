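# Readers/writers for every external format the pipeline touches.  All files
# use BED conventions (0-based half-open); in memory everything is GRanges
# (1-based closed), converted at the file boundary.

#' Read a BED3/BED4/BED6 file into a GRanges interval set
#'
#' Column 4, when present, is stored as the `label` metadata column (chromatin
#' state, TF or gene name depending on the file); column 6 as strand.
#'
#' @param path path to a tab-separated BED file.
#' @param name name recorded for the set (default: file base name).
#' @return a `GRanges` sorted by chromosome and start, with a `label`
#'   metadata column and a `name` attribute in `metadata()`.
#' @export
readIntervals <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines)) {
    gr <- GRanges()
    S4Vectors::metadata(gr)$name <- name
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stopf("%s: line %d has fewer than 3 columns", path, which(ncols < 3L)[1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) stopf("%s: line %d has non-integer coordinates", path, bad[1])
  inv <- which(start0 >= end0)
  if (length(inv))
    stopf("%s: line %d has start >= end (%d >= %d)", path, inv[1],
          start0[inv[1]], end0[inv[1]])
  label <- ifelse(ncols >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  strand <- ifelse(ncols >= 6L, vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                label = label)
  # lexicographic chromosome order regardless of file appearance order
  gr <- gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Write a GRanges to BED (0-based half-open)
#'
#' Emits BED4 when a `label` column is present (BED6 with strand), else BED3.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
writeIntervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  has_label <- !is.null(gr$label) && !all(is.na(gr$label))
  has_strand <- any(as.character(strand(gr)) != "*")
  if (has_label || has_strand) df$label <- ifelse(is.na(gr$label), ".", gr$label)
  if (has_strand) {
    df$score <- 0L
    df$strand <- as.character(strand(gr))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE-like contact list into a LoopSet
#'
#' Expects at least 7 tab-separated columns: `chromA startA endA chromB
#' startB endB tags`.  Anchor pairs are stored in canonical genome order.
#'
#' @param path path to the contact list.
#' @param cellLine cell-line name for the resulting [LoopSet].
#' @return a `LoopSet`.
#' @export
readLoops <- function(path, cellLine = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(LoopSet(cellLine, GRanges(), GRanges()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 7L))
    stopf("%s: line %d has fewer than 7 columns", path,
          which(lengths(fields) < 7L)[1])
  m <- t(vapply(fields, function(f) f[1:7], character(7)))
  coords <- suppressWarnings(apply(m[, c(2, 3, 5, 6), drop = FALSE], 2,
                                   as.integer))
  coords <- matrix(coords, ncol = 4)
  tags <- suppressWarnings(as.integer(m[, 7]))
  if (any(is.na(coords)))
    stopf("%s: line %d has non-integer anchor coordinates", path,
          which(rowSums(is.na(coords)) > 0)[1])
  if (any(is.na(tags)))
    stopf("%s: line %d has a non-integer tag count", path, which(is.na(tags))[1])
  if (any(coords[, 1] >= coords[, 2]) || any(coords[, 3] >= coords[, 4]))
    stopf("%s: anchor with start >= end", path)
  a <- GRanges(m[, 1], IRanges(coords[, 1] + 1L, coords[, 2]))
  b <- GRanges(m[, 4], IRanges(coords[, 3] + 1L, coords[, 4]))
  LoopSet(cellLine, a, b, tags)
}

#' Write a LoopSet to BEDPE (+ tag column)
#'
#' Appends the per-anchor state annotations as comma-joined columns 8 and 9
#' when present.
#'
#' @param loops a [LoopSet].
#' @param path output path.
#' @export
writeLoops <- function(loops, path) {
  a <- anchorsA(loops); b <- anchorsB(loops)
  df <- data.frame(
    chromA = as.character(seqnames(a)), startA = start(a) - 1L, endA = end(a),
    chromB = as.character(seqnames(b)), startB = start(b) - 1L, endB = end(b),
    tags = loopTags(loops))
  st <- anchorStates(loops)
  if (any(lengths(st$A) + lengths(st$B) > 0)) {
    df$statesA <- vapply(as.list(st$A), function(s)
      if (length(s)) paste(sort(s), collapse = ",") else ".", "")
    df$statesB <- vapply(as.list(st$B), function(s)
      if (length(s)) paste(sort(s), collapse = ",") else ".", "")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a MEME-format motif file
#'
#' Parses minimal MEME motif format: a version header, optional background
#' line, and `MOTIF` blocks each followed by a `letter-probability matrix`
#' section.  Rows off unit mass by at most `1e-4` are renormalized; larger
#' deviations are an error.
#'
#' @param path path to the `.meme` file.
#' @return a list of PWM records, each a list with `motif_id`, `tf_name`, and
#'   `matrix` (width x 4, columns A, C, G, T).
#' @export
readPWMs <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- trimws(readLines(path))
  motif_idx <- which(startsWith(lines, "MOTIF"))
  if (!length(motif_idx)) stopf("%s: no MOTIF blocks found", path)
  out <- vector("list", length(motif_idx))
  bounds <- c(motif_idx, length(lines) + 1L)
  for (i in seq_along(motif_idx)) {
    header <- strsplit(lines[motif_idx[i]], "\\s+")[[1]]
    motif_id <- if (length(header) >= 2) header[2] else stopf("MOTIF line lacks an id")
    tf_name <- if (length(header) >= 3) header[3] else motif_id
    block <- lines[(motif_idx[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- grep("^[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}$", block, value = TRUE)
    if (!length(rows)) stopf("motif %s: no letter-probability rows", motif_id)
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    colnames(mat) <- c("A", "C", "G", "T")
    if (any(mat < 0)) stopf("motif %s: negative probability", motif_id)
    rs <- rowSums(mat)
    if (any(abs(rs - 1) > 1e-4))
      stopf("motif %s: row %d sums to %.6f (tolerance 1e-4)", motif_id,
            which(abs(rs - 1) > 1e-4)[1], rs[which(abs(rs - 1) > 1e-4)[1]])
    mat <- mat / rs
    out[[i]] <- list(motif_id = motif_id, tf_name = tf_name, matrix = mat)
  }
  names(out) <- vapply(out, `[[`, "", "motif_id")
  out
}

#' Write PWM records to MEME motif format
#'
#' @param pwms a list of PWM records as returned by [readPWMs()].
#' @param path output path.
#' @param background background base frequencies (A, C, G, T).
#' @export
writePWMs <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies", sprintf(
                 "A %.5f C %.5f G %.5f T %.5f", background[1], background[2],
                 background[3], background[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s %s", p$motif_id, p$tf_name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1, function(r) paste(sprintf("%.6f", r),
                                                    collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a protein-protein interaction edge table
#'
#' Expects a header with columns `protein_a`, `protein_b`, `source`,
#' `score_or_evidence`.  Sources must be `string_db` (numeric score) or
#' `biogrid` (evidence string).  Edges are canonicalized (`protein_a` the
#' lexicographically smaller name), exact duplicates collapsed, and
#' self-edges dropped with a warning reporting how many.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `protein_a`, `protein_b`, `source`,
#'   `score` (NA for biogrid rows), `evidence` (NA for string_db rows).
#' @export
readEdgeTable <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "")
  need <- c("protein_a", "protein_b", "source", "score_or_evidence")
  if (!all(need %in% names(df)))
    stopf("%s: header must name columns %s", path, paste(need, collapse = ", "))
  unknown <- setdiff(unique(df$source), c("string_db", "biogrid"))
  if (length(unknown)) stopf("unknown PPI source token: %s", unknown[1])
  self <- df$protein_a == df$protein_b
  if (any(self)) {
    warnf("dropped %d self-edge(s)", sum(self))
    df <- df[!self, , drop = FALSE]
  }
  swap <- df$protein_a > df$protein_b
  tmp <- df$protein_a[swap]
  df$protein_a[swap] <- df$protein_b[swap]
  df$protein_b[swap] <- tmp
  df <- unique(df)
  out <- data.frame(
    protein_a = df$protein_a, protein_b = df$protein_b, source = df$source,
    score = ifelse(df$source == "string_db",
                   suppressWarnings(as.numeric(df$score_or_evidence)), NA_real_),
    evidence = ifelse(df$source == "biogrid", df$score_or_evidence,
                      NA_character_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read an expression table (genes x samples, header row)
#'
#' @param path TSV with gene identifiers in the first column.
#' @return numeric matrix, genes in rows.
#' @export
readExpression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Write an expression table
#' @param mat genes-by-samples numeric matrix.
#' @param path output path.
#' @export
writeExpression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
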