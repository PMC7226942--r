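test_that("uninformative PWMs produce no significant occurrences", {
  pwm <- list(motif_id = "U", tf_name = "U",
              matrix = matrix(0.25, 2, 4,
                              dimnames = list(NULL, c("A", "C", "G", "T"))))
  occ <- scanPWM(c(s = "ACGTACGTACGT"), pwm, scanConfig())
  expect_equal(nrow(occ), 0)
  # at a permissive threshold every window appears with p = 1
  occ2 <- scanPWM(c(s = "ACGT"), pwm, scanConfig(p_threshold = 0.9999))
  expect_true(all(abs(occ2$pvalue - 1) < 1e-12))
  expect_true(all(abs(occ2$score) < 1e-9))
})

test_that("count-derived width-2 PWM matches dinucleotide enumeration", {
  # counts A:(100,0), C:(0,100) with pseudocount: consensus AC
  m <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0), 2, 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- list(motif_id = "AC", tf_name = "AC", matrix = m)
  cfg <- scanConfig(p_threshold = 0.9999)
  occ <- scanPWM(c(x = "ACAC"), pwm, cfg)
  oracle <- oracleKmerScores(m)
  fwd <- occ[occ$strand == "+", ]
  # the two consensus AC windows pass; the CA window is the worst dinucleotide
  # (enumeration p = 1) and falls above the threshold
  expect_setequal(fwd$position, c(1L, 3L))
  sc_ca <- oracle$lo[1, 2] + oracle$lo[2, 1]
  expect_equal(sum(oracle$prob[oracle$scores >= sc_ca]), 1)
  for (r in seq_len(nrow(fwd))) {
    win <- substr("ACAC", fwd$position[r], fwd$position[r] + 1)
    k <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
    sc <- sum(oracle$lo[cbind(1:2, k)])
    expect_equal(fwd$score[r], sc, tolerance = 2e-3)
    p_lo <- sum(oracle$prob[oracle$scores >= sc - 2e-3])
    p_hi <- sum(oracle$prob[oracle$scores >= sc + 2e-3])
    expect_lte(fwd$pvalue[r], p_lo + 1e-12)
    expect_gte(fwd$pvalue[r], p_hi - 1e-12)
  }
})

test_that("exact scan p-values match k-mer enumeration for random PWMs", {
  set.seed(31)
  cfg <- scanConfig(p_threshold = 0.9999)
  for (trial in 1:12) {
    w <- sample(2:5, 1)
    m <- matrix(rexp(4 * w), w, 4)
    m <- m / rowSums(m)
    colnames(m) <- c("A", "C", "G", "T")
    pwm <- list(motif_id = "m", tf_name = "t", matrix = m)
    oracle <- oracleKmerScores(m)
    s <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
    occ <- scanPWM(setNames(s, "x"), pwm, cfg)
    occ <- occ[occ$strand == "+", ]
    for (r in seq_len(nrow(occ))) {
      win <- substr(s, occ$position[r], occ$position[r] + w - 1)
      k <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
      sc <- sum(oracle$lo[cbind(seq_len(w), k)])
      bound <- w * 1e-3
      p_lo <- sum(oracle$prob[oracle$scores >= sc - bound])
      p_hi <- sum(oracle$prob[oracle$scores >= sc + bound])
      expect_lte(occ$pvalue[r], p_lo + 1e-12)
      expect_gte(occ$pvalue[r], p_hi - 1e-12)
    }
  }
})

test_that("lowering the threshold never adds occurrences", {
  set.seed(5)
  m <- matrix(rexp(16), 4, 4)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  pwm <- list(motif_id = "m", tf_name = "t", matrix = m)
  s <- c(x = paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = ""))
  thresholds <- c(0.5, 0.1, 0.01, 1e-3)
  sets <- lapply(thresholds, function(th)
    with(scanPWM(s, pwm, scanConfig(p_threshold = th)),
         paste(anchor, position, strand)))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("windows containing N are skipped, both strands are scanned", {
  m <- matrix(c(0.97, 0.01, 0.01, 0.01,
                0.01, 0.97, 0.01, 0.01), 2, 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- list(motif_id = "AC", tf_name = "AC", matrix = m)
  cfg <- scanConfig(p_threshold = 0.2)
  occ <- scanPWM(c(x = "ACNGT"), pwm, cfg)
  expect_false(any(occ$position %in% 2:3))   # N windows skipped
  expect_true(any(occ$strand == "+" & occ$position == 1))
  expect_true(any(occ$strand == "-" & occ$position == 4))  # GT = revcomp(AC)
})

test_that("minimal hypergeometric enrichment matches the cutoff oracle", {
  aff <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(rankEnrichment(aff, c("a", "b")), 1 / 6)
  expect_equal(rankEnrichment(aff, names(aff)), 1)
  expect_equal(rankEnrichment(aff, c("c", "d")), 1)
  expect_error(rankEnrichment(aff, c("a", "zz")), "subset")

  # exhaustive oracle over every cutoff on random instances
  set.seed(17)
  for (i in 1:20) {
    N <- sample(5:12, 1)
    aff <- setNames(sample(100, N), paste0("x", seq_len(N)))
    pos <- sample(names(aff), sample.int(N - 1, 1))
    ks <- seq_len(N)
    ord <- order(-aff, names(aff))
    x <- cumsum(names(aff)[ord] %in% pos)
    oracle <- min(phyper(x - 1, length(pos), N - length(pos), ks,
                         lower.tail = FALSE))
    expect_equal(rankEnrichment(aff, pos), oracle)
  }
})

test_that("TF lists reflect planted anchor occupancy", {
  cfg <- smallFixtureConfig()
  ls <- simulateRegulatoryLandscape(cfg)
  cellb <- ls$cells$cellA
  loops <- filterEPLoops(annotateAnchors(cellb$loops, cellb$states))
  tl <- buildTFLists(loops, cellb$genome, ls$pwms, scanConfig())
  # every TF is implanted in enhancer and promoter anchors of some loops
  expect_setequal(tl$list_A, cfg$tfs)
  expect_true(all(tl$final %in% tl$list_A))
  expect_true(all(tl$final %in% tl$list_B))
  # a TF implanted in both anchor classes must reach the final list
  expect_true("TF01" %in% tl$final)

  # empty PWM collection -> empty lists
  tl0 <- buildTFLists(loops, cellb$genome, list(), scanConfig())
  expect_length(tl0$final, 0)
  expect_length(tl0$list_A, 0)
})

test_that("enhancer-only implants reach list A but not the final list", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("T", 4000), collapse = "")))
  # loop with enhancer anchor [101,400], promoter anchor [2101,2400]
  loops <- LoopSet("K", GRanges("chr1", IRanges(101, 400)),
                   GRanges("chr1", IRanges(2101, 2400)), 10L)
  states <- GRanges("chr1", IRanges(c(51, 2051), c(450, 2450)),
                    label = c("Enhancer", "Promoter"))
  loops <- filterEPLoops(annotateAnchors(loops, states))
  cons <- paste(rep("ACGTAC", 3), collapse = "")  # width 18
  Biostrings::subseq(genome[[1]], 151, 150 + nchar(cons)) <- Biostrings::DNAString(cons)
  m <- matrix(0.01, nchar(cons), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(nchar(cons)),
          match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")))] <- 0.97
  pwm <- list(M1 = list(motif_id = "M1", tf_name = "TFE", matrix = m))
  tl <- buildTFLists(loops, genome, pwm, scanConfig())
  expect_equal(tl$list_A, "TFE")
  expect_length(tl$final, 0)
})

test_that("threshold optimization picks the inflection of the Jaccard curve", {
  grid <- 10^-(7:13)
  # per-cell TF sets whose pairwise Jaccard traces exactly the curve
  # (0.9, 0.9, 0.9, 0.6, 0.3, 0.28, 0.27); the largest |second difference|
  # (0.3, by finite differences done by hand) sits at the third grid point
  mkSets <- function(shared, union) {
    a <- c(paste0("s", seq_len(shared)),
           paste0("a", seq_len(union - shared)))
    b <- paste0("s", seq_len(shared))
    list(a = a, b = b)
  }
  frac <- list(c(9, 10), c(9, 10), c(9, 10), c(6, 10), c(3, 10),
               c(28, 100), c(27, 100))
  sets <- lapply(frac, function(f) mkSets(f[1], f[2]))
  jc <- vapply(sets, function(s)
    length(intersect(s$a, s$b)) / length(union(s$a, s$b)), numeric(1))
  expect_equal(jc, c(0.9, 0.9, 0.9, 0.6, 0.3, 0.28, 0.27))
  lists <- list(
    cellA = setNames(lapply(sets, `[[`, "a"), grid),
    cellB = setNames(lapply(sets, `[[`, "b"), grid))
  expect_equal(optimizeThreshold(lists, grid), grid[3])

  # constant curve falls back to 1e-10
  const <- list(
    cellA = setNames(lapply(grid, function(g) c("x", "y")), grid),
    cellB = setNames(lapply(grid, function(g) c("x", "y")), grid))
  expect_equal(optimizeThreshold(const, grid), 1e-10)
  expect_error(optimizeThreshold(const, grid[1:2]), "at least 3")
})
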