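adjFromEdges <- function(n, edges) {
  W <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (k in seq_len(nrow(edges))) {
    W[edges[k, 1], edges[k, 2]] <- 1
    W[edges[k, 2], edges[k, 1]] <- 1
  }
  W
}

test_that("maximal cliques match hand cases and size bounds", {
  K4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(K4) <- 0
  cl <- maximalCliques(K4)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, letters[1:4])

  # a 5-cycle has only edge cliques, all below the size-3 floor
  C5 <- adjFromEdges(5, cbind(1:5, c(2:5, 1)))
  expect_length(maximalCliques(C5), 0)
  expect_length(maximalCliques(C5, minSize = 2), 5)

  # maxSize filters out oversized cliques
  K5 <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(K5) <- 0
  expect_length(maximalCliques(K5, minSize = 3, maxSize = 4), 0)
})

test_that("Bron-Kerbosch equals brute-force subset enumeration", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    A <- matrix(rbinom(n * n, 1, runif(1, 0.2, 0.7)), n, n)
    A <- pmax(A, t(A)) * 1
    diag(A) <- 0
    dimnames(A) <- list(paste0("v", 1:n), paste0("v", 1:n))
    mine <- lapply(maximalCliques(A, minSize = 1, maxSize = n), `[[`,
                   "members")
    oracle <- lapply(oracleMaxCliques(A > 0), function(v) sort(rownames(A)[v]))
    key <- function(l) sort(vapply(l, paste, "", collapse = ","))
    expect_equal(key(mine), key(oracle))
  }
})

test_that("Bron-Kerbosch agrees with igraph's enumeration", {
  library(igraph)
  set.seed(29)
  for (i in 1:15) {
    n <- sample(6:14, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A <- pmax(A, t(A)) * 1
    diag(A) <- 0
    dimnames(A) <- list(paste0("v", 1:n), paste0("v", 1:n))
    mine <- lapply(maximalCliques(A, minSize = 1, maxSize = n), `[[`,
                   "members")
    g <- graph_from_adjacency_matrix(A, mode = "undirected")
    theirs <- lapply(max_cliques(g), function(v) sort(names(v)))
    key <- function(l) sort(vapply(l, paste, "", collapse = ","))
    expect_equal(key(mine), key(theirs))
  }
})

test_that("clique spans count distinct levels and touched communities", {
  cliques <- list(list(members = c("a", "b", "c"), cell_line = "K"),
                  list(members = c("a", "d", "e"), cell_line = "K"))
  fit <- new("HierarchyFit",
             levels = c(a = 2L, b = 2L, c = 2L, d = 1L, e = 5L),
             L = 5L, correctedScore = 1,
             levelProbabilities = matrix(0.2, 5, 5), scoresByL = c(`5` = 1))
  comms <- list(list(members = c("a", "b"), cohesiveness = 1),
                list(members = c("b", "c"), cohesiveness = 1),
                list(members = c("e"), cohesiveness = 1))
  sp <- mapCliqueSpans(cliques, fit, comms)
  expect_equal(sp$levels_spanned, c(1L, 3L))
  expect_equal(sp$communities_touched, c(2L, 2L))
  bad <- list(list(members = c("a", "zz"), cell_line = "K"))
  expect_error(mapCliqueSpans(bad, fit, comms), "missing from hierarchy")
})

test_that("cross-cell clique comparison partitions by exact member equality", {
  cl <- function(...) lapply(list(...), function(m)
    list(members = m, cell_line = NA))
  same <- list(K = cl(c("a", "b", "c")), M = cl(c("c", "b", "a")))
  v <- compareCliquesAcrossCells(same)
  expect_equal(v$shared_by_all, 1)
  expect_equal(unlist(v$specific), c(K = 0L, M = 0L))

  disj <- list(K = cl(c("a", "b", "c")), M = cl(c("d", "e", "f")))
  v2 <- compareCliquesAcrossCells(disj)
  expect_equal(v2$shared_by_all, 0)
  expect_equal(unlist(v2$specific), c(K = 1L, M = 1L))

  three <- list(K = cl(c("a", "b", "c"), c("k1", "k2", "k3")),
                M = cl(c("a", "b", "c"), c("m1", "m2", "m3")),
                H = cl(c("a", "b", "c"), c("h1", "h2", "h3")))
  v3 <- compareCliquesAcrossCells(three)
  expect_equal(v3$shared_by_all, 1)
  expect_equal(unlist(v3$specific), c(K = 1L, M = 1L, H = 1L))
  expect_error(compareCliquesAcrossCells(three["K"]), ">= 2")
})

mkRegFixture <- function() {
  # one EP loop: enhancer anchor A [101,300], promoter anchor B [1101,1300]
  loops <- LoopSet("K", GRanges("chr1", IRanges(101, 300)),
                   GRanges("chr1", IRanges(1101, 1300)), 10L,
                   statesA = CharacterList(list("Enhancer")),
                   statesB = CharacterList(list("Promoter")))
  occ <- data.frame(
    motif_id = c("m1", "m2", "m3"),
    tf_name = c("TF1", "TF2", "TF3"),
    anchor = c("L1_A", "L1_B", "L1_A"),
    position = 1L, strand = "+", score = 10, pvalue = 1e-12,
    stringsAsFactors = FALSE)
  tss <- GRanges("chr1", IRanges(1200, 1200), label = "geneX")
  list(loops = loops, occ = occ, tss = tss)
}

test_that("regulated genes require TSS overlap and full clique occupancy", {
  fx <- mkRegFixture()
  expect_equal(regulatedGenes(c("TF1", "TF2", "TF3"), fx$loops, fx$occ,
                              fx$tss), "geneX")
  # one clique TF missing from both anchors -> nothing regulated
  expect_equal(regulatedGenes(c("TF1", "TF4"), fx$loops, fx$occ, fx$tss),
               character(0))
  # promoter anchor overlapping no TSS -> nothing regulated
  farTSS <- GRanges("chr1", IRanges(5000, 5000), label = "geneY")
  expect_equal(regulatedGenes(c("TF1", "TF2"), fx$loops, fx$occ, farTSS),
               character(0))
  expect_error(regulatedGenes(c("TF1"), fx$loops, fx$occ, GRanges()),
               "empty TSS")
})

test_that("regulated gene sets are antitone in clique size", {
  cfg <- smallFixtureConfig()
  ls <- simulateRegulatoryLandscape(cfg)
  cell <- ls$cells$cellA
  loops <- filterEPLoops(annotateAnchors(cell$loops, cell$states))
  tl <- buildTFLists(loops, cell$genome, ls$pwms, scanConfig())
  base <- c("TF01", "TF02")
  g2 <- regulatedGenes(base, loops, tl$occurrences, cell$tss)
  g3 <- regulatedGenes(c(base, "TF03"), loops, tl$occurrences, cell$tss)
  g4 <- regulatedGenes(c(base, "TF03", "TF04"), loops, tl$occurrences,
                       cell$tss)
  expect_true(all(g3 %in% g2))
  expect_true(all(g4 %in% g3))
})

test_that("clique patterns classify gene-set agreement and partial sharing", {
  cl <- function(m) list(members = m, cell_line = NA)
  cliques <- list(K = list(cl(c("a", "b", "c")), cl(c("a", "b", "d", "e"))),
                  M = list(cl(c("a", "b", "c")), cl(c("a", "b", "d", "f"))))
  genes <- list(
    K = list("a,b,c" = c("g1", "g2"), "a,b,d,e" = c("g3")),
    M = list("a,b,c" = c("g1", "g2"), "a,b,d,f" = c("g9")))
  pat <- classifyCliquePatterns(cliques, genes)
  expect_equal(
    pat$pattern[pat$clique_a == "a,b,c" & pat$clique_b == "a,b,c"],
    "same-clique-same-genes")
  expect_equal(
    pat$pattern[pat$clique_a == "a,b,d,e" & pat$clique_b == "a,b,d,f"],
    "partial-TF-sharing")

  genes$M$`a,b,c` <- c("h1", "h2")  # disjoint genes, same clique
  pat2 <- classifyCliquePatterns(cliques, genes)
  expect_equal(
    pat2$pattern[pat2$clique_a == "a,b,c" & pat2$clique_b == "a,b,c"],
    "same-clique-different-genes")
})

test_that("expression coherence recovers correlations and the exact Wilcoxon", {
  x <- rbind(TFa = 1:3, TFb = 1:3, TFc = 3:1)
  cl <- list(list(members = c("TFa", "TFb"), cell_line = NA))
  res <- expressionCoherence(cl, x)
  expect_equal(res$within, 1)
  expect_equal(res$between, c(-1, -1))

  # one-sided exact Wilcoxon on {0.9, 0.8} vs {0.1, 0.2} equals 1/6 by
  # enumeration of all 6 rank arrangements
  expect_equal(wilcox.test(c(0.9, 0.8), c(0.1, 0.2),
                           alternative = "greater")$p.value, 1 / 6)

  # constant expression rows are excluded with a warning
  y <- rbind(TFa = 1:4, TFb = c(2, 1, 4, 3), TFc = rep(5, 4),
             TFd = c(4, 3, 2, 1))
  cl2 <- list(list(members = c("TFa", "TFb"), cell_line = NA),
              list(members = c("TFc", "TFd"), cell_line = NA))
  expect_warning(res2 <- expressionCoherence(cl2, y), "constant expression")
  expect_length(res2$within, 1)
  expect_error(expressionCoherence(cl, x[, 1:2]), ">= 3 expression samples")
  expect_error(
    expressionCoherence(list(list(members = c("TFa", "ZZ"))), x),
    "missing from expression")
})
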