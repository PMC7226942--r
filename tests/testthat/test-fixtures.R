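test_that("fixture configuration validates planted structure", {
  expect_s3_class(fixtureConfig(), "fixture_config")
  expect_error(fixtureConfig(fraction_ep = 1.2), "fraction_ep")
  expect_error(fixtureConfig(planted_levels = c(4L, 4L)), "sum to n_tfs")
  expect_error(fixtureConfig(planted_cliques = list(c("TF01", "TF12"))),
               "not inside any planted community")
  expect_error(fixtureConfig(planted_biclusters =
                               list(list(cliques = 1:99, genes = 1:2))),
               "exceed")
  expect_error(
    simulateRegulatoryLandscape(fixtureConfig(chrom_len = 20000L,
                                              n_loops = 60L)),
    "genome too small")
})

test_that("landscapes are deterministic under a fixed seed", {
  cfg <- smallFixtureConfig(seed = 5)
  l1 <- simulateRegulatoryLandscape(cfg)
  l2 <- simulateRegulatoryLandscape(cfg)
  expect_identical(l1$consensus, l2$consensus)
  expect_identical(as.character(l1$cells$cellA$genome),
                   as.character(l2$cells$cellA$genome))
  expect_identical(start(l1$peaksets$TF01), start(l2$peaksets$TF01))
  n1 <- simulateNetworkTruth(cfg)
  n2 <- simulateNetworkTruth(cfg)
  expect_identical(n1$directed, n2$directed)
  expect_identical(n1$expression, n2$expression)

  # and written bundles are byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeFixtureBundle(l1, n1, d1)
  writeFixtureBundle(l2, n2, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
})

test_that("every EP loop joins an Enhancer anchor to a TSS-bearing Promoter anchor", {
  cfg <- smallFixtureConfig(seed = 2)
  ls <- simulateRegulatoryLandscape(cfg)
  for (cell in ls$cells) {
    ann <- annotateAnchors(cell$loops, cell$states)
    ep <- filterEPLoops(ann, minTags = 5)
    n_ep <- round(cfg$fraction_ep * cfg$n_loops)
    expect_equal(length(ep), n_ep)
    st <- anchorStates(ep)
    expect_true(all(vapply(as.list(st$A), function(s) "Enhancer" %in% s,
                           logical(1))))
    expect_true(all(vapply(as.list(st$B), function(s) "Promoter" %in% s,
                           logical(1))))
    hits <- findOverlaps(anchorsB(ep), cell$tss)
    expect_setequal(queryHits(hits), seq_len(n_ep))
  }
})

test_that("fraction_ep = 1 makes every loop survive the EP filter", {
  cfg <- fixtureConfig(seed = 4, n_chroms = 2L, chrom_len = 200000L,
                       n_tfs = 4L, n_loops = 12L, fraction_ep = 1,
                       planted_levels = c(2L, 2L),
                       planted_communities = list(c("TF01", "TF02"),
                                                  c("TF03", "TF04")),
                       planted_cliques = list(c("TF01", "TF02")),
                       colocal_pairs = list(c("TF01", "TF02")),
                       n_sim_cliques = 4L, n_genes = 10L,
                       planted_biclusters = list(list(cliques = 1:2,
                                                      genes = 1:4)))
  ls <- simulateRegulatoryLandscape(cfg)
  cell <- ls$cells$cellA
  ep <- filterEPLoops(annotateAnchors(cell$loops, cell$states))
  expect_equal(length(ep), length(cell$loops))
})

test_that("implanted consensus motifs are present in the planted anchors", {
  cfg <- smallFixtureConfig(seed = 3)
  ls <- simulateRegulatoryLandscape(cfg)
  cell <- ls$cells$cellA
  n_ep <- round(cfg$fraction_ep * cfg$n_loops)
  for (tf in cfg$tfs[1:3]) {
    planted <- which(cell$present_enh[, tf])
    for (i in planted[1]) {
      a <- anchorsA(cell$loops)[i]
      seqA <- as.character(Biostrings::subseq(
        cell$genome[[as.character(seqnames(a))]], start(a), end(a)))
      expect_true(grepl(ls$consensus[[tf]], seqA, fixed = TRUE))
    }
  }
})

test_that("planted co-localizing pairs share peak midpoints within 50 bp", {
  cfg <- fixtureConfig(seed = 6)
  ls <- simulateRegulatoryLandscape(cfg)
  pr <- cfg$colocal_pairs[[1]]
  a <- ls$peaksets[[pr[1]]]
  b <- ls$peaksets[[pr[2]]]
  midsA <- (start(a) + end(a)) / 2
  midsB <- (start(b) + end(b)) / 2
  share <- mean(vapply(seq_along(a), function(i) {
    same <- as.character(seqnames(b)) == as.character(seqnames(a))[i]
    any(abs(midsB[same] - midsA[i]) <= 50)
  }, logical(1)))
  expect_gte(share, 0.8)
})

test_that("network truth plants levels, cliques and correlated expression", {
  cfg <- fixtureConfig(seed = 8)
  nt <- simulateNetworkTruth(cfg)
  lv <- unlist(nt$truth$levels)
  down <- mean(lv[nt$directed$from] < lv[nt$directed$to])
  expect_gte(down, 0.95)
  expect_setequal(names(lv), cfg$tfs)
  expect_true(all(c(nt$directed$from, nt$directed$to) %in% cfg$tfs))

  # surviving PPI edges contain each planted clique as a complete subgraph,
  # and no outside node extends it
  edges <- readEdgeTableFromFrame(nt$ppi_table)
  A <- build3DMatrix(cfg$tfs, edges)
  for (cl in cfg$planted_cliques) {
    sub <- A[cl, cl]
    expect_true(all(sub[upper.tri(sub)] == 1))
    outside <- setdiff(cfg$tfs, cl)
    expect_false(any(apply(A[cl, outside, drop = FALSE], 2,
                           function(x) all(x == 1))))
  }

  # expression blocks correlate within planted cliques
  for (cl in cfg$planted_cliques) {
    cors <- cor(t(nt$expression[cl, ]), method = "spearman")
    expect_gte(min(cors[upper.tri(cors)]), 0.7)
  }

  # zero noise makes within-clique expression rank-identical
  nt0 <- simulateNetworkTruth(fixtureConfig(seed = 8,
                                            expression_noise_sd = 0))
  for (cl in cfg$planted_cliques) {
    cors <- cor(t(nt0$expression[cl, ]), method = "spearman")
    expect_equal(min(cors), 1)
  }
})
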