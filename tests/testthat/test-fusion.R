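ppiTable <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_a = r[[1]], protein_b = r[[2]], source = r[[3]],
               score = if (r[[3]] == "string_db") as.numeric(r[[4]]) else NA,
               evidence = if (r[[3]] == "biogrid") r[[4]] else NA,
               stringsAsFactors = FALSE)))
}

test_that("3D adjacency requires both databases and a strict score cutoff", {
  tfs <- c("CTCF", "RAD21", "SMC3")
  e <- ppiTable(list("CTCF", "RAD21", "string_db", 450),
                list("CTCF", "RAD21", "biogrid", "experimental"),
                list("CTCF", "SMC3", "string_db", 400),
                list("CTCF", "SMC3", "biogrid", "experimental"),
                list("RAD21", "SMC3", "string_db", 800))
  A <- build3DMatrix(tfs, e)
  expect_equal(A["CTCF", "RAD21"], 1)   # both sources, score > 400
  expect_equal(A["CTCF", "SMC3"], 0)    # score exactly 400 fails (strict)
  expect_equal(A["RAD21", "SMC3"], 0)   # STRING only
  expect_true(isSymmetric(A))
  expect_error(build3DMatrix(character(), e), "empty")
})

test_that("edges outside the final TF list are excluded", {
  e <- ppiTable(list("A", "B", "string_db", 900),
                list("A", "B", "biogrid", "experimental"))
  A <- build3DMatrix(c("A", "C"), e)
  expect_equal(sum(A), 0)
})

test_that("SNF equals the literal update-equation oracle on a 3x3 pair", {
  W1 <- matrix(c(0, .8, .2, .8, 0, .5, .2, .5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W2 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3, dimnames = dimnames(W1))
  got <- snfFuse(W1, W2, fusionConfig(K = 2, t = 1))
  expect_equal(got$fused, oracleSNF(W1, W2, K = 2, t = 1),
               ignore_attr = TRUE, tolerance = 1e-12)
  # and over several iterations
  got5 <- snfFuse(W1, W2, fusionConfig(K = 2, t = 5))
  expect_equal(got5$fused, oracleSNF(W1, W2, K = 2, t = 5),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("fused kernels stay symmetric and non-negative at every iteration", {
  set.seed(11)
  W <- matrix(runif(100), 10, 10)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- list(paste0("t", 1:10), paste0("t", 1:10))
  A <- matrix(rbinom(100, 1, 0.3), 10, 10)
  A <- pmax(A, t(A)) * 1
  diag(A) <- 0
  dimnames(A) <- dimnames(W)
  res <- snfFuse(W, A, fusionConfig(K = 3, t = 20))
  expect_true(all(res$trajectory$symmetric))
  expect_true(all(res$trajectory$nonneg))
  expect_true(all(is.finite(res$fused)))
  expect_gte(min(res$fused), 0)
})

test_that("fusion commutes with TF relabeling", {
  set.seed(3)
  n <- 8
  W <- matrix(runif(n^2), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  A <- matrix(rbinom(n^2, 1, 0.4), n, n)
  A <- pmax(A, t(A)) * 1
  diag(A) <- 0
  nm <- paste0("t", seq_len(n))
  dimnames(W) <- dimnames(A) <- list(nm, nm)
  perm <- sample(n)
  f1 <- snfFuse(W, A, fusionConfig(K = 3, t = 4))$fused
  f2 <- snfFuse(W[perm, perm], A[perm, perm], fusionConfig(K = 3, t = 4))$fused
  expect_equal(f2, f1[rownames(f2), colnames(f2)], tolerance = 1e-12)
})

test_that("fusion restricts to the TF set shared by both matrices", {
  nm1 <- c("a", "b", "c", "d")
  W <- matrix(runif(16), 4, 4, dimnames = list(nm1, nm1))
  W <- (W + t(W)) / 2; diag(W) <- 0
  nm2 <- c("b", "c", "d", "e")
  A <- matrix(1, 4, 4, dimnames = list(nm2, nm2)); diag(A) <- 0
  res <- snfFuse(W, A, fusionConfig(K = 2, t = 2))
  expect_equal(rownames(res$fused), c("b", "c", "d"))
  expect_error(snfFuse(W[1:2, 1:2], A, fusionConfig()), "fewer than 3")
})

test_that("self-fusion keeps backbone edges heavier than non-backbone", {
  # the K-NN backbone of the input should retain more fused weight than the
  # discarded tail even after diffusion
  n <- 10
  W <- outer(1:n, 1:n, function(i, j) exp(-abs(i - j) / 3))
  diag(W) <- 0
  dimnames(W) <- list(paste0("t", 1:n), paste0("t", 1:n))
  K <- 3
  res <- snfFuse(W, W, fusionConfig(K = K, t = 20))
  inBackbone <- matrix(FALSE, n, n)
  for (i in 1:n) {
    w <- W[i, ]; w[i] <- -Inf
    inBackbone[i, order(w, decreasing = TRUE)[1:K]] <- TRUE
  }
  bb <- inBackbone | t(inBackbone)
  off <- row(W) != col(W)
  expect_gt(mean(res$fused[bb & off]), mean(res$fused[!bb & off]))
})

test_that("binarization keeps weights strictly above the mean off-diagonal", {
  nm <- c("a", "b", "c", "d")
  f <- matrix(0.1, 4, 4, dimnames = list(nm, nm))
  f["a", "b"] <- f["b", "a"] <- 0.9
  f["a", "c"] <- f["c", "a"] <- 0.9
  f["b", "c"] <- f["c", "b"] <- 0.9
  diag(f) <- 0
  directed <- data.frame(from = c("a", "a", "a"), to = c("b", "c", "d"))
  net <- binarizeAndOrient(f, directed, fusionConfig())
  e <- networkEdges(net)
  expect_equal(nrow(e), 3)
  expect_setequal(paste(e$a, e$b), c("a b", "a c", "b c"))
  # directed pair whose undirected edge was dropped is excluded
  d <- directedEdges(net)
  expect_setequal(paste(d$from, d$to), c("a b", "a c"))
  expect_s4_class(net, "TFNetwork")

  allEq <- matrix(0.5, 4, 4, dimnames = list(nm, nm)); diag(allEq) <- 0
  expect_warning(net0 <- binarizeAndOrient(allEq, directed, fusionConfig()),
                 "degenerate")
  expect_equal(nrow(networkEdges(net0)), 0)
})
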