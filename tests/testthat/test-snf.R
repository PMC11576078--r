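test_that("pairwise distances are metric and match hand geometry", {
  H <- rbind(c(0, 3, 0), c(0, 4, 0))
  d <- pairwise_distance(H, standardize = FALSE)
  expect_equal(d[1, 2], 5)            # 3-4-5 triangle
  expect_equal(d[1, 3], 0)            # identical columns
  expect_equal(diag(d), rep(0, 3))
  set.seed(6)
  H2 <- matrix(rnorm(4 * 6), 4, 6)
  d2 <- pairwise_distance(H2)
  expect_equal(d2, t(d2))
  for (i in 1:6) for (j in 1:6) for (l in 1:6)
    expect_lte(d2[i, j], d2[i, l] + d2[l, j] + 1e-12)
  expect_error(pairwise_distance(matrix(1, 2, 5)), "constant")
  expect_error(pairwise_distance(matrix(1:2, 2, 1)), "2 columns")
})

test_that("standardization drops constant rows and equalizes feature scale", {
  H <- rbind(c(1, 2, 3, 4), c(10, 20, 30, 40), c(7, 7, 7, 7))
  d <- pairwise_distance(H)         # rows 1 and 2 standardize identically
  z <- (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4))
  expect_equal(d, sqrt(2) * as.matrix(dist(z)), ignore_attr = TRUE)
})

test_that("affinity kernel matches its pairwise definition on a toy", {
  # 3 collinear points at 0, 1, 2
  d <- as.matrix(dist(c(0, 1, 2)))
  S <- affinity_kernel(d, K = 2, mu = 0.5)
  expect_equal(S, oracle_affinity(d, K = 2, mu = 0.5), ignore_attr = TRUE)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(S, t(S))
  # coincident points are maximally similar
  d0 <- matrix(0, 3, 3)
  expect_equal(affinity_kernel(d0, K = 2, mu = 0.5),
               matrix(1, 3, 3), ignore_attr = TRUE)
  # hand evaluation for the collinear pair (0, 1) with K = 2, mu = 0.5:
  # neighbor means are (0+1... ) eps = (1.5 + 1.5 + 1)/3 for the far
  # pair; check one entry explicitly against the formula
  eps01 <- (mean(c(1, 2)) + mean(c(1, 1)) + 1) / 3
  expect_equal(S[1, 2], exp(-1 / (0.5 * eps01)))
  set.seed(13)
  pts <- matrix(rnorm(2 * 9), 2)
  dd <- as.matrix(dist(t(pts)))
  expect_error(affinity_kernel(dd, K = 9), "K")
})

test_that("global kernel has half diagonals and unit row sums", {
  set.seed(14)
  M <- matrix(runif(49, 0.1, 1), 7)
  S <- (M + t(M)) / 2; diag(S) <- 1
  P <- global_kernel(S)
  expect_equal(diag(P), rep(0.5, 7))
  expect_equal(rowSums(P), rep(1, 7))
  expect_true(all(P >= 0))
  S3 <- matrix(1, 3, 3)
  expect_equal(global_kernel(S3)[1, 2], 0.25)
  # tiny off-diagonal mass must not cancel against the unit diagonal
  S_eps <- diag(5) + 1e-30
  expect_equal(rowSums(global_kernel(S_eps)), rep(1, 5))
})

test_that("local kernel restricts rows to K-nearest sets including self", {
  set.seed(15)
  M <- matrix(runif(36, 0.1, 0.9), 6)
  S <- (M + t(M)) / 2; diag(S) <- 1
  D <- local_kernel(S, K = 3)
  expect_equal(rowSums(D), rep(1, 6))
  expect_equal(rowSums(D > 0), rep(3L, 6))      # support size K, self in it
  expect_true(all(diag(D) > 0))
  # b outside N_a gets exactly 0
  for (a in 1:6) {
    far <- order(S[a, ])[1]
    if (far != a) expect_equal(D[a, far], 0)
  }
  # full neighborhood: row-normalized S
  Dn <- local_kernel(S, K = 5)
  o <- order(S[1, ], decreasing = TRUE)[1:5]
  expect_equal(sum(Dn[1, -o] > 0), if (1 %in% o) 0L else 1L)
  expect_error(local_kernel(S, K = 6), "K")
})

test_that("fusion preserves symmetry, positivity and row structure", {
  set.seed(16)
  mk <- function() {
    M <- matrix(runif(400, 0.05, 1), 20)
    S <- (M + t(M)) / 2; diag(S) <- 1
    S
  }
  S_list <- list(mk(), mk(), mk())
  f <- snf_fuse(S_list, K = 5, iterations = 8)
  G <- f$G
  expect_equal(G, t(G))
  expect_true(all(G >= 0) && all(is.finite(G)))
  # single layer degenerates to its own normalized network
  f1 <- snf_fuse(S_list[1], K = 5, iterations = 8)
  P1 <- global_kernel(S_list[[1]])
  expect_equal(f1$G, (P1 + t(P1)) / 2)
  expect_error(snf_fuse(list(mk(), matrix(1, 5, 5))), "same samples")
})

test_that("fusing identical block-diagonal networks keeps the block support", {
  S <- block_similarity(c(5, 5, 5, 5))
  f <- snf_fuse(list(S, S, S), K = 4, iterations = 10)
  lab <- rep(1:4, each = 5)
  off_block <- f$G[outer(lab, lab, "!=")]
  expect_true(all(off_block == 0))
  expect_true(all(f$G[outer(lab, lab, "==")] > 0))
})

test_that("permuting samples permutes the fused network identically", {
  set.seed(17)
  ds <- small_sim(sigma2 = 2, signal_prop = 0.5, seed = 17, n = 20L, p = 30L)
  build <- function(layers) {
    S <- lapply(layers, function(x)
      affinity_kernel(pairwise_distance(x), K = 6))
    snf_fuse(S, K = 6, iterations = 6)$G
  }
  G <- build(ds$layers)
  perm <- sample(20)
  Gp <- build(lapply(ds$layers, function(x) x[, perm]))
  expect_equal(Gp, G[perm, perm], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("status matrices stay row-stochastic with half diagonal per iteration", {
  set.seed(18)
  mk <- function() {
    M <- matrix(runif(225, 0.05, 1), 15)
    S <- (M + t(M)) / 2; diag(S) <- 1
    S
  }
  S_list <- list(mk(), mk())
  P <- lapply(S_list, global_kernel)
  D <- lapply(S_list, local_kernel, K = 5)
  for (t in 1:5) {
    P_new <- lapply(1:2, function(m) {
      other <- P[[setdiff(1:2, m)]]
      Pm <- D[[m]] %*% other %*% t(D[[m]])
      metaSNF:::.renormalize_status((Pm + t(Pm)) / 2)
    })
    P <- P_new
    for (Pm in P) {
      expect_equal(rowSums(Pm), rep(1, 15), tolerance = 1e-8)
      expect_equal(diag(Pm), rep(0.5, 15))
    }
  }
})
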