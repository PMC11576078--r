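test_that("kl_divergence matches direct evaluation and its conventions", {
  expect_equal(kl_divergence(matrix(2), matrix(1), matrix(1)),
               2 * log(2) - 2 + 1)
  # zero entry in A contributes exactly (WH)_ij
  expect_equal(kl_divergence(matrix(0), matrix(1), matrix(0.7)), 0.7)
  set.seed(4)
  W <- matrix(runif(12), 4); H <- matrix(runif(15), 3)
  A <- W %*% H
  expect_equal(kl_divergence(A, W, H), 0, tolerance = 1e-10)
  A2 <- matrix(rexp(20), 4, 5)
  expect_equal(kl_divergence(A2, W, H), oracle_kl(A2, pmax(W %*% H, 1e-12)),
               tolerance = 1e-12)
  expect_error(kl_divergence(A2, W, matrix(1, 2, 5)), "conformable")
  expect_error(kl_divergence(-A2, W, H), "non-negative")
})

test_that("multiplicative updates leave an exact factorization unchanged", {
  set.seed(11)
  W0 <- matrix(runif(20, 0.2, 1), 10, 2)
  H0 <- matrix(runif(12, 0.2, 1), 2, 6)
  A <- W0 %*% H0
  fit <- fit_kl_nmf(A, 2, max_iter = 50, tol = 0,
                    init = list(W = W0, H = H0))
  expect_equal(fit$W, W0, tolerance = 1e-8)
  expect_equal(fit$H, H0, tolerance = 1e-8)
  expect_true(all(fit$kl_history < 1e-8))
})

test_that("KL loss is non-increasing, non-negative factors, deterministic", {
  set.seed(2)
  A <- matrix(rexp(30 * 12), 30, 12)
  f1 <- fit_kl_nmf(A, 3, seed = 5, max_iter = 400, tol = 0, check_every = 1)
  f2 <- fit_kl_nmf(A, 3, seed = 5, max_iter = 400, tol = 0, check_every = 1)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_true(all(diff(f1$kl_history) <= 1e-9))
  expect_true(min(f1$W) >= 0 && min(f1$H) >= 0)
  # an exactly factorizable matrix is fit to (near-)zero divergence
  set.seed(7)
  W0 <- matrix(runif(16, 0.5, 2), 8, 2)
  H0 <- matrix(runif(12, 0.5, 2), 2, 6)
  f22 <- fit_kl_nmf(W0 %*% H0, 2, seed = 3, max_iter = 5000, tol = 1e-14)
  expect_lt(f22$kl / sum(W0 %*% H0), 1e-6)
})

test_that("scaling the input rescales the loss but not the partitions", {
  set.seed(9)
  A <- matrix(rexp(40 * 16), 40, 16)
  fa <- fit_kl_nmf(A, 3, seed = 2, max_iter = 200, tol = 0)
  fb <- fit_kl_nmf(5 * A, 3, seed = 2, max_iter = 200, tol = 0)
  expect_equal(fb$kl_history, 5 * fa$kl_history, tolerance = 1e-6)
  assign_a <- max.col(t(fa$H), ties.method = "first")
  assign_b <- max.col(t(fb$H), ties.method = "first")
  expect_identical(assign_a, assign_b)
})

test_that("rank bounds and degenerate inputs are rejected", {
  A <- matrix(rexp(24), 6, 4)
  expect_error(fit_kl_nmf(A, 0), "rank")
  expect_error(fit_kl_nmf(A, 4), "rank")
  expect_error(fit_kl_nmf(matrix(0, 4, 4), 2), "zero")
})

test_that("consensus matrices are symmetric, unit-diagonal and in [0,1]", {
  set.seed(21)
  A <- matrix(rexp(30 * 15), 30, 15)
  cons <- nmf_consensus(A, 3, n_runs = 4, seed = 8, max_iter = 150,
                        tol = 1e-4)
  C <- cons$consensus
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, 15))
  expect_true(all(C >= 0 & C <= 1))
  # single run: binary connectivity
  c1 <- nmf_consensus(A, 3, n_runs = 1, seed = 8, max_iter = 150,
                      tol = 1e-4)
  expect_true(all(c1$consensus %in% c(0, 1)))
  expect_error(nmf_consensus(A, 3, n_runs = 0), "n_runs")
})

# Parts-structured toy: feature block b is active exactly in sample
# block b, so a rank-3 factorization has an unambiguous optimum and the
# argmax partition is the planted one.
block_parts <- function(lab, p_per_block = 8, hi = 5, lo = 0.05,
                        jitter = 0.02, seed = 99) {
  set.seed(seed)
  k <- length(unique(lab))
  A <- matrix(lo, p_per_block * k, length(lab))
  for (b in seq_len(k))
    A[(b - 1) * p_per_block + seq_len(p_per_block), lab == b] <- hi
  A + matrix(runif(length(A), 0, jitter), nrow(A))
}

test_that("well-separated blocks give an exact block-indicator consensus", {
  lab <- rep(1:3, each = 6)
  A <- block_parts(lab)
  for (runs in c(3, 10)) {
    cons <- nmf_consensus(A, 3, n_runs = runs, seed = 5, max_iter = 500,
                          tol = 1e-8)
    expect_equal(cons$consensus, outer(lab, lab, function(a, b)
      as.numeric(a == b)), tolerance = 1e-12)
  }
})

test_that("cophenetic coefficient matches a brute-force Pearson oracle", {
  # exact block indicator: perfectly stable, coefficient 1
  C <- block_similarity(c(3, 3, 2))
  expect_equal(cophenetic_coefficient(C)$rho, 1)
  # constant off-diagonal: undefined variance
  Cu <- matrix(0.4, 6, 6); diag(Cu) <- 1
  expect_true(cophenetic_coefficient(Cu)$undefined)
  # random symmetric consensus vs direct computation over all 28 pairs
  set.seed(12)
  n <- 8
  M <- matrix(runif(n * n), n)
  C2 <- (M + t(M)) / 2; diag(C2) <- 1
  got <- cophenetic_coefficient(C2)
  d <- as.dist(1 - C2)
  cd <- cophenetic(hclust(d, method = "average"))
  expect_equal(got$rho, cor(as.vector(d), as.vector(cd)), tolerance = 1e-12)
  expect_false(got$undefined)
})

test_that("rank-selection rule picks the first of the largest cophenetic drop", {
  pick <- metaSNF:::.select_from_rho
  expect_equal(pick(2:5, c(0.99, 0.98, 0.80, 0.79)), 3L)
  # tie between drops (3,4) and (4,5): smallest k wins
  expect_equal(pick(2:5, c(0.90, 0.90, 0.70, 0.50)), 3L)
  # no positive drop: fall back to the largest coefficient
  expect_equal(pick(2:5, c(0.70, 0.80, 0.90, 0.95)), 5L)
  expect_error(select_rank(matrix(rexp(40), 8, 5), ranks = 3L), "2 candidate")
  expect_error(select_rank(matrix(rexp(40), 8, 5), ranks = c(2L, 4L)),
               "consecutive")
})

test_that("select_rank recovers the block count of separable data", {
  lab <- rep(1:3, each = 8)
  A <- block_parts(lab, seed = 41)
  sel <- select_rank(A, ranks = 2:5, n_runs = 5, seed = 3, max_iter = 500,
                     tol = 1e-8)
  expect_equal(sel$selected_rank, 3L)
})

test_that("extract_metagenes returns the lowest-KL restart at the chosen rank", {
  lab <- rep(1:3, each = 7)
  A <- block_parts(lab, seed = 51)
  fit <- extract_metagenes(A, ranks = 2:4, n_runs = 4, seed = 2,
                           max_iter = 400, tol = 1e-8)
  expect_equal(nrow(fit$H), fit$rank)
  expect_equal(fit$rank, fit$rank_selection$selected_rank)
  # argmax over metagenes reproduces the planted blocks
  expect_equal(oracle_nmi(max.col(t(fit$H), ties.method = "first"), lab), 1)
  # fixed rank bypasses selection
  f4 <- extract_metagenes(A, rank = 4, n_runs = 2, seed = 2,
                          max_iter = 200, tol = 1e-6)
  expect_equal(nrow(f4$H), 4L)
  expect_null(f4$rank_selection)
  # determinism of the full stage
  g <- extract_metagenes(A, ranks = 2:4, n_runs = 4, seed = 2,
                         max_iter = 400, tol = 1e-8)
  expect_identical(fit$H, g$H)
})
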