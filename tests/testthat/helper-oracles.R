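# Independent brute-force oracles used to pin expected values.

# KL divergence by direct elementwise summation (no vectorized shortcuts).
oracle_kl <- function(A, WH) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    a <- A[i, j]; b <- WH[i, j]
    s <- s + (if (a > 0) a * log(a / b) else 0) - a + b
  }
  s
}

# NMI from first principles: explicit entropies and mutual information
# over the empirical joint distribution, natural logs.
oracle_nmi <- function(u, v) {
  n <- length(u)
  uu <- unique(u); vv <- unique(v)
  pu <- sapply(uu, function(a) mean(u == a))
  pv <- sapply(vv, function(b) mean(v == b))
  hu <- -sum(pu * log(pu)); hv <- -sum(pv * log(pv))
  mi <- 0
  for (a in seq_along(uu)) for (b in seq_along(vv)) {
    p <- mean(u == uu[a] & v == vv[b])
    if (p > 0) mi <- mi + p * log(p / (pu[a] * pv[b]))
  }
  mi / sqrt(hu * hv)
}

euc <- function(x, y) sqrt(sum((x - y)^2))

# Validity indices from their definitions, loop form.
oracle_validity <- function(x, labels) {
  ks <- sort(unique(labels)); k <- length(ks)
  n <- nrow(x)
  cent <- t(sapply(ks, function(c) colMeans(x[labels == c, , drop = FALSE])))
  scat <- sapply(seq_len(k), function(c) {
    idx <- which(labels == ks[c])
    mean(apply(x[idx, , drop = FALSE], 1, euc, y = cent[c, ]))
  })
  dbi <- mean(sapply(seq_len(k), function(i) {
    max(sapply(setdiff(seq_len(k), i), function(j)
      (scat[i] + scat[j]) / euc(cent[i, ], cent[j, ])))
  }))
  grand <- colMeans(x)
  ssw <- sum(sapply(seq_len(k), function(c) {
    idx <- which(labels == ks[c])
    sum(apply(x[idx, , drop = FALSE], 1,
              function(r) sum((r - cent[c, ])^2)))
  }))
  ssb <- sum(sapply(seq_len(k), function(c)
    sum(labels == ks[c]) * sum((cent[c, ] - grand)^2)))
  ch <- (ssb / (k - 1)) / (ssw / (n - k))
  within_max <- 0; between_min <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d <- euc(x[i, ], x[j, ])
    if (labels[i] == labels[j]) within_max <- max(within_max, d)
    else between_min <- min(between_min, d)
  }
  list(dbi = dbi, ch = ch, di = between_min / within_max)
}

# Scaled exponential kernel evaluated pair by pair from its definition
# (K nearest neighbors, self excluded from the neighbor means).
oracle_affinity <- function(d, K, mu) {
  n <- nrow(d)
  m1 <- sapply(seq_len(n), function(a) mean(sort(d[a, -a])[seq_len(K)]))
  S <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    eps <- (m1[a] + m1[b] + d[a, b]) / 3
    S[a, b] <- if (eps <= 0) 1 else exp(-d[a, b]^2 / (mu * eps))
  }
  diag(S) <- 1
  (S + t(S)) / 2
}

# Block-diagonal similarity matrix: unit blocks, eps elsewhere.
block_similarity <- function(sizes, eps = 0) {
  lab <- rep(seq_along(sizes), sizes)
  S <- ifelse(outer(lab, lab, "=="), 1, eps)
  diag(S) <- 1
  S
}

# Small multi-omics dataset for fast pipeline tests.
small_sim <- function(sigma2, signal_prop = 1, seed = 1, n = 40L, p = 60L) {
  simulate_multiomics(n_samples = n, n_features = p, sigma2 = sigma2,
                      signal_prop = signal_prop, seed = seed)
}
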