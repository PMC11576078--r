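#' Pairwise sample distances from a feature-by-sample matrix
#'
#' Euclidean distances between sample columns. By default each feature
#' (row) is standardized to mean 0 and unit variance first, so that
#' metagenes or raw features on different scales contribute comparably;
#' constant rows are dropped before standardization.
#'
#' @param H numeric matrix, features (or metagenes) x samples, n >= 2.
#' @param standardize standardize rows before computing distances
#'   (default \code{TRUE}).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(H, standardize = TRUE) {
  if (!is.matrix(H) || ncol(H) < 2L)
    stop("'H' must be a matrix with at least 2 columns")
  if (standardize) {
    s <- apply(H, 1L, stats::sd)
    keep <- s > 0
    if (!any(keep)) stop("all rows are constant; no distance is defined")
    H <- (H[keep, , drop = FALSE] - rowMeans(H[keep, , drop = FALSE])) /
      s[keep]
  }
  d <- as.matrix(stats::dist(t(H)))
  dimnames(d) <- list(colnames(H), colnames(H))
  d
}

#' Scaled exponential similarity kernel
#'
#' Converts a distance matrix into sample similarities
#' \deqn{S(a,b) = \exp\left(-\frac{d^2(a,b)}{\mu\,\varepsilon_{a,b}}\right)}
#' with the locally adaptive scale
#' \eqn{\varepsilon_{a,b} = (\overline{d}(a, N_a) + \overline{d}(b, N_b)
#' + d(a,b))/3}, where \eqn{N_a} is the set of the K nearest neighbors
#' of a (self excluded from the mean). The scale adapts to each pair's
#' local neighborhood density; mu (conventionally 0.5) multiplies it.
#'
#' Because \eqn{\varepsilon} is linear in distance while the numerator is
#' quadratic, the exponent grows with the absolute distance scale: the
#' kernel is sharply local in high-dimensional raw feature spaces
#' (standardized 1000-feature layers put exponents near -90) and much
#' smoother in low-dimensional metagene spaces. This asymmetry is what
#' makes metagene compression pay off at high noise. For inputs beyond
#' roughly 10^5 standardized features the exponent approaches the
#' double-precision underflow limit; compress such layers (e.g. by the
#' metagene stage) before building affinities.
#'
#' @param dist_mat symmetric distance matrix with zero diagonal.
#' @param K neighborhood size used for the local scale, 1 <= K < n.
#' @param mu kernel bandwidth multiplier (> 0, default 0.5).
#' @return symmetric similarity matrix with unit diagonal, entries in
#'   (0, 1].
#' @export
affinity_kernel <- function(dist_mat, K = 20L, mu = 0.5) {
  n <- nrow(dist_mat)
  if (!is.matrix(dist_mat) || n != ncol(dist_mat))
    stop("'dist_mat' must be a square matrix")
  K <- as.integer(K)
  if (K < 1L || K >= n) stop("'K' must satisfy 1 <= K < n")
  if (mu <= 0) stop("'mu' must be > 0")
  d <- (dist_mat + t(dist_mat)) / 2
  diag(d) <- 0
  # mean distance to the K nearest neighbors, self excluded
  nn_mean <- vapply(seq_len(n), function(a) {
    mean(sort(d[a, -a], partial = K)[seq_len(K)])
  }, numeric(1))
  eps_ab <- (outer(nn_mean, nn_mean, "+") + d) / 3
  S <- ifelse(eps_ab <= 0, 1, exp(-d^2 / (mu * eps_ab)))
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(dist_mat)
  S
}

#' Global (row-stochastic) kernel P
#'
#' Normalizes a similarity matrix so that each diagonal entry is exactly
#' 1/2 and each row's off-diagonal entries sum to 1/2:
#' \eqn{P(a,b) = S(a,b) / (2 \sum_{f \ne a} S(a,f))} for \eqn{b \ne a}.
#' P carries the full (global) similarity information into the fusion
#' iteration.
#'
#' @param S symmetric similarity matrix; every row must have positive
#'   off-diagonal mass.
#' @return row-stochastic matrix with diagonal 1/2.
#' @export
global_kernel <- function(S) {
  S_off <- S
  diag(S_off) <- 0                # avoid cancellation in the row sums
  off_mass <- rowSums(S_off)
  if (any(off_mass <= 0)) stop("a sample has zero off-diagonal similarity")
  P <- S_off / (2 * off_mass)
  diag(P) <- 0.5
  P
}

#' Local affinity kernel D
#'
#' Restricts each row of a similarity matrix to the sample's K-nearest-
#' neighbor set (by similarity; self is always included as its own nearest
#' neighbor) and row-normalizes: \eqn{D(a,b) = S(a,b)/\sum_{f \in N_a}
#' S(a,f)} for \eqn{b \in N_a}, 0 otherwise. D carries only the reliable
#' local affinities and acts as the message carrier during fusion.
#'
#' @param S symmetric similarity matrix with unit diagonal.
#' @param K neighborhood size, 2 <= K < n; the neighbor set of a sample
#'   counts K members in total, the sample itself (its own nearest
#'   neighbor at distance 0) always among them.
#' @return row-stochastic matrix supported on each row's K-nearest set.
#' @export
local_kernel <- function(S, K = 20L) {
  n <- nrow(S)
  K <- as.integer(K)
  if (K < 2L || K >= n) stop("'K' must satisfy 2 <= K < n")
  D <- matrix(0, n, n, dimnames = dimnames(S))
  for (a in seq_len(n)) {
    o <- order(S[a, ], decreasing = TRUE)
    idx <- union(a, o)[seq_len(K)]          # self first, then next-best
    D[a, idx] <- S[a, idx] / sum(S[a, idx])
  }
  D
}

# Re-impose the P-form (diagonal 1/2, rows summing to 1) on a status matrix.
.renormalize_status <- function(P) {
  off_mass <- rowSums(P) - diag(P)
  off_mass[off_mass == 0] <- 1
  P <- P / (2 * off_mass)
  diag(P) <- 0.5
  P
}

#' Fuse similarity networks by iterative message passing
#'
#' Runs the similarity-network-fusion iteration on M per-layer similarity
#' matrices. Each layer m keeps a status matrix \eqn{P^{(m)}} (initialized
#' by [global_kernel()]); at every iteration it is replaced by
#' \deqn{P^{(m)} \leftarrow D^{(m)} \left(\frac{\sum_{f \ne m} P^{(f)}}{M-1}
#' \right) (D^{(m)})^\top,}
#' i.e. each layer diffuses the average of the other layers' networks
#' through its own local neighborhood graph, then the result is
#' symmetrized and renormalized to the P-form for numerical stability.
#' The fused network G is the average of the M status matrices after the
#' final iteration, renormalized and symmetrized the same way.
#'
#' With a single layer (M = 1) there are no cross-layer messages and G is
#' simply that layer's normalized network.
#'
#' @param S_list list of symmetric similarity matrices sharing the sample
#'   ordering (all n x n).
#' @param K neighborhood size for the local kernels (default 20).
#' @param iterations number of fusion iterations T (default 20).
#' @return list with \code{G} (n x n symmetric non-negative fused
#'   network), \code{iterations_run}, and \code{sample_ids}.
#' @export
snf_fuse <- function(S_list, K = 20L, iterations = 20L) {
  if (!is.list(S_list) || length(S_list) < 1L)
    stop("'S_list' must be a non-empty list of similarity matrices")
  n <- nrow(S_list[[1]])
  if (any(vapply(S_list, function(S) nrow(S) != n || ncol(S) != n,
                 logical(1))))
    stop("all similarity matrices must share the same samples")
  ids <- colnames(S_list[[1]])
  M <- length(S_list)
  P <- lapply(S_list, global_kernel)
  if (M == 1L) {
    G <- (P[[1]] + t(P[[1]])) / 2
    return(list(G = G, iterations_run = 0L, sample_ids = ids))
  }
  D <- lapply(S_list, local_kernel, K = K)
  iterations <- as.integer(iterations)
  for (t in seq_len(iterations)) {
    P_new <- vector("list", M)
    for (m in seq_len(M)) {
      other <- Reduce(`+`, P[-m]) / (M - 1)
      Pm <- D[[m]] %*% other %*% t(D[[m]])
      Pm <- (Pm + t(Pm)) / 2
      P_new[[m]] <- .renormalize_status(Pm)
    }
    P <- P_new
  }
  G <- Reduce(`+`, P) / M
  G <- .renormalize_status(G)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)
  list(G = G, iterations_run = iterations, sample_ids = ids)
}
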