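# Symmetric normalized Laplacian L = I - Deg^{-1/2} G Deg^{-1/2} of a
# non-negative affinity matrix; isolated rows get degree 1 so L stays finite.
.normalized_laplacian <- function(G) {
  deg <- rowSums(G)
  deg[deg <= 0] <- 1
  inv_sqrt <- 1 / sqrt(deg)
  L <- -G * outer(inv_sqrt, inv_sqrt)
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

#' Estimate the number of clusters by the eigengap heuristic
#'
#' Computes the symmetric normalized Laplacian of the fused network, sorts
#' its eigenvalues ascending, and returns the k in \code{[k_min, k_max]}
#' maximizing the gap \eqn{\lambda_{k+1} - \lambda_k}. For a graph with c
#' well-separated components the first c eigenvalues are near 0 and the
#' gap at c is large, so the heuristic recovers the component count.
#' Ties go to the smallest k.
#'
#' @param G symmetric non-negative affinity (fused network) matrix.
#' @param k_min,k_max search range, \code{2 <= k_min <= k_max < n}.
#' @return integer k, with attribute \code{"eigenvalues"} (the leading
#'   \code{k_max + 1} Laplacian eigenvalues).
#' @export
eigengap_k <- function(G, k_min = 2L, k_max = 10L) {
  n <- nrow(G)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 2L || k_max < k_min || k_max >= n)
    stop("need 2 <= k_min <= k_max < n")
  ev <- sort(eigen(.normalized_laplacian(G), symmetric = TRUE,
                   only.values = TRUE)$values)
  n_comp <- sum(ev < 1e-8)           # connected components
  if (n_comp > k_max) {
    warning(sprintf(paste("graph has %d components but k_max = %d;",
                          "returning k_max"), n_comp, k_max))
    return(structure(k_max, eigenvalues = ev[seq_len(k_max + 1L)]))
  }
  gaps <- ev[(k_min + 1L):(k_max + 1L)] - ev[k_min:k_max]
  k <- k_min + which.max(gaps) - 1L
  structure(k, eigenvalues = ev[seq_len(k_max + 1L)])
}

#' Spectral clustering of a fused network
#'
#' Normalized spectral clustering: takes the k eigenvectors of the
#' symmetric normalized Laplacian with the smallest eigenvalues,
#' renormalizes each sample's row of the eigenvector matrix to unit
#' length, and clusters the rows with k-means (50 restarts, seeded so the
#' partition is deterministic given \code{seed}).
#'
#' @param G symmetric non-negative affinity matrix.
#' @param k number of clusters, 2 <= k < n.
#' @param seed integer seed for the k-means restarts.
#' @return integer vector of cluster labels in 1..k (attribute
#'   \code{"eigenvalues"} carries the k leading Laplacian eigenvalues);
#'   labels are only meaningful up to permutation.
#' @export
spectral_clustering <- function(G, k, seed = 1L) {
  n <- nrow(G)
  k <- as.integer(k)
  if (k < 2L || k >= n) stop("'k' must satisfy 2 <= k < n")
  eig <- eigen(.normalized_laplacian(G), symmetric = TRUE)
  ord <- order(eig$values)                 # ascending
  U <- eig$vectors[, ord[seq_len(k)], drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  set.seed(.derive_seed(seed, 977L))
  km <- stats::kmeans(U, centers = k, nstart = 50L, iter.max = 100L)
  structure(as.integer(km$cluster),
            eigenvalues = sort(eig$values)[seq_len(k)])
}
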