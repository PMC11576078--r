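#' Normalized mutual information between two partitions
#'
#' \deqn{NMI(U, V) = \frac{I(U, V)}{\sqrt{H(U) H(V)}}}
#' computed from the empirical contingency table with natural logarithms
#' and the convention \eqn{0 \log 0 = 0}. Symmetric in its arguments and
#' invariant to relabeling; 1 means identical partitions, 0 means
#' independent ones. When both partitions are single clusters the measure
#' is undefined; identical trivial partitions return 1 with a warning,
#' otherwise \code{NA} is returned with a warning.
#'
#' @param u,v cluster label vectors of equal length (any atomic type).
#' @return a number in [0, 1] (or NA in the degenerate case).
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition, relabeled
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: independent
#' @export
nmi <- function(u, v) {
  if (length(u) != length(v)) stop("'u' and 'v' must have equal length")
  if (length(u) < 2L) stop("need at least 2 samples")
  tab <- table(u, v)
  n <- sum(tab)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  hu <- -sum(ifelse(pu > 0, pu * log(pu), 0))
  hv <- -sum(ifelse(pv > 0, pv * log(pv), 0))
  if (hu == 0 && hv == 0) {
    warning("both partitions are single clusters; NMI undefined")
    return(if (nrow(tab) == 1L && ncol(tab) == 1L) 1 else NA_real_)
  }
  if (hu == 0 || hv == 0) return(0)
  pj <- tab / n
  expected <- outer(pu, pv)
  terms <- pj * log(pj / expected)
  mi <- sum(terms[pj > 0])
  mi / sqrt(hu * hv)
}

#' Spectral embedding of a similarity network
#'
#' Embeds samples into \code{dim} coordinates using the eigenvectors of
#' the symmetric normalized Laplacian with the smallest eigenvalues (the
#' same subspace spectral clustering uses). Gives similarity matrices a
#' concrete metric space in which geometric cluster-validity indices and
#' low-dimensional scatter views are well defined.
#'
#' @param G symmetric non-negative similarity matrix.
#' @param dim embedding dimension, 1 <= dim < n.
#' @return n x dim coordinate matrix (rows = samples).
#' @export
similarity_to_embedding <- function(G, dim) {
  n <- nrow(G)
  dim <- as.integer(dim)
  if (dim < 1L || dim >= n) stop("'dim' must satisfy 1 <= dim < n")
  eig <- eigen(.normalized_laplacian(G), symmetric = TRUE)
  ord <- order(eig$values)
  emb <- eig$vectors[, ord[seq_len(dim)], drop = FALSE]
  rownames(emb) <- rownames(G)
  emb
}

#' Internal cluster-validity indices
#'
#' Davies-Bouldin (lower is better), Calinski-Harabasz (higher is better)
#' and Dunn (higher is better) indices by their textbook Euclidean
#' definitions, computed on a coordinate matrix -- typically a spectral
#' embedding of the fused network (see [similarity_to_embedding()]).
#'
#' @param x n x d coordinate matrix.
#' @param labels cluster labels, k >= 2 non-empty clusters.
#' @return list with \code{dbi}, \code{ch}, \code{di} and
#'   \code{embedding_dim}.
#' @export
validity_indices <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  if (length(labels) != n) stop("'labels' length must match rows of 'x'")
  k <- max(labels)
  if (k < 2L) stop("need at least 2 clusters")
  cl_idx <- split(seq_len(n), labels)
  centroids <- t(vapply(cl_idx, function(i)
    colMeans(x[i, , drop = FALSE]), numeric(ncol(x))))
  grand <- colMeans(x)

  # within-cluster mean distance to centroid (DB scatter) and SSW/SSB (CH)
  scatter <- numeric(k); ssw <- 0
  for (j in seq_len(k)) {
    dif <- sweep(x[cl_idx[[j]], , drop = FALSE], 2L, centroids[j, ])
    dd <- sqrt(rowSums(dif^2))
    scatter[j] <- mean(dd)
    ssw <- ssw + sum(dd^2)
  }
  sizes <- lengths(cl_idx)
  ssb <- sum(sizes * rowSums(sweep(centroids, 2L, grand)^2))
  ch <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))

  cent_d <- as.matrix(stats::dist(centroids))
  db_terms <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (scatter[i] + scatter[j]) / cent_d[i, j], numeric(1)))
  }, numeric(1))
  dbi <- mean(db_terms)

  d_all <- as.matrix(stats::dist(x))
  min_between <- Inf; max_within <- 0
  for (i in seq_len(k)) {
    ii <- cl_idx[[i]]
    if (length(ii) > 1L)
      max_within <- max(max_within, max(d_all[ii, ii]))
    for (j in seq_len(k)) if (j > i) {
      min_between <- min(min_between, min(d_all[ii, cl_idx[[j]]]))
    }
  }
  di <- if (max_within == 0) Inf else min_between / max_within

  list(dbi = dbi, ch = ch, di = di, embedding_dim = ncol(x))
}
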