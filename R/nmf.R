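#' @useDynLib metaSNF, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Generalized Kullback-Leibler divergence between a matrix and its
#' factorization
#'
#' Computes \eqn{KL(A; WH) = \sum_{ij} A_{ij} \log(A_{ij}/(WH)_{ij}) -
#' A_{ij} + (WH)_{ij}} with the convention \eqn{0 \log 0 = 0}. This is the
#' loss the metagene factorization minimizes; it is 0 iff \eqn{WH = A}
#' elementwise.
#'
#' @param A non-negative matrix (features x samples).
#' @param W non-negative factor (features x rank).
#' @param H non-negative factor (rank x samples).
#' @return a single non-negative number.
#' @examples
#' kl_divergence(matrix(2), matrix(1), matrix(1))  # 2*log(2) - 1
#' @export
kl_divergence <- function(A, W, H) {
  if (!is.matrix(A) || !is.matrix(W) || !is.matrix(H))
    stop("A, W, H must be matrices")
  if (ncol(W) != nrow(H) || nrow(W) != nrow(A) || ncol(H) != ncol(A))
    stop("shapes of A, W, H are not conformable")
  if (min(A) < 0 || min(W) < 0 || min(H) < 0)
    stop("A, W, H must be non-negative")
  WH <- pmax(W %*% H, 1e-12)
  Asafe <- ifelse(A == 0, 1, A)
  sum(A * log(Asafe / WH)) - sum(A) + sum(WH)
}

# Seeded uniform initialization scaled so that E[(WH)_ij] ~ mean(A).
.init_factors <- function(A, rank, seed) {
  set.seed(as.integer(seed))
  s <- sqrt(mean(A) / rank)
  p <- nrow(A); n <- ncol(A)
  list(W = matrix(stats::runif(p * rank), p, rank) * s,
       H = matrix(stats::runif(rank * n), rank, n) * s)
}

#' Fit a KL-divergence NMF by multiplicative updates
#'
#' Factorizes a non-negative layer \code{A} (features x samples) as
#' \code{W \%*\% H} with \code{rank} metagenes, using the multiplicative
#' updates that monotonically decrease the generalized Kullback-Leibler
#' divergence. Initial factors are i.i.d. uniform draws scaled by
#' \code{sqrt(mean(A)/rank)}, seeded so a fit is deterministic.
#'
#' The loss is evaluated every \code{check_every} iterations (and at the
#' start); the fit stops when the relative change between consecutive
#' evaluations drops below \code{tol} or after \code{max_iter} updates.
#'
#' @param A non-negative matrix, no all-zero content.
#' @param rank number of metagenes, \code{1 <= rank < min(dim(A))}.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps (default 2000).
#' @param tol relative KL-change stopping tolerance (default 1e-6).
#' @param check_every evaluate the loss every this many sweeps (default 10).
#' @param init optional list with components \code{W} and \code{H} used
#'   instead of the random initialization (warm starts, fixed-point
#'   checks).
#' @return an object of class \code{"kl_nmf"}: list with \code{W},
#'   \code{H}, \code{rank}, \code{kl_history} (non-increasing),
#'   \code{kl} (final loss), \code{iterations}, \code{converged},
#'   \code{seed}.
#' @examples
#' A <- matrix(runif(60), 10, 6)
#' fit <- fit_kl_nmf(A, rank = 2, seed = 1)
#' fit$kl
#' @export
fit_kl_nmf <- function(A, rank, seed = 1L, max_iter = 2000L, tol = 1e-6,
                       check_every = 10L, init = NULL) {
  if (!is.matrix(A) || !is.numeric(A)) stop("'A' must be a numeric matrix")
  if (min(A) < 0) stop("'A' must be non-negative")
  if (all(A == 0)) stop("'A' is all zero; factorization is degenerate")
  rank <- as.integer(rank)
  if (rank < 1L || rank >= min(dim(A)))
    stop("'rank' must satisfy 1 <= rank < min(dim(A))")
  if (is.null(init)) init <- .init_factors(A, rank, seed)
  fit <- .kl_nmf_fit_cpp(A, init$W, init$H, as.integer(max_iter), tol,
                         as.integer(check_every))
  structure(list(W = fit$W, H = fit$H, rank = rank,
                 kl_history = fit$kl_history,
                 kl = fit$kl_history[length(fit$kl_history)],
                 iterations = fit$iterations, converged = fit$converged,
                 seed = as.integer(seed)),
            class = "kl_nmf")
}

# Hard sample partition from a metagene matrix: argmax over rows of H,
# ties toward the smallest metagene index (max.col "first").
.hard_assign <- function(H) {
  if (nrow(H) == 1L) rep(1L, ncol(H)) else max.col(t(H), ties.method = "first")
}

# Deterministic derived seeds, kept below 2^31 - 1.
.derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * as.double(i)) %% 2147483647)
}

#' Consensus matrix over repeated NMF restarts
#'
#' Runs [fit_kl_nmf()] \code{n_runs} times from distinct seeded random
#' initializations; each run yields a hard partition of the samples
#' (argmax over metagenes). The consensus entry (a, b) is the fraction of
#' runs in which samples a and b fall in the same cluster. Its cophenetic
#' correlation measures how stable clustering at this rank is.
#'
#' @inheritParams fit_kl_nmf
#' @param n_runs number of restarts (>= 1; 30 is the conventional default).
#' @return list with \code{consensus} (n x n, symmetric, unit diagonal,
#'   entries in [0, 1]), \code{rank}, \code{n_runs}, \code{cophenetic}
#'   (see [cophenetic_coefficient()]), \code{cophenetic_undefined},
#'   \code{best_fit} (the restart with the lowest final KL), and
#'   \code{kl_by_run}.
#' @export
nmf_consensus <- function(A, rank, n_runs = 30L, seed = 1L,
                          max_iter = 2000L, tol = 1e-6, check_every = 10L) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("'n_runs' must be >= 1")
  n <- ncol(A)
  co <- matrix(0, n, n)
  best_fit <- NULL
  kl_by_run <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- fit_kl_nmf(A, rank, seed = .derive_seed(seed, r),
                      max_iter = max_iter, tol = tol,
                      check_every = check_every)
    lab <- .hard_assign(fit$H)
    co <- co + (outer(lab, lab, "=="))
    kl_by_run[r] <- fit$kl
    if (is.null(best_fit) || fit$kl < best_fit$kl) best_fit <- fit
  }
  consensus <- co / n_runs
  diag(consensus) <- 1
  cc <- cophenetic_coefficient(consensus)
  list(consensus = consensus, rank = as.integer(rank), n_runs = n_runs,
       cophenetic = cc$rho, cophenetic_undefined = cc$undefined,
       best_fit = best_fit, kl_by_run = kl_by_run)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Converts the consensus matrix to distances \code{1 - consensus}, builds
#' an average-linkage hierarchical clustering, and returns the Pearson
#' correlation between the consensus distances and the tree's cophenetic
#' distances over all unordered sample pairs. Values near 1 indicate a
#' stable (nearly ultrametric) consensus. When either distance vector is
#' constant the correlation is undefined and flagged; callers that use the
#' coefficient for rank stability treat that case as perfectly stable.
#'
#' @param consensus symmetric matrix with entries in [0, 1] and unit
#'   diagonal, at least 3 samples.
#' @return list with \code{rho} (in [-1, 1], or \code{NA} when undefined)
#'   and \code{undefined} (logical).
#' @export
cophenetic_coefficient <- function(consensus) {
  if (!is.matrix(consensus) || nrow(consensus) != ncol(consensus))
    stop("'consensus' must be a square matrix")
  n <- nrow(consensus)
  if (n < 3L) stop("need at least 3 samples")
  if (max(abs(consensus - t(consensus))) > 1e-8)
    stop("'consensus' must be symmetric")
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cd) == 0)
    return(list(rho = NA_real_, undefined = TRUE))
  list(rho = stats::cor(as.vector(d), as.vector(cd)), undefined = FALSE)
}

# Selection rule: first of the two consecutive ranks with the largest
# cophenetic drop (ties toward the smallest k); if no positive drop, the
# rank with the largest coefficient.
.select_from_rho <- function(ranks, rho) {
  drops <- rho[-length(rho)] - rho[-1]
  if (any(drops > 0)) ranks[which.max(drops)] else ranks[which.max(rho)]
}

#' Select the factorization rank by cophenetic stability
#'
#' Scans consecutive candidate ranks, computes the cophenetic correlation
#' \eqn{\rho_k} of each rank's consensus matrix, and selects the first of
#' the two consecutive ranks with the largest drop
#' \eqn{\rho_k - \rho_{k+1}} (ties toward the smallest k). A rank whose
#' coefficient is undefined because the consensus is constant is treated
#' as perfectly stable (\eqn{\rho = 1}). If no consecutive pair shows a
#' positive drop, the rank with the largest \eqn{\rho_k} is returned.
#'
#' @inheritParams nmf_consensus
#' @param ranks consecutive ascending integer candidates, length >= 2.
#' @return list with \code{candidate_ranks}, \code{cophenetic_by_rank},
#'   \code{selected_rank}, and \code{consensus_by_rank} (the per-rank
#'   results from [nmf_consensus()], reusable by callers).
#' @export
select_rank <- function(A, ranks = 2:8, n_runs = 30L, seed = 1L,
                        max_iter = 2000L, tol = 1e-6, check_every = 10L) {
  ranks <- as.integer(ranks)
  if (length(ranks) < 2L) stop("need at least 2 candidate ranks")
  if (any(diff(ranks) != 1L)) stop("'ranks' must be consecutive ascending")
  res <- lapply(seq_along(ranks), function(i)
    nmf_consensus(A, ranks[i], n_runs = n_runs,
                  seed = .derive_seed(seed, 131 * i),
                  max_iter = max_iter, tol = tol, check_every = check_every))
  rho <- vapply(res, function(r)
    if (r$cophenetic_undefined) 1.0 else r$cophenetic, numeric(1))
  sel <- .select_from_rho(ranks, rho)
  list(candidate_ranks = ranks,
       cophenetic_by_rank = stats::setNames(rho, ranks),
       selected_rank = sel,
       consensus_by_rank = res)
}

#' Extract the metagene matrix of one omics layer
#'
#' Runs the full per-layer factorization stage: rank selection by
#' cophenetic stability (unless \code{rank} is fixed), then returns the
#' restart with the lowest final KL divergence at the selected rank. The
#' \code{H} component of the result is the metagene matrix handed to the
#' network-fusion stage.
#'
#' @inheritParams select_rank
#' @param rank optional fixed rank; when given, rank selection is skipped.
#' @return a \code{"kl_nmf"} fit (see [fit_kl_nmf()]) with an added
#'   \code{rank_selection} element (\code{NULL} when the rank was fixed).
#' @export
extract_metagenes <- function(A, ranks = 2:8, rank = NULL, n_runs = 30L,
                              seed = 1L, max_iter = 2000L, tol = 1e-6,
                              check_every = 10L) {
  if (!is.null(rank)) {
    cons <- nmf_consensus(A, rank, n_runs = n_runs, seed = seed,
                          max_iter = max_iter, tol = tol,
                          check_every = check_every)
    fit <- cons$best_fit
    fit$rank_selection <- NULL
    return(fit)
  }
  sel <- select_rank(A, ranks = ranks, n_runs = n_runs, seed = seed,
                     max_iter = max_iter, tol = tol,
                     check_every = check_every)
  i <- match(sel$selected_rank, sel$candidate_ranks)
  fit <- sel$consensus_by_rank[[i]]$best_fit
  sel$consensus_by_rank <- NULL            # drop bulky per-rank matrices
  fit$rank_selection <- sel
  fit
}
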