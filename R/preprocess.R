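#' Remove features and samples with too many missing values
#'
#' Drops features (rows) whose fraction of missing entries is strictly
#' greater than \code{max_missing}, then drops samples (columns) by the
#' same rule on the reduced matrix. A value of exactly the threshold is
#' retained.
#'
#' @param x numeric matrix, features x samples, NA marking missing cells.
#' @param max_missing maximum tolerated missing fraction (default 0.30).
#' @return the filtered matrix, with attribute \code{"removed"} listing
#'   the dropped feature and sample names (or indices).
#' @export
drop_high_missing <- function(x, max_missing = 0.30) {
  if (!is.matrix(x)) stop("'x' must be a matrix")
  if (max_missing < 0 || max_missing >= 1)
    stop("'max_missing' must lie in [0, 1)")
  f_miss <- rowMeans(is.na(x))
  keep_f <- f_miss <= max_missing
  x2 <- x[keep_f, , drop = FALSE]
  s_miss <- colMeans(is.na(x2))
  keep_s <- s_miss <= max_missing
  out <- x2[, keep_s, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L)
    stop("missing-rate filter removed everything")
  attr(out, "removed") <- list(
    features = if (is.null(rownames(x))) which(!keep_f) else
      rownames(x)[!keep_f],
    samples = if (is.null(colnames(x))) which(!keep_s) else
      colnames(x)[!keep_s])
  out
}

#' Impute missing entries by K-nearest-neighbor averaging
#'
#' For each sample (column) with missing cells, finds the \code{k} nearest
#' other samples by Euclidean distance over the features both samples
#' observe (distances scaled to the full feature count), and replaces each
#' missing cell by the mean of the neighbors' observed values for that
#' feature. Falls back to the feature's overall mean if no neighbor
#' observes it. Observed cells are never altered.
#'
#' @param x numeric matrix, features x samples, with NA missing cells.
#' @param k number of neighbor samples (default 10).
#' @return the completed matrix (no NA cells remain).
#' @export
knn_impute <- function(x, k = 10L) {
  if (!is.matrix(x)) stop("'x' must be a matrix")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (!anyNA(x)) return(x)
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 samples to impute")
  k <- min(k, n - 1L)
  if (any(colSums(!is.na(x)) == 0L))
    stop("a sample has all features missing; cannot impute")
  feat_mean <- rowMeans(x, na.rm = TRUE)
  out <- x
  for (q in which(colSums(is.na(x)) > 0L)) {
    # scaled Euclidean distance over co-observed features
    dvec <- vapply(seq_len(n), function(r) {
      if (r == q) return(Inf)
      co <- !is.na(x[, q]) & !is.na(x[, r])
      if (!any(co)) return(Inf)
      sqrt(sum((x[co, q] - x[co, r])^2) / sum(co))
    }, numeric(1))
    nb <- order(dvec)[seq_len(k)]
    nb <- nb[is.finite(dvec[nb])]
    for (i in which(is.na(x[, q]))) {
      vals <- x[i, nb]
      vals <- vals[!is.na(vals)]
      out[i, q] <- if (length(vals)) mean(vals) else feat_mean[i]
    }
  }
  out
}

#' log2(x + 1) transform
#'
#' Compresses the dynamic range of non-negative expression counts to
#' mitigate extreme values; strictly monotone, so entry ordering is
#' preserved.
#'
#' @param x numeric matrix with entries >= 0.
#' @return the transformed matrix.
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("'x' must be non-negative")
  log2(x + 1)
}

#' Remove features with low variation
#'
#' Computes per-feature mean, variance, and coefficient of variation
#' (sd/mean), and the given percentile cutoff of each statistic across
#' features. Under the default \code{"intersection"} mode a feature is
#' removed only when it falls below the cutoff for all three statistics;
#' \code{"union"} removes it if it is below any cutoff. Features with
#' zero mean have an undefined coefficient of variation; they are
#' assigned +Inf (never removed by the CV criterion) and flagged.
#'
#' @param x complete numeric matrix, features x samples.
#' @param percentile percentile cutoff in [0, 1) (e.g. 0.15 for
#'   expression, 0.25 for methylation).
#' @param mode \code{"intersection"} (default) or \code{"union"}.
#' @return the retained submatrix, with attribute \code{"removed"} (names
#'   or indices of dropped features) and \code{"cv_undefined"} (features
#'   whose CV was undefined).
#' @export
low_variation_filter <- function(x, percentile = 0.15,
                                 mode = c("intersection", "union")) {
  if (!is.matrix(x) || anyNA(x)) stop("'x' must be a complete matrix")
  if (percentile < 0 || percentile >= 1)
    stop("'percentile' must lie in [0, 1)")
  mode <- match.arg(mode)
  mu <- rowMeans(x)
  v <- apply(x, 1L, stats::var)
  cv <- ifelse(mu == 0, Inf, sqrt(v) / mu)
  cuts <- c(mean = stats::quantile(mu, percentile, names = FALSE),
            var = stats::quantile(v, percentile, names = FALSE),
            cv = stats::quantile(cv[is.finite(cv)], percentile,
                                 names = FALSE))
  below <- cbind(mu < cuts["mean"], v < cuts["var"], cv < cuts["cv"])
  drop <- if (mode == "intersection") rowSums(below) == 3L else
    rowSums(below) > 0L
  out <- x[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stop("variation filter removed every feature")
  nm <- rownames(x)
  attr(out, "removed") <- if (is.null(nm)) which(drop) else nm[drop]
  attr(out, "cv_undefined") <- if (is.null(nm)) which(mu == 0) else
    nm[mu == 0]
  out
}
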