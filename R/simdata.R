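#' Synthetic multi-omics data with planted subtype structure
#'
#' Generates three omics layers in which each layer carries a 3-group mean
#' structure over the samples; the three per-layer groupings are chosen so
#' that their common refinement is a 4-subtype partition with equal block
#' sizes. No single layer identifies the four subtypes -- only the
#' integration of all layers does, which is the situation the method is
#' designed for.
#'
#' Signal features take their sample group's mean plus Gaussian noise
#' N(0, sigma2); the remaining (non-signal) features take mean 0 plus the
#' same noise, so they carry no information about the grouping. With the
#' default 200 samples, the per-layer group means and sample blocks are
#'
#' \itemize{
#'   \item layer 1: mean 1 on samples 1-50, 0 on 51-150, 3 on 151-200
#'   \item layer 2: mean 0 on samples 1-50 and 101-150, 2 on 51-100, 3 on 151-200
#'   \item layer 3: mean 2 on samples 1-100, 1 on 101-150, 3 on 151-200
#' }
#'
#' so the true subtypes are the blocks 1-50, 51-100, 101-150, 151-200.
#' For other sample counts the same block proportions (1/4 each) are used.
#'
#' @param n_samples number of samples (divisible by 4; default 200).
#' @param n_features number of features per layer (default 1000).
#' @param sigma2 noise variance (>= 0).
#' @param signal_prop fraction of features per layer that carry the group
#'   means, in (0, 1].
#' @param seed integer seed; the dataset is bit-reproducible given the seed.
#' @return an object of class \code{"sim_dataset"}: a list with
#'   \code{layers} (list of 3 feature-by-sample matrices with feature and
#'   sample dimnames), \code{true_labels} (integer 1..4 per sample),
#'   \code{layer_groups} (3-column integer matrix of per-layer group
#'   indices), \code{signal_features} (list of integer index vectors), and
#'   \code{scenario} (the generating parameters).
#' @examples
#' ds <- simulate_multiomics(n_samples = 40, n_features = 50,
#'                           sigma2 = 6, signal_prop = 0.2, seed = 1)
#' sapply(ds$layers, dim)
#' table(ds$true_labels)
#' @export
simulate_multiomics <- function(n_samples = 200L, n_features = 1000L,
                                sigma2 = 6, signal_prop = 0.2, seed = NULL) {
  if (length(sigma2) != 1L || !is.finite(sigma2) || sigma2 < 0)
    stop("'sigma2' must be a single finite value >= 0")
  if (length(signal_prop) != 1L || !is.finite(signal_prop) ||
      signal_prop <= 0 || signal_prop > 1)
    stop("'signal_prop' must lie in (0, 1]")
  n_samples <- as.integer(n_samples)
  n_features <- as.integer(n_features)
  if (n_samples < 4L || n_samples %% 4L != 0L)
    stop("'n_samples' must be a positive multiple of 4")
  if (n_features < 1L) stop("'n_features' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  q <- n_samples %/% 4L                 # subtype block size
  subtype <- rep(1:4, each = q)
  # per-layer 3-way groupings whose meet is the 4-subtype partition
  layer_groups <- cbind(
    c(1L, 2L, 2L, 3L)[subtype],         # layer 1: {1},{2,3},{4}
    c(1L, 2L, 1L, 3L)[subtype],         # layer 2: {1,3},{2},{4}
    c(1L, 1L, 2L, 3L)[subtype]          # layer 3: {1,2},{3},{4}
  )
  group_means <- list(c(1, 0, 3), c(0, 2, 3), c(2, 1, 3))

  n_signal <- max(1L, as.integer(round(signal_prop * n_features)))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  sd_noise <- sqrt(sigma2)

  layers <- vector("list", 3L)
  signal_features <- vector("list", 3L)
  for (m in 1:3) {
    mu_col <- group_means[[m]][layer_groups[, m]]   # length n_samples
    mean_mat <- matrix(0, n_features, n_samples)
    sig_idx <- seq_len(n_signal)
    mean_mat[sig_idx, ] <- rep(mu_col, each = n_signal)
    noise <- matrix(stats::rnorm(n_features * n_samples, sd = sd_noise),
                    n_features, n_samples)
    x <- mean_mat + noise
    dimnames(x) <- list(sprintf("L%d_F%04d", m, seq_len(n_features)),
                        sample_ids)
    layers[[m]] <- x
    signal_features[[m]] <- sig_idx
  }

  structure(list(
    layers = layers,
    true_labels = subtype,
    layer_groups = layer_groups,
    signal_features = signal_features,
    scenario = list(n_samples = n_samples, n_features = n_features,
                    n_layers = 3L, sigma2 = sigma2,
                    signal_prop = signal_prop, seed = seed)
  ), class = "sim_dataset")
}

#' Shift a matrix to be non-negative
#'
#' Subtracts the global minimum when it is negative, leaving all pairwise
#' differences between entries intact. Needed to condition simulated
#' (Gaussian) layers before non-negative factorization.
#'
#' @param x numeric matrix with finite entries.
#' @return the shifted matrix; unchanged if already non-negative.
#' @examples
#' shift_nonnegative(matrix(c(-1, 1), 1))  # [[0, 2]]
#' @export
shift_nonnegative <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (any(!is.finite(x))) stop("'x' contains non-finite entries")
  mn <- min(x)
  if (mn < 0) x - mn else x
}

#' Write a simulated dataset to delimited text files
#'
#' Writes one TSV per layer (features in rows, first column the feature ID,
#' header the sample IDs), a labels TSV (sample ID, true subtype) and a
#' JSON sidecar with the generating scenario.
#'
#' @param ds a \code{sim_dataset} from [simulate_multiomics()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in seq_along(ds$layers)) {
    p <- file.path(dir, sprintf("layer%d.tsv", m))
    write_omics_matrix(ds$layers[[m]], p)
    paths <- c(paths, p)
  }
  lab <- file.path(dir, "true_labels.tsv")
  utils::write.table(
    data.frame(sample_id = colnames(ds$layers[[1]]),
               subtype = ds$true_labels),
    lab, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "scenario.json")
  jsonlite::write_json(ds$scenario, js, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(c(paths, lab, js))
}
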