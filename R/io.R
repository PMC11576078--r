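#' Read an omics matrix from delimited text
#'
#' Expects features in rows: the first column holds feature IDs and the
#' header holds sample IDs. The delimiter is taken from the file
#' extension (TSV default, comma for .csv). "NA" and empty fields are
#' read as missing.
#'
#' @param path file path.
#' @param sep field delimiter; guessed from the extension when NULL.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_omics_matrix <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, na.strings = c("NA", ""),
                          comment.char = "")
  as.matrix(df)
}

#' Write an omics matrix as TSV
#'
#' Features in rows, first column the feature ID, header the sample IDs.
#'
#' @param x numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_omics_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Write cluster labels as a two-column TSV.
.write_labels <- function(ids, labels, path) {
  utils::write.table(data.frame(sample_id = ids, subtype = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a metagene decomposition to text files
#'
#' Writes the gene-coefficient matrix W and the metagene matrix H as
#' labeled TSV, plus (when the fit carries one) the rank-selection
#' report as JSON: candidate ranks, per-rank cophenetic coefficients,
#' and the selected rank.
#'
#' @param fit a \code{"kl_nmf"} fit from [fit_kl_nmf()] or
#'   [extract_metagenes()].
#' @param dir output directory (created if missing).
#' @param feature_ids,sample_ids optional dimension labels; defaults are
#'   positional.
#' @return invisibly, the paths written.
#' @export
write_nmf_fit <- function(fit, dir, feature_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(fit, "kl_nmf"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  W <- fit$W; H <- fit$H
  mg <- sprintf("MG%02d", seq_len(fit$rank))
  dimnames(W) <- list(feature_ids %||%
                        sprintf("F%05d", seq_len(nrow(W))), mg)
  dimnames(H) <- list(mg, sample_ids %||%
                        sprintf("S%03d", seq_len(ncol(H))))
  pw <- file.path(dir, "W.tsv"); ph <- file.path(dir, "H.tsv")
  write_omics_matrix(W, pw)
  write_omics_matrix(H, ph)
  paths <- c(pw, ph)
  if (!is.null(fit$rank_selection)) {
    pj <- file.path(dir, "rank_selection.json")
    sel <- fit$rank_selection
    jsonlite::write_json(
      list(candidate_ranks = sel$candidate_ranks,
           cophenetic_by_rank = as.list(sel$cophenetic_by_rank),
           selected_rank = sel$selected_rank),
      pj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pj)
  }
  invisible(paths)
}
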