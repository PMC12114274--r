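# Delimited-text interchange for the pipeline stages. Everything is plain
# TSV so matrices, pose sets and fit reports stay diffable.

#' Write a feature matrix as delimited text
#'
#' Emits `row_id`, `V1...Vp` and the `I%` column, plus a sidecar catalog
#' mapping each variable index to its rendered residue key (`Trp74`,
#' `WSer73`).
#'
#' @param fm a `FeatureMatrix`.
#' @param path output TSV path.
#' @param catalog_path sidecar path (default `<path>.catalog.tsv`).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path,
                                 catalog_path = paste0(path, ".catalog.tsv")) {
  df <- data.frame(row_id = fm$row_ids, fm$values,
                   `I%` = fm$response, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fm$catalog, catalog_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path matrix TSV path.
#' @param catalog_path sidecar path (default `<path>.catalog.tsv`); when
#'   absent, a catalog with bare `Vj` labels is reconstructed.
#' @return a `FeatureMatrix`.
#' @export
read_feature_matrix <- function(path,
                                catalog_path = paste0(path, ".catalog.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  resp_col <- ncol(df)
  values <- as.matrix(df[, -c(1, resp_col), drop = FALSE])
  rownames(values) <- df$row_id
  if (file.exists(catalog_path)) {
    catalog <- utils::read.delim(catalog_path, stringsAsFactors = FALSE)
  } else {
    catalog <- data.frame(index = colnames(values),
                          residue_key = colnames(values),
                          bridged = FALSE, label = colnames(values),
                          stringsAsFactors = FALSE)
  }
  new_feature_matrix(values, df[[resp_col]], catalog)
}

#' Write a pose set as delimited text
#'
#' One row per pose: `pose_id`, `energy`, then `x_i`, `y_i`, `z_i`
#' coordinate triples in the shared atom order.
#'
#' @param poses list of `Pose` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pose_set <- function(poses, path) {
  n_at <- nrow(poses[[1]]$coords)
  mat <- t(vapply(poses, function(p) {
    c(p$pose_id, p$energy, as.vector(t(p$coords)))
  }, numeric(2 + 3 * n_at)))
  colnames(mat) <- c("pose_id", "energy",
                     paste0(c("x_", "y_", "z_"), rep(seq_len(n_at), each = 3)))
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pose set written by [write_pose_set()]
#'
#' @param path pose TSV path.
#' @return list of `Pose` objects.
#' @export
read_pose_set <- function(path) {
  df <- utils::read.delim(path)
  n_at <- (ncol(df) - 2) / 3
  if (n_at != round(n_at)) stop("pose table must have 3 coordinate columns per atom")
  lapply(seq_len(nrow(df)), function(i) {
    pose(df$pose_id[i], df$energy[i],
         matrix(as.numeric(df[i, -(1:2)]), ncol = 3, byrow = TRUE))
  })
}

#' Read a two-column activity table
#'
#' Delimited text with a ligand-id column and a percent-inhibition
#' column (header names are free; the first two columns are used).
#'
#' @param path TSV/CSV path (delimiter sniffed from the extension).
#' @return named numeric vector of I% keyed by ligand id.
#' @export
read_activity_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a two-column dose-response table
#'
#' @param path TSV/CSV path with dose (uM) and normalized response (%)
#'   columns.
#' @return data frame with columns `dose` and `response`.
#' @export
read_dose_response <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  data.frame(dose = as.numeric(df[[1]]), response = as.numeric(df[[2]]))
}
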