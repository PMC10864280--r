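#' Read a sample-by-feature table from TSV
#'
#' Expects a header row, features as columns and the first column named
#' `sample_id`; empty cells are read as `NA` (missing), as written by
#' [write_feature_table()].
#'
#' @param path TSV file path.
#' @return Numeric matrix with sample IDs as rownames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("first column of a feature table must be 'sample_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write a sample-by-feature table to TSV
#'
#' Missing values are written as empty cells.
#'
#' @param x Numeric matrix, sample IDs as rownames.
#' @param path Output TSV path.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV with columns `sample_id`, `pair_id`, `zygosity`, `md` and
#'   any covariates.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pair_id", "zygosity", "md")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  md
}

# align a feature table's rows to a metadata table by sample_id, erroring on
# samples present in one but not the other
align_samples <- function(features, metadata) {
  miss <- setdiff(metadata$sample_id, rownames(features))
  if (length(miss))
    stop("samples in metadata but not in feature table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  features[metadata$sample_id, , drop = FALSE]
}
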