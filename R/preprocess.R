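#' Remove samples below a sequencing-depth threshold
#'
#' Samples whose total read count is strictly less than `min_depth` are
#' excluded (a sample at exactly the threshold is retained). Removals are
#' recorded in the `"filter_log"` attribute.
#'
#' @param counts Integer count matrix (samples x features).
#' @param min_depth Minimum total reads per sample (default 10000).
#' @return Filtered count matrix.
#' @export
filter_samples_by_depth <- function(counts, min_depth = 10000) {
  check_counts(counts)
  keep <- rowSums(counts) >= min_depth
  if (!all(keep))
    message(sum(!keep), " sample(s) below depth ", min_depth, " removed")
  out <- counts[keep, , drop = FALSE]
  attr(out, "filter_log") <- list(removed_samples = rownames(counts)[!keep])
  out
}

#' Apply the standard taxon prevalence/abundance filters
#'
#' In order: (1) taxa observed only once in the whole dataset (total count
#' 1) are removed; (2) taxa must appear in more than one sample; (3) taxa
#' with no counts at all are removed; (4) empty samples are removed. The
#' rules overlap (1-2 imply 3) but are applied in that order so the
#' removal log attributes each taxon to the first rule that catches it.
#'
#' @param counts Integer count matrix (samples x taxa).
#' @return Filtered matrix with a `"filter_log"` attribute listing removals
#'   per rule.
#' @export
filter_taxa <- function(counts) {
  check_counts(counts)
  log <- list()
  r1 <- colSums(counts) == 1L
  log$singleton_taxa <- colnames(counts)[r1]
  counts <- counts[, !r1, drop = FALSE]
  r2 <- colSums(counts > 0) <= 1L & colSums(counts) > 0L
  log$single_sample_taxa <- colnames(counts)[r2]
  counts <- counts[, !r2, drop = FALSE]
  r3 <- colSums(counts) == 0L
  log$zero_taxa <- colnames(counts)[r3]
  counts <- counts[, !r3, drop = FALSE]
  r4 <- rowSums(counts) == 0L
  log$empty_samples <- rownames(counts)[r4]
  counts <- counts[!r4, , drop = FALSE]
  attr(counts, "filter_log") <- log
  counts
}

#' Agglomerate feature counts to genus level
#'
#' Sums counts of features mapping to the same genus. Features with no genus
#' assignment (`NA` or "") are grouped as `"unclassified <parent>"` when a
#' parent-rank column (e.g. family) is present in the taxonomy map, or
#' `"unclassified"` otherwise.
#'
#' @param counts Count matrix (samples x features).
#' @param taxonomy data.frame with columns `feature_id`, `genus`, and
#'   optionally a parent rank (e.g. `family`) used to label unclassified
#'   features.
#' @return Count matrix (samples x genera).
#' @export
agglomerate_to_genus <- function(counts, taxonomy) {
  stopifnot(is.data.frame(taxonomy),
            all(c("feature_id", "genus") %in% names(taxonomy)))
  idx <- match(colnames(counts), taxonomy$feature_id)
  if (anyNA(idx))
    stop("features missing from taxonomy map: ",
         paste(utils::head(colnames(counts)[is.na(idx)], 5L), collapse = ", "))
  genus <- taxonomy$genus[idx]
  unk <- is.na(genus) | genus == ""
  if (any(unk)) {
    parent_col <- setdiff(names(taxonomy), c("feature_id", "genus"))[1L]
    parent <- if (!is.na(parent_col)) taxonomy[[parent_col]][idx] else NULL
    genus[unk] <- if (is.null(parent)) "unclassified" else
      ifelse(is.na(parent[unk]) | parent[unk] == "", "unclassified",
             paste("unclassified", parent[unk]))
  }
  out <- t(rowsum(t(counts), group = genus))
  out[, unique(genus), drop = FALSE]
}

#' Centered log-ratio (CLR) transform
#'
#' Per sample, zeros are replaced by `zero_replacement` and each count is
#' divided by the geometric mean of the sample and log-transformed:
#' `clr(x) = log(x) - mean(log(x))`. Each transformed row sums to zero and
#' the transform is invariant to multiplying a (zero-free) sample by a
#' positive constant.
#'
#' @param counts Nonnegative matrix (samples x features).
#' @param zero_replacement Pseudo-value substituted for zero counts
#'   (default 0.5, half the minimal observable count).
#' @return Numeric matrix of CLR values with attribute `kind = "clr"`.
#' @export
clr_transform <- function(counts, zero_replacement = 0.5) {
  if (any(counts < 0)) stop("CLR requires nonnegative values")
  if (any(rowSums(counts) == 0)) stop("CLR undefined for empty samples")
  x <- ifelse(counts == 0, zero_replacement, counts)
  lx <- log(x)
  out <- lx - rowMeans(lx)
  attr(out, "kind") <- "clr"
  out
}

#' Preprocess a metabolite panel
#'
#' Order of operations: (1) drop metabolites missing in more than
#' `max_missing_frac` of individuals; (2) impute remaining missing cells
#' with the metabolite's median of observed values; (3) `log(x + 1)`;
#' (4) center each metabolite to mean 0 and scale to SD 1. Metabolites with
#' zero variance after the log transform cannot be scaled and are dropped
#' with a warning.
#'
#' @param metab Numeric matrix (samples x metabolites), `NA` = missing.
#' @param max_missing_frac Maximum tolerated missing fraction (default
#'   0.25; a metabolite missing in strictly more than this fraction is
#'   removed).
#' @param sd_type `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n - 1) SD for scaling.
#' @return Numeric matrix with attribute `kind = "log-z"` and a
#'   `"dropped"` attribute naming removed metabolites.
#' @export
preprocess_metabolites <- function(metab, max_missing_frac = 0.25,
                                   sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- nrow(metab)
  frac_missing <- colMeans(is.na(metab))
  drop_missing <- frac_missing > max_missing_frac
  x <- metab[, !drop_missing, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- stats::median(x[!na, j])
  }
  x <- log(x + 1)
  sds <- apply(x, 2L, stats::sd)
  if (sd_type == "population") sds <- sds * sqrt((n - 1) / n)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning("dropping zero-variance metabolite(s): ",
            paste(colnames(x)[degenerate], collapse = ", "))
    x <- x[, !degenerate, drop = FALSE]
    sds <- sds[!degenerate]
  }
  out <- sweep(sweep(x, 2L, colMeans(x)), 2L, sds, "/")
  attr(out, "kind") <- "log-z"
  attr(out, "dropped") <- c(colnames(metab)[drop_missing],
                            names(sds)[degenerate])
  out
}

#' Impute missing covariate values
#'
#' Numeric covariates are imputed with their median; binary (two-level) and
#' categorical covariates with their mode, ties broken toward the "no
#' exposure" level (0/"F"/FALSE, else the first sorted level).
#'
#' @param metadata data.frame of sample covariates.
#' @param cols Columns to impute (default: all except the identifier
#'   columns `sample_id`, `pair_id`, `zygosity`, `md`).
#' @return `metadata` with missing values filled in.
#' @export
impute_confounders <- function(metadata,
                               cols = setdiff(names(metadata),
                                              c("sample_id", "pair_id",
                                                "zygosity", "md"))) {
  for (nm in cols) {
    v <- metadata[[nm]]
    if (!anyNA(v)) next
    na <- is.na(v)
    obs <- v[!na]
    if (length(obs) == 0L) stop("covariate '", nm, "' entirely missing")
    if (is.numeric(v) && length(unique(obs)) > 2L) {
      v[na] <- stats::median(obs)
    } else {
      tab <- table(obs)
      best <- names(tab)[tab == max(tab)]
      pick <- intersect(c("0", "F", "FALSE", "no"), best)
      mode_val <- if (length(pick)) pick[1L] else sort(best)[1L]
      v[na] <- if (is.numeric(v)) as.numeric(mode_val) else mode_val
    }
    metadata[[nm]] <- v
  }
  metadata
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("expected a numeric matrix of counts (samples x features)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  invisible(counts)
}
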