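#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|a - b|) / sum(a + b)` computed on relative abundances (each vector
#' is normalized to sum 1 first, making the measure invariant to common
#' positive scaling); 0 for identical compositions, 1 for disjoint
#' supports.
#'
#' @param a,b Nonnegative abundance vectors over the same feature set.
#' @param relative Normalize to relative abundances first (default `TRUE`).
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b, relative = TRUE) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("abundances must be nonnegative")
  if (sum(a) == 0 || sum(b) == 0)
    stop("Bray-Curtis undefined for an all-zero sample")
  if (relative) { a <- a / sum(a); b <- b / sum(b) }
  sum(abs(a - b)) / sum(a + b)
}

#' Euclidean distance between two profiles
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(sum((a - b)^2))
}

#' Pairwise distances labeled by twin-pair relationship
#'
#' Computes all pairwise distances between samples (Bray-Curtis on relative
#' abundances via [vegan::vegdist()], or Euclidean) and tags every
#' sample pair as `within_pair` (co-twins) or `outside_pair`, and by
#' zygosity: `MZ`/`DZ` when both samples belong to pairs of that zygosity,
#' `cross` otherwise.
#'
#' @param features Numeric matrix (samples x features); counts for
#'   `metric = "bray"` (converted to relative abundances), any scale for
#'   `"euclidean"`.
#' @param metadata data.frame with `sample_id`, `pair_id`, `zygosity`
#'   matching the rows of `features`.
#' @param metric `"bray"` or `"euclidean"`.
#' @param max_outside Optional cap on the number of outside-pair distances
#'   retained (deterministic subsample under `subsample_seed`); `Inf` keeps
#'   all.
#' @param subsample_seed Seed for the optional subsample.
#' @return data.frame of class `distance_set`: `id_a`, `id_b`, `metric`,
#'   `distance`, `relation` (within_pair/outside_pair), `zygosity`
#'   (MZ/DZ/cross).
#' @export
pair_distances <- function(features, metadata,
                           metric = c("bray", "euclidean"),
                           max_outside = Inf, subsample_seed = 1L) {
  metric <- match.arg(metric)
  features <- align_samples(features, metadata)
  d <- if (metric == "bray") {
    rel <- features / rowSums(features)
    vegan::vegdist(rel, method = "bray")
  } else {
    stats::dist(features)
  }
  n <- nrow(features)
  ia <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  pid <- metadata$pair_id
  zyg <- metadata$zygosity
  within <- pid[ia] == pid[ib]
  zpair <- ifelse(zyg[ia] == zyg[ib], zyg[ia], "cross")
  out <- data.frame(id_a = metadata$sample_id[ia],
                    id_b = metadata$sample_id[ib],
                    metric = metric, distance = as.vector(d),
                    relation = ifelse(within, "within_pair", "outside_pair"),
                    zygosity = zpair, stringsAsFactors = FALSE)
  if (is.finite(max_outside)) {
    outs <- which(out$relation == "outside_pair")
    if (length(outs) > max_outside) {
      old <- .Random.seed_save()
      set.seed(subsample_seed)
      drop <- sample(outs, length(outs) - max_outside)
      .Random.seed_restore(old)
      out <- out[-drop, , drop = FALSE]
    }
  }
  class(out) <- c("distance_set", "data.frame")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compare two groups of distances with a normality-gated test
#'
#' Shapiro-Wilk is run on each group (on a deterministic evenly-spaced
#' subsample of 5000 when a group is larger, the test's implementation
#' limit); if both groups look normal (p > 0.05) a two-sample Student
#' t-test is used, otherwise a Wilcoxon rank-sum test; two-sided either
#' way. Note that pairwise distances sharing samples are not independent
#' observations; the p-values are descriptive, as is conventional for this
#' comparison.
#'
#' @param x,y Numeric vectors of distances (each of length >= 3).
#' @return List: `test` ("t" or "wilcoxon"), `statistic`, `p.value`,
#'   `shapiro_p` (length 2), `mean_x`, `mean_y`.
#' @export
compare_distance_groups <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 distances (Shapiro-Wilk undefined)")
  sw <- vapply(list(x, y), function(v) {
    if (length(v) > 5000L)
      v <- v[round(seq(1L, length(v), length.out = 5000L))]
    if (stats::sd(v) == 0) return(0)   # degenerate: clearly non-normal path
    stats::shapiro.test(v)$p.value
  }, numeric(1L))
  if (all(sw > 0.05)) {
    ht <- stats::t.test(x, y)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    test <- "wilcoxon"
  }
  list(test = test, statistic = unname(ht$statistic), p.value = ht$p.value,
       shapiro_p = sw, mean_x = mean(x), mean_y = mean(y))
}

#' Within-pair vs outside-pair and MZ-vs-DZ distance comparisons
#'
#' Runs the two standard beta-diversity contrasts on a labeled distance
#' set: (1) within-pair distances of MZ vs DZ pairs; (2) within-pair vs
#' outside-pair distances over all samples (outside-pair always excludes
#' one's own co-twin by construction). For the MZ-vs-DZ restricted
#' comparison only same-zygosity distances are used.
#'
#' @param distances A `distance_set` from [pair_distances()].
#' @return data.frame: one row per comparison with group means, test used
#'   and p-value.
#' @export
compare_dissimilarity <- function(distances) {
  w <- distances[distances$relation == "within_pair", , drop = FALSE]
  o <- distances[distances$relation == "outside_pair", , drop = FALSE]
  cmp1 <- compare_distance_groups(w$distance[w$zygosity == "MZ"],
                                  w$distance[w$zygosity == "DZ"])
  cmp2 <- compare_distance_groups(w$distance, o$distance)
  data.frame(
    comparison = c("within_pair_MZ_vs_DZ", "within_vs_outside_pair"),
    metric = distances$metric[1L],
    mean_group1 = c(cmp1$mean_x, cmp2$mean_x),
    mean_group2 = c(cmp1$mean_y, cmp2$mean_y),
    test = c(cmp1$test, cmp2$test),
    statistic = c(cmp1$statistic, cmp2$statistic),
    p = c(cmp1$p.value, cmp2$p.value),
    stringsAsFactors = FALSE)
}
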