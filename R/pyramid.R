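#' Paired Wilcoxon signed-rank test on within-pair differences
#'
#' Classical convention: zero differences are discarded before ranking; the
#' exact null distribution is used when 25 or fewer nonzero differences
#' remain and no ties are present, otherwise the normal approximation with
#' mid-ranks, tie correction and continuity correction. If every
#' difference is zero the test is degenerate: p = 1, direction 0.
#'
#' @param d Numeric vector of within-pair differences (affected minus
#'   healthy co-twin).
#' @return List: `statistic` (V, the positive-rank sum), `p.value`,
#'   `direction` (sign of the median difference, zeros included), `n_used`
#'   (nonzero differences).
#' @export
signed_rank_test <- function(d) {
  stopifnot(is.numeric(d))
  d <- d[!is.na(d)]
  direction <- sign(stats::median(d))
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(statistic = 0, p.value = 1, direction = 0, n_used = 0L))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, exact = length(nz) <= 25L, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       direction = direction, n_used = length(nz))
}

#' Pairwise screening of one pyramid layer over discordant pairs
#'
#' For each feature, forms the within-pair difference (affected member minus
#' healthy member) over the discordant pairs of the requested layer and
#' applies the paired Wilcoxon signed-rank test (two-sided). Layers:
#' `"a"` = MZ discordant pairs, `"b"` = DZ discordant pairs, `"c"` = all
#' discordant pairs. No multiple-testing correction is applied within these
#' layers; raw p-values are thresholded at `alpha` (correction happens in
#' the mixed-model layers).
#'
#' @param features Numeric matrix (samples x features) on an
#'   interval scale (CLR genera, log-z metabolites, pathway abundances).
#' @param metadata data.frame with `sample_id`, `pair_id`, `zygosity`,
#'   `md`.
#' @param layer `"a"`, `"b"` or `"c"`.
#' @param alpha Per-feature significance level (0.05 by default; a looser
#'   0.1 is conventional for noisy predicted-pathway features).
#' @param feature_kind Tag copied into the result (e.g. "genus").
#' @return data.frame of class `layer_result`: `feature`, `layer`,
#'   `feature_kind`, `n_pairs`, `statistic`, `p`, `direction`,
#'   `significant`.
#' @export
pairwise_layer <- function(features, metadata, layer = c("a", "b", "c"),
                           alpha = 0.05, feature_kind = "feature") {
  layer <- match.arg(layer)
  pc <- classify_pairs(metadata)
  disc <- pc$pair_id[pc$class == "discordant" &
                       (layer == "c" |
                          (layer == "a" & pc$zygosity == "MZ") |
                          (layer == "b" & pc$zygosity == "DZ"))]
  if (length(disc) == 0L) stop("no discordant pairs for layer ", layer)
  if (length(disc) < 6L)
    warning("only ", length(disc),
            " discordant pairs in layer ", layer, "; power is very limited")
  md <- metadata[metadata$pair_id %in% disc, , drop = FALSE]
  md <- md[order(md$pair_id, -md$md), , drop = FALSE]  # affected first
  features <- align_samples(features, md)
  aff <- seq(1L, nrow(md), by = 2L)
  diffs <- features[aff, , drop = FALSE] - features[aff + 1L, , drop = FALSE]
  res <- lapply(seq_len(ncol(diffs)), function(j) signed_rank_test(diffs[, j]))
  out <- data.frame(
    feature = colnames(features),
    layer = layer, feature_kind = feature_kind,
    n_pairs = length(disc),
    statistic = vapply(res, `[[`, numeric(1L), "statistic"),
    p = vapply(res, `[[`, numeric(1L), "p.value"),
    direction = vapply(res, `[[`, numeric(1L), "direction"),
    stringsAsFactors = FALSE)
  out$significant <- out$p < alpha
  class(out) <- c("layer_result", "data.frame")
  out
}

#' Overlaps of significant features between layers
#'
#' Set algebra on the significant-feature sets of two or more layer (or
#' mixed-model screen) results: all pairwise and the full intersection,
#' plus per-layer exclusive sets.
#'
#' @param results Named list of result data.frames, each with columns
#'   `feature` and `significant` (e.g. layers "a", "b", "c").
#' @return List: `sets` (significant features per layer), `pairwise`
#'   (named list of pairwise intersections), `common` (intersection over
#'   all layers), `counts` (summary data.frame).
#' @export
layer_overlaps <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L,
            !is.null(names(results)))
  sets <- lapply(results, function(r) r$feature[r$significant])
  nm <- names(sets)
  pw <- list()
  for (i in seq_along(nm)[-length(nm)])
    for (j in (i + 1L):length(nm))
      pw[[paste(nm[i], nm[j], sep = "&")]] <-
        intersect(sets[[i]], sets[[j]])
  common <- Reduce(intersect, sets)
  counts <- data.frame(
    set = c(nm, names(pw), "all"),
    n = c(vapply(sets, length, integer(1L)),
          vapply(pw, length, integer(1L)), length(common)),
    stringsAsFactors = FALSE)
  list(sets = sets, pairwise = pw, common = common, counts = counts)
}

#' Build the feature-by-layer consistency ledger
#'
#' One row per feature that was significant in at least one layer; one
#' column of ticks per layer; a `consistent` flag set when the feature is
#' significant in every layer in which it was tested. For the mixed-model
#' layers the tick is placed at raw p < `lmm_tick_alpha` by default (the
#' convention used when FDR-adjusted calls are reported separately);
#' `lmm_tick = "q"` instead ticks at the FDR threshold used in the screen.
#'
#' @param layer_results Named list of `layer_result` data.frames (layers
#'   a-c).
#' @param lmm_results Named list of mixed-model screen results (layers d-e,
#'   from [screen_features()]), or `NULL`.
#' @param lmm_tick `"p"` (raw p-value tick, default) or `"q"` (FDR tick).
#' @param lmm_tick_alpha Raw-p tick level (default 0.05).
#' @param annotation Optional data.frame `feature`, `family` merged into
#'   the ledger.
#' @return data.frame of class `consistency_ledger`: `feature`, one
#'   logical column per layer, `direction` (from the last layer the
#'   feature was significant in), `consistent`.
#' @export
build_ledger <- function(layer_results, lmm_results = NULL,
                         lmm_tick = c("p", "q"), lmm_tick_alpha = 0.05,
                         annotation = NULL) {
  lmm_tick <- match.arg(lmm_tick)
  all_res <- layer_results
  if (!is.null(lmm_results)) {
    lmm_results <- lapply(lmm_results, function(r) {
      r$significant <- if (lmm_tick == "p") r$p < lmm_tick_alpha else
        r$q < attr(r, "fdr_threshold")
      r
    })
    all_res <- c(all_res, lmm_results)
  }
  stopifnot(!is.null(names(all_res)))
  feats <- unique(unlist(lapply(all_res, function(r) r$feature[r$significant])))
  if (length(feats) == 0L) {
    out <- data.frame(feature = character(0L), consistent = logical(0L))
    class(out) <- c("consistency_ledger", "data.frame")
    return(out)
  }
  ticks <- sapply(all_res, function(r) {
    v <- rep(NA, length(feats))        # NA = not tested in that layer
    m <- match(feats, r$feature)
    v[!is.na(m)] <- r$significant[m[!is.na(m)]]
    v
  })
  ticks <- matrix(ticks, nrow = length(feats),
                  dimnames = list(NULL, names(all_res)))
  dirs <- rep(NA_real_, length(feats))
  for (r in all_res) {
    m <- match(feats, r$feature)
    dcol <- if ("direction" %in% names(r)) r$direction else
      sign(r$beta_md)
    hit <- !is.na(m) & r$significant[ifelse(is.na(m), 1L, m)]
    dirs[hit] <- dcol[m[hit]]
  }
  out <- data.frame(feature = feats, ticks, direction = dirs,
                    consistent = apply(ticks, 1L, function(v)
                      all(v[!is.na(v)]) && any(!is.na(v))),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(annotation))
    out <- merge(out, annotation, by = "feature", all.x = TRUE, sort = FALSE)
  class(out) <- c("consistency_ledger", "data.frame")
  out
}
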