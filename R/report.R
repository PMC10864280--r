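#' Run the full pyramid-layer analysis and write a report bundle
#'
#' Orchestrates the pipeline end to end: preprocessing (taxon and depth
#' filters, CLR; metabolite missingness rule, imputation, log-z scaling;
#' covariate imputation), pair-level cohort description, beta-diversity
#' comparisons, pairwise screening of the discordant-pair layers a-c for
#' every feature family, the zygosity-stratified mixed-model screens d and
#' e, the feature-by-layer consistency ledger, and the genus-pathway
#' correlation network computed on the layer-d population. All tables are
#' written as TSV under `out_dir` together with a short markdown summary;
#' with a fixed input cohort the outputs are byte-identical across runs.
#'
#' @param counts Genus (or ASV) count matrix, samples x features.
#' @param metabolites Metabolite concentration matrix, `NA` = missing.
#' @param pathways Predicted pathway abundance matrix.
#' @param metadata Individual-level metadata (`sample_id`, `pair_id`,
#'   `zygosity`, `md`, covariates).
#' @param out_dir Output directory, created if absent; `NULL` skips
#'   writing.
#' @param taxonomy Optional feature-to-genus map for
#'   [agglomerate_to_genus()]; `NULL` when `counts` is already at genus
#'   level.
#' @param min_depth Sequencing-depth exclusion threshold.
#' @param alpha_pairwise Raw significance level of layers a-c (genera and
#'   metabolites).
#' @param alpha_pathway Raw significance level of layers a-c for predicted
#'   pathways.
#' @param fdr_features BH threshold of the mixed-model screens for genera
#'   and metabolites.
#' @param fdr_pathways BH threshold of the mixed-model screens for
#'   pathways.
#' @param covariates Mixed-model covariate set.
#' @return A list of class `pyramid_report` with every intermediate result
#'   (`cohort_summary`, `association_tests`, `dissimilarity`, `layers`,
#'   `screens`, `ledger`, `network`, `preprocessed`), invisibly.
#' @export
run_all <- function(counts, metabolites, pathways, metadata,
                    out_dir = NULL, taxonomy = NULL,
                    min_depth = 10000,
                    alpha_pairwise = 0.05, alpha_pathway = 0.1,
                    fdr_features = 0.2, fdr_pathways = 0.25,
                    covariates = c("age", "sex", "bmi", "antibiotics",
                                   "veg", "fruit")) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", what, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- preprocess -----------------------------------------------------
  pre <- stage("preprocess", {
    if (!is.null(taxonomy)) counts <- agglomerate_to_genus(counts, taxonomy)
    counts <- filter_taxa(filter_samples_by_depth(counts, min_depth))
    keep <- rownames(counts)
    metadata <- metadata[metadata$sample_id %in% keep, , drop = FALSE]
    # drop pairs broken by sample filtering, then re-align all tables
    sizes <- table(metadata$pair_id)
    metadata <- metadata[metadata$pair_id %in% names(sizes)[sizes == 2L], ,
                         drop = FALSE]
    metadata <- impute_confounders(metadata, cols = covariates)
    counts <- counts[metadata$sample_id, , drop = FALSE]
    list(counts = counts,
         clr = clr_transform(counts),
         metab = preprocess_metabolites(
           align_samples(metabolites, metadata)),
         pathways = align_samples(pathways, metadata),
         metadata = metadata)
  })
  md <- pre$metadata

  ## -- cohort structure ----------------------------------------------
  summ <- stage("cohort_structure", cohort_summary(md))
  assoc <- stage("cohort_structure", zygosity_association_tests(md))

  ## -- dissimilarity ---------------------------------------------------
  dis <- stage("dissimilarity", rbind(
    compare_dissimilarity(pair_distances(pre$counts, md, "bray")),
    compare_dissimilarity(pair_distances(pre$metab, md, "euclidean"))))

  ## -- pairwise layers a-c ---------------------------------------------
  fams <- list(genus = list(x = pre$clr, alpha = alpha_pairwise),
               metabolite = list(x = pre$metab, alpha = alpha_pairwise),
               pathway = list(x = pre$pathways, alpha = alpha_pathway))
  layers <- stage("pyramid", {
    out <- list()
    for (fam in names(fams))
      for (ly in c("a", "b", "c"))
        out[[paste(fam, ly, sep = "_")]] <-
          pairwise_layer(fams[[fam]]$x, md, layer = ly,
                         alpha = fams[[fam]]$alpha, feature_kind = fam)
    out
  })

  ## -- mixed-model screens d, e ----------------------------------------
  screens <- stage("lmm", {
    out <- list()
    for (fam in names(fams)) {
      thr <- if (fam == "pathway") fdr_pathways else fdr_features
      for (st in c("d", "e"))
        out[[paste(fam, st, sep = "_")]] <-
          screen_features(fams[[fam]]$x, md, setup = st,
                          fdr_threshold = thr, covariates = covariates)
    }
    out
  })

  ## -- consistency ledger ----------------------------------------------
  ledgers <- stage("ledger", {
    lapply(stats::setNames(nm = names(fams)), function(fam) {
      build_ledger(
        layer_results = stats::setNames(
          layers[paste(fam, c("a", "b", "c"), sep = "_")],
          c("a", "b", "c")),
        lmm_results = stats::setNames(
          screens[paste(fam, c("d", "e"), sep = "_")],
          c("d", "e")))
    })
  })

  ## -- network on the layer-d population --------------------------------
  network <- stage("network", {
    diff_g <- unique(unlist(c(
      lapply(layers[paste0("genus_", c("a", "b", "c"))],
             function(r) r$feature[r$significant]),
      lapply(screens[paste0("genus_", c("d", "e"))],
             function(r) r$feature[r$significant]))))
    diff_p <- unique(unlist(c(
      lapply(layers[paste0("pathway_", c("a", "b", "c"))],
             function(r) r$feature[r$significant]),
      lapply(screens[paste0("pathway_", c("d", "e"))],
             function(r) r$feature[r$significant]))))
    if (length(diff_g) && length(diff_p))
      build_network(pre$clr, pre$pathways, setup_samples(md, "d"),
                    diff_g, diff_p)
    else suppressWarnings(
      build_network(pre$clr, pre$pathways, setup_samples(md, "d"),
                    character(0), character(0)))
  })

  report <- structure(
    list(cohort_summary = summ, association_tests = assoc,
         dissimilarity = dis, layers = layers, screens = screens,
         ledger = ledgers, network = network, preprocessed = pre),
    class = "pyramid_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

#' Write a `pyramid_report` bundle to disk
#'
#' @param report A `pyramid_report` from [run_all()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(x, f)
    utils::write.table(as.data.frame(x), file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$cohort_summary, "cohort_summary.tsv")
  wt(report$association_tests, "association_tests.tsv")
  wt(report$dissimilarity, "dissimilarity_summary.tsv")
  for (nm in names(report$layers))
    wt(report$layers[[nm]], paste0("layer_", nm, ".tsv"))
  for (nm in names(report$screens))
    wt(report$screens[[nm]], paste0("lmm_", nm, ".tsv"))
  for (nm in names(report$ledger))
    wt(report$ledger[[nm]], paste0("ledger_", nm, ".tsv"))
  write_edges(report$network, file.path(out_dir, "edges.tsv"))
  writeLines(report_summary_lines(report),
             file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

report_summary_lines <- function(report) {
  s <- report$cohort_summary
  hits <- vapply(report$layers, function(r) sum(r$significant), integer(1L))
  shits <- vapply(report$screens, function(r) sum(r$significant), integer(1L))
  cons <- vapply(report$ledger, function(l) sum(l$consistent), integer(1L))
  c("# Pyramid-layer co-twin analysis",
    "",
    "## Cohort",
    sprintf("- %s: %d pairs (%d discordant, %d both affected, %d both healthy); prevalence %.1f%%; proband-wise concordance %.0f%%",
            s$zygosity, s$total_pairs, s$discordant_pairs,
            s$concordant_affected_pairs, s$concordant_healthy_pairs,
            100 * s$prevalence, 100 * s$proband_concordance),
    sprintf("- total pairs: %d", attr(s, "total_pairs")),
    "",
    "## Per-layer significant features",
    sprintf("- %s: %d", names(hits), hits),
    sprintf("- %s (FDR): %d", names(shits), shits),
    "",
    "## Consistency ledger",
    sprintf("- %s: %d feature(s) consistent across all tested layers",
            names(cons), cons),
    "",
    sprintf("## Network: %d genus-pathway edge(s)", nrow(report$network)))
}

#' @export
print.pyramid_report <- function(x, ...) {
  writeLines(report_summary_lines(x))
  invisible(x)
}
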