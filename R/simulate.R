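#' Simulation configuration for a synthetic twin cohort
#'
#' Bundles every knob of the synthetic twin-cohort generator. The defaults
#' describe a cohort with the structure of a typical adult twin registry
#' sample: 97 monozygotic (MZ) and 122 dizygotic (DZ) same-sex pairs, a
#' lifetime mental-disorder (MD) prevalence of about a third, and MZ twins
#' more concordant in phenotype (liability correlation 0.8 vs 0.4) and more
#' similar in their microbiomes (larger pair-shared variance) than DZ twins.
#'
#' Phenotypes follow a liability-threshold model: each pair draws a bivariate
#' standard-normal liability with correlation `liability_corr_mz` (MZ) or
#' `liability_corr_dz` (DZ), and a twin is affected when its liability
#' exceeds `qnorm(1 - prevalence)`. Microbial counts come from a
#' log-normal-multinomial model in which each sample's latent log-abundance
#' is a genus baseline plus a pair-shared Gaussian effect (variance
#' `pair_var_mz` or `pair_var_dz`; larger shared variance makes co-twins
#' more similar relative to strangers), plus a disease shift on the spiked
#' genera, plus individual noise (`residual_var`); counts are then drawn
#' multinomially at `seq_depth` reads, so every sample's counts sum to
#' `seq_depth`. Metabolites are an analogous pair-correlated log-normal
#' panel with missing-at-random masking; predicted pathways are noisy linear
#' combinations of genus CLR values (see [simulate_pathways()]).
#'
#' @param n_mz_pairs,n_dz_pairs Number of MZ / DZ twin pairs.
#' @param prevalence Population phenotype prevalence in \[0, 1\].
#' @param liability_corr_mz,liability_corr_dz Within-pair liability
#'   correlations in \[0, 1\]; expected proband-wise concordance increases
#'   monotonically in these.
#' @param n_genera,n_metabolites,n_pathways Feature-universe sizes.
#' @param n_affected_genera,n_affected_metabolites Number of features given a
#'   true disease effect.
#' @param effect_size_genus Disease shift on the latent log-abundance scale.
#'   The default was fixed once by simulation so that a single spiked genus
#'   reaches roughly 90% recovery power in the mixed-model screen of the
#'   healthy-co-twin vs MD-twin setup at FDR < 0.2 under this configuration.
#' @param effect_size_metabolite Disease shift on the latent (log) metabolite
#'   scale, in residual-SD units.
#' @param pair_var_mz,pair_var_dz Variance of the pair-shared effect on the
#'   latent scale, per zygosity.
#' @param residual_var Individual (within-pair) latent variance.
#' @param baseline_sd SD of the per-genus baseline log-abundance; controls
#'   how uneven the average composition is.
#' @param seq_depth Sequencing depth (reads per sample).
#' @param missing_rate_metabolite Missing-at-random cell probability for the
#'   metabolite panel.
#' @param pathway_noise_sd SD of the additive noise on simulated pathways.
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_mz_pairs = 97L, n_dz_pairs = 122L,
                       prevalence = 0.33,
                       liability_corr_mz = 0.8, liability_corr_dz = 0.4,
                       n_genera = 50L, n_metabolites = 100L,
                       n_pathways = 40L,
                       n_affected_genera = 1L, n_affected_metabolites = 3L,
                       effect_size_genus = 0.7,
                       effect_size_metabolite = 0.8,
                       pair_var_mz = 1.0, pair_var_dz = 0.6,
                       residual_var = 1.0, baseline_sd = 1.5,
                       seq_depth = 20000L,
                       missing_rate_metabolite = 0.05,
                       pathway_noise_sd = 1.0,
                       seed = 1L) {
  cfg <- list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    prevalence = prevalence,
    liability_corr_mz = liability_corr_mz,
    liability_corr_dz = liability_corr_dz,
    n_genera = as.integer(n_genera),
    n_metabolites = as.integer(n_metabolites),
    n_pathways = as.integer(n_pathways),
    n_affected_genera = as.integer(n_affected_genera),
    n_affected_metabolites = as.integer(n_affected_metabolites),
    effect_size_genus = effect_size_genus,
    effect_size_metabolite = effect_size_metabolite,
    pair_var_mz = pair_var_mz, pair_var_dz = pair_var_dz,
    residual_var = residual_var, baseline_sd = baseline_sd,
    seq_depth = as.integer(seq_depth),
    missing_rate_metabolite = missing_rate_metabolite,
    pathway_noise_sd = pathway_noise_sd,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  counts <- c("n_mz_pairs", "n_dz_pairs", "n_genera", "n_metabolites",
              "n_pathways", "seq_depth")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop(sprintf("'%s' must be a positive count", nm))
  probs <- c("prevalence", "missing_rate_metabolite")
  for (nm in probs)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm))
  for (nm in c("liability_corr_mz", "liability_corr_dz"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must be a correlation in [0, 1]", nm))
  for (nm in c("pair_var_mz", "pair_var_dz", "residual_var", "baseline_sd",
               "pathway_noise_sd"))
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm))
  if (cfg$n_affected_genera > cfg$n_genera ||
      cfg$n_affected_metabolites > cfg$n_metabolites)
    stop("affected feature counts exceed the feature universe")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Twin-cohort simulation configuration\n")
  cat(sprintf("  pairs: %d MZ + %d DZ; prevalence %.2f; liability corr %.2f/%.2f\n",
              x$n_mz_pairs, x$n_dz_pairs, x$prevalence,
              x$liability_corr_mz, x$liability_corr_dz))
  cat(sprintf("  features: %d genera (%d spiked at %+.2f), %d metabolites, %d pathways\n",
              x$n_genera, x$n_affected_genera, x$effect_size_genus,
              x$n_metabolites, x$n_pathways))
  cat(sprintf("  variances: pair MZ %.2f / DZ %.2f, residual %.2f; depth %d\n",
              x$pair_var_mz, x$pair_var_dz, x$residual_var, x$seq_depth))
  invisible(x)
}

#' Simulate binary phenotypes under a liability-threshold model
#'
#' Draws, for every pair, a bivariate standard-normal liability with the
#' zygosity-specific correlation and thresholds it at
#' `qnorm(1 - prevalence)`. Perfect correlation therefore forces both twins
#' to the same status, and zero correlation makes the co-twin of an affected
#' individual affected with probability equal to the prevalence.
#'
#' @param config A [sim_config()].
#' @return A data.frame with one row per individual: `sample_id`, `pair_id`,
#'   `zygosity` ("MZ"/"DZ"), `md` (0/1 disease status).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_pairs <- config$n_mz_pairs + config$n_dz_pairs
  zyg <- rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs))
  r <- ifelse(zyg == "MZ", config$liability_corr_mz, config$liability_corr_dz)
  # shared/unique decomposition is valid for r in [0, 1]
  shared <- stats::rnorm(n_pairs)
  l1 <- sqrt(r) * shared + sqrt(1 - r) * stats::rnorm(n_pairs)
  l2 <- sqrt(r) * shared + sqrt(1 - r) * stats::rnorm(n_pairs)
  thr <- stats::qnorm(1 - config$prevalence)
  pair_id <- sprintf("P%03d", seq_len(n_pairs))
  data.frame(
    sample_id = paste0(rep(pair_id, each = 2L), c("a", "b")),
    pair_id = rep(pair_id, each = 2L),
    zygosity = rep(zyg, each = 2L),
    md = as.integer(as.vector(rbind(l1, l2)) > thr),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth manifest for a simulated cohort
#'
#' Chooses which genera and metabolites carry a true disease effect and
#' builds the pathway loading matrix. Affected genera are drawn from the
#' more abundant half of the baseline composition so that a latent-scale
#' shift is not swamped by multinomial sampling noise on rare taxa; signs
#' alternate (+, -, +, ...). The default pathway loading matrix assigns each
#' pathway one driving genus (cycling through the genus list) with weight 1.
#'
#' @param config A [sim_config()].
#' @param baseline Per-genus baseline log-abundances (length `n_genera`).
#' @return A list of class `ground_truth` with elements `affected_genera`
#'   and `affected_metabolites` (named numeric vectors of signed effects)
#'   and `pathway_loadings` (pathway x genus matrix).
#' @export
make_ground_truth <- function(config, baseline) {
  stopifnot(inherits(config, "sim_config"), length(baseline) == config$n_genera)
  genera <- genus_names(config$n_genera)
  metabs <- metabolite_names(config$n_metabolites)
  top <- genera[order(baseline, decreasing = TRUE)][
    seq_len(max(config$n_affected_genera, ceiling(config$n_genera / 2)))]
  ag <- sample(top, config$n_affected_genera)
  sg <- rep_len(c(1, -1), config$n_affected_genera)
  am <- sample(metabs, config$n_affected_metabolites)
  sm <- rep_len(c(1, -1), config$n_affected_metabolites)
  load <- matrix(0, nrow = config$n_pathways, ncol = config$n_genera,
                 dimnames = list(pathway_names(config$n_pathways), genera))
  for (j in seq_len(config$n_pathways))
    load[j, ((j - 1L) %% config$n_genera) + 1L] <- 1
  structure(list(
    affected_genera = stats::setNames(sg * config$effect_size_genus, ag),
    affected_metabolites = stats::setNames(sm * config$effect_size_metabolite, am),
    pathway_loadings = load
  ), class = "ground_truth")
}

genus_names <- function(n) sprintf("g%03d", seq_len(n))
metabolite_names <- function(n) sprintf("m%03d", seq_len(n))
pathway_names <- function(n) sprintf("ko%03d", seq_len(n))

#' Simulate a genus-level count table
#'
#' Latent log-abundance for sample i and genus g is
#' `baseline_g + pair_effect_{j[i],g} + md_i * effect_g + eps_{ig}` with the
#' pair effect variance set by the pair's zygosity; counts are multinomial
#' draws of `seq_depth` reads from `softmax(latent)`, so each row sums to
#' the sequencing depth.
#'
#' @param config A [sim_config()].
#' @param phenotypes Output of [simulate_phenotypes()].
#' @param truth Output of [make_ground_truth()].
#' @param baseline Per-genus baseline log-abundances.
#' @return Integer count matrix (samples x genera) with sample IDs as
#'   rownames.
#' @export
simulate_counts <- function(config, phenotypes, truth, baseline) {
  stopifnot(inherits(config, "sim_config"))
  if (config$seq_depth <= 0) stop("sequencing depth must be positive")
  n <- nrow(phenotypes)
  G <- config$n_genera
  genera <- genus_names(G)
  eff <- stats::setNames(numeric(G), genera)
  eff[names(truth$affected_genera)] <- truth$affected_genera
  pair_idx <- match(phenotypes$pair_id, unique(phenotypes$pair_id))
  n_pairs <- max(pair_idx)
  pair_zyg <- phenotypes$zygosity[!duplicated(phenotypes$pair_id)]
  pair_sd <- ifelse(pair_zyg == "MZ", sqrt(config$pair_var_mz),
                    sqrt(config$pair_var_dz))
  pair_eff <- matrix(stats::rnorm(n_pairs * G), n_pairs, G) * pair_sd
  eta <- matrix(rep(baseline, each = n), n, G) +
    pair_eff[pair_idx, , drop = FALSE] +
    outer(phenotypes$md, eff) +
    matrix(stats::rnorm(n * G, sd = sqrt(config$residual_var)), n, G)
  prob <- exp(eta - apply(eta, 1L, max))
  prob <- prob / rowSums(prob)
  counts <- t(apply(prob, 1L, function(p)
    stats::rmultinom(1L, size = config$seq_depth, prob = p)[, 1L]))
  dimnames(counts) <- list(phenotypes$sample_id, genera)
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a pair-correlated metabolite panel with missingness
#'
#' Each metabolite is log-normal: its latent value is a metabolite-specific
#' mean plus a pair-shared effect, a disease shift for the spiked
#' metabolites, and individual noise, then exponentiated so concentrations
#' are positive and right-skewed (as NMR panels are). Cells are masked
#' missing-at-random (`NA`, never zero) at `missing_rate_metabolite`.
#'
#' @inheritParams simulate_counts
#' @return Numeric matrix (samples x metabolites) with `NA` for missing.
#' @export
simulate_metabolites <- function(config, phenotypes, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(phenotypes)
  M <- config$n_metabolites
  metabs <- metabolite_names(M)
  eff <- stats::setNames(numeric(M), metabs)
  eff[names(truth$affected_metabolites)] <- truth$affected_metabolites
  mu <- stats::rnorm(M, mean = 1, sd = 0.5)
  pair_idx <- match(phenotypes$pair_id, unique(phenotypes$pair_id))
  n_pairs <- max(pair_idx)
  pair_zyg <- phenotypes$zygosity[!duplicated(phenotypes$pair_id)]
  pair_sd <- ifelse(pair_zyg == "MZ", sqrt(config$pair_var_mz),
                    sqrt(config$pair_var_dz))
  pair_eff <- matrix(stats::rnorm(n_pairs * M), n_pairs, M) * pair_sd
  lat <- matrix(rep(mu, each = n), n, M) +
    pair_eff[pair_idx, , drop = FALSE] +
    outer(phenotypes$md, eff) +
    matrix(stats::rnorm(n * M, sd = sqrt(config$residual_var)), n, M)
  x <- exp(lat)
  if (config$missing_rate_metabolite > 0) {
    mask <- matrix(stats::runif(n * M) < config$missing_rate_metabolite, n, M)
    x[mask] <- NA_real_
  }
  dimnames(x) <- list(phenotypes$sample_id, metabs)
  x
}

#' Simulate predicted pathway abundances from genus counts
#'
#' Pathway j is `sum_g loadings[j, g] * CLR(g) + noise`, so known
#' genus-pathway rank correlations exist by construction and are recoverable
#' by the correlation-network stage. An identity loading with zero noise
#' makes each pathway a copy of its genus's CLR values (Spearman rho = 1).
#'
#' @param counts Genus count matrix (samples x genera).
#' @param truth A `ground_truth` (its `pathway_loadings` are used).
#' @param noise_sd SD of the additive Gaussian noise.
#' @return Numeric matrix (samples x pathways).
#' @export
simulate_pathways <- function(counts, truth, noise_sd = 1.0) {
  clr <- clr_transform(counts)
  load <- truth$pathway_loadings
  stopifnot(ncol(clr) == ncol(load))
  pw <- clr %*% t(load)
  if (noise_sd > 0)
    pw <- pw + matrix(stats::rnorm(length(pw), sd = noise_sd),
                      nrow(pw), ncol(pw))
  dimnames(pw) <- list(rownames(counts), rownames(load))
  pw
}

#' Simulate host covariates (confounders)
#'
#' Emits plausible marginal distributions for the covariates the mixed model
#' adjusts for: age (shared within a pair, mean 65 SD 7.7 years), sex
#' (pair-shared, 97% female as in predominantly female twin registries), BMI
#' (pair-correlated, mean 26.3 SD 4.7 kg/m^2), antibiotics use in the prior
#' month (Bernoulli 0.1), and weekly vegetable and fruit intake
#' (pair-correlated, truncated at zero). With `leakage > 0` BMI is nudged by
#' disease status, which creates confounded features for testing that the
#' mixed model's covariate adjustment works.
#'
#' @param config A [sim_config()].
#' @param phenotypes Output of [simulate_phenotypes()].
#' @param leakage Additive shift of BMI per MD unit (default 0, no leakage).
#' @return `phenotypes` with columns `age`, `sex` ("F"/"M"), `bmi`,
#'   `antibiotics` (0/1), `veg`, `fruit` appended.
#' @export
simulate_confounders <- function(config, phenotypes, leakage = 0) {
  stopifnot(inherits(config, "sim_config"))
  pid <- unique(phenotypes$pair_id)
  n_pairs <- length(pid)
  idx <- match(phenotypes$pair_id, pid)
  n <- nrow(phenotypes)
  age_pair <- pmin(pmax(stats::rnorm(n_pairs, 65, 7.7), 40), 90)
  sex_pair <- ifelse(stats::runif(n_pairs) < 0.97, "F", "M")
  bmi <- pmax(16, 26.3 + (stats::rnorm(n_pairs, sd = sqrt(0.5)) * 4.7)[idx] +
                stats::rnorm(n, sd = sqrt(0.5)) * 4.7 +
                leakage * phenotypes$md)
  veg <- pmax(0, round(7 + (stats::rnorm(n_pairs, sd = 2))[idx] +
                         stats::rnorm(n, sd = 2)))
  fruit <- pmax(0, round(5 + (stats::rnorm(n_pairs, sd = 2))[idx] +
                           stats::rnorm(n, sd = 2)))
  cbind(phenotypes,
        data.frame(age = age_pair[idx], sex = sex_pair[idx], bmi = bmi,
                   antibiotics = as.integer(stats::runif(n) < 0.1),
                   veg = veg, fruit = fruit, stringsAsFactors = FALSE))
}

#' Simulate a complete twin cohort
#'
#' Orchestrates phenotypes, ground truth, counts, metabolites, pathways and
#' confounders under a single seed; a fixed seed yields a bit-identical
#' cohort.
#'
#' @param config A [sim_config()].
#' @param leakage Passed to [simulate_confounders()].
#' @return A list of class `twin_cohort`: `metadata` (data.frame), `counts`,
#'   `metabolites`, `pathways` (matrices keyed by sample ID), `truth`
#'   (`ground_truth`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), leakage = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  phen <- simulate_phenotypes(config)
  baseline <- stats::rnorm(config$n_genera, sd = config$baseline_sd)
  truth <- make_ground_truth(config, baseline)
  counts <- simulate_counts(config, phen, truth, baseline)
  metab <- simulate_metabolites(config, phen, truth)
  pathways <- simulate_pathways(counts, truth,
                                noise_sd = config$pathway_noise_sd)
  metadata <- simulate_confounders(config, phen, leakage = leakage)
  structure(list(metadata = metadata, counts = counts, metabolites = metab,
                 pathways = pathways, truth = truth, config = config,
                 baseline = stats::setNames(baseline,
                                            genus_names(config$n_genera))),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Synthetic twin cohort: %d individuals (%d pairs), %d genera, %d metabolites, %d pathways\n",
              nrow(x$metadata), length(unique(x$metadata$pair_id)),
              ncol(x$counts), ncol(x$metabolites), ncol(x$pathways)))
  cat(sprintf("  affected: %s\n",
              paste(names(x$truth$affected_genera), collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to TSV files plus a ground-truth JSON
#'
#' Emits `counts.tsv`, `metabolites.tsv` (empty cell = missing),
#' `pathways.tsv`, `metadata.tsv` and `truth.json` into `dir`.
#'
#' @param cohort A `twin_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_feature_table(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  write_feature_table(cohort$pathways, file.path(dir, "pathways.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    affected_genera = as.list(cohort$truth$affected_genera),
    affected_metabolites = as.list(cohort$truth$affected_metabolites),
    pathway_loadings = cohort$truth$pathway_loadings
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
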