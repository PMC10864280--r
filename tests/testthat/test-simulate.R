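test_that("config validation rejects impossible values", {
  expect_error(sim_config(prevalence = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(liability_corr_mz = -0.2), "correlation")
  expect_error(sim_config(n_genera = 0), "positive count")
  expect_error(sim_config(seq_depth = -5), "positive count")
  expect_error(sim_config(n_affected_genera = 30, n_genera = 10), "exceed")
})

test_that("a fixed seed gives a bit-identical cohort", {
  a <- simulate_cohort(small_config(seed = 11L))
  b <- simulate_cohort(small_config(seed = 11L))
  expect_identical(a$counts, b$counts)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$metadata, b$metadata)
  c2 <- simulate_cohort(small_config(seed = 12L))
  expect_false(identical(a$counts, c2$counts))
})

test_that("counts are nonnegative integers summing to the sequencing depth", {
  co <- simulate_cohort(small_config(seq_depth = 4321L))
  expect_true(all(co$counts >= 0))
  expect_type(co$counts, "integer")
  expect_true(all(rowSums(co$counts) == 4321L))
})

test_that("perfect liability correlation makes every pair concordant", {
  cfg <- small_config(liability_corr_mz = 1, liability_corr_dz = 1,
                      prevalence = 0.3, seed = 3L)
  set.seed(3L)
  ph <- simulate_phenotypes(cfg)
  pc <- classify_pairs(ph)
  expect_equal(sum(pc$class == "discordant"), 0L)
})

test_that("zero liability correlation gives co-twin risk equal to prevalence", {
  cfg <- sim_config(n_mz_pairs = 5000L, n_dz_pairs = 1L, prevalence = 0.3,
                    liability_corr_mz = 0, liability_corr_dz = 0, seed = 4L)
  set.seed(4L)
  ph <- simulate_phenotypes(cfg)
  pc <- classify_pairs(ph[ph$zygosity == "MZ", ])
  s <- attr(pc, "summary")
  conc <- proband_concordance(s["MZ", "concordant_affected"],
                              s["MZ", "discordant"])
  # binomial SE of the concordance estimate at ~3000 affected probands
  expect_lt(abs(conc - 0.3), 3 * sqrt(0.3 * 0.7 / 2500))
})

test_that("empirical proband concordance matches the quadrature oracle and is higher for MZ", {
  cfg <- sim_config(n_mz_pairs = 5000L, n_dz_pairs = 5000L,
                    prevalence = 0.33, liability_corr_mz = 0.8,
                    liability_corr_dz = 0.4, seed = 5L)
  set.seed(5L)
  ph <- simulate_phenotypes(cfg)
  pc <- classify_pairs(ph)
  s <- attr(pc, "summary")
  for (z in c("MZ", "DZ")) {
    r <- if (z == "MZ") 0.8 else 0.4
    expected <- concordance_oracle(r, 0.33)
    got <- proband_concordance(s[z, "concordant_affected"],
                               s[z, "discordant"])
    n_prob <- 2 * s[z, "concordant_affected"] + s[z, "discordant"]
    expect_lt(abs(got - expected),
              4 * sqrt(expected * (1 - expected) / n_prob))
  }
  expect_gt(proband_concordance(s["MZ", "concordant_affected"],
                                s["MZ", "discordant"]),
            proband_concordance(s["DZ", "concordant_affected"],
                                s["DZ", "discordant"]))
})

test_that("oracle itself is sane at its closed-form ends", {
  expect_equal(concordance_oracle(1, 0.3), 1)
  expect_equal(concordance_oracle(0, 0.3), 0.3, tolerance = 1e-8)
})

test_that("a spiked genus shifts its CLR mean in the spiked direction", {
  cfg <- sim_config(n_mz_pairs = 300L, n_dz_pairs = 300L, n_genera = 30L,
                    n_affected_genera = 1L, effect_size_genus = 1,
                    seq_depth = 5000L, seed = 6L)
  co <- simulate_cohort(cfg)
  g <- names(co$truth$affected_genera)[1]
  clr <- clr_transform(co$counts)
  d <- mean(clr[co$metadata$md == 1, g]) - mean(clr[co$metadata$md == 0, g])
  expect_gt(d * sign(co$truth$affected_genera[1]), 0.2)
})

test_that("metabolite missingness behaves as configured", {
  co0 <- simulate_cohort(small_config(missing_rate_metabolite = 0))
  expect_false(anyNA(co0$metabolites))
  co3 <- simulate_cohort(small_config(missing_rate_metabolite = 0.3,
                                      seed = 8L))
  expect_gt(mean(is.na(co3$metabolites)), 0.25)
  # a feature missing at rate 0.3 must fall to the 25% missingness rule
  pp <- preprocess_metabolites(co3$metabolites)
  expect_lt(ncol(pp), ncol(co3$metabolites))
})

test_that("identity pathway loadings with zero noise give perfect rank correlation", {
  cfg <- small_config(n_pathways = 10L, n_genera = 10L,
                      pathway_noise_sd = 0)
  co <- simulate_cohort(cfg)
  clr <- clr_transform(co$counts)
  for (j in 1:3) {
    g <- colnames(clr)[j]
    expect_equal(spearman_cor(clr[, g], co$pathways[, j])$rho, 1)
  }
})

test_that("confounders are pair-correlated and age/sex shared within pair", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 400L, n_dz_pairs = 400L,
                                   n_genera = 5L, n_metabolites = 5L,
                                   n_pathways = 2L, seq_depth = 1000L,
                                   seed = 9L))
  md <- co$metadata
  first <- !duplicated(md$pair_id)
  expect_true(all(tapply(md$age, md$pair_id, function(a) a[1] == a[2])))
  expect_true(all(tapply(md$sex, md$pair_id,
                         function(s) s[1] == s[2])))
  bmi1 <- md$bmi[first]; bmi2 <- md$bmi[!first]
  expect_gt(cor(bmi1, bmi2), 0.2)
})

test_that("cohort round-trips through the TSV + JSON bundle", {
  co <- simulate_cohort(small_config(missing_rate_metabolite = 0.1))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  counts <- read_feature_table(file.path(dir, "counts.tsv"))
  expect_equal(unname(counts), unname(co$counts * 1.0))
  metab <- read_feature_table(file.path(dir, "metabolites.tsv"))
  expect_equal(is.na(metab), is.na(co$metabolites))
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, co$metadata$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(names(truth$affected_genera),
                  names(co$truth$affected_genera))
})
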