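test_that("block likelihood equals the dense multivariate-normal density", {
  set.seed(51)
  maxdiff <- 0
  for (k in 1:10) {
    n_pairs <- sample(8:20, 1)
    des <- random_twin_design(n_pairs, p_covar = 2)
    y <- rnorm(2 * n_pairs)
    s2 <- runif(1, 0.3, 2); szM <- runif(1, 0, 1.5); szD <- runif(1, 0, 1.5)
    ll <- lmm_loglik(y, des$X, des$pair, des$zygosity, s2, szM, szD)
    ord <- order(des$pair)
    d <- dense_lmm_loglik(y[ord], des$X[ord, ], des$pair[ord],
                          des$zygosity[ord], s2, szM, szD, attr(ll, "beta"))
    maxdiff <- max(maxdiff, abs(as.numeric(ll) - d))
  }
  expect_lt(maxdiff, 1e-8)
})

test_that("profiled GLS at zero pair variance reduces to OLS", {
  set.seed(52)
  des <- random_twin_design(25, p_covar = 1)
  y <- rnorm(50)
  ll <- lmm_loglik(y, des$X, des$pair, des$zygosity, 1.3, 0, 0)
  ord <- order(des$pair)
  b_ols <- stats::coef(stats::lm.fit(des$X[ord, ], y[ord]))
  expect_lt(max(abs(attr(ll, "beta") - b_ols)), 1e-8)
})

test_that("the equal-variance constrained fit matches an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(53)
  for (k in 1:3) {
    des <- random_twin_design(60, p_covar = 1)
    y <- simulate_lmm_response(des, beta = c(1, 0.5, 0.3),
                               s2 = 1, szM = 0.6, szD = 0.6)
    f <- fit_lmm(y, des$X, des$pair, des$zygosity, equal_pair_var = TRUE)
    m <- lme4::lmer(y ~ md + c1 + (1 | pair),
                    data = data.frame(y = y, md = des$X[, "md"],
                                      c1 = des$X[, "c1"], pair = des$pair),
                    REML = FALSE)
    expect_lt(abs(f$loglik - as.numeric(stats::logLik(m))), 1e-6)
    expect_lt(max(abs(f$coefficients$estimate -
                        unname(lme4::fixef(m)))), 1e-5)
    # the zygosity-stratified model nests the constrained one
    fu <- fit_lmm(y, des$X, des$pair, des$zygosity)
    expect_gte(fu$loglik, f$loglik - 1e-8)
  }
})

test_that("the optimum dominates random variance evaluations", {
  set.seed(54)
  des <- random_twin_design(40, p_covar = 0)
  y <- simulate_lmm_response(des, beta = c(0.5, 1), s2 = 1,
                             szM = 0.8, szD = 0.3)
  f <- fit_lmm(y, des$X, des$pair, des$zygosity)
  for (k in 1:50) {
    ll <- lmm_loglik(y, des$X, des$pair, des$zygosity,
                     runif(1, 0.05, 4), runif(1, 0, 3), runif(1, 0, 3))
    expect_lte(as.numeric(ll), f$loglik + 1e-6)
  }
})

test_that("estimates are invariant to sample reordering and pair relabeling", {
  set.seed(55)
  des <- random_twin_design(40, p_covar = 1)
  y <- simulate_lmm_response(des, beta = c(1, 0.4, 0.2), s2 = 1,
                             szM = 0.7, szD = 0.4)
  f1 <- fit_lmm(y, des$X, des$pair, des$zygosity)
  perm <- sample(length(y))
  f2 <- fit_lmm(y[perm], des$X[perm, ], des$pair[perm], des$zygosity[perm])
  relab <- setNames(sprintf("q%03d", seq_along(unique(des$pair))),
                    sample(unique(des$pair)))
  f3 <- fit_lmm(y, des$X, relab[des$pair], des$zygosity)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
  expect_equal(f1$coefficients$estimate, f3$coefficients$estimate,
               tolerance = 1e-7)
})

test_that("a singular design names the collinear column", {
  des <- random_twin_design(10)
  X <- cbind(des$X, dup = des$X[, "md"])
  expect_error(fit_lmm(rnorm(20), X, des$pair, des$zygosity),
               "singular")
})

test_that("variance components track the generating process", {
  set.seed(56)
  des <- random_twin_design(400, p_covar = 0)
  y <- simulate_lmm_response(des, beta = c(1, 0.5), s2 = 1,
                             szM = 1.2, szD = 0.3)
  f <- fit_lmm(y, des$X, des$pair, des$zygosity)
  expect_lt(abs(f$sigma2 - 1), 0.25)
  expect_lt(abs(f$sigma2_mz - 1.2), 0.45)
  expect_lt(abs(f$sigma2_dz - 0.3), 0.3)
  # with no pair effects the fitted pair variances collapse toward zero
  y0 <- simulate_lmm_response(des, beta = c(1, 0.5), s2 = 1, szM = 0, szD = 0)
  f0 <- fit_lmm(y0, des$X, des$pair, des$zygosity)
  expect_lt(f0$sigma2_mz, 0.1)
  expect_lt(f0$sigma2_dz, 0.1)
  expect_lt(abs(f0$coefficients$estimate[2] - 0.5),
            3 * f0$coefficients$se[2])
})

test_that("screen_features uses the correct setup populations and BH step-up", {
  md <- table1_metadata()
  set.seed(57)
  md$age <- rep(round(rnorm(219, 65, 7)), each = 2)
  md$sex <- rep(sample(c("F", "M"), 219, TRUE, c(0.97, 0.03)), each = 2)
  md$bmi <- rnorm(438, 26, 4)
  md$antibiotics <- rbinom(438, 1, 0.1)
  md$veg <- rpois(438, 7); md$fruit <- rpois(438, 5)
  d_set <- setup_samples(md, "d")
  expect_equal(sum(d_set$md == 0), 74L)
  expect_equal(sum(d_set$md == 1), 144L)
  e_set <- setup_samples(md, "e")
  expect_equal(sum(e_set$md == 0), 294L)
  expect_equal(sum(e_set$md == 1), 144L)
  x <- matrix(rnorm(438 * 4), 438, 4,
              dimnames = list(md$sample_id, paste0("f", 1:4)))
  res <- screen_features(x, md, "d", fdr_threshold = 0.2)
  expect_equal(attr(res, "n_healthy"), 74L)
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
  # hand BH check through the same machinery: q of sorted p (p1 <= ...) is
  # min over j >= i of m * p_j / j
  p <- sort(res$p); m <- length(p)
  hand <- rev(cummin(rev(m * p / seq_len(m))))
  expect_equal(sort(res$q), pmin(hand, 1), tolerance = 1e-12)
  # constant features are skipped with a message
  x2 <- cbind(x, flat = 1)
  expect_message(res2 <- screen_features(x2, md, "d"), "constant")
  expect_false("flat" %in% res2$feature)
})

test_that("a spiked genus is recovered by the layer-d screen with the right sign", {
  cfg <- sim_config(n_mz_pairs = 97L, n_dz_pairs = 122L, n_genera = 25L,
                    n_affected_genera = 1L, effect_size_genus = 1.2,
                    seq_depth = 5000L, seed = 58L)
  co <- simulate_cohort(cfg)
  clr <- clr_transform(co$counts)
  res <- screen_features(clr, co$metadata, "d", fdr_threshold = 0.2)
  g <- names(co$truth$affected_genera)[1]
  expect_true(res$significant[res$feature == g])
  expect_equal(res$direction[res$feature == g],
               unname(sign(co$truth$affected_genera[1])))
})
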