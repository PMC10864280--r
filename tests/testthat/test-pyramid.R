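test_that("signed-rank test matches brute-force enumeration on tie-free data", {
  set.seed(12)
  for (k in 1:40) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n), 6)
    d <- d[d != 0]
    if (length(d) < 4) next
    got <- signed_rank_test(d)
    expect_equal(got$p.value, brute_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("uniform-shift fixture gives the exact doubled tail p", {
  # every affected twin exceeds its co-twin: the most extreme assignment,
  # two-sided exact p = 2 / 2^6
  d <- c(0.3, 0.5, 0.2, 0.8, 0.4, 0.6)
  res <- signed_rank_test(d)
  expect_equal(res$p.value, 2 / 64)
  expect_equal(res$direction, 1)
})

test_that("degenerate differences are handled by convention", {
  res0 <- signed_rank_test(rep(0, 8))
  expect_equal(res0$p.value, 1)
  expect_equal(res0$direction, 0)
  # zeros dropped before ranking
  res <- signed_rank_test(c(0, 0, 0.3, 0.5, 0.2, 0.8, 0.4, 0.6))
  expect_equal(res$p.value, 2 / 64)
  expect_equal(res$n_used, 6L)
})

test_that("null p-values are close to uniform", {
  set.seed(13)
  p <- replicate(400, signed_rank_test(rnorm(20))$p.value)
  grid <- seq(0, 1, 0.01)
  D <- max(abs(vapply(grid, function(g) mean(p <= g), numeric(1)) - grid))
  expect_lt(D, 0.08)
  expect_lt(abs(mean(p) - 0.5), 0.05)
})

test_that("pairwise_layer screens the right pairs and finds a spiked feature", {
  cfg <- sim_config(n_mz_pairs = 80L, n_dz_pairs = 80L, n_genera = 20L,
                    n_affected_genera = 1L, effect_size_genus = 1.5,
                    seq_depth = 5000L, seed = 41L)
  co <- simulate_cohort(cfg)
  clr <- clr_transform(co$counts)
  pc <- classify_pairs(co$metadata)
  ra <- pairwise_layer(clr, co$metadata, "a", feature_kind = "genus")
  rb <- pairwise_layer(clr, co$metadata, "b")
  rc <- pairwise_layer(clr, co$metadata, "c")
  s <- attr(pc, "summary")
  expect_equal(ra$n_pairs[1], unname(s["MZ", "discordant"]))
  expect_equal(rb$n_pairs[1], unname(s["DZ", "discordant"]))
  expect_equal(rc$n_pairs[1], sum(s[, "discordant"]))
  g <- names(co$truth$affected_genera)[1]
  expect_true(rc$significant[rc$feature == g])
  expect_equal(rc$direction[rc$feature == g],
               unname(sign(co$truth$affected_genera[1])))
  expect_equal(ra$feature_kind[1], "genus")
})

test_that("pairwise_layer demands discordant pairs and warns when few", {
  md <- table1_metadata()
  md_conc <- md[!md$pair_id %in%
                  classify_pairs(md)$pair_id[
                    classify_pairs(md)$class == "discordant"], ]
  x <- matrix(rnorm(nrow(md_conc) * 3), ncol = 3,
              dimnames = list(md_conc$sample_id, paste0("f", 1:3)))
  expect_error(pairwise_layer(x, md_conc, "a"), "no discordant pairs")
  md_small <- md[md$pair_id %in% c("MZ001", "MZ002"), ]
  xs <- matrix(rnorm(4 * 3), ncol = 3,
               dimnames = list(md_small$sample_id, paste0("f", 1:3)))
  expect_warning(pairwise_layer(xs, md_small, "a"), "power is very limited")
})

test_that("layer overlap set algebra is correct", {
  mk <- function(sig, all = paste0("f", 1:6))
    data.frame(feature = all, significant = all %in% sig,
               stringsAsFactors = FALSE)
  ov <- layer_overlaps(list(a = mk(c("f1", "f2")), b = mk(c("f2", "f3")),
                            c = mk(c("f2", "f4"))))
  expect_equal(ov$pairwise[["a&b"]], "f2")
  expect_equal(ov$common, "f2")
  expect_equal(ov$counts$n[ov$counts$set == "all"], 1L)
  # disjoint and identical sets
  ov2 <- layer_overlaps(list(a = mk("f1"), b = mk("f2")))
  expect_length(ov2$common, 0)
  ov3 <- layer_overlaps(list(a = mk(c("f1", "f5")), b = mk(c("f1", "f5"))))
  expect_setequal(ov3$common, c("f1", "f5"))
})

test_that("the consistency ledger ticks and flags as specified", {
  mk <- function(sig, all, dir = 1)
    data.frame(feature = all, significant = all %in% sig,
               direction = dir, stringsAsFactors = FALSE)
  all_f <- paste0("f", 1:4)
  layers <- list(a = mk(c("f1", "f2"), all_f), b = mk("f1", all_f),
                 c = mk(c("f1", "f3"), all_f))
  lmm_d <- data.frame(feature = all_f, p = c(0.01, 0.2, 0.03, 0.6),
                      q = c(0.1, 0.5, 0.15, 0.9),
                      beta_md = c(1, -1, 1, 1), stringsAsFactors = FALSE)
  attr(lmm_d, "fdr_threshold") <- 0.2
  led <- build_ledger(layers, list(d = lmm_d))
  expect_setequal(led$feature, c("f1", "f2", "f3"))
  # f1 significant in a, b, c and d (p=0.01<0.05) -> consistent
  expect_true(led$consistent[led$feature == "f1"])
  expect_false(led$consistent[led$feature == "f2"])
  # q-based ticks change the rule
  led_q <- build_ledger(layers, list(d = lmm_d), lmm_tick = "q")
  expect_true(led_q$consistent[led_q$feature == "f1"])
  # empty input
  led0 <- build_ledger(list(a = mk(character(0), all_f)))
  expect_equal(nrow(led0), 0L)
})
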