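mk_counts <- function(m) {
  mat <- do.call(rbind, m)
  dimnames(mat) <- list(paste0("s", seq_len(nrow(mat))),
                        paste0("t", seq_len(ncol(mat))))
  storage.mode(mat) <- "integer"
  mat
}

test_that("depth filter removes strictly-below-threshold samples only", {
  x2 <- mk_counts(list(c(9998, 1), c(5000, 5000), c(10000, 10000)))
  rownames(x2) <- c("s9999", "s10000", "s20000")
  expect_message(out2 <- filter_samples_by_depth(x2, 10000), "removed")
  expect_setequal(rownames(out2), c("s10000", "s20000"))
  expect_equal(attr(out2, "filter_log")$removed_samples, "s9999")
})

test_that("taxon filters apply the four rules in order and log removals", {
  # t1: total count 1 (rule 1); t2: in one sample only (rule 2);
  # t3: all zero (rule 3); t4, t5 fine; s4 empty after t3 removal (rule 4)
  x <- mk_counts(list(
    c(1, 5, 0, 10, 3),
    c(0, 0, 0, 12, 4),
    c(0, 0, 0, 9, 2),
    c(0, 0, 0, 0, 0)))
  out <- filter_taxa(x)
  log <- attr(out, "filter_log")
  expect_equal(log$singleton_taxa, "t1")
  expect_equal(log$single_sample_taxa, "t2")
  expect_equal(log$zero_taxa, "t3")
  expect_equal(log$empty_samples, "s4")
  expect_setequal(colnames(out), c("t4", "t5"))
  expect_equal(nrow(out), 3L)
  # idempotent
  again <- filter_taxa(out)
  expect_equal(again, out, ignore_attr = TRUE)
})

test_that("genus agglomeration sums counts and labels unclassified features", {
  x <- mk_counts(list(c(3, 4, 2, 1, 7), c(1, 1, 1, 1, 1)))
  tax <- data.frame(
    feature_id = paste0("t", 1:5),
    genus = c("Bacteroides", "Bacteroides", "Dorea", NA, NA),
    family = c("Bacteroidaceae", "Bacteroidaceae", "Lachnospiraceae",
               "Ruminococcaceae", "Ruminococcaceae"),
    stringsAsFactors = FALSE)
  out <- agglomerate_to_genus(x, tax)
  expect_equal(ncol(out), 3L)
  expect_equal(out["s1", "Bacteroides"], 7)
  expect_equal(out["s1", "Dorea"], 2)
  expect_equal(out["s1", "unclassified Ruminococcaceae"], 8)
  # identity map leaves the table unchanged
  id_tax <- data.frame(feature_id = paste0("t", 1:5),
                       genus = paste0("t", 1:5), stringsAsFactors = FALSE)
  expect_equal(agglomerate_to_genus(x, id_tax)[, colnames(x)], x * 1.0,
               ignore_attr = TRUE)
  expect_error(agglomerate_to_genus(x, tax[1:3, ]), "missing from taxonomy")
})

test_that("CLR matches its closed form, sums to zero and is scale invariant", {
  even <- matrix(c(4, 4, 4, 4), 1, dimnames = list("s1", paste0("g", 1:4)))
  expect_equal(unname(clr_transform(even)[1, ]), rep(0, 4))
  two <- matrix(c(1, 10), 1)
  expect_equal(unname(clr_transform(two)[1, ]),
               c(-0.5 * log(10), 0.5 * log(10)), tolerance = 1e-12)
  set.seed(42)
  x <- matrix(rgamma(200 * 25, 2, 0.1), 200, 25)
  clr <- clr_transform(x)
  expect_lt(max(abs(rowSums(clr))), 1e-9)
  clr_scaled <- clr_transform(x * 7.3)
  expect_lt(max(abs(clr - clr_scaled)), 1e-9)
  expect_error(clr_transform(matrix(c(-1, 2), 1)), "nonnegative")
  expect_error(clr_transform(matrix(c(0, 0), 1)), "empty")
})

test_that("metabolite preprocessing follows drop -> impute -> log -> scale", {
  n <- 20L
  x <- matrix(rexp(n * 3), n, 3,
              dimnames = list(paste0("s", 1:n), c("keep", "edge", "drop")))
  x[1:5, "edge"] <- NA          # 25% missing: kept (rule is strictly >25%)
  x[1:6, "drop"] <- NA          # 30% missing: dropped
  out <- preprocess_metabolites(x)
  expect_setequal(colnames(out), c("keep", "edge"))
  expect_equal(attr(out, "dropped"), "drop")
  # every retained feature has mean 0 and population SD 1
  expect_lt(max(abs(colMeans(out))), 1e-9)
  psd <- apply(out, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(psd - 1)), 1e-9)
  # hand example: values (0, e-1) -> log1p gives (0, 1) -> z = +-1/sqrt(..)
  h <- matrix(c(0, exp(1) - 1), 2, 1, dimnames = list(c("a", "b"), "h"))
  got <- preprocess_metabolites(h)
  expect_equal(unname(got[, 1]), c(-1, 1), tolerance = 1e-9)
  # imputation fills with the observed median (2) before the log, so the
  # imputed sample equals the middle observed sample after scaling
  x2 <- matrix(c(1, 2, 3, NA), 4, 1, dimnames = list(paste0("s", 1:4), "m"))
  out2 <- preprocess_metabolites(x2)
  expect_false(anyNA(out2))
  expect_equal(out2["s4", "m"], out2["s2", "m"])
})

test_that("zero-variance metabolites are dropped with a warning", {
  x <- matrix(c(1, 1, 1, 1, 2, 3), 3, 2,
              dimnames = list(paste0("s", 1:3), c("flat", "ok")))
  expect_warning(out <- preprocess_metabolites(x), "zero-variance")
  expect_equal(colnames(out), "ok")
})

test_that("confounder imputation uses medians and mode with ties toward no-exposure", {
  md <- data.frame(sample_id = paste0("s", 1:4), pair_id = rep("p1", 4),
                   zygosity = "MZ", md = 0,
                   bmi = c(20, 25, 30, NA),
                   antibiotics = c(0, 1, NA, NA),
                   sex = c("F", "F", "M", NA),
                   stringsAsFactors = FALSE)
  out <- impute_confounders(md)
  expect_equal(out$bmi[4], 25)
  expect_equal(out$antibiotics[3:4], c(0, 0))  # 0/1 tie -> 0
  expect_equal(out$sex[4], "F")
  expect_identical(impute_confounders(out), out)
})
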