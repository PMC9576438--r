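test_that("fold sizes differ by at most one and splits reproduce by seed", {
  assoc <- association_table(sprintf("r%03d", 1:403),
                             sprintf("d%03d", rep(1:31, length.out = 403)))
  f <- split_folds(assoc, k = 10, rng_seed = 1)
  expect_equal(as.vector(sort(table(f))), c(rep(40L, 7), rep(41L, 3)))
  expect_identical(split_folds(assoc, 10, 1), f)
  others <- vapply(2:6, function(s) {
    identical(split_folds(assoc, 10, s), f)
  }, logical(1L))
  expect_false(any(others))
  # 10 pairs in 10 folds: singletons
  small <- association_table(sprintf("r%d", 1:10), rep("d1", 10))
  expect_equal(as.vector(sort(table(split_folds(small, 10, 1)))),
               rep(1L, 10))
  expect_error(split_folds(small, 11, 1), "fewer association pairs")
})

test_that("AUC equals brute-force concordant-pair counting", {
  expect_equal(auc_mw(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc_mw(0.5, 0.5), 0.5)
  expect_equal(auc_mw(c(0.9, 0.8), c(0.85, 0.7)), 0.75)
  set.seed(31)
  for (i in 1:50) {
    pos <- round(stats::runif(sample(1:20, 1)), 2)  # rounding forces ties
    neg <- round(stats::runif(sample(1:20, 1)), 2)
    expect_equal(auc_mw(pos, neg), auc_brute(pos, neg), tolerance = 1e-12)
  }
  expect_error(auc_mw(numeric(), 1), "non-empty")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:10) {
    pos <- stats::rnorm(15, mean = 0.5)
    neg <- stats::rnorm(25)
    ref <- as.numeric(pROC::auc(
      response = c(rep(1, 15), rep(0, 25)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE))
    expect_equal(auc_mw(pos, neg), ref, tolerance = 1e-12)
  }
})

test_that("independent validation rejects an all-positive pair universe", {
  net <- path3_net()
  ds <- list(d1 = "a")
  rs <- list(r1 = "b")
  expect_error(
    independent_validation(net, ds, rs, association_table("r1", "d1")),
    "AUC undefined")
})

test_that("label-shuffled associations give chance-level validation AUC", {
  set.seed(42)
  study <- std_study()
  aucs <- vapply(1:10, function(i) {
    shuffled <- association_table(
      sample(sprintf("drg%03d", 1:12), 16, replace = TRUE),
      sample(sprintf("dis%03d", 1:8), 16, replace = TRUE))
    independent_validation(study$network, study$disease_sets,
                           study$drug_sets, shuffled)
  }, numeric(1L))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("cross-validation tests every association exactly once per repeat", {
  study <- std_study()
  assoc <- study$associations
  # partition property, directly on the fold assignment
  for (seed in 1:3) {
    f <- split_folds(assoc, k = 4, rng_seed = seed)
    expect_equal(length(f), nrow(assoc))
    expect_true(all(f %in% 1:4))
  }
  # 2-fold, 1 repeat on a 4-pair toy: 2 AUC values
  toy <- simulate_study(synthetic_config(n_diseases = 2, n_drugs = 3,
                                         n_planted = 4, rng_seed = 5))
  cv <- run_cv(toy$network, toy$disease_sets, toy$drug_sets,
               toy$associations, k = 2, repeats = 1, rng_seed = 9)
  expect_equal(dim(cv$auc), c(1L, 2L))
  expect_true(all(cv$auc >= 0 & cv$auc <= 1, na.rm = TRUE))
})

test_that("cross-validation result carries its configuration", {
  study <- std_study()
  cv <- run_cv(study$network, study$disease_sets, study$drug_sets,
               study$associations, k = 4, repeats = 2, rng_seed = 3)
  expect_s3_class(cv, "rwr_cv")
  expect_equal(dim(cv$auc), c(2L, 4L))
  expect_equal(cv$config[c("k", "repeats", "rng_seed")],
               list(k = 4L, repeats = 2L, rng_seed = 3L))
  expect_equal(cv$mean_auc, mean(cv$auc, na.rm = TRUE))
  expect_true(all(cv$per_disease >= 0 & cv$per_disease <= 1))
  s <- summary(cv)
  expect_equal(s$n, sum(!is.na(cv$auc)))
})

test_that("training-fold seeds are identical when the fold is deleted", {
  study <- std_study()
  assoc <- study$associations
  f <- split_folds(assoc, k = 4, rng_seed = 11)
  train <- assoc[f != 1, , drop = FALSE]
  seeds_masked <- build_seeds(study$disease_sets, train, "disease",
                              study$network, partner_sets = study$drug_sets)
  # physically delete the fold: write the training table, reload, rebuild
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_associations(association_table(train$drug, train$disease), tf)
  seeds_deleted <- build_seeds(study$disease_sets, read_associations(tf),
                               "disease", study$network,
                               partner_sets = study$drug_sets)
  expect_identical(seeds_masked, seeds_deleted)
})

test_that("class averages follow the first-listed-class rule", {
  cv <- structure(list(per_disease = c(d1 = 0.6, d2 = 0.8, d3 = 0.9)),
                  class = "rwr_cv")
  out <- auc_by_class(cv, list(d1 = "C04", d2 = "C04"))
  expect_equal(unname(out["C04"]), 0.7)
  # multi-class disease counts only under its first class
  out2 <- auc_by_class(cv, list(d1 = c("C04", "C06"), d2 = "C06"))
  expect_equal(out2, c(C04 = 0.6, C06 = 0.8))
  # single-disease class mirrors that disease
  expect_equal(unname(auc_by_class(cv, list(d3 = "C11"))["C11"]), 0.9)
  expect_warning(auc_by_class(cv, list(d1 = "C04", dx = "C20")), "dx")
})
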