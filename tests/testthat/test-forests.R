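# shared small parameter matrix for forest tests
make_params <- function(n = 120, p = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              sprintf("par%02d", seq_len(p))))
  m
}

test_that("a single informative column dominates OOB accuracy and VIMP", {
  m <- make_params(n = 150)
  labels <- stats::setNames(ifelse(m[, "par05"] > 0, 1L, 2L), rownames(m))
  fit <- fit_pattern_forest(m, labels,
                            forest_spec("classification", n_trees = 300,
                                        mtry_grid = c(1, 3, 6), seed = 5))
  expect_lt(fit$report$oob_error, 0.05)
  expect_equal(fit$importance$parameter[1], "par05")
  expect_equal(fit$report$best_mtry,
               fit$report$grid$mtry[which.min(fit$report$grid$oob_error)])
})

test_that("permuted labels give chance-level error and near-zero VIMP", {
  m <- make_params(n = 150, seed = 2)
  set.seed(99)
  labels <- stats::setNames(sample(rep(1:2, each = 75)), rownames(m))
  fit <- fit_pattern_forest(m, labels,
                            forest_spec("classification", n_trees = 300,
                                        mtry_grid = 3, seed = 6))
  expect_gt(fit$report$oob_error, 0.3)  # chance is 0.5
  # VIMP distribution centred near zero
  expect_lt(abs(mean(fit$importance$vimp)), 0.02)
  expect_error(fit_pattern_forest(m, stats::setNames(rep(1L, 150), rownames(m))),
               "at least two")
})

test_that("outlier singletons are excluded from training and scored post hoc", {
  m <- make_params(n = 61, seed = 3)
  labels <- stats::setNames(c(ifelse(m[1:60, "par01"] > 0, 1L, 2L), 9L),
                            rownames(m))
  fit <- fit_pattern_forest(m, labels,
                            forest_spec("classification", n_trees = 200,
                                        mtry_grid = 3, seed = 7))
  expect_named(fit$report$outlier_predictions, rownames(m)[61])
  expect_true(fit$report$outlier_predictions %in% 1:2)
})

test_that("mild-vs-healthy forest separates shifted groups and reports OOB AUC", {
  m0 <- make_params(n = 80, seed = 4)
  m1 <- make_params(n = 80, seed = 5)
  m1[, "par03"] <- m1[, "par03"] + 10
  fit <- fit_mild_vs_healthy_forest(m1, m0,
                                    forest_spec("regression", n_trees = 300,
                                                mtry_grid = c(1, 6), seed = 8))
  expect_gt(fit$report$auc, 0.97)
  expect_equal(fit$importance$parameter[1], "par03")
  expect_length(fit$marginal_effects, 6)
  me <- fit$marginal_effects[["par03"]]
  expect_identical(names(me), c("value", "oob_prediction", "smoothed"))
  # smoothed response rises with the separating parameter
  expect_gt(mean(me$smoothed[me$value > 5]), mean(me$smoothed[me$value < 5]))
  # identical distributions give chance-level AUC
  fit0 <- fit_mild_vs_healthy_forest(make_params(80, seed = 6),
                                     make_params(80, seed = 7),
                                     forest_spec("regression", n_trees = 300,
                                                 mtry_grid = 6, seed = 9))
  expect_lt(abs(fit0$report$auc - 0.5), 0.12)
  expect_error(fit_mild_vs_healthy_forest(m1[0, ], m0), "non-empty")
})

test_that("AUC equals the Mann-Whitney rank statistic on the same scores", {
  set.seed(17)
  for (i in 1:10) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    expect_equal(gaitpatterns:::oob_auc(y, s), rank_auc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("clinical forests score binary targets by AUC and age by rho", {
  m <- make_params(n = 140, seed = 8)
  age <- 5 + 10 * stats::plogis(m[, "par02"]) + rnorm(140, 0, 0.5)
  fit <- fit_clinical_forest(m, age,
                             forest_spec("regression", n_trees = 300,
                                         mtry_grid = c(1, 4), seed = 10))
  expect_identical(fit$report$criterion, "spearman_rho")
  expect_gt(fit$report$goodness, 0.8)
  expect_equal(fit$importance$parameter[1], "par02")
  # independent binary target: chance AUC; unknowns are dropped and counted
  yb <- rbinom(140, 1, 0.5); yb[1:10] <- NA
  fitb <- fit_clinical_forest(m, yb,
                              forest_spec("regression", n_trees = 300,
                                          mtry_grid = 4, seed = 11))
  expect_identical(fitb$report$criterion, "auc")
  expect_equal(fitb$report$n_dropped, 10)
  expect_lt(abs(fitb$report$goodness - 0.5), 0.15)
  expect_error(fit_clinical_forest(m, rep(NA_real_, 140)), "every cycle")
})

test_that("OOB error is stable under column permutation and a constant column", {
  m <- make_params(n = 120, seed = 12)
  labels <- stats::setNames(ifelse(m[, "par07"] + 0.5 * rnorm(120) > 0, 1L, 2L),
                            rownames(m))
  spec <- forest_spec("classification", n_trees = 500, mtry_grid = 3, seed = 13)
  base <- fit_pattern_forest(m, labels, spec)$report$oob_error
  perm <- fit_pattern_forest(m[, sample(ncol(m))], labels, spec)$report$oob_error
  cst <- fit_pattern_forest(cbind(m, const = 1), labels, spec)$report$oob_error
  expect_lt(abs(base - perm), 0.06)
  expect_lt(abs(base - cst), 0.06)
})
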