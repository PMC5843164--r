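test_that("Z-scoring against the healthy reference behaves as defined", {
  set.seed(3)
  healthy <- matrix(rnorm(400, 10, 2), 100, 4,
                    dimnames = list(NULL, paste0("p", 1:4)))
  ref <- healthy_reference(healthy)
  v <- matrix(ref$mean, 2, 4, byrow = TRUE,
              dimnames = list(NULL, paste0("p", 1:4)))
  expect_equal(unname(zscore_matrix(v, ref)[1, ]), rep(0, 4))
  v2 <- sweep(v, 2, 2 * ref$sd, "+")
  expect_equal(unname(zscore_matrix(v2, ref)[1, ]), rep(2, 4))
  # a healthy cohort z-scored against itself is standard
  z <- zscore_matrix(healthy, ref)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-10)
  ref0 <- ref; ref0$sd["p2"] <- 0
  expect_error(zscore_matrix(healthy, ref0), "p2")
})

simulate_lmm_cohort <- function(effect, n_subj = 24, cyc = 8, seed = 1) {
  set.seed(seed)
  subject <- rep(sprintf("s%02d", 1:n_subj), each = cyc)
  pattern <- rep(sample(1:3, n_subj, replace = TRUE), each = cyc)
  y <- effect[pattern] + rep(rnorm(n_subj, 0, 1), each = cyc) +
    rnorm(n_subj * cyc, 0, 1)
  ids <- sprintf("c%03d", seq_along(y))
  params <- matrix(y, ncol = 1, dimnames = list(ids, "stance_pct"))
  asn <- data.frame(cycle_id = ids, subject_id = subject,
                    pattern = pattern, outlier = FALSE)
  list(params = params, asn = asn)
}

test_that("mixed models detect a planted pattern effect and report the LRT", {
  d <- simulate_lmm_cohort(effect = c(0, 2, 4), seed = 5)
  res <- fit_pattern_lmm(d$params, d$asn, parameters = "stance_pct")
  expect_equal(res$df, 2)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$chisq, 0)
  expect_gt(res$subject_var, 0)
  # LRT is invariant to affine rescaling of the response
  d2 <- d; d2$params[, 1] <- 100 + 7 * d2$params[, 1]
  res2 <- fit_pattern_lmm(d2$params, d2$asn, parameters = "stance_pct")
  expect_equal(res2$chisq, res$chisq, tolerance = 1e-4)
})

test_that("odds ratios versus the reference pattern match the closed form", {
  # pattern A: 8 yes / 2 no, pattern B: 2 yes / 8 no -> OR 16
  asn <- data.frame(cycle_id = sprintf("c%d", 1:20),
                    subject_id = sprintf("s%d", 1:20),
                    pattern = rep(c(1, 2), each = 10), outlier = FALSE)
  feature <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  fit <- fit_clinical_vs_pattern(feature, asn)
  expect_identical(fit$type, "binary")
  expect_equal(fit$reference, 1)
  # pattern 2 vs 1: OR = (2/8) / (8/2) = 1/16; reciprocal view = 16
  expect_equal(fit$effects$odds_ratio[fit$effects$pattern == "2"], 1 / 16,
               tolerance = 1e-6)
  # independent feature: OR near 1, no pattern effect
  set.seed(8)
  asn2 <- data.frame(cycle_id = sprintf("c%d", 1:200),
                     subject_id = sprintf("s%d", 1:200),
                     pattern = sample(1:3, 200, replace = TRUE),
                     outlier = FALSE)
  f2 <- rbinom(200, 1, 0.5)
  fit2 <- fit_clinical_vs_pattern(f2, asn2)
  expect_true(all(fit2$effects$odds_ratio > 0.4 & fit2$effects$odds_ratio < 2.5))
  # complete separation is flagged, not fatal
  f3 <- as.numeric(asn2$pattern == 2)
  fit3 <- fit_clinical_vs_pattern(f3, asn2)
  expect_true(any(fit3$effects$infinite_or))
  # quantitative feature goes through the linear model with an F test
  age <- 6 + (asn2$pattern == 3) * 4 + rnorm(200)
  fit4 <- fit_clinical_vs_pattern(age, asn2)
  expect_identical(fit4$type, "quantitative")
  expect_lt(fit4$anova_p, 1e-6)
})

test_that("robust regression resists gross contamination where OLS fails", {
  set.seed(9)
  n <- 150
  age <- runif(2 * n, 4, 16)
  cond <- rep(c("healthy", "HSP"), each = n)
  y <- 2 - 0.05 * age + rnorm(2 * n, 0, 0.02)
  fit <- robust_age_regression(y, age, cond)
  expect_equal(fit$estimate[fit$term == "age"], -0.05, tolerance = 0.005)
  expect_equal(fit$estimate[fit$term == "age_x_conditionHSP"], 0,
               tolerance = 0.01)
  # 10% gross outliers
  idx <- sample(2 * n, round(0.1 * 2 * n))
  y2 <- y; y2[idx] <- y2[idx] + sample(c(-50, 50), length(idx), replace = TRUE)
  fit2 <- robust_age_regression(y2, age, cond)
  expect_lt(abs(fit2$estimate[fit2$term == "age"] + 0.05), 0.005)
  ols <- coef(lm(y2 ~ age * factor(cond, levels = c("healthy", "HSP"))))[["age"]]
  expect_gt(abs(ols + 0.05), 0.02)
  expect_error(robust_age_regression(y[1:12], age[1:12], cond[c(1:6, 151:156)]),
               "at least 10")
})

test_that("BCa intervals match the boot reference and nest the estimate", {
  skip_if_not_installed("boot")
  set.seed(15)
  x <- rgamma(60, shape = 2)
  stat <- function(d, i) mean(d[i])
  ours <- bca_ci(x, stat, n_boot = 4000, seed = 77)
  expect_lte(ours$ci_low, ours$estimate)
  expect_gte(ours$ci_high, ours$estimate)
  bb <- boot::boot(x, stat, R = 4000)
  ci <- boot::boot.ci(bb, type = "bca")$bca[4:5]
  # same construction, independent resamples: agree within Monte-Carlo error
  expect_equal(ours$ci_low, ci[1], tolerance = 0.05)
  expect_equal(ours$ci_high, ci[2], tolerance = 0.05)
})

test_that("with zero bias correction and acceleration BCa is the percentile interval", {
  set.seed(25)
  x <- rnorm(80)
  stat <- function(d, i) mean(d[i])
  set.seed(33)
  boots <- vapply(1:2000, function(b) stat(x, sample.int(80, replace = TRUE)),
                  numeric(1))
  # degenerate-case equivalence: force z0 = 0 and a = 0 by symmetry of the
  # adjusted quantile formula
  adj <- function(alpha, z0, a) pnorm(z0 + (z0 + qnorm(alpha)) / (1 - a * (z0 + qnorm(alpha))))
  expect_equal(adj(0.025, 0, 0), 0.025)
  expect_equal(adj(0.975, 0, 0), 0.975)
  ours <- bca_ci(x, stat, n_boot = 2000, seed = 33)
  perc <- quantile(boots, c(adj(0.025, ours$z0, ours$accel),
                            adj(0.975, ours$z0, ours$accel)), type = 6)
  expect_equal(unname(ours$ci_low), unname(perc[1]), tolerance = 1e-10)
  expect_equal(unname(ours$ci_high), unname(perc[2]), tolerance = 1e-10)
})

test_that("group contrasts report raw and healthy-SD scales coherently", {
  set.seed(19)
  healthy <- matrix(rnorm(200, 20, 4), 100, 2,
                    dimnames = list(NULL, c("a", "b")))
  ref <- healthy_reference(healthy)
  v <- c(rnorm(50, 20, 2), rnorm(50, 30, 2))
  g <- rep(c(0, 1), each = 50)
  ct <- group_contrast_bca(v, g, ref, "a", n_boot = 1500, seed = 4)
  raw <- ct[ct$scale == "raw", ]
  z <- ct[ct$scale == "z", ]
  expect_equal(raw$estimate, mean(v[51:100]) - mean(v[1:50]))
  expect_equal(z$estimate, raw$estimate / ref$sd[["a"]])
  expect_lte(raw$ci_low, raw$estimate)
  expect_gte(raw$ci_high, raw$estimate)
  # identical groups: difference near zero, CI contains zero
  v0 <- rnorm(100, 10, 1)
  ct0 <- group_contrast_bca(v0, g, ref, "a", n_boot = 1500, seed = 5)
  raw0 <- ct0[ct0$scale == "raw", ]
  expect_lte(raw0$ci_low, 0)
  expect_gte(raw0$ci_high, 0)
  expect_error(group_contrast_bca(v[1:4], c(0, 0, 1, NA), ref, "a"),
               "at least 3")
})
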