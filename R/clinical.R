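#' Healthy reference distribution of the gait parameters
#'
#' Per-parameter mean and standard deviation computed from the healthy
#' cohort's cycles, used to express patient values as Z-scores
#' (standardized distance from the healthy average).
#'
#' @param healthy_params parameter matrix of the healthy cycles.
#' @return Object of class `healthy_reference`: list with `mean` and `sd`
#'   named vectors.
#' @export
healthy_reference <- function(healthy_params) {
  mu <- colMeans(healthy_params)
  sd <- apply(healthy_params, 2, stats::sd)
  structure(list(mean = mu, sd = sd), class = "healthy_reference")
}

#' Z-score a parameter matrix against the healthy reference
#'
#' @param params parameter matrix (cycles x parameters).
#' @param ref a [healthy_reference()].
#' @return Matrix of the same shape, z = (value - healthy mean) / healthy
#'   SD per column.
#' @export
zscore_matrix <- function(params, ref) {
  cols <- colnames(params)
  if (!all(cols %in% names(ref$mean)))
    stop("reference does not cover column(s): ",
         paste(setdiff(cols, names(ref$mean)), collapse = ", "))
  bad <- cols[ref$sd[cols] == 0]
  if (length(bad))
    stop("zero healthy SD for column(s): ", paste(bad, collapse = ", "))
  sweep(sweep(params, 2, ref$mean[cols]), 2, ref$sd[cols], "/")
}

#' Mixed-model test of pattern effects on spatio-temporal performance
#'
#' For each spatio-temporal parameter, fits a Gaussian linear mixed model
#' with the gait pattern as fixed effect and a random intercept per
#' subject (repeated cycles per subject), by full maximum likelihood, and
#' tests the pattern effect by a likelihood-ratio test against the model
#' without it (chi-squared with levels - 1 degrees of freedom). Outlier
#' (singleton) patterns are excluded before fitting.
#'
#' @param params parameter matrix containing the spatio-temporal columns.
#' @param assignment pattern assignment data frame (`cycle_id`,
#'   `subject_id`, `pattern`, `outlier`).
#' @param parameters which columns to test (default the six
#'   spatio-temporal parameters).
#' @return Data frame with one row per parameter: `parameter`, `chisq`,
#'   `df`, `p_value`, `subject_var`, `singular` (logical flag).
#' @export
fit_pattern_lmm <- function(params, assignment,
                            parameters = spatiotemporal_names()) {
  keep <- !assignment$outlier
  dat <- data.frame(
    pattern = factor(assignment$pattern[keep]),
    subject = factor(assignment$subject_id[keep]))
  if (nlevels(dat$pattern) < 2) stop("need at least 2 patterns")
  if (nlevels(dat$subject) < 2) stop("need at least 2 subjects")
  idx <- match(assignment$cycle_id[keep], rownames(params))
  res <- lapply(parameters, function(p) {
    dat$y <- params[idx, p]
    full <- suppressMessages(
      lme4::lmer(y ~ pattern + (1 | subject), data = dat, REML = FALSE))
    null <- suppressMessages(
      lme4::lmer(y ~ 1 + (1 | subject), data = dat, REML = FALSE))
    lrt <- stats::anova(null, full)
    vc <- as.data.frame(lme4::VarCorr(full))
    data.frame(parameter = p,
               chisq = lrt$Chisq[2], df = lrt$Df[2],
               p_value = lrt$`Pr(>Chisq)`[2],
               subject_var = vc$vcov[vc$grp == "subject"],
               singular = lme4::isSingular(full),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Relate a clinical feature to the gait pattern
#'
#' Cycle-level models with the pattern dummy-coded against the most common
#' pattern as reference: a linear model with an ANOVA F-test for
#' quantitative features (age), and a log-linear (binomial logit) model
#' with per-pattern odds ratios for binary features. Complete separation
#' (a pattern with an all-identical binary outcome) is reported with an
#' `infinite_or` flag rather than failing.
#'
#' @param feature numeric vector aligned with `assignment` rows
#'   (quantitative, or 0/1 for binary features); `NA` dropped.
#' @param assignment pattern assignment data frame.
#' @param type `"auto"` (binary if only 0/1), `"quantitative"` or
#'   `"binary"`.
#' @return List with `type`, `reference` pattern, `anova_p` (overall
#'   pattern test) and `effects`: per-pattern estimates versus reference
#'   (differences for quantitative features; odds ratios for binary ones)
#'   with p-values and separation flags.
#' @export
fit_clinical_vs_pattern <- function(feature, assignment,
                                    type = c("auto", "quantitative", "binary")) {
  type <- match.arg(type)
  keep <- !assignment$outlier & !is.na(feature)
  pat <- assignment$pattern[keep]
  y <- feature[keep]
  reference <- as.integer(names(which.max(table(pat))))
  f <- stats::relevel(factor(pat), ref = as.character(reference))
  if (type == "auto")
    type <- if (all(y %in% c(0, 1))) "binary" else "quantitative"
  if (type == "quantitative") {
    fit <- stats::lm(y ~ f)
    an <- stats::anova(fit)
    co <- summary(fit)$coefficients[-1, , drop = FALSE]
    effects <- data.frame(pattern = sub("^f", "", rownames(co)),
                          estimate = co[, "Estimate"],
                          p_value = co[, "Pr(>|t|)"],
                          infinite_or = FALSE, row.names = NULL)
    list(type = type, reference = reference,
         anova_p = an$`Pr(>F)`[1], effects = effects)
  } else {
    fit <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
    co <- summary(fit)$coefficients[-1, , drop = FALSE]
    sep <- abs(co[, "Estimate"]) > 10 | co[, "Std. Error"] > 100
    an <- stats::anova(fit, test = "Chisq")
    effects <- data.frame(pattern = sub("^f", "", rownames(co)),
                          estimate = exp(co[, "Estimate"]),
                          p_value = co[, "Pr(>|z|)"],
                          infinite_or = unname(sep), row.names = NULL)
    names(effects)[2] <- "odds_ratio"
    list(type = type, reference = reference,
         anova_p = an$`Pr(>Chi)`[2], effects = effects)
  }
}

#' Robust MM-estimator regression of a gait parameter on age and condition
#'
#' Fits `parameter ~ age + condition + age:condition` by an MM-type robust
#' estimator (high-breakdown S-estimate refined by a bounded-influence
#' M-step), so that gross outlier cycles do not drive the age slopes.
#' Reports the age slope in the reference (healthy) group, the condition
#' offset, and the interaction slope (how much faster the parameter
#' changes per year in patients), each with a normal-approximation 95% CI.
#'
#' @param values numeric parameter values (one per cycle).
#' @param age ages in years aligned with `values`.
#' @param condition factor or character, `"healthy"` versus `"HSP"`
#'   (healthy is the reference level).
#' @return Data frame: `term`, `estimate`, `ci_low`, `ci_high`,
#'   `std_error`, `p_value`.
#' @export
robust_age_regression <- function(values, age, condition) {
  cond <- factor(condition, levels = c("healthy", "HSP"))
  if (any(table(cond) < 10))
    stop("need at least 10 observations per condition")
  dat <- data.frame(y = values, age = age, cond = cond)
  fit <- MASS::rlm(y ~ age * cond, data = dat, method = "MM", maxit = 400)
  co <- summary(fit)$coefficients
  est <- co[, "Value"]; se <- co[, "Std. Error"]
  z <- est / se
  data.frame(term = c("intercept", "age", "conditionHSP", "age_x_conditionHSP"),
             estimate = unname(est),
             ci_low = unname(est - stats::qnorm(0.975) * se),
             ci_high = unname(est + stats::qnorm(0.975) * se),
             std_error = unname(se),
             p_value = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Bias-corrected and accelerated bootstrap CI for a statistic
#'
#' Standard BCa interval: the bias correction z0 is the normal quantile of
#' the fraction of bootstrap replicates below the point estimate, and the
#' acceleration a comes from the jackknife skewness of the statistic. With
#' z0 = 0 and a = 0 the interval reduces to the percentile interval.
#'
#' @param data data object passed to `statistic`.
#' @param statistic function of (data, integer index vector) returning a
#'   scalar, in the resampling convention of bootstrap libraries.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @param n observation count to resample over (default inferred from
#'   `data`).
#' @param resampler function of `n` returning a bootstrap index vector;
#'   defaults to plain resampling with replacement. A stratified resampler
#'   keeps subgroups represented in every resample.
#' @return List with `estimate`, `ci_low`, `ci_high`, `z0`, `accel`.
#' @export
bca_ci <- function(data, statistic, n_boot = 10000, conf = 0.95,
                   seed = 1L, n = NULL, resampler = NULL) {
  if (is.null(n)) n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (is.null(resampler))
    resampler <- function(n) sample.int(n, n, replace = TRUE)
  est <- statistic(data, seq_len(n))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    statistic(data, resampler(n)), numeric(1))
  prop <- mean(boots < est) + 0.5 * mean(boots == est)
  prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i)
    statistic(data, seq_len(n)[-i]), numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  accel <- if (den == 0) 0 else num / den
  alpha <- (1 - conf) / 2
  adj <- function(a) {
    zq <- z0 + stats::qnorm(a)
    stats::pnorm(z0 + zq / (1 - accel * zq))
  }
  qs <- stats::quantile(boots, probs = c(adj(alpha), adj(1 - alpha)),
                        names = FALSE, type = 6)
  list(estimate = est, ci_low = qs[1], ci_high = qs[2],
       z0 = z0, accel = accel)
}

#' Bootstrap contrast of a gait parameter between two groups
#'
#' Difference of group means (group 1 minus group 0) with a 95% BCa
#' bootstrap CI, reported both in raw units and in healthy-SD units
#' (values Z-scored against the healthy reference before differencing).
#' Resampling is at the cycle level, stratified by group so that both
#' groups stay represented in every resample.
#'
#' @param values numeric parameter values.
#' @param group 0/1 group indicator aligned with `values` (e.g. GMFCS I
#'   = 0 versus II-III = 1); `NA` dropped.
#' @param ref a [healthy_reference()] providing the healthy mean/SD.
#' @param parameter name of the parameter (to look up in `ref`).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return Data frame with rows `raw` and `z` (healthy-SD units):
#'   `scale`, `estimate`, `ci_low`, `ci_high`.
#' @export
group_contrast_bca <- function(values, group, ref, parameter,
                               n_boot = 10000, seed = 1L) {
  keep <- !is.na(group) & !is.na(values)
  v <- values[keep]; g <- group[keep]
  if (min(table(g)) < 3) stop("both groups need at least 3 observations")
  if (length(unique(g)) < 2) stop("a group is empty")
  dat <- data.frame(v = v, g = g)
  stat <- function(d, idx) {
    s <- d[idx, ]
    mean(s$v[s$g == 1]) - mean(s$v[s$g == 0])
  }
  i0 <- which(g == 0); i1 <- which(g == 1)
  strat <- function(n) c(i0[sample.int(length(i0), length(i0), replace = TRUE)],
                         i1[sample.int(length(i1), length(i1), replace = TRUE)])
  raw <- bca_ci(dat, stat, n_boot = n_boot, seed = seed, resampler = strat)
  sd_h <- ref$sd[[parameter]]
  if (is.null(sd_h) || !is.finite(sd_h) || sd_h <= 0)
    stop("reference has no positive SD for '", parameter, "'")
  data.frame(scale = c("raw", "z"),
             estimate = c(raw$estimate, raw$estimate / sd_h),
             ci_low = c(raw$ci_low, raw$ci_low / sd_h),
             ci_high = c(raw$ci_high, raw$ci_high / sd_h),
             row.names = NULL, stringsAsFactors = FALSE)
}
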