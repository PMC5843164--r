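#' Random-forest specification
#'
#' Bundles the forest task and hyperparameters used across the analysis:
#' 1000 trees everywhere, with the mtry grid depending on the question
#' (pattern classification: 1, 3, 6, 12; mild-vs-healthy regression:
#' 1, 14, 29; clinical-feature forests: 1, 7, 14, 28). Remaining
#' tree-building settings follow the classic Breiman defaults of the
#' underlying implementation (classification node size 1, regression node
#' size 5, bootstrap of size n with replacement).
#'
#' @param task `"classification"` or `"regression"`.
#' @param n_trees number of trees (default 1000).
#' @param mtry_grid candidate numbers of variables tried at each split.
#' @param seed integer seed for the forest's randomness.
#' @return Object of class `forest_spec`.
#' @export
forest_spec <- function(task = c("classification", "regression"),
                        n_trees = 1000, mtry_grid = c(1, 3, 6, 12),
                        seed = 1L) {
  task <- match.arg(task)
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(task = task, n_trees = as.integer(n_trees),
                 mtry_grid = as.integer(mtry_grid), seed = as.integer(seed)),
            class = "forest_spec")
}

# Breiman-Cutler permutation importance (mean decrease in accuracy /
# increase in MSE under OOB permutation), ranked decreasingly.
importance_table <- function(rf) {
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  data.frame(parameter = names(sort(imp, decreasing = TRUE)),
             vimp = as.numeric(sort(imp, decreasing = TRUE)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# AUC of scores against a 0/1 response (via ROC; equals the Mann-Whitney
# rank statistic on the same scores)
oob_auc <- function(response, scores) {
  as.numeric(pROC::auc(pROC::roc(response, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Classify gait patterns from the 43 parameters
#'
#' Fits one classification forest per mtry in the grid and reports the one
#' with the lowest out-of-bag (OOB) error. Outlier (singleton) clusters are
#' excluded from training -- a class of size one cannot be OOB-validated --
#' and scored post hoc with the fitted forest.
#'
#' @param params cycles x 43 parameter matrix ([extract_matrix()]).
#' @param labels integer pattern labels (named by cycle id, as from
#'   [pattern_labels()]) or a `gait_patterns` assignment data frame.
#' @param spec a [forest_spec()]; default classification with
#'   mtry grid 1, 3, 6, 12.
#' @return List with `model` (the best [randomForest::randomForest]),
#'   `report` (best mtry, OOB error, per-class error, confusion counts,
#'   the full mtry grid results, post-hoc predictions for excluded
#'   outliers) and `importance` (ranked permutation-importance table).
#' @export
fit_pattern_forest <- function(params, labels,
                               spec = forest_spec("classification")) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$pattern, labels$cycle_id)
  } else lab <- labels
  lab <- lab[rownames(params)]
  if (anyNA(lab)) stop("labels do not cover all parameter rows")
  keep <- lab %in% as.integer(names(which(table(lab) > 1)))
  if (length(unique(lab[keep])) < 2)
    stop("need at least two multi-cycle pattern classes")
  x <- as.data.frame(params[keep, , drop = FALSE])
  y <- factor(lab[keep])
  set.seed(spec$seed)
  fits <- lapply(spec$mtry_grid, function(m)
    randomForest::randomForest(x, y, ntree = spec$n_trees,
                               mtry = min(m, ncol(x)), importance = TRUE))
  oob <- vapply(fits, function(f) f$err.rate[spec$n_trees, "OOB"], numeric(1))
  best <- which.min(oob)
  rf <- fits[[best]]
  outlier_pred <- if (any(!keep)) {
    stats::setNames(as.integer(as.character(
      stats::predict(rf, as.data.frame(params[!keep, , drop = FALSE])))),
      rownames(params)[!keep])
  } else NULL
  list(model = rf,
       report = list(task = "classification",
                     best_mtry = spec$mtry_grid[best],
                     oob_error = unname(oob[best]),
                     grid = data.frame(mtry = spec$mtry_grid, oob_error = oob),
                     per_class_error = rf$confusion[, "class.error"],
                     confusion = rf$confusion[, colnames(rf$confusion) != "class.error"],
                     outlier_predictions = outlier_pred),
       importance = importance_table(rf))
}

#' Distinguish mildly affected gait cycles from healthy ones
#'
#' Regression forest on the 0/1 coding (healthy = 0, mild-pattern
#' patient cycles = 1), mtry grid 1, 14, 29. Goodness of fit is the AUC of
#' the OOB predictions against the label (OOB rather than resubstitution,
#' which would be trivially optimistic). Also returns unadjusted
#' marginal-effect curves for the top-importance parameters: the OOB
#' prediction plotted against the raw parameter value with a running-mean
#' smoother (window 10% of the data).
#'
#' @param params_mild parameter matrix of the mild-pattern patient cycles.
#' @param params_healthy parameter matrix of the healthy cycles.
#' @param spec a [forest_spec()]; default regression, mtry 1, 14, 29.
#' @param n_marginal number of top-importance parameters to return
#'   marginal-effect curves for (default 6).
#' @return List with `model`, `report` (best mtry, `auc`, grid results),
#'   `importance`, and `marginal_effects` (named list of data frames
#'   `value`, `oob_prediction`, `smoothed`).
#' @export
fit_mild_vs_healthy_forest <- function(params_mild, params_healthy,
                                       spec = forest_spec("regression",
                                                          mtry_grid = c(1, 14, 29)),
                                       n_marginal = 6) {
  if (nrow(params_mild) == 0 || nrow(params_healthy) == 0)
    stop("both groups must be non-empty")
  x <- as.data.frame(rbind(params_healthy, params_mild))
  y <- c(rep(0, nrow(params_healthy)), rep(1, nrow(params_mild)))
  set.seed(spec$seed)
  # regression on the 0/1 coding is deliberate; silence the forest's advisory
  fits <- lapply(spec$mtry_grid, function(m)
    suppressWarnings(
      randomForest::randomForest(x, y, ntree = spec$n_trees,
                                 mtry = min(m, ncol(x)), importance = TRUE)))
  aucs <- vapply(fits, function(f) oob_auc(y, f$predicted), numeric(1))
  best <- which.max(aucs)
  rf <- fits[[best]]
  imp <- importance_table(rf)
  top <- utils::head(imp$parameter, n_marginal)
  marg <- lapply(top, function(p) marginal_effect(x[[p]], rf$predicted))
  names(marg) <- top
  list(model = rf,
       report = list(task = "regression", best_mtry = spec$mtry_grid[best],
                     auc = unname(aucs[best]),
                     grid = data.frame(mtry = spec$mtry_grid, auc = aucs)),
       importance = imp, marginal_effects = marg)
}

# unadjusted marginal effect: OOB prediction against the raw parameter with
# a centered running-mean smoother whose window is 10% of the data
marginal_effect <- function(values, oob_pred, window_frac = 0.1) {
  ord <- order(values)
  v <- values[ord]; p <- oob_pred[ord]
  half <- max(1L, floor(length(v) * window_frac / 2))
  sm <- vapply(seq_along(v), function(i) {
    lo <- max(1L, i - half); hi <- min(length(v), i + half)
    mean(p[lo:hi])
  }, numeric(1))
  data.frame(value = v, oob_prediction = p, smoothed = sm)
}

#' Predict a clinical feature from the 43 gait parameters
#'
#' One regression forest per clinical target, mtry grid 1, 7, 14, 28.
#' Binary targets (sex coded female 0 / male 1; GMFCS coded I = 0,
#' II-III = 1; pathology flags coded absent 0 / present 1) are scored by
#' OOB AUC; the quantitative age target by Spearman's rho between OOB
#' predictions and the truth. Cycles whose target is unknown are dropped
#' and counted.
#'
#' @param params cycles x 43 parameter matrix.
#' @param target numeric vector aligned with `params` rows: 0/1 for binary
#'   features, years for age; `NA` for unknowns.
#' @param spec a [forest_spec()]; default regression, mtry 1, 7, 14, 28.
#' @return List with `model`, `report` (best mtry, criterion name and
#'   value, grid results, `n_dropped`), `importance`.
#' @export
fit_clinical_forest <- function(params, target,
                                spec = forest_spec("regression",
                                                   mtry_grid = c(1, 7, 14, 28))) {
  keep <- !is.na(target)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("target is unknown for every cycle")
  x <- as.data.frame(params[keep, , drop = FALSE])
  y <- as.numeric(target[keep])
  binary <- all(y %in% c(0, 1))
  if (binary && length(unique(y)) < 2)
    stop("binary target has a single class")
  set.seed(spec$seed)
  fits <- lapply(spec$mtry_grid, function(m)
    suppressWarnings(
      randomForest::randomForest(x, y, ntree = spec$n_trees,
                                 mtry = min(m, ncol(x)), importance = TRUE)))
  crit <- if (binary) {
    vapply(fits, function(f) oob_auc(y, f$predicted), numeric(1))
  } else {
    vapply(fits, function(f)
      stats::cor(y, f$predicted, method = "spearman"), numeric(1))
  }
  best <- which.max(crit)
  rf <- fits[[best]]
  list(model = rf,
       report = list(task = "regression",
                     criterion = if (binary) "auc" else "spearman_rho",
                     best_mtry = spec$mtry_grid[best],
                     goodness = unname(crit[best]),
                     grid = data.frame(mtry = spec$mtry_grid, value = crit),
                     n_dropped = n_dropped),
       importance = importance_table(rf))
}
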