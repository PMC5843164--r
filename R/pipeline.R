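#' Configuration of a full pipeline run
#'
#' A run is fully determined by (config, inputs). Inputs are either the
#' exchange-format cohort directories (`hsp_dir`, `healthy_dir`) or a
#' [cohort_config()] for synthetic data.
#'
#' @param hsp_dir,healthy_dir exchange-format cohort directories (HSP
#'   cohort may include its healthy subjects, in which case `healthy_dir`
#'   is `NULL` and the clinical `condition` column splits them).
#' @param synthetic a [cohort_config()]; used when no directories given.
#' @param k dendrogram cut (default 7: six patterns plus outlier).
#' @param dtw_step,dtw_normalize,dtw_scale DTW options, see
#'   [dtw_distance_matrix()].
#' @param n_trees forest size (default 1000).
#' @param n_boot bootstrap resamples for contrasts (default 10000).
#' @param out_dir output directory for the report bundle.
#' @param seed master seed; per-stage seeds are spawned from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(hsp_dir = NULL, healthy_dir = NULL,
                            synthetic = cohort_config(),
                            k = 7, dtw_step = "symmetric2",
                            dtw_normalize = TRUE, dtw_scale = FALSE,
                            n_trees = 1000, n_boot = 10000,
                            out_dir = tempfile("gaitrun"), seed = 1L) {
  structure(list(hsp_dir = hsp_dir, healthy_dir = healthy_dir,
                 synthetic = synthetic, k = k, dtw_step = dtw_step,
                 dtw_normalize = dtw_normalize, dtw_scale = dtw_scale,
                 n_trees = n_trees, n_boot = n_boot, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

binary_target <- function(records_df, subject_ids, field) {
  v <- records_df[[field]][match(subject_ids, records_df$subject_id)]
  ifelse(v == "yes", 1, ifelse(v == "no", 0, NA))
}

#' Run the full gait-phenotyping pipeline
#'
#' Executes, in order: ingest (or synthesis), parameter extraction, DTW
#' distance matrix, average linkage, dendrogram cut, pattern summary,
#' pattern classification forest, mild-versus-healthy forest, Z-score
#' tables, mixed models, pattern-versus-clinical models, clinical-feature
#' forests, robust age regressions, and BCa group contrasts. Every stage
#' writes its artifacts under `config$out_dir` and appends to a
#' machine-readable `manifest.json` (stage, status, outputs, seed,
#' elapsed seconds). A stage failure aborts with the stage name; prior
#' outputs persist.
#'
#' @param config a [pipeline_config()].
#' @return The report bundle, invisibly: a list with every stage result
#'   plus `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  bundle <- list(out_dir = config$out_dir)
  stage_i <- 0
  run_stage <- function(name, fn) {
    stage_i <<- stage_i + 1
    seed <- (config$seed * 101 + stage_i) %% .Machine$integer.max
    set.seed(seed)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(seed), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest[[length(manifest) + 1]] <<- list(
      stage = name, index = stage_i, seed = seed, status = "completed",
      outputs = res$outputs %||% character(),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$value
  }
  out_file <- function(...) file.path(config$out_dir, ...)

  data <- run_stage("ingest", function(seed) {
    if (!is.null(config$hsp_dir)) {
      hsp <- read_cohort(config$hsp_dir)
      cycles <- hsp$cycles; records <- hsp$records
      if (!is.null(config$healthy_dir)) {
        h <- read_cohort(config$healthy_dir)
        cycles <- c(cycles, h$cycles); records <- c(records, h$records)
      }
      list(value = list(cycles = cycles, records = records, labels = NULL),
           outputs = character())
    } else {
      cfg <- config$synthetic; cfg$seed <- seed
      coh <- generate_cohort(cfg)
      list(value = coh, outputs = character())
    }
  })
  recs <- clinical_frame(data$records)
  subj_of <- vapply(data$cycles, function(c) c$subject_id, character(1))
  cond_of <- recs$condition[match(subj_of, recs$subject_id)]
  hsp_cycles <- data$cycles[cond_of == "HSP"]
  healthy_cycles <- data$cycles[cond_of == "healthy"]

  params <- run_stage("extract", function(seed) {
    m <- extract_matrix(data$cycles)
    write_parameter_matrix(m, out_file("parameters.csv"))
    write_extraction_rules(out_file("extraction_rules.json"))
    list(value = m, outputs = c("parameters.csv", "extraction_rules.json"))
  })
  hsp_ids <- vapply(hsp_cycles, function(c) c$cycle_id, character(1))
  healthy_ids <- vapply(healthy_cycles, function(c) c$cycle_id, character(1))

  dm <- run_stage("dtw_distance", function(seed) {
    m <- dtw_distance_matrix(hsp_cycles, step = config$dtw_step,
                             normalize = config$dtw_normalize,
                             scale = config$dtw_scale)
    write_distance_matrix(m, out_file("dtw_distances.csv"))
    list(value = m, outputs = "dtw_distances.csv")
  })
  tree <- run_stage("linkage", function(seed) {
    hc <- average_linkage(dm)
    write_dendrogram_newick(hc, out_file("dendrogram.nwk"))
    list(value = hc, outputs = "dendrogram.nwk")
  })
  pat <- run_stage("cut", function(seed) {
    p <- gait_patterns(hsp_cycles, k = config$k, dm = dm)
    write_assignment(p$assignment, out_file("pattern_assignment.csv"))
    list(value = p, outputs = "pattern_assignment.csv")
  })
  psum <- run_stage("pattern_summary", function(seed) {
    s <- pat$summary
    utils::write.csv(s$patterns, out_file("pattern_sizes.csv"), row.names = FALSE)
    utils::write.csv(s$subjects, out_file("subject_usage.csv"), row.names = FALSE)
    list(value = s, outputs = c("pattern_sizes.csv", "subject_usage.csv"))
  })

  hsp_params <- params[hsp_ids, , drop = FALSE]
  healthy_params <- params[healthy_ids, , drop = FALSE]

  pattern_rf <- run_stage("pattern_forest", function(seed) {
    fit <- fit_pattern_forest(hsp_params, pat$assignment,
                              forest_spec("classification",
                                          n_trees = config$n_trees,
                                          mtry_grid = c(1, 3, 6, 12),
                                          seed = seed))
    utils::write.csv(fit$importance, out_file("pattern_forest_importance.csv"),
                     row.names = FALSE)
    list(value = fit, outputs = "pattern_forest_importance.csv")
  })
  mild_rf <- run_stage("mild_vs_healthy_forest", function(seed) {
    mild_ids <- pat$assignment$cycle_id[pat$assignment$pattern == 1]
    fit <- fit_mild_vs_healthy_forest(
      params[mild_ids, , drop = FALSE], healthy_params,
      forest_spec("regression", n_trees = config$n_trees,
                  mtry_grid = c(1, 14, 29), seed = seed))
    utils::write.csv(fit$importance, out_file("mild_forest_importance.csv"),
                     row.names = FALSE)
    for (p in names(fit$marginal_effects))
      utils::write.csv(fit$marginal_effects[[p]],
                       out_file(sprintf("marginal_%s.csv", p)),
                       row.names = FALSE)
    list(value = fit, outputs = c("mild_forest_importance.csv",
                                  sprintf("marginal_%s.csv",
                                          names(fit$marginal_effects))))
  })
  ref <- healthy_reference(healthy_params)
  zsc <- run_stage("zscore", function(seed) {
    z <- zscore_matrix(hsp_params, ref)
    ord <- order(pat$assignment$pattern)
    utils::write.csv(data.frame(cycle_id = rownames(z)[ord],
                                pattern = pat$assignment$pattern[ord],
                                z[ord, , drop = FALSE], check.names = FALSE),
                     out_file("zscores.csv"), row.names = FALSE)
    list(value = z, outputs = "zscores.csv")
  })
  lmm <- run_stage("mixed_models", function(seed) {
    r <- fit_pattern_lmm(hsp_params, pat$assignment)
    utils::write.csv(r, out_file("mixed_models.csv"), row.names = FALSE)
    list(value = r, outputs = "mixed_models.csv")
  })

  hsp_subj <- subj_of[cond_of == "HSP"]
  asn_subj <- pat$assignment$subject_id
  clin_pat <- run_stage("clinical_vs_pattern", function(seed) {
    feats <- list(
      age = recs$age[match(asn_subj, recs$subject_id)],
      sex = ifelse(recs$sex[match(asn_subj, recs$subject_id)] == "male", 1, 0),
      gmfcs23 = ifelse(recs$gmfcs[match(asn_subj, recs$subject_id)] == "I", 0, 1),
      polyneuropathy = binary_target(recs, asn_subj, "polyneuropathy"),
      abnormal_vep = binary_target(recs, asn_subj, "abnormal_vep"),
      thin_corpus_callosum = binary_target(recs, asn_subj, "thin_corpus_callosum"))
    res <- lapply(names(feats), function(nm)
      fit_clinical_vs_pattern(feats[[nm]], pat$assignment))
    names(res) <- names(feats)
    tab <- do.call(rbind, lapply(names(res), function(nm) {
      e <- res[[nm]]$effects
      measure <- names(e)[2]
      names(e)[2] <- "estimate"
      data.frame(feature = nm, measure = measure,
                 reference = res[[nm]]$reference,
                 anova_p = res[[nm]]$anova_p, e)
    }))
    utils::write.csv(tab, out_file("clinical_vs_pattern.csv"), row.names = FALSE)
    list(value = res, outputs = "clinical_vs_pattern.csv")
  })

  all_subj <- subj_of
  clin_rf <- run_stage("clinical_forests", function(seed) {
    targets <- list(
      age = recs$age[match(hsp_subj, recs$subject_id)],
      sex = ifelse(recs$sex[match(hsp_subj, recs$subject_id)] == "male", 1, 0),
      gmfcs = ifelse(recs$gmfcs[match(hsp_subj, recs$subject_id)] == "I", 0, 1),
      polyneuropathy = binary_target(recs, hsp_subj, "polyneuropathy"),
      abnormal_vep = binary_target(recs, hsp_subj, "abnormal_vep"),
      thin_corpus_callosum = binary_target(recs, hsp_subj, "thin_corpus_callosum"))
    res <- lapply(names(targets), function(nm)
      tryCatch(
        fit_clinical_forest(hsp_params, targets[[nm]],
                            forest_spec("regression", n_trees = config$n_trees,
                                        mtry_grid = c(1, 7, 14, 28),
                                        seed = seed)),
        error = function(e) list(error = conditionMessage(e))))
    names(res) <- names(targets)
    ok <- names(res)[vapply(res, function(r) is.null(r$error), logical(1))]
    tab <- do.call(rbind, lapply(ok, function(nm)
      data.frame(feature = nm, criterion = res[[nm]]$report$criterion,
                 best_mtry = res[[nm]]$report$best_mtry,
                 goodness = res[[nm]]$report$goodness)))
    utils::write.csv(tab, out_file("clinical_forest_fit.csv"), row.names = FALSE)
    list(value = res, outputs = "clinical_forest_fit.csv")
  })

  robust <- run_stage("robust_age_regressions", function(seed) {
    top4 <- utils::head(clin_rf$age$importance$parameter, 4)
    age_all <- recs$age[match(all_subj, recs$subject_id)]
    res <- lapply(top4, function(p)
      data.frame(parameter = p,
                 robust_age_regression(params[, p], age_all, cond_of)))
    tab <- do.call(rbind, res)
    utils::write.csv(tab, out_file("robust_age_regressions.csv"), row.names = FALSE)
    list(value = tab, outputs = "robust_age_regressions.csv")
  })

  contrasts <- run_stage("bca_contrasts", function(seed) {
    feats <- c("gmfcs", "polyneuropathy", "thin_corpus_callosum")
    rows <- list()
    for (nm in feats) {
      if (!is.null(clin_rf[[nm]]$error)) next
      grp <- switch(nm,
        gmfcs = ifelse(recs$gmfcs[match(hsp_subj, recs$subject_id)] == "I", 0, 1),
        binary_target(recs, hsp_subj, nm))
      gtab <- table(grp[!is.na(grp)])
      if (length(gtab) < 2 || min(gtab) < 3) next
      top4 <- utils::head(clin_rf[[nm]]$importance$parameter, 4)
      for (p in top4) {
        ct <- group_contrast_bca(hsp_params[, p], grp, ref, p,
                                 n_boot = config$n_boot, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(feature = nm, parameter = p, ct)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, out_file("bca_contrasts.csv"), row.names = FALSE)
    list(value = tab, outputs = "bca_contrasts.csv")
  })

  bundle <- c(bundle, list(
    data = data, params = params, distance = dm, tree = tree,
    patterns = pat, pattern_summary = psum, pattern_forest = pattern_rf,
    mild_forest = mild_rf, reference = ref, zscores = zsc,
    mixed_models = lmm, clinical_vs_pattern = clin_pat,
    clinical_forests = clin_rf, robust_age = robust,
    contrasts = contrasts, manifest = manifest))
  class(bundle) <- "gait_pipeline_bundle"
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Human-readable summary of a pipeline bundle
#'
#' Mirrors the study's reporting surfaces: cluster sizes and fractions,
#' per-subject usage, top importances, mixed-model table, clinical-forest
#' goodness of fit, robust age slopes and contrast table. Missing stages
#' are listed as absent rather than failing.
#'
#' @param bundle result of [run_pipeline()].
#' @param path optional file to write the report to.
#' @return Character vector of report lines, invisibly.
#' @export
make_report <- function(bundle, path = NULL) {
  lines <- c("Gait phenotyping pipeline report",
             strrep("=", 40))
  absent <- function(nm) sprintf("[%s: not run]", nm)
  if (!is.null(bundle$pattern_summary)) {
    p <- bundle$pattern_summary$patterns
    lines <- c(lines, "", "Pattern sizes:")
    lines <- c(lines, sprintf("  pattern %d: %d cycles (%.1f%%)%s",
                              p$pattern, p$size, 100 * p$fraction,
                              ifelse(p$outlier, " [outlier]", "")))
    u <- table(bundle$pattern_summary$subjects$usage_class)
    lines <- c(lines, "Per-subject usage:",
               sprintf("  %s: %d (%.1f%%)", names(u), as.integer(u),
                       100 * as.integer(u) / sum(u)))
  } else lines <- c(lines, absent("pattern summary"))
  if (!is.null(bundle$pattern_forest)) {
    r <- bundle$pattern_forest$report
    lines <- c(lines, "",
               sprintf("Pattern forest: best mtry %d, OOB error %.2f%%",
                       r$best_mtry, 100 * r$oob_error),
               "  top importance:",
               sprintf("    %s (%.4f)",
                       utils::head(bundle$pattern_forest$importance$parameter, 5),
                       utils::head(bundle$pattern_forest$importance$vimp, 5)))
  } else lines <- c(lines, absent("pattern forest"))
  if (!is.null(bundle$mild_forest)) {
    r <- bundle$mild_forest$report
    lines <- c(lines, sprintf("Mild vs healthy forest: best mtry %d, AUC %.3f",
                              r$best_mtry, r$auc))
  } else lines <- c(lines, absent("mild-vs-healthy forest"))
  if (!is.null(bundle$mixed_models)) {
    m <- bundle$mixed_models
    lines <- c(lines, "", "Mixed models (pattern effect):",
               sprintf("  %s: chi2(%d) = %.2f, p = %.4g%s", m$parameter,
                       m$df, m$chisq, m$p_value,
                       ifelse(m$singular, " [singular fit]", "")))
  } else lines <- c(lines, absent("mixed models"))
  if (!is.null(bundle$clinical_forests)) {
    lines <- c(lines, "", "Clinical-feature forests:")
    for (nm in names(bundle$clinical_forests)) {
      fitr <- bundle$clinical_forests[[nm]]
      lines <- c(lines, if (!is.null(fitr$error)) {
        sprintf("  %s: not fit (%s)", nm, fitr$error)
      } else {
        sprintf("  %s: best mtry %d, %s = %.3f", nm, fitr$report$best_mtry,
                fitr$report$criterion, fitr$report$goodness)
      })
    }
  } else lines <- c(lines, absent("clinical forests"))
  if (!is.null(bundle$robust_age)) {
    t <- bundle$robust_age
    sl <- t[t$term == "age", ]
    lines <- c(lines, "", "Robust age slopes (healthy reference group):",
               sprintf("  %s: %.4f [%.4f, %.4f]", sl$parameter, sl$estimate,
                       sl$ci_low, sl$ci_high))
  } else lines <- c(lines, absent("robust age regressions"))
  if (!is.null(bundle$contrasts)) {
    ct <- bundle$contrasts[bundle$contrasts$scale == "raw", ]
    lines <- c(lines, "", "Group contrasts (raw units, 95% BCa CI):",
               sprintf("  %s / %s: %.2f [%.2f, %.2f]", ct$feature,
                       ct$parameter, ct$estimate, ct$ci_low, ct$ci_high))
  } else lines <- c(lines, absent("contrasts"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
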