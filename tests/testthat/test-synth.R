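test_that("the healthy template has physiologic landmarks", {
  tp <- healthy_template()
  g <- epoch_grid()
  knee <- eval_channel_for_test(tp, "knee_flexion")
  # knee flexion at initial contact is small (0-10 degrees)
  expect_gt(knee[1], 0); expect_lt(knee[1], 10)
  # swing peak between 60 and 75% of the cycle
  expect_gte(g[which.max(knee)], 60); expect_lte(g[which.max(knee)], 75)
  ankle <- eval_channel_for_test(tp, "ankle_dorsiflexion")
  # push-off plantarflexion trough just around toe-off
  expect_lt(min(ankle[g >= 55 & g <= 70]), -10)
  # stance is about 60%
  expect_equal(unname(tp$events[["toe_off"]]), 60)
  hip <- eval_channel_for_test(tp, "hip_flexion")
  expect_gt(hip[1], 25)          # flexed at initial contact
  expect_lt(min(hip), 0)         # extends in late stance
})

test_that("pattern operators are identities at severity 0 and directional at 1", {
  tp <- healthy_template()
  expect_equal(apply_pattern(tp, 2, severity = 0), tp)
  expect_error(apply_pattern(tp, 9), "unknown pattern")
  base <- param_vector_for_test(tp)
  p2 <- param_vector_for_test(apply_pattern(tp, 2))
  # pattern II: anterior tilt, hip flexion and knee flexion at IC elevated
  expect_gt(p2[["mean_pelvic_tilt"]], base[["mean_pelvic_tilt"]])
  expect_gt(p2[["hip_flexion_at_initial_contact"]],
            base[["hip_flexion_at_initial_contact"]])
  expect_gt(p2[["knee_flexion_at_initial_contact"]],
            base[["knee_flexion_at_initial_contact"]])
  expect_gt(p2[["time_to_peak_knee_flexion"]],
            base[["time_to_peak_knee_flexion"]])
  p5 <- param_vector_for_test(apply_pattern(tp, 5))
  # pattern V: equinus and recurvatum
  expect_lt(p5[["min_ankle_dorsiflexion_stance"]],
            base[["min_ankle_dorsiflexion_stance"]])
  expect_lt(p5[["min_knee_flexion_stance"]], 0)
  p4 <- param_vector_for_test(apply_pattern(tp, 4))
  # pattern IV: crouch with reduced, delayed knee peak
  expect_gt(p4[["min_knee_flexion_stance"]], base[["min_knee_flexion_stance"]])
  expect_lt(p4[["max_knee_flexion"]], base[["max_knee_flexion"]])
  expect_gt(p4[["time_to_peak_knee_flexion"]],
            base[["time_to_peak_knee_flexion"]])
})

test_that("signature deviations grow monotonically with severity", {
  tp <- healthy_template()
  base <- param_vector_for_test(tp)
  sig <- list(`2` = "mean_pelvic_tilt", `4` = "mean_hip_flexion_stance",
              `5` = "mean_ankle_dorsiflexion_single_support",
              `6` = "knee_flexion_at_initial_contact")
  for (pid in names(sig)) {
    dev <- vapply(c(0, 0.5, 1, 1.5), function(s)
      abs(param_vector_for_test(apply_pattern(tp, pid, s))[[sig[[pid]]]] -
            base[[sig[[pid]]]]), numeric(1))
    expect_true(all(diff(dev) > -1e-9))
  }
})

test_that("generated cohorts are valid, deterministic and labelled", {
  cfg <- cohort_config(n_subjects = 4, n_healthy = 3, seed = 123)
  coh <- generate_cohort(cfg)
  # every cycle passes validation (constructed through gait_cycle already,
  # revalidate explicitly)
  for (cyc in coh$cycles) expect_silent(validate_gait_cycle(cyc))
  expect_equal(length(coh$cycles), nrow(coh$labels))
  expect_setequal(coh$labels$condition, c("HSP", "healthy"))
  # outlier planted exactly once
  expect_equal(sum(coh$labels$pattern == 0, na.rm = TRUE), 1)
  # determinism
  coh2 <- generate_cohort(cfg)
  expect_equal(coh$cycles[[5]]$angles, coh2$cycles[[5]]$angles)
  expect_identical(coh$labels, coh2$labels)
  # single-subject single-pattern config
  cfg1 <- cohort_config(n_subjects = 1, n_healthy = 0,
                        pattern_mixture = c(1, 0, 0, 0, 0, 0),
                        usage_mixture = c(1, 0, 0), cycles_per_limb = 5,
                        plant_outlier = FALSE, seed = 2)
  coh1 <- generate_cohort(cfg1)
  expect_equal(length(coh1$cycles), 10)
  expect_true(all(coh1$labels$pattern == 1))
  expect_error(cohort_config(pattern_mixture = c(1, 1, 0, 0, 0, 0)),
               "sum to 1")
})

test_that("healthy records carry no pathology and usage classes match labels", {
  coh <- generate_cohort(cohort_config(n_subjects = 10, n_healthy = 5, seed = 3))
  recs <- do.call(rbind, lapply(coh$records, function(r)
    data.frame(id = r$subject_id, cond = r$condition, pn = r$polyneuropathy)))
  expect_true(all(recs$pn[recs$cond == "healthy"] == "no"))
  # recompute usage classes from the labels (excluding the planted outlier)
  lab <- coh$labels[coh$labels$condition == "HSP" & coh$labels$pattern != 0, ]
  for (sid in unique(lab$subject_id)) {
    sub <- lab[lab$subject_id == sid, ]
    per_limb <- lapply(split(sub$pattern, sub$side), unique)
    cls <- if (any(lengths(per_limb) > 1)) "two patterns in one limb"
    else if (length(unique(sub$pattern)) > 1) "different pattern per limb"
    else "single pattern"
    expect_identical(coh$usage$usage_class[coh$usage$subject_id == sid], cls)
  }
})

test_that("pattern-I cycles stay mild while severe patterns deviate strongly", {
  coh <- generate_cohort(cohort_config(seed = 9))
  params <- extract_matrix(coh$cycles)
  lab <- coh$labels
  healthy <- params[lab$condition == "healthy", , drop = FALSE]
  ref <- healthy_reference(healthy)
  z <- zscore_matrix(params[lab$condition == "HSP", , drop = FALSE], ref)
  zlab <- lab$pattern[lab$condition == "HSP"]
  if (any(zlab == 1)) {
    z1 <- abs(colMeans(z[zlab == 1, , drop = FALSE]))
    # most parameters of the mild pattern lie within ~1 healthy SD
    expect_gt(mean(z1 < 1.5), 0.6)
  }
  for (p in c(4, 5)) if (sum(zlab == p) > 3) {
    sig <- switch(as.character(p), `4` = "min_knee_flexion_single_support",
                  `5` = "mean_ankle_dorsiflexion_single_support")
    expect_gt(abs(mean(z[zlab == p, sig])), 2)
  }
})
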