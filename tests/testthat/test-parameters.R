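test_that("spatio-temporal parameters follow their definitions", {
  cyc <- toy_cycle(stride_time = 1, stride_length = 1.2, subject_height = 1.5)
  st <- extract_spatiotemporal(cyc)
  expect_equal(st[["normalized_walking_speed"]], 0.8)
  expect_equal(st[["cadence"]], 2)
  expect_equal(st[["stance_pct"]], 60)
  expect_equal(st[["first_double_support_pct"]], 10)
  expect_equal(st[["single_support_pct"]], 40)
  expect_equal(st[["second_double_support_pct"]], 10)
  # doubling stride time at fixed length halves cadence and speed
  cyc2 <- toy_cycle(stride_time = 2, stride_length = 1.2, subject_height = 1.5)
  st2 <- extract_spatiotemporal(cyc2)
  expect_equal(st2[["cadence"]], st[["cadence"]] / 2)
  expect_equal(st2[["normalized_walking_speed"]],
               st[["normalized_walking_speed"]] / 2)
})

test_that("kinematic rules compute operators over their windows", {
  # constant pelvic tilt: mean = the constant, range = 0
  cyc <- toy_cycle(channels = list(pelvic_tilt = 12, knee_flexion = 7.5),
                   all_channels = TRUE)
  kin <- extract_kinematic(cyc)
  expect_length(kin, 37)
  expect_equal(kin[["mean_pelvic_tilt"]], 12)
  expect_equal(kin[["range_pelvic_tilt"]], 0)
  expect_equal(kin[["knee_flexion_at_initial_contact"]], 7.5)
  # planted sinusoid: knee = 30 + 25 sin(2 pi t/100 - pi/2), peak at 50%
  g <- epoch_grid()
  knee <- 30 + 25 * sin(2 * pi * g / 100 - pi / 2)
  cyc2 <- toy_cycle(channels = list(knee_flexion = knee), all_channels = TRUE)
  kin2 <- extract_kinematic(cyc2)
  expect_equal(kin2[["time_to_peak_knee_flexion"]], 50)
  expect_equal(kin2[["max_knee_flexion"]], 55)
  expect_equal(kin2[["min_knee_flexion_stance"]], 5)
  # missing channel errors name the affected parameters
  cyc3 <- toy_cycle(channels = list(pelvic_tilt = 1))
  expect_error(extract_kinematic(cyc3), "mean_pelvic_rotation")
})

test_that("shift equivariance and window monotonicity hold", {
  set.seed(7)
  smooth <- function() {
    x <- stats::filter(rnorm(221), rep(1 / 21, 21), sides = 2)
    as.numeric(x[11:211]) * 10 + 20
  }
  for (rep in 1:5) {
    vals <- lapply(stats::setNames(gait_channels(), gait_channels()),
                   function(ch) smooth())
    ev <- gait_events(sort(runif(1, 5, 15)), runif(1, 40, 55), runif(1, 58, 70))
    cyc <- toy_cycle(channels = vals, events = ev, all_channels = TRUE)
    kin <- extract_kinematic(cyc)
    # add a constant to the knee channel only
    vals2 <- vals; vals2$knee_flexion <- vals$knee_flexion + 5
    kin2 <- extract_kinematic(toy_cycle(channels = vals2, events = ev,
                                        all_channels = TRUE))
    shifted <- c("knee_flexion_at_initial_contact", "min_knee_flexion_stance",
                 "max_knee_flexion", "max_knee_flexion_single_support")
    unchanged <- c("range_knee_flexion", "time_to_peak_knee_flexion",
                   "mean_pelvic_tilt", "range_knee_flexion_second_ds_swing")
    for (p in shifted) expect_equal(kin2[[p]], kin[[p]] + 5, tolerance = 1e-12)
    for (p in unchanged) expect_equal(kin2[[p]], kin[[p]], tolerance = 1e-12)
    # window monotonicity: extrema over stance bound extrema of sub-windows
    expect_gte(max(kin[["max_knee_flexion_first_double_support"]],
                   kin[["max_knee_flexion_single_support"]]) + 1e-9,
               kin[["max_knee_flexion_first_double_support"]])
    expect_lte(kin[["min_knee_flexion_stance"]],
               kin[["min_knee_flexion_single_support"]] + 1e-12)
    expect_gte(kin[["max_knee_flexion"]],
               kin[["max_knee_flexion_single_support"]])
  }
})

test_that("time_of_max lands on the grid argmax of a unimodal series", {
  g <- epoch_grid()
  for (peak in c(33.2, 47.9, 71.4)) {
    knee <- 50 - (g - peak)^2 / 10
    kin <- extract_kinematic(toy_cycle(channels = list(knee_flexion = knee),
                                       all_channels = TRUE))
    expect_equal(kin[["time_to_peak_knee_flexion"]],
                 g[which.min(abs(g - peak))])
  }
})

test_that("matrix extraction agrees with per-cycle extraction", {
  coh <- planted_cohort(n_per = 2, k = 3, seed = 3)
  # give cycles all channels so the full table extracts
  cycles <- lapply(coh$cycles, function(cyc) {
    set.seed(match(cyc$cycle_id, vapply(coh$cycles, `[[`, "", "cycle_id")))
    vals <- lapply(stats::setNames(gait_channels(), gait_channels()),
                   function(ch) rnorm(201, 10, 3))
    toy_cycle(cyc$cycle_id, cyc$subject_id, channels = vals,
              all_channels = TRUE)
  })
  m <- extract_matrix(cycles)
  expect_equal(dim(m), c(6, 43))
  expect_identical(colnames(m), parameter_names())
  for (i in seq_along(cycles))
    expect_equal(unname(m[i, ]),
                 unname(c(extract_spatiotemporal(cycles[[i]]),
                          extract_kinematic(cycles[[i]]))))
  # permutation equivariance of rows
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(extract_matrix(cycles[perm]), m[perm, ])
  # errors carry the cycle id
  bad <- planted_cohort(n_per = 1, k = 1)$cycles
  expect_error(extract_matrix(bad), "g1_1")
})

test_that("extraction rule table is total, auditable and exportable", {
  rules <- extraction_rules()
  expect_equal(nrow(rules), 37)
  expect_false(anyDuplicated(rules$parameter) > 0)
  expect_true(all(rules$channel %in% gait_channels()))
  expect_true(all(rules$operator %in% c("value_at", "min", "max", "mean",
                                        "range", "time_of_max", "time_of_min")))
  f <- withr::local_tempfile(fileext = ".json")
  write_extraction_rules(f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$parameter, rules$parameter)
})
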