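#' The kinematic parameter extraction rule table
#'
#' Each of the 37 kinematic parameters is defined by one
#' (channel, window, operator) rule. Windows refer to the phase windows of
#' the cycle ([phase_windows()]), their unions
#' (`first_ds_single_support` = first double support plus single support,
#' `second_ds_swing` = second double support plus swing), the whole
#' `cycle`, or the `initial_contact` event (epoch 0). Operators are
#' `value_at`, `min`, `max`, `mean`, `range`, `time_of_max` and
#' `time_of_min`; the `time_of_*` operators return the percent of the whole
#' gait cycle at which the extremum occurs, ties broken toward the earliest
#' epoch. The table is exported as JSON by [write_extraction_rules()] so
#' the mapping is auditable.
#'
#' @return Data frame with columns `parameter`, `channel`, `window`,
#'   `operator` (37 rows, canonical order).
#' @export
extraction_rules <- function() {
  r <- function(parameter, channel, window, operator)
    data.frame(parameter = parameter, channel = channel, window = window,
               operator = operator, stringsAsFactors = FALSE)
  rbind(
    r("mean_pelvic_tilt", "pelvic_tilt", "cycle", "mean"),
    r("range_pelvic_tilt", "pelvic_tilt", "cycle", "range"),
    r("pelvic_rotation_at_initial_contact", "pelvic_rotation", "initial_contact", "value_at"),
    r("mean_pelvic_rotation", "pelvic_rotation", "cycle", "mean"),
    r("range_pelvic_rotation_second_double_support", "pelvic_rotation", "second_double_support", "range"),
    r("range_pelvic_rotation_terminal_swing", "pelvic_rotation", "terminal_swing", "range"),
    r("mean_pelvic_obliquity_stance", "pelvic_obliquity", "stance", "mean"),
    r("hip_flexion_at_initial_contact", "hip_flexion", "initial_contact", "value_at"),
    r("min_hip_flexion", "hip_flexion", "cycle", "min"),
    r("mean_hip_flexion_stance", "hip_flexion", "stance", "mean"),
    r("max_hip_flexion_swing", "hip_flexion", "swing", "max"),
    r("time_to_max_hip_flexion_swing", "hip_flexion", "swing", "time_of_max"),
    r("range_hip_flexion", "hip_flexion", "cycle", "range"),
    r("mean_hip_abduction_first_ds_single_support", "hip_abduction", "first_ds_single_support", "mean"),
    r("max_hip_abduction_swing", "hip_abduction", "swing", "max"),
    r("mean_hip_rotation_stance", "hip_rotation", "stance", "mean"),
    r("mean_hip_rotation_swing", "hip_rotation", "swing", "mean"),
    r("knee_flexion_at_initial_contact", "knee_flexion", "initial_contact", "value_at"),
    r("min_knee_flexion_stance", "knee_flexion", "stance", "min"),
    r("max_knee_flexion_first_double_support", "knee_flexion", "first_double_support", "max"),
    r("max_knee_flexion_single_support", "knee_flexion", "single_support", "max"),
    r("min_knee_flexion_single_support", "knee_flexion", "single_support", "min"),
    r("max_knee_flexion", "knee_flexion", "cycle", "max"),
    r("time_to_peak_knee_flexion", "knee_flexion", "cycle", "time_of_max"),
    r("range_knee_flexion_second_ds_swing", "knee_flexion", "second_ds_swing", "range"),
    r("range_knee_flexion", "knee_flexion", "cycle", "range"),
    r("ankle_dorsiflexion_at_initial_contact", "ankle_dorsiflexion", "initial_contact", "value_at"),
    r("max_ankle_dorsiflexion_stance", "ankle_dorsiflexion", "stance", "max"),
    r("min_ankle_dorsiflexion_stance", "ankle_dorsiflexion", "stance", "min"),
    r("range_ankle_dorsiflexion_stance", "ankle_dorsiflexion", "stance", "range"),
    r("mean_ankle_dorsiflexion_first_double_support", "ankle_dorsiflexion", "first_double_support", "mean"),
    r("mean_ankle_dorsiflexion_single_support", "ankle_dorsiflexion", "single_support", "mean"),
    r("mean_ankle_dorsiflexion_second_double_support", "ankle_dorsiflexion", "second_double_support", "mean"),
    r("max_ankle_dorsiflexion_swing", "ankle_dorsiflexion", "swing", "max"),
    r("min_ankle_dorsiflexion_swing", "ankle_dorsiflexion", "swing", "min"),
    r("range_ankle_dorsiflexion_swing", "ankle_dorsiflexion", "swing", "range"),
    r("mean_foot_progression_stance", "foot_progression", "stance", "mean")
  )
}

#' Canonical names of the 43 gait parameters
#'
#' The six spatio-temporal parameters followed by the 37 kinematic
#' parameters, in canonical column order.
#'
#' @return Character vector of length 43.
#' @export
parameter_names <- function() {
  c(spatiotemporal_names(), extraction_rules()$parameter)
}

#' @rdname parameter_names
#' @export
spatiotemporal_names <- function() {
  c("normalized_walking_speed", "cadence", "stance_pct",
    "first_double_support_pct", "single_support_pct",
    "second_double_support_pct")
}

#' Export the extraction rule table as JSON
#'
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_extraction_rules <- function(path) {
  jsonlite::write_json(extraction_rules(), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Spatio-temporal parameters of one gait cycle
#'
#' Cadence is steps per second (two steps per stride); normalized walking
#' speed is raw walking speed (stride length over stride time) divided by
#' subject height, in 1/s; the four phase percentages are the widths of the
#' phase windows derived from the gait events.
#'
#' @param cycle a [gait_cycle()].
#' @return Named numeric vector of the 6 spatio-temporal parameters.
#' @export
extract_spatiotemporal <- function(cycle) {
  if (cycle$stride_time <= 0) stop("stride_time must be > 0")
  w <- phase_windows(cycle$events)
  width <- function(win) win[2] - win[1]
  c(normalized_walking_speed =
      (cycle$stride_length / cycle$stride_time) / cycle$subject_height,
    cadence = 2 / cycle$stride_time,
    stance_pct = width(w$stance),
    first_double_support_pct = width(w$first_double_support),
    single_support_pct = width(w$single_support),
    second_double_support_pct = width(w$second_double_support))
}

resolve_window <- function(name, w) {
  switch(name,
         cycle = NULL,
         initial_contact = "initial_contact",
         first_ds_single_support = c(0, w$single_support[2]),
         second_ds_swing = c(w$second_double_support[1], 100),
         stance = w$stance,
         first_double_support = w$first_double_support,
         single_support = w$single_support,
         second_double_support = w$second_double_support,
         swing = w$swing,
         terminal_swing = w$terminal_swing,
         stop("unknown window '", name, "'"))
}

apply_operator <- function(values, operator, idx) {
  g <- epoch_grid()
  v <- values[idx]
  switch(operator,
         value_at = values[1],  # initial contact is exactly epoch 0
         min = min(v),
         max = max(v),
         mean = mean(v),
         range = max(v) - min(v),
         time_of_max = g[idx][which.max(v)],
         time_of_min = g[idx][which.min(v)],
         stop("unknown operator '", operator, "'"))
}

#' Kinematic parameters of one gait cycle
#'
#' Applies the extraction rule table to the cycle's channels and phase
#' windows. All values are in degrees except the `time_to_*` parameters,
#' which are in percent of the gait cycle.
#'
#' @param cycle a [gait_cycle()].
#' @param rules rule table, by default [extraction_rules()].
#' @return Named numeric vector of 37 kinematic parameters.
#' @export
extract_kinematic <- function(cycle, rules = extraction_rules()) {
  w <- phase_windows(cycle$events)
  have <- colnames(cycle$angles)
  missing_ch <- setdiff(unique(rules$channel), have)
  if (length(missing_ch)) {
    affected <- rules$parameter[rules$channel %in% missing_ch]
    stop("missing channel(s) ", paste(missing_ch, collapse = ", "),
         " required for parameter(s): ", paste(affected, collapse = ", "))
  }
  out <- vapply(seq_len(nrow(rules)), function(i) {
    rule <- rules[i, ]
    win <- resolve_window(rule$window, w)
    vals <- cycle$angles[, rule$channel]
    if (identical(win, "initial_contact")) return(vals[1])
    apply_operator(vals, rule$operator, epochs_in_window(win))
  }, numeric(1))
  names(out) <- rules$parameter
  out
}

#' Full parameter matrix of a cohort of cycles
#'
#' One row per cycle in input order, 43 columns in canonical order
#' (spatio-temporal first, then kinematic). Row names are cycle ids.
#'
#' @param cycles list of [gait_cycle()] objects.
#' @param rules kinematic rule table, by default [extraction_rules()].
#' @return Numeric matrix, cycles x 43.
#' @export
extract_matrix <- function(cycles, rules = extraction_rules()) {
  rows <- lapply(cycles, function(cyc) {
    tryCatch(c(extract_spatiotemporal(cyc), extract_kinematic(cyc, rules)),
             error = function(e)
               stop("cycle '", cyc$cycle_id, "': ", conditionMessage(e),
                    call. = FALSE))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(cycles, function(c) c$cycle_id, character(1))
  m
}

#' Write a parameter matrix as delimited text
#'
#' @param params matrix from [extract_matrix()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_parameter_matrix <- function(params, path) {
  df <- data.frame(cycle_id = rownames(params), params,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
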