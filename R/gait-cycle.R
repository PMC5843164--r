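#' @useDynLib gaitpatterns, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Controlled vocabulary of joint-angle channels
#'
#' The ten named angle channels a gait cycle may carry. The first five are
#' the sagittal-plane channels (flexion/extension sign convention: positive
#' is flexion, dorsiflexion or anterior tilt; negative is extension) and are
#' mandatory for every cycle; the remaining five are transverse/coronal
#' channels needed only for the full kinematic parameter set.
#'
#' @return Character vector of channel names.
#' @export
gait_channels <- function() {
  c(sagittal_channels(),
    "pelvic_rotation", "pelvic_obliquity", "hip_abduction", "hip_rotation",
    "foot_progression")
}

#' @rdname gait_channels
#' @export
sagittal_channels <- function() {
  c("pelvic_tilt", "hip_flexion", "knee_flexion", "ankle_dorsiflexion",
    "forefoot_flexion")
}

#' Epoch grid of a time-normalized gait cycle
#'
#' Gait cycles are time-normalized to 201 epochs at 0.5% spacing covering
#' 0--100% of the cycle (initial contact to the next initial contact of the
#' same foot).
#'
#' @return Numeric vector of length 201: 0, 0.5, ..., 100.
#' @export
epoch_grid <- function() seq(0, 100, by = 0.5)

N_EPOCHS <- 201L

#' Gait events of one cycle
#'
#' Timing of the three intra-cycle events, in percent of the gait cycle.
#' Initial contact is epoch 0 by convention, so the events must satisfy
#' 0 < opposite_toe_off < opposite_initial_contact < toe_off < 100.
#'
#' @param opposite_toe_off contralateral toe-off, % of cycle (end of first
#'   double support).
#' @param opposite_initial_contact contralateral foot strike, % of cycle
#'   (end of single support).
#' @param toe_off ipsilateral toe-off, % of cycle (end of stance).
#' @return Object of class `gait_events` (a named list).
#' @export
gait_events <- function(opposite_toe_off, opposite_initial_contact, toe_off) {
  ev <- list(opposite_toe_off = as.numeric(opposite_toe_off),
             opposite_initial_contact = as.numeric(opposite_initial_contact),
             toe_off = as.numeric(toe_off))
  if (anyNA(ev) || !all(vapply(ev, is.finite, logical(1))))
    stop("gait events must be finite numbers")
  if (!(0 < ev$opposite_toe_off &&
        ev$opposite_toe_off < ev$opposite_initial_contact &&
        ev$opposite_initial_contact < ev$toe_off && ev$toe_off < 100))
    stop("gait events must satisfy 0 < opposite_toe_off < ",
         "opposite_initial_contact < toe_off < 100")
  structure(ev, class = "gait_events")
}

#' Construct a validated gait cycle
#'
#' One time-normalized stride of one limb: a 201-epoch matrix of named angle
#' channels, the intra-cycle events, and stride metadata. The five sagittal
#' channels are mandatory; the five non-sagittal channels are optional but
#' required for full kinematic parameter extraction.
#'
#' @param cycle_id unique identifier of the cycle.
#' @param subject_id identifier of the subject the cycle belongs to.
#' @param side `"left"` or `"right"`.
#' @param angles numeric matrix, 201 rows (epochs 0..100%) by one column per
#'   channel; column names from [gait_channels()]; values in degrees.
#' @param events a [gait_events()] object.
#' @param stride_time stride duration in seconds (> 0).
#' @param stride_length stride length in meters (>= 0).
#' @param subject_height subject height in meters (> 0).
#' @return Object of class `gait_cycle`.
#' @export
gait_cycle <- function(cycle_id, subject_id, side, angles, events,
                       stride_time, stride_length, subject_height) {
  side <- match.arg(side, c("left", "right"))
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  cyc <- structure(
    list(cycle_id = as.character(cycle_id),
         subject_id = as.character(subject_id),
         side = side, angles = angles,
         events = events,
         stride_time = as.numeric(stride_time),
         stride_length = as.numeric(stride_length),
         subject_height = as.numeric(subject_height)),
    class = "gait_cycle")
  validate_gait_cycle(cyc)
  cyc
}

#' Validate a gait cycle against its invariants
#'
#' Checks epoch count, channel vocabulary, presence of the sagittal
#' channels, finiteness of all angles, event ordering and positivity of the
#' stride metadata. Errors name the cycle and the violated rule.
#'
#' @param cycle a `gait_cycle` object.
#' @return The cycle, invisibly, if valid.
#' @export
validate_gait_cycle <- function(cycle) {
  id <- cycle$cycle_id
  fail <- function(rule) stop("cycle '", id, "': ", rule, call. = FALSE)
  if (!inherits(cycle$events, "gait_events")) fail("events missing or invalid")
  a <- cycle$angles
  if (nrow(a) != N_EPOCHS)
    fail(sprintf("expected 201 epochs, got %d", nrow(a)))
  ch <- colnames(a)
  if (is.null(ch) || anyDuplicated(ch))
    fail("angle columns must carry unique channel names")
  unknown <- setdiff(ch, gait_channels())
  if (length(unknown))
    fail(paste0("unknown channel(s): ", paste(unknown, collapse = ", ")))
  missing_sag <- setdiff(sagittal_channels(), ch)
  if (length(missing_sag))
    fail(paste0("missing mandatory sagittal channel(s): ",
                paste(missing_sag, collapse = ", ")))
  if (!all(is.finite(a))) fail("non-finite angle values")
  if (!is.finite(cycle$stride_time) || cycle$stride_time <= 0)
    fail("stride_time must be > 0")
  if (!is.finite(cycle$stride_length) || cycle$stride_length < 0)
    fail("stride_length must be >= 0")
  if (!is.finite(cycle$subject_height) || cycle$subject_height <= 0)
    fail("subject_height must be > 0")
  invisible(cycle)
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("<gait_cycle %s> subject %s, %s side, %d channels\n",
              x$cycle_id, x$subject_id, x$side, ncol(x$angles)))
  cat(sprintf("  events: OTO %.1f%%, OIC %.1f%%, TO %.1f%% | stride %.2f s, %.2f m\n",
              x$events$opposite_toe_off, x$events$opposite_initial_contact,
              x$events$toe_off, x$stride_time, x$stride_length))
  invisible(x)
}

#' Subject-level clinical record
#'
#' @param subject_id subject identifier.
#' @param age age in years (2--20 for this pediatric cohort model).
#' @param sex `"female"` or `"male"`.
#' @param gmfcs Gross Motor Function Classification System stage,
#'   `"I"`, `"II"` or `"III"`.
#' @param polyneuropathy,abnormal_vep,thin_corpus_callosum `"yes"`, `"no"`
#'   or `"unknown"`.
#' @param condition `"HSP"` or `"healthy"`. Healthy subjects must carry all
#'   pathology flags `"no"`.
#' @return Object of class `clinical_record`.
#' @export
clinical_record <- function(subject_id, age, sex, gmfcs = "I",
                            polyneuropathy = "no", abnormal_vep = "no",
                            thin_corpus_callosum = "no",
                            condition = c("HSP", "healthy")) {
  condition <- match.arg(condition)
  sex <- match.arg(sex, c("female", "male"))
  gmfcs <- match.arg(gmfcs, c("I", "II", "III"))
  flag <- function(x) match.arg(x, c("yes", "no", "unknown"))
  rec <- structure(
    list(subject_id = as.character(subject_id), age = as.numeric(age),
         sex = sex, gmfcs = gmfcs,
         polyneuropathy = flag(polyneuropathy),
         abnormal_vep = flag(abnormal_vep),
         thin_corpus_callosum = flag(thin_corpus_callosum),
         condition = condition),
    class = "clinical_record")
  if (!is.finite(rec$age) || rec$age < 2 || rec$age > 20)
    stop("subject '", rec$subject_id, "': age must lie in [2, 20] years")
  if (condition == "healthy" &&
      any(c(rec$polyneuropathy, rec$abnormal_vep,
            rec$thin_corpus_callosum) != "no"))
    stop("subject '", rec$subject_id,
         "': healthy subjects must have all pathology flags 'no'")
  rec
}

#' Phase windows of the gait cycle derived from the events
#'
#' Segments the cycle into the standard support phases, each a half-open
#' interval `[a, b)` in percent of cycle: stance `[0, toe_off)` split into
#' first double support `[0, opposite_toe_off)`, single support
#' `[opposite_toe_off, opposite_initial_contact)` and second double support
#' `[opposite_initial_contact, toe_off)`; swing `[toe_off, 100)`. Terminal
#' swing is defined as the final third of the swing window (a conventional
#' split; the interval is returned explicitly so it can be changed).
#'
#' @param events a [gait_events()] object.
#' @return Object of class `phase_windows`: a named list of `c(start, end)`
#'   intervals in percent of cycle.
#' @export
phase_windows <- function(events) {
  if (!inherits(events, "gait_events")) stop("events must be a gait_events object")
  oto <- events$opposite_toe_off
  oic <- events$opposite_initial_contact
  to <- events$toe_off
  structure(list(
    stance = c(0, to),
    first_double_support = c(0, oto),
    single_support = c(oto, oic),
    second_double_support = c(oic, to),
    swing = c(to, 100),
    terminal_swing = c(100 - (100 - to) / 3, 100)
  ), class = "phase_windows")
}

#' Resample a raw angle trace onto the 201-epoch grid
#'
#' Monotone piecewise-cubic (Fritsch--Carlson) interpolation of an
#' irregularly sampled angle trace onto the fixed 0--100% grid. Monotone
#' interpolation keeps kinematic curves smooth without overshooting at
#' peaks. The endpoints of the input must span the full cycle and are
#' preserved exactly.
#'
#' @param times sample times in percent of cycle, strictly increasing,
#'   covering `[0, 100]`.
#' @param angles angle values in degrees, same length as `times`.
#' @return Numeric vector of 201 angles on [epoch_grid()].
#' @export
resample_to_epochs <- function(times, angles) {
  if (length(times) != length(angles)) stop("times and angles differ in length")
  if (length(times) < 4) stop("need at least 4 samples spanning the cycle")
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing")
  if (times[1] > 0 || times[length(times)] < 100)
    stop("samples must span the full cycle [0, 100]")
  f <- stats::splinefun(times, angles, method = "monoH.FC")
  out <- f(epoch_grid())
  # endpoints exact by construction of the grid when 0 and 100 are knots
  out[1] <- angles[which.min(times)]
  out[N_EPOCHS] <- angles[which.max(times)]
  out
}

# Logical index of epochs inside a half-open window [a, b); the epoch at
# exactly b belongs to the next window. `window = NULL` means the whole
# cycle including the closing epoch at 100%.
epochs_in_window <- function(window = NULL) {
  g <- epoch_grid()
  if (is.null(window)) return(rep(TRUE, N_EPOCHS))
  g >= window[1] & g < window[2]
}
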