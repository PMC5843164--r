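circ_dist <- function(t, center) pmin(abs(t - center), 100 - abs(t - center))

# evaluate one channel's parametric curve on the epoch grid:
# offset + low-order harmonics + periodic (wrapped) Gaussian bumps
eval_channel <- function(ch, t = epoch_grid()) {
  v <- rep(ch$offset, length(t))
  for (h in ch$harm)
    v <- v + h$amp * cos(2 * pi * h$k * (t - h$phase) / 100)
  for (b in ch$bumps)
    v <- v + b$amp * exp(-0.5 * (circ_dist(t, b$center) / b$width)^2)
  v
}

#' Parametric healthy gait template
#'
#' Smooth periodic curves per channel built from a constant offset,
#' low-order harmonics and wrapped Gaussian bumps, with physiologic
#' landmarks: hip flexion peaks in terminal swing and reaches peak
#' extension mid-stance; knee flexion shows the loading-response hump and
#' a swing peak near 70% of the cycle; the ankle plantarflexes at push-off
#' just before toe-off; stance occupies about 60% of the cycle (events at
#' 10, 50 and 60%). The template is the deterministic skeleton the
#' generator perturbs with pattern operators and noise.
#'
#' @return List with `channels` (named per-channel parameter lists),
#'   `events` (numeric: opposite_toe_off, opposite_initial_contact,
#'   toe_off) and `spatio` (speed/cadence multipliers, both 1).
#' @export
healthy_template <- function() {
  harm <- function(k, amp, phase) list(k = k, amp = amp, phase = phase)
  bump <- function(center, width, amp) list(center = center, width = width, amp = amp)
  channels <- list(
    pelvic_tilt = list(offset = 8, harm = list(harm(2, 1.5, 10)), bumps = list()),
    hip_flexion = list(offset = 12, harm = list(harm(1, 23, -5)), bumps = list()),
    knee_flexion = list(offset = 4, harm = list(),
                        bumps = list(load = bump(14, 7, 13),
                                     swing = bump(70, 9, 56))),
    ankle_dorsiflexion = list(offset = 0, harm = list(),
                              bumps = list(early = bump(5, 4, -7),
                                           stance = bump(42, 15, 10),
                                           pushoff = bump(63, 6, -22))),
    forefoot_flexion = list(offset = -2, harm = list(),
                            bumps = list(early = bump(8, 5, -4),
                                         pushoff = bump(62, 7, -14))),
    pelvic_rotation = list(offset = 0, harm = list(harm(1, 5, 0)), bumps = list()),
    pelvic_obliquity = list(offset = 0, harm = list(harm(2, 2, 25)), bumps = list()),
    hip_abduction = list(offset = -2, harm = list(harm(1, 4, 60)), bumps = list()),
    hip_rotation = list(offset = 2, harm = list(harm(1, 4, 30)), bumps = list()),
    foot_progression = list(offset = -8, harm = list(harm(2, 2, 0)), bumps = list())
  )
  list(channels = channels,
       events = c(opposite_toe_off = 10, opposite_initial_contact = 50,
                  toe_off = 60),
       spatio = c(speed_mult = 1, cadence_mult = 1))
}

#' Perturbation signatures of the six sagittal gait patterns
#'
#' Pure operators on the healthy template, expressed in degrees or percent
#' of cycle at severity 1 and scaled linearly with severity. The
#' signatures encode the published pattern narratives: I is mild (slight
#' anterior pelvic tilt, slightly delayed knee peak, prolonged stance);
#' II adds marked anterior tilt with the "double hump", elevated hip
#' flexion and knee flexion at initial contact; III has severe stance
#' knee extension (recurvatum) with a reduced, delayed swing peak; IV is
#' crouch-like (stance knee flexion, hip-extension deficit, excess
#' dorsiflexion, lost push-off, slow); V combines double-hump tilt,
#' recurvatum and equinus (plantarflexion bias in ankle and forefoot);
#' VI is jump-knee-like (high knee flexion at initial contact and load
#' response, double-hump tilt, mild equinus, near-normal spatio-temporal
#' performance). All magnitudes live here, not in the synthesis code.
#'
#' @return Named list (patterns `"1"`..`"6"`) of operator lists.
#' @export
pattern_specs <- function() {
  bump <- function(center, width, amp) list(center = center, width = width, amp = amp)
  list(
    `1` = list(offsets = c(pelvic_tilt = 3, hip_flexion = 2.5),
               hump_amp = 0,
               bumps = list(knee_flexion = list(ic = bump(0, 8, 4))),
               knee_peak_delay = 2.5, knee_peak_scale = 1,
               ankle_pushoff_scale = 1,
               spatio = c(speed_mult = 0.95, cadence_mult = 0.97,
                          stance_shift = 4, ds_shift = 0.8)),
    `2` = list(offsets = c(pelvic_tilt = 9, hip_flexion = 9),
               hump_amp = 3,
               bumps = list(knee_flexion = list(ic = bump(0, 9, 13))),
               knee_peak_delay = 8, knee_peak_scale = 0.92,
               ankle_pushoff_scale = 1,
               spatio = c(speed_mult = 0.92, cadence_mult = 0.95,
                          stance_shift = 3, ds_shift = 0.8)),
    `3` = list(offsets = c(pelvic_tilt = 3),
               hump_amp = 0, pelvic_rot_amp = 4,
               bumps = list(hip_flexion = list(ext_deficit = bump(45, 13, 11)),
                            knee_flexion = list(recurvatum = bump(33, 16, -15)),
                            ankle_dorsiflexion = list(late_pf = bump(72, 7, -10))),
               knee_peak_delay = 8, knee_peak_scale = 0.7,
               ankle_pushoff_scale = 0.7,
               spatio = c(speed_mult = 0.85, cadence_mult = 0.9,
                          stance_shift = 3, ds_shift = 1.5)),
    `4` = list(offsets = c(ankle_dorsiflexion = 8),
               hump_amp = 0,
               bumps = list(hip_flexion = list(ext_deficit = bump(45, 13, 12)),
                            knee_flexion = list(crouch = bump(28, 18, 17),
                                                ic = bump(0, 9, 14))),
               knee_peak_delay = 8, knee_peak_scale = 0.8,
               ankle_pushoff_scale = 0.4,
               spatio = c(speed_mult = 0.7, cadence_mult = 0.85,
                          stance_shift = 6, ds_shift = 2.5)),
    `5` = list(offsets = c(pelvic_tilt = 10, ankle_dorsiflexion = -14,
                           forefoot_flexion = -10),
               hump_amp = 4,
               bumps = list(hip_flexion = list(ext_deficit = bump(45, 13, 8)),
                            knee_flexion = list(recurvatum = bump(30, 12, -13))),
               knee_peak_delay = 5, knee_peak_scale = 0.8,
               ankle_pushoff_scale = 0.8,
               spatio = c(speed_mult = 0.7, cadence_mult = 0.9,
                          stance_shift = 6, ds_shift = 2.5)),
    `6` = list(offsets = c(pelvic_tilt = 8, ankle_dorsiflexion = -7,
                           forefoot_flexion = -5),
               hump_amp = 3,
               bumps = list(hip_flexion = list(ic = bump(0, 12, 10)),
                            knee_flexion = list(ic = bump(0, 11, 17))),
               knee_peak_delay = 6, knee_peak_scale = 1,
               ankle_pushoff_scale = 0.9,
               spatio = c(speed_mult = 0.95, cadence_mult = 0.98,
                          stance_shift = 2, ds_shift = 0.5))
  )
}

#' Apply a pattern signature to the template at a given severity
#'
#' Operators are applied in a fixed order -- constant offsets, harmonic
#' (double hump) modulation, peak delay/attenuation of the knee swing
#' bump and push-off attenuation, then event-locked bumps -- and every
#' magnitude scales linearly with `severity`; severity 0 is the identity.
#'
#' @param template template parameter list from [healthy_template()].
#' @param spec one element of [pattern_specs()] (or a pattern id
#'   `1`..`6`).
#' @param severity non-negative scalar (default 1).
#' @return A modified template parameter list.
#' @export
apply_pattern <- function(template, spec, severity = 1) {
  if (severity < 0) stop("severity must be >= 0")
  if (is.numeric(spec) || is.character(spec)) {
    id <- as.character(spec)
    if (!id %in% names(pattern_specs())) stop("unknown pattern id '", id, "'")
    spec <- pattern_specs()[[id]]
  }
  tp <- template
  for (ch in names(spec$offsets))
    tp$channels[[ch]]$offset <- tp$channels[[ch]]$offset +
      severity * spec$offsets[[ch]]
  if (spec$hump_amp != 0)
    tp$channels$pelvic_tilt$harm[[1]]$amp <-
      tp$channels$pelvic_tilt$harm[[1]]$amp + severity * spec$hump_amp
  if (!is.null(spec$pelvic_rot_amp))
    tp$channels$pelvic_rotation$harm[[1]]$amp <-
      tp$channels$pelvic_rotation$harm[[1]]$amp + severity * spec$pelvic_rot_amp
  sw <- tp$channels$knee_flexion$bumps$swing
  sw$center <- sw$center + severity * spec$knee_peak_delay
  sw$amp <- sw$amp * (1 + severity * (spec$knee_peak_scale - 1))
  tp$channels$knee_flexion$bumps$swing <- sw
  po <- tp$channels$ankle_dorsiflexion$bumps$pushoff
  po$amp <- po$amp * (1 + severity * (spec$ankle_pushoff_scale - 1))
  tp$channels$ankle_dorsiflexion$bumps$pushoff <- po
  for (ch in names(spec$bumps))
    for (nm in names(spec$bumps[[ch]])) {
      b <- spec$bumps[[ch]][[nm]]
      b$amp <- severity * b$amp
      if (b$amp != 0) tp$channels[[ch]]$bumps[[nm]] <- b
    }
  sh <- severity * spec$spatio[["stance_shift"]]
  ds <- severity * spec$spatio[["ds_shift"]]
  ev <- template$events
  to <- ev[["toe_off"]] + sh
  tp$events <- c(opposite_toe_off = ev[["opposite_toe_off"]] * to / ev[["toe_off"]] + ds,
                 opposite_initial_contact = ev[["opposite_initial_contact"]] * to / ev[["toe_off"]] - ds,
                 toe_off = to)
  tp$spatio <- c(speed_mult = 1 + severity * (spec$spatio[["speed_mult"]] - 1),
                 cadence_mult = 1 + severity * (spec$spatio[["cadence_mult"]] - 1))
  tp
}

# smooth periodic cycle-level noise: white noise on a coarse control grid,
# periodic spline onto the epoch grid, rescaled to the requested SD
smooth_noise <- function(sd, n_ctrl = 10) {
  if (sd <= 0) return(rep(0, N_EPOCHS))
  ctrl_t <- seq(0, 100, length.out = n_ctrl + 1)[-(n_ctrl + 1)]
  ctrl_v <- stats::rnorm(n_ctrl)
  f <- stats::splinefun(c(ctrl_t, 100), c(ctrl_v, ctrl_v[1]), method = "periodic")
  v <- f(epoch_grid())
  v * sd / max(stats::sd(v), 1e-9)
}

#' Configuration of a synthetic gait cohort
#'
#' Defaults emulate the structure of a pediatric HSP gait-lab cohort:
#' 26 patients plus 33 healthy controls, up to five selected cycles per
#' limb, a pattern mixture dominated by the two mildest patterns, 65.4%
#' of patients using a single pattern (27% a different pattern per limb,
#' 7.7% two patterns in one limb), subject-level random curve offsets
#' (SD 2 degrees per channel), smooth within-cycle noise (SD 1.5 degrees)
#' and clinical features statistically coupled to pattern membership
#' (older subjects in patterns III-V, youngest in VI; stage II-III,
#' polyneuropathy, abnormal VEP and thin corpus callosum most frequent in
#' the severe patterns). One extreme stretched-stance outlier cycle is
#' planted to exercise singleton handling.
#'
#' @param n_subjects number of patient subjects (default 26).
#' @param n_healthy number of healthy subjects (default 33).
#' @param pattern_mixture probability of each pattern 1..6 as a subject's
#'   primary pattern; must sum to 1.
#' @param usage_mixture probabilities of the three per-subject usage
#'   classes (single pattern; different pattern per limb; two patterns in
#'   one limb).
#' @param cycles_per_limb integer range of selected cycles per limb.
#' @param subject_sd SD (degrees) of the subject-level random intercept
#'   per channel.
#' @param cycle_sd SD (degrees) of the smooth cycle-level noise.
#' @param event_sd SD (% of cycle) of the event-timing jitter.
#' @param plant_outlier plant the stretched-stance outlier cycle.
#' @param clinical_coupling per-pattern clinical probabilities and age
#'   means; see the default for the expected shape.
#' @param seed integer seed; the whole cohort is reproducible from
#'   (config, seed).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 26, n_healthy = 33,
                          pattern_mixture = c(0.42, 0.22, 0.11, 0.11, 0.07, 0.07),
                          usage_mixture = c(0.654, 0.27, 0.077),
                          cycles_per_limb = 3:5,
                          subject_sd = 2, cycle_sd = 1.5, event_sd = 0.8,
                          plant_outlier = TRUE,
                          clinical_coupling = NULL, seed = 1L) {
  if (abs(sum(pattern_mixture) - 1) > 1e-8)
    stop("pattern_mixture must sum to 1")
  if (any(pattern_mixture < 0) || any(usage_mixture < 0))
    stop("mixture probabilities must be non-negative")
  if (is.null(clinical_coupling))
    clinical_coupling <- list(
      age_mean = c(7.5, 7.5, 11.5, 11.5, 14, 4.5), age_sd = 1.8,
      p_gmfcs23 = c(0.10, 0.85, 0.80, 0.90, 0.80, 0.90),
      p_gmfcs3_given_23 = 0.25,
      p_polyneuropathy = c(0.35, 0.35, 0.65, 0.10, 0.50, 0.30),
      p_abnormal_vep = c(0.20, 0.20, 0.60, 0.05, 0.05, 0.20),
      p_thin_cc = c(0.15, 0.45, 0.65, 0.15, 0.15, 0.15),
      severity_mean_gmfcs1 = 0.9, severity_mean_gmfcs23 = 1.15,
      severity_sd = 0.06)
  structure(list(n_subjects = n_subjects, n_healthy = n_healthy,
                 pattern_mixture = pattern_mixture / sum(pattern_mixture),
                 usage_mixture = usage_mixture / sum(usage_mixture),
                 cycles_per_limb = cycles_per_limb,
                 subject_sd = subject_sd, cycle_sd = cycle_sd,
                 event_sd = event_sd, plant_outlier = plant_outlier,
                 clinical_coupling = clinical_coupling,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# synthesize one gait cycle from perturbed template parameters plus the
# subject's random effects (curve offsets, event shift, pace multipliers)
synth_cycle <- function(tp, cycle_id, subject_id, side, age, height,
                        subj, cycle_sd, event_sd) {
  chans <- names(tp$channels)
  angles <- vapply(chans, function(ch)
    eval_channel(tp$channels[[ch]]) + subj$offsets[[ch]] +
      smooth_noise(cycle_sd), numeric(N_EPOCHS))
  colnames(angles) <- chans
  ev <- tp$events + subj$ev_shift * c(0.3, 0.8, 1) +
    stats::rnorm(3, 0, event_sd)
  ev <- pmin(pmax(ev, c(3, 30, 45)), c(25, 58, 88))
  ev <- sort(ev)
  cadence <- max(0.8, (2.45 - 0.046 * age) * tp$spatio[["cadence_mult"]] *
                   subj$cad_mult * exp(stats::rnorm(1, 0, 0.03)))
  stride_time <- 2 / cadence
  norm_speed <- max(0.2, (1.42 - 0.05 * age) * tp$spatio[["speed_mult"]] *
                      subj$speed_mult + stats::rnorm(1, 0, 0.05))
  gait_cycle(cycle_id = cycle_id, subject_id = subject_id, side = side,
             angles = angles,
             events = gait_events(ev[1], ev[2], ev[3]),
             stride_time = stride_time,
             stride_length = norm_speed * height * stride_time,
             subject_height = height)
}

#' Generate a synthetic gait cohort with known ground truth
#'
#' Draws per-subject pattern usage from the configured mixtures, clinical
#' features from the per-pattern coupling table (with a subject severity
#' scalar that is higher in functional stages II-III), and synthesizes
#' cycles as the pattern-perturbed template plus subject random offsets
#' and smooth cycle noise. Healthy subjects are the unperturbed template
#' with the same noise model. Ground-truth labels (pattern per cycle, 0
#' for the planted outlier, NA for healthy cycles; usage class per
#' subject) are returned alongside.
#'
#' @param config a [cohort_config()].
#' @return List with `cycles`, `records`, `labels` (data frame:
#'   `cycle_id`, `subject_id`, `side`, `condition`, `pattern`,
#'   `severity`), `usage` (data frame: `subject_id`, `usage_class`) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  pick1 <- function(x) x[sample.int(length(x), 1)]
  template <- healthy_template()
  cc <- config$clinical_coupling
  cycles <- list(); records <- list(); labels <- list(); usage <- list()
  draw_subject <- function(subject_id, condition, pattern_by_limb, sev) {
    age <- if (condition == "HSP") {
      p1 <- pattern_by_limb$left[1]
      min(17, max(4, stats::rnorm(1, cc$age_mean[p1], cc$age_sd)))
    } else stats::runif(1, 4, 16)
    height <- 0.92 + 0.052 * age + stats::rnorm(1, 0, 0.03)
    offsets <- stats::setNames(stats::rnorm(length(gait_channels()), 0,
                                            config$subject_sd),
                               gait_channels())
    list(age = age, height = height, offsets = offsets, severity = sev,
         ev_shift = stats::rnorm(1, 0, 1.2),
         cad_mult = exp(stats::rnorm(1, 0, 0.04)),
         speed_mult = exp(stats::rnorm(1, 0, 0.06)))
  }
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("P%02d", s)
    cls <- sample(c("single pattern", "different pattern per limb",
                    "two patterns in one limb"), 1,
                  prob = config$usage_mixture)
    p_main <- sample(1:6, 1, prob = config$pattern_mixture)
    p_alt <- if (cls == "single pattern") p_main else {
      others <- setdiff(1:6, p_main)
      probs <- config$pattern_mixture[others]
      if (sum(probs) == 0) probs <- rep(1, length(others))
      sample(others, 1, prob = probs)
    }
    pattern_by_limb <- switch(cls,
      "single pattern" = list(left = p_main, right = p_main),
      "different pattern per limb" = list(left = p_main, right = p_alt),
      "two patterns in one limb" = list(left = c(p_main, p_alt), right = p_main))
    gmfcs23 <- stats::runif(1) < cc$p_gmfcs23[p_main]
    gmfcs <- if (!gmfcs23) "I" else
      if (stats::runif(1) < cc$p_gmfcs3_given_23) "III" else "II"
    sev <- max(0.4, stats::rnorm(1, if (gmfcs23) cc$severity_mean_gmfcs23
                                 else cc$severity_mean_gmfcs1,
                                 cc$severity_sd))
    subj <- draw_subject(sid, "HSP", pattern_by_limb, sev)
    records[[sid]] <- clinical_record(
      subject_id = sid, age = subj$age,
      sex = sample(c("female", "male"), 1, prob = c(11, 15)),
      gmfcs = gmfcs,
      polyneuropathy = ifelse(stats::runif(1) < cc$p_polyneuropathy[p_main], "yes", "no"),
      abnormal_vep = ifelse(stats::runif(1) < cc$p_abnormal_vep[p_main], "yes", "no"),
      thin_corpus_callosum = ifelse(stats::runif(1) < cc$p_thin_cc[p_main], "yes", "no"),
      condition = "HSP")
    usage[[sid]] <- cls
    for (side in c("left", "right")) {
      pats <- pattern_by_limb[[side]]
      n_cyc <- pick1(config$cycles_per_limb)
      limb_pats <- if (length(pats) == 1) rep(pats, n_cyc) else
        pats[1 + (seq_len(n_cyc) %% 2)]
      for (i in seq_len(n_cyc)) {
        cid <- sprintf("%s_%s_%02d", sid, substr(side, 1, 1), i)
        tp <- apply_pattern(template, limb_pats[i], severity = subj$severity)
        cyc <- synth_cycle(tp, cid, sid, side, subj$age, subj$height,
                           subj, config$cycle_sd, config$event_sd)
        cycles[[cid]] <- cyc
        labels[[cid]] <- data.frame(cycle_id = cid, subject_id = sid,
                                    side = side, condition = "HSP",
                                    pattern = limb_pats[i],
                                    severity = subj$severity)
      }
    }
  }
  if (config$plant_outlier) {
    sid <- sprintf("P%02d", config$n_subjects)
    subj_age <- records[[sid]]$age
    tp <- apply_pattern(template, 5, severity = 1.6)
    tp$events <- c(opposite_toe_off = 22, opposite_initial_contact = 65,
                   toe_off = 82)
    tp$channels$pelvic_tilt$offset <- tp$channels$pelvic_tilt$offset + 8
    tp$spatio[["speed_mult"]] <- 0.4
    cid <- sprintf("%s_l_out", sid)
    out_subj <- list(offsets = stats::setNames(rep(0, length(gait_channels())),
                                               gait_channels()),
                     ev_shift = 0, cad_mult = 1, speed_mult = 1)
    cycles[[cid]] <- synth_cycle(tp, cid, sid, "left", subj_age,
                                 0.92 + 0.052 * subj_age, out_subj,
                                 config$cycle_sd, config$event_sd)
    labels[[cid]] <- data.frame(cycle_id = cid, subject_id = sid,
                                side = "left", condition = "HSP",
                                pattern = 0, severity = 1.6)
  }
  for (s in seq_len(config$n_healthy)) {
    sid <- sprintf("H%02d", s)
    subj <- draw_subject(sid, "healthy", NULL, 0)
    records[[sid]] <- clinical_record(
      subject_id = sid, age = subj$age,
      sex = sample(c("female", "male"), 1, prob = c(10, 23)),
      condition = "healthy")
    for (side in c("left", "right")) {
      n_cyc <- pick1(config$cycles_per_limb)
      for (i in seq_len(n_cyc)) {
        cid <- sprintf("%s_%s_%02d", sid, substr(side, 1, 1), i)
        cycles[[cid]] <- synth_cycle(template, cid, sid, side, subj$age,
                                     subj$height, subj,
                                     config$cycle_sd, config$event_sd)
        labels[[cid]] <- data.frame(cycle_id = cid, subject_id = sid,
                                    side = side, condition = "healthy",
                                    pattern = NA_integer_, severity = 0)
      }
    }
  }
  label_df <- do.call(rbind, labels)
  rownames(label_df) <- NULL
  list(cycles = unname(cycles), records = unname(records),
       labels = label_df,
       usage = data.frame(subject_id = names(usage),
                          usage_class = unlist(usage), row.names = NULL),
       config = config)
}
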