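# Independent oracles and small fixture builders used across the suite.

# Exhaustive DTW by enumerating every admissible warping path over the
# (n x m) local-cost grid with steps (1,1), (1,0), (0,1); the diagonal
# step carries weight `wdiag` and the first cell carries weight `wdiag`.
# Only usable for tiny series (path count grows like the Delannoy numbers).
enum_dtw <- function(a, b, wdiag = 2, normalize = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  d <- outer(seq_len(n), seq_len(m),
             Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
  best <- Inf
  walk <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n && j < m) walk(i + 1, j + 1, acc + wdiag * d[i + 1, j + 1])
    if (i < n) walk(i + 1, j, acc + d[i + 1, j])
    if (j < m) walk(i, j + 1, acc + d[i, j + 1])
  }
  walk(1, 1, wdiag * d[1, 1])
  if (normalize) best / (n + m) else best
}

# Naive O(n^3) average-linkage clustering: returns merge heights in order.
naive_average_linkage_heights <- function(dm) {
  dm <- as.matrix(dm)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- mean(dm[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Mann-Whitney rank form of the AUC.
rank_auc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Minimal synthetic gait cycle with chosen channel values (constant or
# given 201-vectors); remaining sagittal channels constant 0.
toy_cycle <- function(cycle_id = "c1", subject_id = "s1", side = "left",
                      channels = list(), events = gait_events(10, 50, 60),
                      stride_time = 1, stride_length = 1.2,
                      subject_height = 1.5, all_channels = FALSE) {
  base <- if (all_channels) gait_channels() else sagittal_channels()
  ang <- matrix(0, nrow = 201, ncol = length(base),
                dimnames = list(NULL, base))
  for (ch in names(channels)) {
    v <- channels[[ch]]
    ang[, ch] <- if (length(v) == 1) rep(v, 201) else v
  }
  gait_cycle(cycle_id, subject_id, side, ang, events,
             stride_time, stride_length, subject_height)
}

# Small planted-cluster cohort: `k` groups of cycles separated by large
# per-channel offsets, with mild within-group noise.
planted_cohort <- function(n_per = 5, k = 3, sep = 25, noise = 1,
                           seed = 1) {
  set.seed(seed)
  cycles <- list(); truth <- integer(0)
  for (g in seq_len(k)) for (i in seq_len(n_per)) {
    id <- sprintf("g%d_%d", g, i)
    vals <- lapply(stats::setNames(sagittal_channels(), sagittal_channels()),
                   function(ch) g * sep + stats::rnorm(201, 0, noise))
    cycles[[id]] <- toy_cycle(id, subject_id = sprintf("s%d", g),
                              channels = vals)
    truth <- c(truth, g)
  }
  list(cycles = unname(cycles), truth = truth)
}

# Evaluate one template channel on the grid (internal synthesis primitive).
eval_channel_for_test <- function(tp, ch)
  gaitpatterns:::eval_channel(tp$channels[[ch]])

# Noise-free parameter vector of a (possibly pattern-perturbed) template,
# synthesized at a reference age of 8 years.
param_vector_for_test <- function(tp, age = 8, height = 1.33) {
  chans <- names(tp$channels)
  ang <- vapply(chans, function(ch) eval_channel_for_test(tp, ch),
                numeric(201))
  colnames(ang) <- chans
  cadence <- (2.45 - 0.046 * age) * tp$spatio[["cadence_mult"]]
  stride_time <- 2 / cadence
  norm_speed <- (1.42 - 0.05 * age) * tp$spatio[["speed_mult"]]
  cyc <- gait_cycle("tpl", "tpl", "left", ang,
                    gait_events(tp$events[["opposite_toe_off"]],
                                tp$events[["opposite_initial_contact"]],
                                tp$events[["toe_off"]]),
                    stride_time, norm_speed * height * stride_time, height)
  c(extract_spatiotemporal(cyc), extract_kinematic(cyc))
}
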