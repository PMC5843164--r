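#' Multivariate DTW dissimilarity between two gait cycles
#'
#' Dynamic time warping over the requested channels, with local cost
#' d(i, j) equal to the Euclidean norm of the difference between the
#' channel vectors of the two cycles at epochs i and j. The default step
#' pattern is the symmetric pattern with weight 2 on the diagonal (the
#' common default of the reference DTW formulation), whose cumulative cost
#' admits normalization by n + m so that distances are comparable across
#' pairs; the symmetric weight-1 pattern and unnormalized costs are
#' available as options. No warping-window constraint is applied: all
#' cycles share the 201-epoch grid, so the full dynamic program is cheap.
#'
#' @param a,b [gait_cycle()] objects (or bare numeric matrices with
#'   matching channel columns).
#' @param channels channels to include; default the five sagittal channels.
#' @param step `"symmetric2"` (diagonal weight 2, default) or
#'   `"symmetric1"`.
#' @param normalize divide the cumulative cost by n + m (default `TRUE`).
#' @param scale z-score each channel across both series before warping
#'   (default `FALSE`; all channels share units of degrees).
#' @return Non-negative dissimilarity, symmetric in (a, b).
#' @export
dtw_distance <- function(a, b, channels = sagittal_channels(),
                         step = c("symmetric2", "symmetric1"),
                         normalize = TRUE, scale = FALSE) {
  step <- match.arg(step)
  ma <- channel_matrix(a, channels)
  mb <- channel_matrix(b, channels)
  if (scale) {
    for (ch in seq_along(channels)) {
      v <- c(ma[, ch], mb[, ch])
      mu <- mean(v); sd <- stats::sd(v)
      if (sd > 0) { ma[, ch] <- (ma[, ch] - mu) / sd; mb[, ch] <- (mb[, ch] - mu) / sd }
    }
  }
  cost <- dtw_cost_cpp(ma, mb, step == "symmetric2")
  if (normalize) cost / (nrow(ma) + nrow(mb)) else cost
}

channel_matrix <- function(x, channels) {
  m <- if (inherits(x, "gait_cycle")) x$angles else as.matrix(x)
  missing_ch <- setdiff(channels, colnames(m))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  m[, channels, drop = FALSE]
}

#' Pairwise DTW distance matrix of a cohort
#'
#' Computes [dtw_distance()] for every unordered pair once (symmetry is
#' structural) via the compiled all-pairs kernel.
#'
#' @inheritParams dtw_distance
#' @param cycles list of at least two [gait_cycle()] objects.
#' @return Symmetric n x n matrix with zero diagonal; dimnames are cycle
#'   ids.
#' @export
dtw_distance_matrix <- function(cycles, channels = sagittal_channels(),
                                step = c("symmetric2", "symmetric1"),
                                normalize = TRUE, scale = FALSE) {
  step <- match.arg(step)
  if (length(cycles) < 2) stop("need at least 2 cycles")
  mats <- lapply(cycles, channel_matrix, channels = channels)
  if (scale) {
    for (ch in seq_along(channels)) {
      v <- unlist(lapply(mats, function(m) m[, ch]))
      mu <- mean(v); sd <- stats::sd(v)
      if (sd > 0) mats <- lapply(mats, function(m) { m[, ch] <- (m[, ch] - mu) / sd; m })
    }
  }
  cube <- unlist(mats, use.names = FALSE)
  n_ep <- nrow(mats[[1]])
  dm <- dtw_pairwise_cpp(cube, n_ep, length(channels), length(mats),
                         step == "symmetric2")
  if (normalize) dm <- dm / (2 * n_ep)
  ids <- vapply(cycles, function(c)
    if (inherits(c, "gait_cycle")) c$cycle_id else "", character(1))
  if (all(nzchar(ids))) dimnames(dm) <- list(ids, ids)
  dm
}

#' Write a distance matrix as delimited text
#'
#' @param dm matrix from [dtw_distance_matrix()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(cycle_id = rownames(dm), dm, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
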