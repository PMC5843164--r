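#' Average-linkage hierarchical clustering of a distance matrix
#'
#' Unweighted average linkage (UPGMA on dissimilarities): the distance
#' between two clusters is the mean of all cross-pair dissimilarities.
#' Average linkage is monotone, so merge heights are non-decreasing.
#'
#' @param dm symmetric dissimilarity matrix with zero diagonal.
#' @return An [stats::hclust] tree.
#' @export
average_linkage <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 2) stop("need at least 2 observations")
  if (any(dm < 0) || any(abs(dm - t(dm)) > 1e-8) || any(diag(dm) != 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  stats::hclust(stats::as.dist(dm), method = "average")
}

#' Cut a dendrogram into k flat patterns
#'
#' Undoes the last k - 1 merges of the tree. Clusters are relabeled by
#' decreasing size (the largest cluster becomes pattern 1), with ties in
#' size broken by the height at which the cluster formed (lower first);
#' clusters of size 1 are flagged as outliers.
#'
#' @param hc an [stats::hclust] tree (e.g. from [average_linkage()]).
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return Data frame with columns `id`, `pattern` (integer 1..k) and
#'   `outlier` (logical).
#' @export
cut_dendrogram <- function(hc, k) {
  n <- length(hc$order)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n)
    stop("k must lie in [1, ", n, "]")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  # precompute leaf contents of every internal merge node
  contents <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    contents[[i]] <- unlist(lapply(kids, function(kid)
      if (kid < 0) -kid else contents[[kid]]))
  }
  # height at which each flat cluster last merged internally (0 = singleton)
  cl_height <- vapply(names(sizes), function(cl) {
    members <- which(raw == as.integer(cl))
    if (length(members) == 1) return(0)
    h <- 0
    for (i in seq_len(nrow(hc$merge)))
      if (all(contents[[i]] %in% members)) h <- max(h, hc$height[i])
    h
  }, numeric(1))
  ord <- order(-as.integer(sizes), cl_height)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  pattern <- relabel[raw]
  new_sizes <- table(pattern)
  ids <- if (!is.null(hc$labels)) hc$labels else as.character(seq_len(n))
  data.frame(id = ids, pattern = pattern,
             outlier = as.integer(new_sizes[as.character(pattern)]) == 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit sagittal gait patterns to a cohort of cycles
#'
#' The core classification step: pairwise multivariate DTW dissimilarities
#' over the five sagittal channels, average-linkage hierarchical
#' clustering, and an explicit k-cut of the dendrogram into flat patterns.
#' The default k = 7 corresponds to six patterns plus one outlier group in
#' a cohort of the size and heterogeneity this method was designed for;
#' the cut is a parameter because the number of interpretable groups is a
#' judgement the dendrogram supports but does not dictate.
#'
#' @param cycles list of [gait_cycle()] objects.
#' @param k number of flat clusters to cut (default 7).
#' @param channels channels entering the DTW cost (default sagittal five).
#' @param dm optional precomputed distance matrix (skips the DTW step).
#' @param ... further options passed to [dtw_distance_matrix()].
#' @return Object of class `gait_patterns` with components `distance`
#'   (matrix), `tree` ([stats::hclust]), `assignment` (data frame:
#'   `cycle_id`, `subject_id`, `side`, `pattern`, `outlier`), `k`, and
#'   `summary` (see [pattern_summary()]).
#' @export
gait_patterns <- function(cycles, k = 7, channels = sagittal_channels(),
                          dm = NULL, ...) {
  if (is.null(dm)) dm <- dtw_distance_matrix(cycles, channels = channels, ...)
  hc <- average_linkage(dm)
  cut <- cut_dendrogram(hc, k)
  meta <- data.frame(
    cycle_id = vapply(cycles, function(c) c$cycle_id, character(1)),
    subject_id = vapply(cycles, function(c) c$subject_id, character(1)),
    side = vapply(cycles, function(c) c$side, character(1)),
    stringsAsFactors = FALSE)
  assignment <- merge(meta, cut, by.x = "cycle_id", by.y = "id", sort = FALSE)
  assignment <- assignment[match(meta$cycle_id, assignment$cycle_id), ]
  rownames(assignment) <- NULL
  structure(list(distance = dm, tree = hc, assignment = assignment, k = k,
                 channels = channels,
                 summary = pattern_summary(assignment)),
            class = "gait_patterns")
}

#' Per-pattern and per-subject summary of a pattern assignment
#'
#' Cluster sizes and fractions, and the per-subject pattern-usage class:
#' `"single pattern"` (all of the subject's cycles share one pattern),
#' `"different pattern per limb"` (each limb uses one pattern but the limbs
#' differ), or `"two patterns in one limb"` (some limb mixes patterns).
#'
#' @param assignment data frame with columns `cycle_id`, `subject_id`,
#'   `side`, `pattern`, `outlier`.
#' @return List with `patterns` (data frame: pattern, size, fraction,
#'   outlier) and `subjects` (data frame: subject_id, usage_class).
#' @export
pattern_summary <- function(assignment) {
  tab <- table(assignment$pattern)
  patterns <- data.frame(pattern = as.integer(names(tab)),
                         size = as.integer(tab),
                         fraction = as.numeric(tab) / nrow(assignment))
  patterns$outlier <- patterns$size == 1
  usage <- vapply(split(assignment, assignment$subject_id), function(sub) {
    per_limb <- lapply(split(sub$pattern, sub$side), unique)
    if (any(vapply(per_limb, length, integer(1)) > 1))
      return("two patterns in one limb")
    if (length(unique(sub$pattern)) > 1) return("different pattern per limb")
    "single pattern"
  }, character(1))
  list(patterns = patterns,
       subjects = data.frame(subject_id = names(usage), usage_class = usage,
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' @export
print.gait_patterns <- function(x, ...) {
  p <- x$summary$patterns
  cat(sprintf("Gait pattern classification: %d cycles, k = %d cut\n",
              nrow(x$assignment), x$k))
  cat(sprintf("  %d multi-cycle pattern(s), %d outlier cycle(s)\n",
              sum(!p$outlier), sum(p$outlier)))
  for (i in seq_len(nrow(p)))
    cat(sprintf("  pattern %d: %d cycles (%.1f%%)%s\n", p$pattern[i],
                p$size[i], 100 * p$fraction[i],
                if (p$outlier[i]) " [outlier]" else ""))
  invisible(x)
}

#' @export
summary.gait_patterns <- function(object, ...) {
  print(object)
  usage <- table(object$summary$subjects$usage_class)
  cat("Per-subject pattern usage:\n")
  for (cls in names(usage))
    cat(sprintf("  %s: %d (%.1f%%)\n", cls, usage[[cls]],
                100 * usage[[cls]] / sum(usage)))
  invisible(object$summary)
}

#' @export
plot.gait_patterns <- function(x, ...) {
  plot(x$tree, labels = FALSE, hang = -1,
       main = "Average-linkage dendrogram of DTW distances",
       xlab = "gait cycles", sub = "", ...)
  stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}

#' Pattern labels of a fitted classification
#'
#' @param pat a [gait_patterns()] fit.
#' @return Integer vector of pattern labels named by cycle id.
#' @export
pattern_labels <- function(pat) {
  stats::setNames(pat$assignment$pattern, pat$assignment$cycle_id)
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via the standard ultrametric
#' conversion of the tree.
#'
#' @param hc an [stats::hclust] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a pattern assignment as delimited text
#'
#' @param assignment assignment data frame from a [gait_patterns()] fit.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.csv(assignment, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions up to relabeling, 0 is the expected value
#' under independent random partitions.
#'
#' @param x,y label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("partitions must have equal length")
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(x), 2)
  expected <- b * c / n2
  denom <- (b + c) / 2 - expected
  if (denom == 0) return(1)
  (a - expected) / denom
}
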