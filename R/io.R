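#' Write a cohort in the plain-text exchange format
#'
#' The exchange format is one long-format CSV per cycle
#' (`cycles/<cycle_id>.csv` with columns `epoch_pct, channel, degrees`),
#' a JSON sidecar per cycle (`cycles/<cycle_id>.json` carrying identity,
#' events and stride metadata), and a single `clinical.csv` table for the
#' cohort with the clinical-record fields (unknowns written as empty
#' strings). Angles are written with 4 decimal places; a write/read round
#' trip is exact at that precision.
#'
#' @param cycles list of [gait_cycle()] objects.
#' @param records list of [clinical_record()] objects.
#' @param path output directory (created if needed).
#' @param labels optional data frame of ground-truth labels (e.g. from the
#'   synthetic generator) written as `labels.csv`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cycles, records, path, labels = NULL) {
  cyc_dir <- file.path(path, "cycles")
  dir.create(cyc_dir, recursive = TRUE, showWarnings = FALSE)
  for (cyc in cycles) {
    a <- round(cyc$angles, 4)
    long <- data.frame(
      epoch_pct = rep(epoch_grid(), times = ncol(a)),
      channel = rep(colnames(a), each = nrow(a)),
      degrees = as.vector(a))
    utils::write.csv(long, file.path(cyc_dir, paste0(cyc$cycle_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
    meta <- list(cycle_id = cyc$cycle_id, subject_id = cyc$subject_id,
                 side = cyc$side,
                 events = unclass(cyc$events),
                 stride_time_s = cyc$stride_time,
                 stride_length_m = cyc$stride_length,
                 subject_height_m = cyc$subject_height)
    jsonlite::write_json(meta, file.path(cyc_dir, paste0(cyc$cycle_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  clin <- do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$subject_id, age = r$age, sex = r$sex,
               gmfcs = r$gmfcs,
               polyneuropathy = ifelse(r$polyneuropathy == "unknown", "", r$polyneuropathy),
               abnormal_vep = ifelse(r$abnormal_vep == "unknown", "", r$abnormal_vep),
               thin_corpus_callosum = ifelse(r$thin_corpus_callosum == "unknown", "", r$thin_corpus_callosum),
               condition = r$condition)))
  utils::write.csv(clin, file.path(path, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(labels))
    utils::write.csv(labels, file.path(path, "labels.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from the exchange format
#'
#' Reads every cycle under `<path>/cycles/`, validates it against the
#' gait-cycle invariants, and reads the cohort clinical table. Cycles that
#' fail validation are rejected; by default any rejection is an error with
#' a per-file report.
#'
#' @param path cohort directory as written by [write_cohort()].
#' @param on_invalid `"error"` (default) or `"skip"`: whether invalid cycle
#'   files abort the read or are dropped with a warning naming each file
#'   and rule.
#' @return List with elements `cycles` (list of `gait_cycle`), `records`
#'   (list of `clinical_record`) and `rejected` (character vector of
#'   per-file failure reports).
#' @export
read_cohort <- function(path, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  cyc_dir <- file.path(path, "cycles")
  if (!dir.exists(cyc_dir)) stop("no 'cycles' directory under ", path)
  files <- sort(list.files(cyc_dir, pattern = "\\.csv$", full.names = TRUE))
  cycles <- list(); rejected <- character()
  for (f in files) {
    res <- tryCatch(read_cycle_file(f), error = function(e)
      structure(conditionMessage(e), class = "try-error"))
    if (inherits(res, "try-error")) {
      rejected <- c(rejected, paste0(basename(f), ": ", unclass(res)))
    } else cycles[[res$cycle_id]] <- res
  }
  if (length(rejected) && on_invalid == "error")
    stop("invalid cycle file(s):\n  ", paste(rejected, collapse = "\n  "))
  if (length(rejected)) warning("skipped invalid cycle file(s):\n  ",
                                paste(rejected, collapse = "\n  "))
  records <- read_clinical_table(file.path(path, "clinical.csv"))
  known <- vapply(records, function(r) r$subject_id, character(1))
  orphans <- setdiff(vapply(cycles, function(c) c$subject_id, character(1)), known)
  if (length(orphans))
    stop("cycle subject id(s) missing from clinical table: ",
         paste(orphans, collapse = ", "))
  list(cycles = unname(cycles), records = records, rejected = rejected)
}

read_cycle_file <- function(csv_path) {
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(json_path))
    stop("missing JSON sidecar ", basename(json_path))
  long <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("epoch_pct", "channel", "degrees")
  if (!all(need %in% names(long)))
    stop("expected columns epoch_pct, channel, degrees")
  chans <- unique(long$channel)
  n_per <- table(long$channel)
  if (any(n_per != N_EPOCHS))
    stop(sprintf("expected 201 epochs per channel, got %d for '%s'",
                 min(n_per), names(n_per)[which.min(n_per)]))
  angles <- vapply(chans, function(ch) {
    sub <- long[long$channel == ch, ]
    sub$degrees[order(sub$epoch_pct)]
  }, numeric(N_EPOCHS))
  colnames(angles) <- chans
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  gait_cycle(cycle_id = meta$cycle_id, subject_id = meta$subject_id,
             side = meta$side, angles = angles,
             events = gait_events(meta$events$opposite_toe_off,
                                  meta$events$opposite_initial_contact,
                                  meta$events$toe_off),
             stride_time = meta$stride_time_s,
             stride_length = meta$stride_length_m,
             subject_height = meta$subject_height_m)
}

read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("missing clinical table ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    flag <- function(x) if (is.na(x) || x == "") "unknown" else x
    clinical_record(subject_id = row$subject_id, age = as.numeric(row$age),
                    sex = row$sex, gmfcs = row$gmfcs,
                    polyneuropathy = flag(row$polyneuropathy),
                    abnormal_vep = flag(row$abnormal_vep),
                    thin_corpus_callosum = flag(row$thin_corpus_callosum),
                    condition = row$condition)
  })
}

# clinical records as a data frame keyed by subject_id
clinical_frame <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$subject_id, age = r$age, sex = r$sex,
               gmfcs = r$gmfcs, polyneuropathy = r$polyneuropathy,
               abnormal_vep = r$abnormal_vep,
               thin_corpus_callosum = r$thin_corpus_callosum,
               condition = r$condition, stringsAsFactors = FALSE)))
}
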