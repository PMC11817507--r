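# Cohort assembly: per-segment records, the calcification-based exclusion
# rule for baseline GCA segments, and the patient-wise train/test split.
#
# The exclusion rule mirrors pre-selection of the training data: baseline
# GCA segments whose vessel wall is heavily calcified (visual score 3 or 4,
# i.e. more than a quarter of the wall) are removed so that
# atherosclerosis-like uptake does not contaminate the GCA class. Follow-up
# scans are never filtered - they must reflect the clinical situation.

#' Build a per-segment record table from a cohort
#'
#' One row per (patient, segment) with identity, group, calcification score
#' and scan type. Feature columns are appended later by
#' [extract_cohort_features()].
#'
#' @param cohort A list of patients from [generate_cohort()], or follow-up
#'   scans from [generate_followup_scan()] (pass `scan_type = "followup"`).
#' @param scan_type "baseline" or "followup".
#' @return A data frame with columns `patient_id`, `scan_id`, `segment`,
#'   `group`, `calc_score`, `scan_type`.
#' @export
segment_records <- function(cohort, scan_type = c("baseline", "followup")) {
  scan_type <- match.arg(scan_type)
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$meta$patient_id,
               scan_id = paste0(p$meta$patient_id, "_",
                                substr(scan_type, 1, 2)),
               segment = SEGMENT_LEVELS,
               group = p$meta$group,
               calc_score = as.integer(unname(p$calc_scores)),
               scan_type = scan_type,
               stringsAsFactors = FALSE)
  }))
}

#' Exclude heavily calcified baseline GCA segments
#'
#' Retains records with `calc_score <= max_score`. The rule applies only to
#' baseline GCA records: atherosclerosis records and follow-up scans (rows
#' with `scan_type == "followup"`) always pass through untouched. The
#' filter is idempotent and preserves row order.
#'
#' @param records A segment record data frame with a `calc_score` column.
#' @param max_score Highest retained score (default 2, i.e. scores 3 and 4
#'   are excluded).
#' @return The filtered data frame.
#' @export
filter_calcified <- function(records, max_score = 2L) {
  stopifnot(is.data.frame(records), "calc_score" %in% names(records))
  subject <- rep(TRUE, nrow(records))
  if ("group" %in% names(records)) subject <- records$group == "GCA"
  if ("scan_type" %in% names(records)) {
    subject <- subject & records$scan_type != "followup"
  }
  keep <- !subject | records$calc_score <= max_score
  records[keep, , drop = FALSE]
}

#' Patient-wise, group-stratified train/test split
#'
#' All segments of a patient land on the same side of the split; the number
#' of test patients per group is the rounded fraction of that group's
#' patients (at least one). Reproducible from `seed`.
#'
#' @param records Segment record data frame with `patient_id` and `group`.
#' @param test_fraction Target fraction of patients in the test set,
#'   strictly inside (0, 1).
#' @param seed Integer seed.
#' @return A `split_assignment` list with `train_patient_ids`,
#'   `test_patient_ids`, `fraction` and `seed`.
#' @export
split_patientwise <- function(records, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop_petvasc("test_fraction must lie strictly between 0 and 1",
                 class = "petvasc_validation_error")
  }
  pat <- unique(records[, c("patient_id", "group")])
  counts <- table(pat$group)
  if (any(counts < 2)) {
    stop_petvasc("each group needs at least 2 patients for a stratified split",
                 class = "petvasc_validation_error")
  }
  test_ids <- with_seed(seed, {
    unlist(lapply(names(counts), function(g) {
      ids <- pat$patient_id[pat$group == g]
      n_test <- max(1L, round(test_fraction * length(ids)))
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  structure(list(
    train_patient_ids = sort(setdiff(pat$patient_id, test_ids)),
    test_patient_ids = sort(test_ids),
    fraction = test_fraction, seed = as.integer(seed)
  ), class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d train / %d test patients (target %.0f%% test, seed %d)\n",
              length(x$train_patient_ids), length(x$test_patient_ids),
              100 * x$fraction, x$seed))
  invisible(x)
}

#' Write / read a split assignment as JSON
#'
#' The JSON copy includes the seed so a split can be audited and re-drawn.
#'
#' @param split A `split_assignment`.
#' @param path JSON file path.
#' @return `path` (write) or the `split_assignment` (read).
#' @export
write_split_assignment <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_assignment
#' @export
read_split_assignment <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_patient_ids = as.character(x$train_patient_ids),
                 test_patient_ids = as.character(x$test_patient_ids),
                 fraction = x$fraction, seed = as.integer(x$seed)),
            class = "split_assignment")
}

#' Simulate a metadata-only segment record table
#'
#' A fast fixture generator for cohort-level logic: it reproduces the
#' record structure of [generate_cohort()] (patients, segments, groups,
#' calcification scores with exactly `n_calcified_gca_segments` GCA
#' segments scoring 3-4) without simulating any image data.
#'
#' @param n_gca,n_athero Patients per group.
#' @param n_calcified_gca_segments GCA segments flagged with score >= 3.
#' @param seed Integer seed.
#' @return A segment record data frame (no feature columns).
#' @export
simulate_segment_records <- function(n_gca, n_athero = 0,
                                     n_calcified_gca_segments = n_gca,
                                     seed = 1L) {
  stopifnot(n_calcified_gca_segments <= 4 * n_gca)
  with_seed(seed, {
    ids <- c(sprintf("GCA%03d", seq_len(n_gca)),
             sprintf("ATH%03d", seq_len(n_athero)))
    groups <- c(rep("GCA", n_gca), rep("ATHERO", n_athero))
    flagged <- sample(4L * n_gca, n_calcified_gca_segments)
    rows <- lapply(seq_along(ids), function(i) {
      calc <- if (groups[i] == "GCA") {
        slot <- (i - 1L) * 4L + 1:4
        ifelse(slot %in% flagged, sample(3:4, 4, replace = TRUE),
               sample(0:2, 4, replace = TRUE))
      } else sample(0:4, 4, replace = TRUE)
      data.frame(patient_id = ids[i], scan_id = paste0(ids[i], "_ba"),
                 segment = SEGMENT_LEVELS, group = groups[i],
                 calc_score = as.integer(calc), scan_type = "baseline",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
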