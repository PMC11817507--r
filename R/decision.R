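# Scan-level decision rules: max-segment aggregation, the Youden operating
# threshold, and diagnostic metrics with Wilson confidence intervals.

#' Aggregate segment probabilities to a scan-level probability
#'
#' The scan probability is the highest predicted probability among its
#' (one to four) segments: a scan is as suspicious as its most suspicious
#' segment.
#'
#' @param segment_probs Numeric vector of per-segment probabilities in
#'   `[0, 1]` (optionally named by segment).
#' @return The maximum, a single probability.
#' @examples
#' aggregate_scan(c(ascending = 0.45, descending = 0.75,
#'                  arch = 0.66, abdominal = 0.74))  # 0.75
#' @export
aggregate_scan <- function(segment_probs) {
  if (length(segment_probs) == 0) {
    stop_petvasc("no segment probabilities to aggregate",
                 class = "petvasc_validation_error")
  }
  if (any(!is.finite(segment_probs)) || any(segment_probs < 0) ||
      any(segment_probs > 1)) {
    stop_petvasc("segment probabilities must lie in [0, 1]",
                 class = "petvasc_validation_error")
  }
  max(segment_probs)
}

#' Youden-optimal probability threshold
#'
#' Maximises the (generalised) Youden index
#' `J = 2 * (w * sensitivity + (1 - w) * specificity) - 1` over candidate
#' thresholds: the midpoints between consecutive sorted unique
#' probabilities plus -Inf and +Inf. With the default weight `w = 0.5`
#' this is the classical `J = sensitivity + specificity - 1`. A scan is
#' called active when its probability is greater than or equal to the
#' threshold; ties in J are resolved towards the highest qualifying
#' threshold.
#'
#' @param scan_probs Numeric probabilities, one per scan.
#' @param labels Logical or factor/character labels; `TRUE`/"active" =
#'   positive.
#' @param weight Sensitivity weight `w` in the generalised index (default
#'   0.5).
#' @return The selected threshold.
#' @export
youden_cutoff <- function(scan_probs, labels, weight = 0.5) {
  y <- as_active_logical(labels)
  if (length(unique(y)) < 2) {
    stop_petvasc("both classes must be present to place a threshold",
                 class = "petvasc_validation_error")
  }
  stopifnot(length(scan_probs) == length(y))
  u <- sort(unique(scan_probs))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  j <- vapply(cand, function(th) {
    sens <- mean(scan_probs[y] >= th)
    spec <- mean(scan_probs[!y] < th)
    2 * (weight * sens + (1 - weight) * spec) - 1
  }, numeric(1))
  best <- max(j)
  max(cand[j >= best - 1e-12])   # ties resolved high
}

as_active_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- tolower(as.character(labels))
  if (!all(l %in% c("active", "inactive", "gca", "athero", "true", "false",
                    "1", "0"))) {
    stop_petvasc("labels must be logical or active/inactive (or GCA/ATHERO)",
                 class = "petvasc_validation_error")
  }
  l %in% c("active", "gca", "true", "1")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`; `c(NA, NA)` when `n == 0`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  pmin(pmax(c(centre - half, centre + half), 0), 1)
}

#' Diagnostic performance report
#'
#' Confusion counts plus PPV, NPV and accuracy, each with a 95% Wilson
#' score interval. Undefined proportions (e.g. PPV with no positive calls)
#' are reported as NA with NA intervals.
#'
#' @param calls Predicted labels (logical or active/inactive), or `NULL`
#'   when counts are given directly.
#' @param labels Reference labels, aligned with `calls`.
#' @param counts Optional named vector/list `c(tp =, fp =, fn =, tn =)`
#'   overriding `calls`/`labels`.
#' @param conf Confidence level for the intervals.
#' @return A `diagnostic_report` list with `tp`, `fp`, `fn`, `tn`, `ppv`,
#'   `npv`, `accuracy` and `*_ci` fields.
#' @export
diagnostic_report <- function(calls = NULL, labels = NULL, counts = NULL,
                              conf = 0.95) {
  if (is.null(counts)) {
    cl <- as_active_logical(calls)
    y <- as_active_logical(labels)
    stopifnot(length(cl) == length(y))
    counts <- c(tp = sum(cl & y), fp = sum(cl & !y),
                fn = sum(!cl & y), tn = sum(!cl & !y))
  }
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  prop <- function(x, m) if (m > 0) x / m else NA_real_
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    ppv = prop(tp, tp + fp), ppv_ci = wilson_ci(tp, tp + fp, conf),
    npv = prop(tn, tn + fn), npv_ci = wilson_ci(tn, tn + fn, conf),
    accuracy = prop(tp + tn, n), accuracy_ci = wilson_ci(tp + tn, n, conf),
    conf = conf
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  fmt <- function(v, ci) {
    if (is.na(v)) "NA" else
      sprintf("%.2f [%.2f-%.2f]", v, ci[1], ci[2])
  }
  cat(sprintf("<diagnostic_report> n = %d (tp %d, fp %d, fn %d, tn %d)\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  PPV %s  NPV %s  accuracy %s (Wilson %.0f%% CI)\n",
              fmt(x$ppv, x$ppv_ci), fmt(x$npv, x$npv_ci),
              fmt(x$accuracy, x$accuracy_ci), 100 * x$conf))
  invisible(x)
}

#' Build scan-level decisions from segment probabilities
#'
#' Groups a per-segment probability table by scan, aggregates with
#' [aggregate_scan()], and applies the threshold.
#'
#' @param records Data frame with `scan_id` and `segment` columns.
#' @param probs Per-segment probabilities aligned with `records`.
#' @param threshold Decision threshold: calls are "active" when the scan
#'   probability is >= threshold.
#' @return A data frame with one row per scan: `scan_id`, per-segment
#'   probabilities, `scan_prob` and `call`.
#' @export
scan_decisions <- function(records, probs, threshold) {
  stopifnot(nrow(records) == length(probs))
  out <- lapply(split(seq_len(nrow(records)), records$scan_id), function(ix) {
    sp <- stats::setNames(probs[ix], records$segment[ix])
    scan_prob <- aggregate_scan(sp)
    row <- as.list(stats::setNames(rep(NA_real_, 4), SEGMENT_LEVELS))
    row[names(sp)] <- sp
    c(list(scan_id = records$scan_id[ix][1]), row,
      list(scan_prob = scan_prob,
           call = if (scan_prob >= threshold) "active" else "inactive"))
  })
  df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}
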