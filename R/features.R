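# Public feature-extraction surface: the frozen 95-feature manifest,
# first-order statistics, per-segment extraction, cohort-level extraction
# and correlation-based pruning.

FOS_NAMES <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
               "Percentile10", "Percentile90", "Maximum", "Mean", "Median",
               "InterquartileRange", "Range", "MeanAbsoluteDeviation",
               "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
               "Kurtosis", "Variance", "Uniformity")

GLCM_NAMES <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy",
                "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1",
                "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
                "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
                "SumEntropy", "SumSquares")

NGTDM_NAMES <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength")

#' The frozen 95-feature manifest
#'
#' Feature names in their canonical order: 18 first-order (prefix `fos_`),
#' 24 co-occurrence (`glcm_`), 16 run-length (`glrlm_`), 16 size-zone
#' (`glszm_`), 5 neighbouring-grey-tone-difference (`ngtdm_`), 14
#' dependence (`gldm_`), then `SULmax` and `SULmean`. This order is stable
#' across runs and defines the canonical scan order for
#' [prune_correlated()].
#'
#' @return A character vector of length 95.
#' @export
feature_manifest <- function() {
  c(paste0("fos_", FOS_NAMES),
    paste0("glcm_", GLCM_NAMES),
    paste0("glrlm_", GLRLM_NAMES),
    paste0("glszm_", GLSZM_NAMES),
    paste0("ngtdm_", NGTDM_NAMES),
    paste0("gldm_", GLDM_NAMES),
    "SULmax", "SULmean")
}

#' Grey-level discretisation settings
#'
#' Texture matrices are computed on intensities discretised with a fixed
#' bin width anchored at the ROI minimum (the usual recommendation for PET,
#' where absolute SUL differences are meaningful). The default bin width of
#' 0.25 SUL gives roughly 6-16 levels on typical wall ROIs.
#'
#' @param bin_width Bin width in SUL units (> 0).
#' @param min_roi_voxels Smallest ROI accepted for extraction.
#' @return A `discretisation_settings` list.
#' @export
discretisation_settings <- function(bin_width = 0.25, min_roi_voxels = 10L) {
  assert_positive(bin_width, "bin_width")
  structure(list(bin_width = bin_width,
                 min_roi_voxels = as.integer(min_roi_voxels)),
            class = "discretisation_settings")
}

fos_features <- function(x, g, ng, voxel_volume) {
  n <- length(x)
  p <- tabulate(g, nbins = ng) / n
  m <- mean(x)
  v <- sum((x - m)^2) / n
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  inner <- x[x >= q[1] & x <= q[5]]
  skew <- if (v > 0) (sum((x - m)^3) / n) / v^1.5 else 0
  kurt <- if (v > 0) (sum((x - m)^4) / n) / v^2 else 0
  stats::setNames(c(
    sum(x^2),
    sum(x^2) * voxel_volume,
    -sum(p * xlog2(p)),
    min(x), q[1], q[5], max(x), m, q[3],
    q[4] - q[2],
    max(x) - min(x),
    mean(abs(x - m)),
    if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    sqrt(mean(x^2)),
    skew, kurt, v,
    sum(p^2)
  ), paste0("fos_", FOS_NAMES))
}

#' Extract the 95-feature vector for one segment
#'
#' Computes 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14
#' GLDM features on the discretised ROI plus SULmax and SULmean on the raw
#' SUL values. GLCM and GLRLM are built per 3D direction (13 directions)
#' and averaged; GLSZM zones, NGTDM neighbourhoods and GLDM dependence
#' counts use the 26-connected neighbourhood. Constant-valued ROIs are
#' handled by limit conventions (skewness, kurtosis and entropies 0).
#'
#' @param sul A [sul_volume()] (or any volume whose values to featurise).
#' @param mask A [segment_mask()], or a logical/0-1 array on the same grid.
#' @param segment When `mask` is a [segment_mask()]: the segment to
#'   extract, either a label 1-4 or a name from
#'   `c("ascending", "arch", "descending", "abdominal")`.
#' @param settings [discretisation_settings()].
#' @return A named numeric vector of length 95 in manifest order.
#' @export
extract_features <- function(sul, mask, segment = NULL,
                             settings = discretisation_settings()) {
  stopifnot(inherits(sul, "petvasc_volume"))
  mask_logical <- resolve_mask(mask, segment, dim(sul$values))
  n_vox <- sum(mask_logical)
  if (n_vox < settings$min_roi_voxels) {
    stop_petvasc(sprintf("ROI has %d voxels; at least %d required",
                         n_vox, settings$min_roi_voxels),
                 class = "petvasc_degenerate_roi")
  }
  roi <- roi_from_mask(sul$values, mask_logical, settings$bin_width)
  nb <- neighbour_stats(roi)
  out <- c(
    fos_features(roi$x, roi$g, roi$ng, prod(sul$spacing)),
    stats::setNames(glcm_features(roi), paste0("glcm_", GLCM_NAMES)),
    stats::setNames(glrlm_features(roi), paste0("glrlm_", GLRLM_NAMES)),
    stats::setNames(glszm_features(roi), paste0("glszm_", GLSZM_NAMES)),
    stats::setNames(ngtdm_features(roi, nb), paste0("ngtdm_", NGTDM_NAMES)),
    stats::setNames(gldm_features(roi, nb), paste0("gldm_", GLDM_NAMES)),
    SULmax = max(roi$x), SULmean = mean(roi$x))
  out[feature_manifest()]
}

resolve_mask <- function(mask, segment, expected_dim) {
  if (inherits(mask, "segment_mask")) {
    if (is.null(segment)) {
      m <- mask$values > 0L
    } else {
      lab <- if (is.character(segment)) match(segment, SEGMENT_LEVELS)
             else as.integer(segment)
      if (is.na(lab) || lab < 1L || lab > 4L) {
        stop_petvasc("segment must be a label 1-4 or a segment name",
                     class = "petvasc_validation_error")
      }
      m <- mask$values == lab
    }
  } else if (is.array(mask)) {
    m <- mask > 0
  } else {
    stop_petvasc("mask must be a segment_mask or an array",
                 class = "petvasc_validation_error")
  }
  if (!identical(dim(m), as.integer(expected_dim))) {
    stop_petvasc("mask and volume grids differ",
                 class = "petvasc_validation_error")
  }
  m
}

#' Extract features for a whole cohort
#'
#' For each patient: convert the PET volume to SUL, resample volume and
#' mask to isotropic spacing, and extract the 95-feature vector per
#' segment. Segments whose mask is empty (or below `min_roi_voxels`) after
#' resampling are dropped with a warning.
#'
#' @param cohort List of patients from [generate_cohort()] /
#'   [generate_followup_scan()] (a single scan may be passed inside
#'   `list(...)`).
#' @param settings [discretisation_settings()].
#' @param target_spacing Isotropic spacing in mm for resampling (default 2).
#' @param scan_type "baseline" or "followup", recorded per row.
#' @return A data frame: record columns (`patient_id`, `scan_id`,
#'   `segment`, `group`, `calc_score`, `scan_type`) then the 95 feature
#'   columns in manifest order.
#' @export
extract_cohort_features <- function(cohort,
                                    settings = discretisation_settings(),
                                    target_spacing = 2.0,
                                    scan_type = c("baseline", "followup")) {
  scan_type <- match.arg(scan_type)
  rows <- lapply(cohort, function(p) {
    sul <- resample_isotropic(to_sul(p$pet, p$meta), target_spacing)
    msk <- resample_isotropic(p$mask, target_spacing)
    recs <- lapply(1:4, function(seg) {
      feats <- tryCatch(extract_features(sul, msk, seg, settings),
                        petvasc_degenerate_roi = function(e) NULL)
      if (is.null(feats)) {
        warning(sprintf("dropping %s/%s: ROI degenerate after resampling",
                        p$meta$patient_id, SEGMENT_LEVELS[seg]))
        return(NULL)
      }
      cbind(data.frame(patient_id = p$meta$patient_id,
                       scan_id = paste0(p$meta$patient_id, "_",
                                        substr(scan_type, 1, 2)),
                       segment = SEGMENT_LEVELS[seg],
                       group = p$meta$group,
                       calc_score = as.integer(p$calc_scores[seg]),
                       scan_type = scan_type,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(feats), check.names = FALSE))
    })
    do.call(rbind, Filter(Negate(is.null), recs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drop highly collinear features
#'
#' Greedy scan in canonical manifest order: a feature is dropped iff its
#' absolute Pearson correlation with an earlier kept feature exceeds
#' `threshold`. Deterministic given column order. Zero-variance features
#' have no defined correlation; they are kept with a warning.
#'
#' @param table A data frame or matrix whose feature columns are numeric
#'   (non-feature record columns are ignored).
#' @param threshold Absolute correlation above which a feature is dropped
#'   (default 0.9).
#' @return A list with `kept` and `dropped` character vectors of feature
#'   names.
#' @export
prune_correlated <- function(table, threshold = 0.9) {
  tab <- as.data.frame(table)[, setdiff(colnames(table), RECORD_COLUMNS),
                              drop = FALSE]
  mat <- as.matrix(tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE])
  if (nrow(mat) < 2) {
    stop_petvasc("at least two segments are needed to estimate correlations",
                 class = "petvasc_validation_error")
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance feature(s) kept: %s",
                    paste(colnames(mat)[sds == 0], collapse = ", ")))
  }
  kept <- character(0)
  dropped <- character(0)
  for (nm in colnames(mat)) {
    if (sds[nm] == 0) { kept <- c(kept, nm); next }
    r <- if (length(kept)) {
      prev <- kept[sds[kept] > 0]
      if (length(prev)) {
        max(abs(suppressWarnings(stats::cor(mat[, nm], mat[, prev]))), na.rm = TRUE)
      } else 0
    } else 0
    if (r > threshold) dropped <- c(dropped, nm) else kept <- c(kept, nm)
  }
  list(kept = kept, dropped = dropped)
}

RECORD_COLUMNS <- c("patient_id", "scan_id", "segment", "group",
                    "calc_score", "scan_type")

#' Split a feature table into record columns and feature matrix
#'
#' @param table A feature table from [extract_cohort_features()].
#' @return A list with `records` (data frame) and `features` (numeric
#'   matrix).
#' @export
feature_table_parts <- function(table) {
  rec <- table[, intersect(RECORD_COLUMNS, names(table)), drop = FALSE]
  fnames <- setdiff(names(table), RECORD_COLUMNS)
  list(records = rec,
       features = as.matrix(table[, fnames, drop = FALSE]))
}
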