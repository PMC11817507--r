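# Occlusion sensitivity maps: slide a cubic patch over the vessel mask,
# occlude it, re-extract the full feature vector, re-score the model, and
# record the probability change. Positive delta (baseline - occluded)
# means the occluded region supported the active-GCA prediction.

#' Occlusion specification
#'
#' @param patch_size_mm Edge length of the cubic occlusion patch (mm).
#' @param stride_mm Lattice stride between patch positions (mm); must not
#'   exceed the patch size, so patches tile or overlap.
#' @param fill_rule How to occlude: "replace-with-background" (the
#'   default: patch voxels are filled with the ROI minimum, the
#'   grey-patch convention of occlusion-map explainability - radiomic
#'   features are intensive statistics of the ROI, so merely removing
#'   voxels from the mask leaves them nearly unchanged on homogeneous
#'   uptake and yields uninformative flat maps), "replace-with-roi-mean",
#'   or "remove-from-mask" (occluded voxels excluded from feature
#'   computation; kept for sensitivity analysis).
#' @return An `occlusion_spec` list.
#' @export
occlusion_spec <- function(patch_size_mm = 8, stride_mm = 4,
                           fill_rule = c("replace-with-background",
                                         "replace-with-roi-mean",
                                         "remove-from-mask")) {
  fill_rule <- match.arg(fill_rule)
  assert_positive(patch_size_mm, "patch_size_mm")
  assert_positive(stride_mm, "stride_mm")
  if (stride_mm > patch_size_mm) {
    stop_petvasc("stride_mm must not exceed patch_size_mm",
                 class = "petvasc_validation_error")
  }
  structure(list(patch_size_mm = patch_size_mm, stride_mm = stride_mm,
                 fill_rule = fill_rule), class = "occlusion_spec")
}

#' Occlusion sensitivity map for one scan
#'
#' For every segment, the model's baseline probability is computed from
#' the unoccluded features; a cubic patch then moves over the segment's
#' bounding box on a stride lattice, the patch is occluded, features are
#' re-extracted and re-scored, and every mask voxel covered by the patch
#' accumulates `baseline - occluded`. The per-voxel delta is the average
#' over all patches that covered the voxel. Patches that would leave the
#' ROI below `min_roi_voxels` are skipped.
#'
#' @param sul A [sul_volume()] on the analysis grid.
#' @param mask The co-registered [segment_mask()].
#' @param result A fitted `grid_result` (from [cross_validate()]).
#' @param spec An [occlusion_spec()].
#' @param settings [discretisation_settings()] used for feature
#'   extraction.
#' @return An `occlusion_map` list: `delta` (3D array, zero off-mask),
#'   `baseline_probs` (per segment), `coverage` (patch count per voxel),
#'   `spec`.
#' @export
occlusion_map <- function(sul, mask, result, spec = occlusion_spec(),
                          settings = discretisation_settings()) {
  stopifnot(inherits(sul, "petvasc_volume"), inherits(mask, "segment_mask"))
  dm <- dim(sul$values)
  delta_sum <- array(0, dm)
  cover <- array(0L, dm)
  baseline_probs <- stats::setNames(rep(NA_real_, 4), SEGMENT_LEVELS)
  patch_vox <- pmax(1L, as.integer(round(spec$patch_size_mm / sul$spacing)))
  stride_vox <- pmax(1L, as.integer(round(spec$stride_mm / sul$spacing)))
  for (seg in 1:4) {
    seg_idx <- which(mask$values == seg)
    if (length(seg_idx) < settings$min_roi_voxels) next
    base_feats <- extract_features(sul, mask, seg, settings)
    base_prob <- score_features(result, base_feats)
    baseline_probs[seg] <- base_prob
    coords <- arrayInd(seg_idx, dm)
    lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
    starts <- lapply(1:3, function(a) {
      unique(pmax(pmin(seq(lo[a], max(lo[a], hi[a]), by = stride_vox[a]),
                       hi[a] - patch_vox[a] + 1L), 1L))
    })
    seg_mask_arr <- mask$values == seg
    for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
      px <- sx:min(sx + patch_vox[1] - 1L, dm[1])
      py <- sy:min(sy + patch_vox[2] - 1L, dm[2])
      pz <- sz:min(sz + patch_vox[3] - 1L, dm[3])
      patch <- array(FALSE, dm)
      patch[px, py, pz] <- TRUE
      hit <- patch & seg_mask_arr
      n_hit <- sum(hit)
      if (n_hit == 0) next
      occluded <- occlude_once(sul, seg_mask_arr, hit, spec, settings)
      if (is.null(occluded)) next   # ROI would become degenerate
      d <- base_prob - score_features(result, occluded)
      delta_sum[hit] <- delta_sum[hit] + d
      cover[hit] <- cover[hit] + 1L
    }
  }
  delta <- ifelse(cover > 0, delta_sum / pmax(cover, 1L), 0)
  structure(list(delta = delta, baseline_probs = baseline_probs,
                 coverage = cover, spec = spec),
            class = "occlusion_map")
}

occlude_once <- function(sul, seg_mask_arr, hit, spec, settings) {
  if (spec$fill_rule == "remove-from-mask") {
    new_mask <- seg_mask_arr & !hit
    if (sum(new_mask) < settings$min_roi_voxels) return(NULL)
    tryCatch(extract_features(sul, new_mask * 1L, NULL, settings),
             petvasc_degenerate_roi = function(e) NULL)
  } else {
    vals <- sul$values
    roi_vals <- vals[seg_mask_arr]
    fill <- if (spec$fill_rule == "replace-with-roi-mean") mean(roi_vals)
            else min(roi_vals)
    vals[hit] <- fill
    vol2 <- sul_volume(vals, sul$spacing, sul$origin)
    extract_features(vol2, seg_mask_arr * 1L, NULL, settings)
  }
}

score_features <- function(result, feats) {
  X <- matrix(feats, nrow = 1, dimnames = list(NULL, names(feats)))
  models <- Filter(Negate(is.null), result$models)
  mean(vapply(models, function(m) {
    m$cls$predict_prob(m$std(X)[, m$features, drop = FALSE])
  }, numeric(1)))
}

#' Mean occlusion delta per segment
#'
#' @param map An `occlusion_map`.
#' @param mask The [segment_mask()] the map was computed on.
#' @return Named numeric vector: mean delta over each segment's covered
#'   voxels.
#' @export
segment_mean_delta <- function(map, mask) {
  vapply(1:4, function(seg) {
    idx <- mask$values == seg & map$coverage > 0
    if (!any(idx)) return(NA_real_)
    mean(map$delta[idx])
  }, numeric(1)) |> stats::setNames(SEGMENT_LEVELS)
}

#' Render an occlusion map as axial overlay slices
#'
#' Writes one PNG per axial slice holding mask voxels: the SUL image in
#' grey with the delta overlaid in a diverging red (positive, supports
#' active GCA) to blue (negative) palette, symmetric about zero.
#'
#' @param map An `occlusion_map`.
#' @param sul Background [sul_volume()].
#' @param dir Output directory for the PNG stack.
#' @param alpha Overlay opacity in (0, 1].
#' @return Paths of the written PNGs, invisibly.
#' @export
render_heatmap <- function(map, sul, dir, alpha = 0.6) {
  stopifnot(identical(dim(map$delta), dim(sul$values)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- dim(sul$values)
  dmax <- max(abs(map$delta))
  bg <- sul$values / max(sul$values, 1e-12)
  slices <- which(apply(map$coverage > 0, 3, any))
  if (!length(slices)) slices <- seq_len(dm[3])
  paths <- character(0)
  for (k in slices) {
    g <- bg[, , k]
    r <- g; b <- g; gg <- g
    if (dmax > 0) {
      d <- map$delta[, , k] / dmax      # in [-1, 1]
      w <- abs(d) * alpha
      r <- r * (1 - w) + w * (d > 0)
      b <- b * (1 - w) + w * (d < 0)
      gg <- gg * (1 - w)
    }
    img <- array(c(t(r), t(gg), t(b)), c(dm[2], dm[1], 3))
    path <- file.path(dir, sprintf("slice_%03d.png", k))
    png::writePNG(pmin(pmax(img, 0), 1), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write the raw delta volume to NIfTI
#' @param map An `occlusion_map`.
#' @param spacing Voxel spacing of the analysis grid.
#' @param path Output `.nii.gz` path.
#' @export
write_occlusion_map <- function(map, spacing, path) {
  img <- RNifti::asNifti(map$delta)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
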