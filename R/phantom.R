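# Synthetic vessel phantom.
#
# The phantom emulates the statistical structure the classifier relies on,
# not aortic anatomy: each scan is a straight cylindrical vessel wall in a
# uniform background, cut axially into four contiguous segments standing in
# for the ascending aorta, arch, descending aorta and abdominal aorta.
# Giant-cell arteritis (GCA) scans carry homogeneous elevated wall uptake;
# atherosclerosis scans carry lower diffuse wall uptake with focal
# high-uptake patches (lipid-plaque surrogates). Activity noise is Gaussian,
# clipped at zero - the pipeline consumes reconstructed images, so full
# Poisson/PSF physics is deliberately out of scope.

#' Parameters of the synthetic vessel phantom
#'
#' Defaults give a scanner-like grid (3.19 x 3.19 x 2 mm voxels) and a
#' class contrast calibrated so the synthetic task is clearly learnable
#' but not degenerate: GCA walls carry homogeneous elevated activity
#' (4200 Bq/mL, voxel CV 0.15), atherosclerotic walls lower diffuse
#' activity (2500 Bq/mL) with on average 2.5 focal 7-mm patches of
#' intermediate activity (3800 Bq/mL) per segment, background 1800 Bq/mL.
#' With a typical injected dose (3 MBq/kg of body weight) and lean body
#' mass these map to wall SUL of roughly 1.3 (GCA) versus 0.8-1.2
#' (atherosclerosis), so GCA segments have both higher SULmax and lower
#' within-segment heterogeneity than atherosclerotic ones - the two
#' contrasts the classifier is meant to exploit.
#'
#' @param n_gca,n_athero Patients per class.
#' @param grid_shape Integer length-3 voxel grid.
#' @param voxel_spacing Numeric length-3 spacing in mm.
#' @param wall_radius_mm Outer radius of the vessel wall.
#' @param wall_thickness_mm Radial thickness of the wall.
#' @param gca_wall_mean,athero_wall_mean,background_mean Mean activity Bq/mL.
#' @param gca_wall_cv Coefficient of variation of activity noise (used for
#'   all tissue classes).
#' @param patch_rate Expected number of focal patches per atherosclerotic
#'   segment (Poisson).
#' @param patch_mean Mean activity of patch voxels, Bq/mL.
#' @param patch_radius_mm Patch radius in mm.
#' @param n_calcified_gca_segments Number of GCA segments (across the whole
#'   cohort) assigned a calcification score of 3 or 4; defaults to one per
#'   GCA patient on average.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(n_gca = 20, n_athero = 20,
                           grid_shape = c(44L, 44L, 64L),
                           voxel_spacing = c(3.19, 3.19, 2.0),
                           wall_radius_mm = 15, wall_thickness_mm = 6,
                           gca_wall_mean = 4200, gca_wall_cv = 0.15,
                           athero_wall_mean = 2500,
                           patch_rate = 2.5, patch_mean = 3800,
                           patch_radius_mm = 7,
                           background_mean = 1800,
                           n_calcified_gca_segments = n_gca,
                           seed = 1L) {
  p <- list(n_gca = as.integer(n_gca), n_athero = as.integer(n_athero),
            grid_shape = as.integer(grid_shape),
            voxel_spacing = as.numeric(voxel_spacing),
            wall_radius_mm = wall_radius_mm,
            wall_thickness_mm = wall_thickness_mm,
            gca_wall_mean = gca_wall_mean, gca_wall_cv = gca_wall_cv,
            athero_wall_mean = athero_wall_mean,
            patch_rate = patch_rate, patch_mean = patch_mean,
            patch_radius_mm = patch_radius_mm,
            background_mean = background_mean,
            n_calcified_gca_segments = as.integer(n_calcified_gca_segments),
            seed = as.integer(seed))
  validate_phantom_params(p)
  class(p) <- "phantom_params"
  p
}

validate_phantom_params <- function(p) {
  for (nm in c("gca_wall_mean", "athero_wall_mean", "patch_mean",
               "background_mean", "wall_radius_mm", "wall_thickness_mm",
               "patch_radius_mm", "gca_wall_cv")) {
    assert_positive(p[[nm]], nm)
  }
  if (p$n_gca < 0 || p$n_athero < 0) {
    stop_petvasc("patient counts must be non-negative",
                 class = "petvasc_validation_error")
  }
  if (p$gca_wall_mean <= p$athero_wall_mean) {
    stop_petvasc("gca_wall_mean must exceed athero_wall_mean (class separation is by construction)",
                 class = "petvasc_validation_error")
  }
  if (p$n_calcified_gca_segments < 0 ||
      p$n_calcified_gca_segments > 4L * p$n_gca) {
    stop_petvasc("n_calcified_gca_segments must lie in [0, 4 * n_gca]",
                 class = "petvasc_validation_error")
  }
  ext <- p$grid_shape * p$voxel_spacing
  if (2 * p$wall_radius_mm >= min(ext[1:2]) - 2 * max(p$voxel_spacing)) {
    stop_petvasc("vessel does not fit in the grid: increase grid_shape or shrink wall_radius_mm",
                 class = "petvasc_geometry_error")
  }
  if (p$grid_shape[3] < 4L) {
    stop_petvasc("grid needs at least 4 axial slices for the four segments",
                 class = "petvasc_geometry_error")
  }
  invisible(p)
}

# Segment mask of the straight-tube vessel: labels 1..4 are contiguous
# axial blocks (ascending, arch, descending, abdominal). Deterministic in
# the geometry parameters, independent of the seed.
phantom_mask <- function(params) {
  d <- params$grid_shape; sp <- params$voxel_spacing
  cx <- d[1] * sp[1] / 2; cy <- d[2] * sp[2] / 2
  x <- (seq_len(d[1]) - 0.5) * sp[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2]
  r2 <- outer((x - cx)^2, (y - cy)^2, `+`)
  outer_r <- params$wall_radius_mm
  inner_r <- params$wall_radius_mm - params$wall_thickness_mm
  wall2d <- r2 <= outer_r^2 & r2 > max(inner_r, 0)^2
  seg_of_slice <- pmin(((seq_len(d[3]) - 1L) * 4L) %/% d[3] + 1L, 4L)
  lab <- array(0L, d)
  for (k in seq_len(d[3])) lab[, , k] <- ifelse(wall2d, seg_of_slice[k], 0L)
  segment_mask(lab, sp)
}

clip0 <- function(x) pmax(x, 0)

# Fill one patient's activity volume given its class.
phantom_activity <- function(params, mask, group) {
  d <- params$grid_shape; cv <- params$gca_wall_cv
  vals <- clip0(array(stats::rnorm(prod(d), params$background_mean,
                                   cv * params$background_mean), d))
  wall_mean <- if (group == "GCA") params$gca_wall_mean else params$athero_wall_mean
  wall_idx <- which(mask$values > 0L)
  vals[wall_idx] <- clip0(stats::rnorm(length(wall_idx), wall_mean,
                                       cv * wall_mean))
  if (group == "ATHERO" && params$patch_rate > 0) {
    vals <- add_patches(vals, params, mask)
  }
  vals
}

# Poisson(patch_rate) spherical high-uptake patches per segment, centred on
# random wall voxels; patch voxels are restricted to the wall.
add_patches <- function(vals, params, mask) {
  d <- params$grid_shape; sp <- params$voxel_spacing
  coords <- arrayInd(which(mask$values > 0L), d)
  wall_lin <- which(mask$values > 0L)
  xyz <- sweep(coords - 0.5, 2, sp, `*`)
  for (seg in 1:4) {
    in_seg <- mask$values[wall_lin] == seg
    if (!any(in_seg)) next
    n_patch <- stats::rpois(1, params$patch_rate)
    if (n_patch == 0) next
    centres <- sample(which(in_seg), min(n_patch, sum(in_seg)))
    for (ci in centres) {
      d2 <- rowSums(sweep(xyz, 2, xyz[ci, ], `-`)^2)
      hit <- wall_lin[d2 <= params$patch_radius_mm^2]
      vals[hit] <- clip0(stats::rnorm(length(hit), params$patch_mean,
                                      params$gca_wall_cv * params$patch_mean))
    }
  }
  vals
}

sample_meta <- function(patient_id, group) {
  sex <- if (stats::runif(1) < 0.5) "male" else "female"
  w <- stats::runif(1, 55, 110)
  list(patient_id = patient_id, sex = sex,
       body_weight = w, bmi = stats::runif(1, 20, 38),
       injected_dose = 3 * w,   # 3 MBq/kg dosing scheme
       group = group)
}

#' Generate a synthetic baseline cohort
#'
#' Produces `n_gca + n_athero` patients, each with metadata, a PET activity
#' volume, a four-segment wall mask and per-segment calcification scores
#' (0-4). Exactly `n_calcified_gca_segments` GCA segments carry a score of
#' 3 or 4; all other GCA segments score at most 2. The output is fully
#' reproducible from `params$seed`, and the mask geometry does not depend
#' on the seed.
#'
#' @param params A [phantom_params()] object.
#' @return A list of patients; each element has `meta`, `pet`
#'   ([pet_volume()]), `mask` ([segment_mask()]) and `calc_scores` (named
#'   integer vector over the four segments).
#' @export
generate_cohort <- function(params) {
  validate_phantom_params(params)
  mask <- phantom_mask(params)
  with_seed(params$seed, {
    groups <- c(rep("GCA", params$n_gca), rep("ATHERO", params$n_athero))
    ids <- c(sprintf("GCA%03d", seq_len(params$n_gca)),
             sprintf("ATH%03d", seq_len(params$n_athero)))
    # which GCA segments (patient x segment) are heavily calcified
    n_gca_seg <- 4L * params$n_gca
    flagged <- if (n_gca_seg > 0) {
      sample(n_gca_seg, params$n_calcified_gca_segments)
    } else integer(0)
    lapply(seq_along(ids), function(i) {
      meta <- sample_meta(ids[i], groups[i])
      vals <- phantom_activity(params, mask, groups[i])
      calc <- if (groups[i] == "GCA") {
        slot <- (match(ids[i], ids) - 1L) * 4L + 1:4
        ifelse(slot %in% flagged, sample(3:4, 4, replace = TRUE),
               sample(0:2, 4, replace = TRUE))
      } else {
        sample(0:4, 4, replace = TRUE, prob = c(0.1, 0.15, 0.25, 0.25, 0.25))
      }
      names(calc) <- SEGMENT_LEVELS
      list(meta = meta, pet = pet_volume(vals, params$voxel_spacing),
           mask = mask, calc_scores = calc)
    })
  })
}

#' Generate a synthetic follow-up scan
#'
#' Follow-up scans model treated GCA patients: an active scan carries the
#' homogeneous GCA wall texture in at least one segment (the remaining
#' segments are quiescent, near background), an inactive scan has all wall
#' segments near background. Calcification scores are sampled but never
#' used for exclusion in follow-up.
#'
#' @param params A [phantom_params()] object.
#' @param active Logical; is the disease active on this scan?
#' @param active_segments Integer indices (1-4) of the hot segments when
#'   `active = TRUE`; default draws a random non-empty subset.
#' @param patient_id Identifier for the scan's patient.
#' @param seed Seed for this scan (defaults to `params$seed`).
#' @return A list with `meta`, `pet`, `mask`, `calc_scores`, `active` and
#'   `active_segments`.
#' @export
generate_followup_scan <- function(params, active, active_segments = NULL,
                                   patient_id = "FUP001",
                                   seed = params$seed) {
  validate_phantom_params(params)
  mask <- phantom_mask(params)
  with_seed(seed, {
    meta <- sample_meta(patient_id, "GCA")
    d <- params$grid_shape; cv <- params$gca_wall_cv
    vals <- clip0(array(stats::rnorm(prod(d), params$background_mean,
                                     cv * params$background_mean), d))
    hot <- integer(0)
    if (isTRUE(active)) {
      hot <- if (is.null(active_segments)) {
        sample(1:4, sample(1:4, 1))
      } else as.integer(active_segments)
      if (length(hot) == 0) {
        stop_petvasc("an active follow-up scan needs at least one hot segment",
                     class = "petvasc_validation_error")
      }
    }
    for (seg in 1:4) {
      idx <- which(mask$values == seg)
      m <- if (seg %in% hot) params$gca_wall_mean else params$background_mean
      vals[idx] <- clip0(stats::rnorm(length(idx), m, cv * m))
    }
    calc <- sample(0:4, 4, replace = TRUE)
    names(calc) <- SEGMENT_LEVELS
    list(meta = meta, pet = pet_volume(vals, params$voxel_spacing),
         mask = mask, calc_scores = calc, active = isTRUE(active),
         active_segments = sort(hot))
  })
}

#' Write a cohort to disk
#'
#' Volumes and masks go to NIfTI (`<id>_pet.nii.gz`, `<id>_mask.nii.gz`),
#' metadata and calcification scores to `cohort.csv` (one row per patient
#' segment) and the generator parameters with their seed to
#' `manifest.json`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param params The [phantom_params()] used, stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(cohort, function(p) {
    write_volume(p$pet, file.path(dir, paste0(p$meta$patient_id, "_pet.nii.gz")))
    write_volume(p$mask, file.path(dir, paste0(p$meta$patient_id, "_mask.nii.gz")))
    data.frame(patient_id = p$meta$patient_id, sex = p$meta$sex,
               weight_kg = p$meta$body_weight, bmi = p$meta$bmi,
               dose_MBq = p$meta$injected_dose, group = p$meta$group,
               segment = SEGMENT_LEVELS, calc_score = unname(p$calc_scores))
  }))
  utils::write.csv(rows, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
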