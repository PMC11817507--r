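# Lightweight S3 containers for 3D scalar grids. A volume is a numeric 3D
# array plus voxel spacing (mm) and a world origin (mm); a segment mask is an
# integer grid with labels 1..4 for the four aortic segments and 0 elsewhere.

#' Construct a PET activity volume
#'
#' @param values Numeric 3D array of activity in Bq/mL.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param origin Numeric length-3 world origin in mm (default 0).
#' @return A `pet_volume` object.
#' @export
pet_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  new_volume(values, spacing, origin, "pet_volume")
}

#' Construct a SUL volume
#'
#' Standardised uptake values normalised to lean body mass (g/mL), typically
#' produced by [to_sul()].
#'
#' @inheritParams pet_volume
#' @param meta Optional list of patient metadata attached for provenance.
#' @return A `sul_volume` object.
#' @export
sul_volume <- function(values, spacing, origin = c(0, 0, 0), meta = NULL) {
  v <- new_volume(values, spacing, origin, "sul_volume")
  attr(v, "meta") <- meta
  v
}

#' Construct a segment label mask
#'
#' @param labels Integer 3D array; 0 = background, 1 = ascending, 2 = arch,
#'   3 = descending, 4 = abdominal.
#' @inheritParams pet_volume
#' @return A `segment_mask` object.
#' @export
segment_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  if (any(!labels %in% 0:4)) {
    stop_petvasc("segment mask labels must be integers in 0..4",
                 class = "petvasc_validation_error")
  }
  new_volume(labels, spacing, origin, "segment_mask")
}

new_volume <- function(values, spacing, origin, class) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_petvasc("volume values must be a 3D array",
                 class = "petvasc_validation_error")
  }
  if (length(spacing) != 3L) {
    stop_petvasc("spacing must have length 3", class = "petvasc_validation_error")
  }
  assert_positive(spacing, "spacing")
  if (class != "segment_mask" && any(!is.finite(values))) {
    stop_petvasc("volume values must be finite", class = "petvasc_validation_error")
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c(class, "petvasc_volume"))
}

#' @export
print.petvasc_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "segment_mask")) {
    n <- tabulate(x$values, nbins = 4L)
    cat(sprintf("  segments (voxels): %s\n",
                paste(sprintf("%s=%d", SEGMENT_LEVELS, n), collapse = ", ")))
  } else {
    cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Read a volume from NIfTI
#'
#' Spacing is taken from the header `pixdim`. Use `as = "mask"` for label
#' images (values coerced to integer).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as Either "pet", "sul", or "mask".
#' @return A volume object of the requested class.
#' @export
read_volume <- function(path, as = c("pet", "sul", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  switch(as,
    pet = pet_volume(vals, sp),
    sul = sul_volume(vals, sp),
    mask = segment_mask(array(as.integer(round(vals)), dim = dim(vals)), sp))
}

#' Write a volume to NIfTI
#'
#' @param vol A volume object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "petvasc_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Linear index offsets of the 26-neighbourhood (and its 13 unique half-space
# directions) for an array of dimension d. Directions are voxel steps.
neighbour_directions_13 <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  # keep one of each +/- pair: lexicographic positive half
  keep <- dirs$dz > 0 | (dirs$dz == 0 & dirs$dy > 0) |
    (dirs$dz == 0 & dirs$dy == 0 & dirs$dx > 0)
  as.matrix(dirs[keep, , drop = FALSE])
}

neighbour_directions_26 <- function() {
  d13 <- neighbour_directions_13()
  rbind(d13, -d13)
}
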