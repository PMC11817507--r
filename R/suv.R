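# SUL normalisation and isotropic resampling.
#
# PET activity (Bq/mL) is converted to standardised uptake value normalised
# to lean body mass (SUL, g/mL):
#
#   SUL = activity / (injected dose / LBM)
#
# with the sex-specific James-type LBM estimate from body weight (kg) and
# BMI (kg/m^2). Volumes are then resampled to isotropic spacing with cubic
# B-spline interpolation (masks with nearest-neighbour to preserve labels).

#' Sex-specific lean body mass estimate
#'
#' LBM in kg from body weight and BMI:
#' males `9270 W / (6680 + 216 BMI)`, females `9270 W / (8780 + 244 BMI)`.
#'
#' @param sex "male" or "female".
#' @param body_weight Body weight in kg (> 0).
#' @param bmi Body-mass index in kg/m^2 (> 0).
#' @return Lean body mass in kg.
#' @examples
#' lean_body_mass("male", 80, 25)   # 61.39 kg
#' lean_body_mass("female", 70, 25) # 43.61 kg
#' @export
lean_body_mass <- function(sex, body_weight, bmi) {
  assert_in(sex, c("male", "female"), "sex")
  assert_positive(body_weight, "body_weight")
  assert_positive(bmi, "bmi")
  if (sex == "male") {
    9270 * body_weight / (6680 + 216 * bmi)
  } else {
    9270 * body_weight / (8780 + 244 * bmi)
  }
}

#' Convert a PET activity volume to SUL
#'
#' Voxelwise `SUL = activity * LBM / dose` with LBM in g and the injected
#' dose in Bq, so a uniform activity numerically equal to dose/LBM per mL
#' maps to SUL = 1. No decay correction is applied (fixed uptake time
#' assumed).
#'
#' @param vol A [pet_volume()].
#' @param meta A list or one-row data frame with fields `sex`, `body_weight`
#'   (or `weight_kg`), `bmi`, `injected_dose` (or `dose_MBq`, in MBq).
#' @return A [sul_volume()] with the same grid.
#' @export
to_sul <- function(vol, meta) {
  stopifnot(inherits(vol, "pet_volume"))
  meta <- as.list(meta)
  get_field <- function(...) {
    for (nm in c(...)) if (!is.null(meta[[nm]]) && !is.na(meta[[nm]])) return(meta[[nm]])
    stop_petvasc(sprintf("metadata field `%s` is missing", ..1),
                 class = "petvasc_metadata_error")
  }
  sex <- as.character(get_field("sex"))
  w <- as.numeric(get_field("body_weight", "weight_kg"))
  bmi <- as.numeric(get_field("bmi"))
  dose_mbq <- as.numeric(get_field("injected_dose", "dose_MBq"))
  assert_positive(dose_mbq, "injected_dose")
  lbm_g <- lean_body_mass(sex, w, bmi) * 1000
  dose_bq <- dose_mbq * 1e6
  sul_volume(vol$values * lbm_g / dose_bq, vol$spacing, vol$origin, meta = meta)
}

#' Resample a volume to isotropic voxel spacing
#'
#' Scalar volumes are interpolated with a cubic B-spline (with the exact
#' prefilter, so polynomials up to degree three are reproduced); segment
#' masks use nearest-neighbour so labels are preserved. The voxel-centre
#' convention is used and the physical extent of the grid is kept.
#'
#' @param vol A volume object (scalar volume or [segment_mask()]).
#' @param target_spacing Isotropic target spacing in mm (> 0).
#' @return A volume of the same class on the new grid.
#' @export
resample_isotropic <- function(vol, target_spacing = 2.0) {
  assert_positive(target_spacing, "target_spacing")
  stopifnot(inherits(vol, "petvasc_volume"))
  d_in <- dim(vol$values)
  sp_in <- vol$spacing
  extent <- d_in * sp_in
  d_out <- pmax(1L, as.integer(ceiling(extent / target_spacing - 1e-9)))
  # continuous input index (1-based, voxel centres) of each output centre
  idx <- lapply(1:3, function(a) {
    ((seq_len(d_out[a]) - 0.5) * target_spacing) / sp_in[a] + 0.5
  })
  if (inherits(vol, "segment_mask")) {
    nn <- lapply(1:3, function(a) pmin(pmax(round(idx[[a]]), 1L), d_in[a]))
    out <- vol$values[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
    return(segment_mask(array(out, d_out), rep(target_spacing, 3), vol$origin))
  }
  coef <- vol$values
  for (a in 1:3) coef <- apply_along(coef, a, bspline_prefilter)
  out <- coef
  for (a in 1:3) {
    W <- bspline_weights(idx[[a]], dim(out)[a])
    out <- tensor_mult(out, W, a)
  }
  res <- new_volume(out, rep(target_spacing, 3), vol$origin, class(vol)[1])
  attr(res, "meta") <- attr(vol, "meta")
  res
}

# ---- cubic B-spline machinery -------------------------------------------

# In-place prefilter of a 1D signal: converts samples to B-spline
# coefficients (Unser's recursive filter, mirror boundaries).
bspline_prefilter <- function(s) {
  n <- length(s)
  if (n == 1L) return(s)
  z <- sqrt(3) - 2
  s <- s * 6
  horizon <- ceiling(log(1e-14) / log(abs(z)))
  c_plus <- numeric(n)
  c_plus[1] <- if (n > horizon) {
    sum(s[seq_len(horizon)] * z^(seq_len(horizon) - 1))
  } else {
    # exact initialisation over the whole-sample mirror extension
    z2n <- z^(2 * n - 2)
    k <- 2:(n - 1)
    (s[1] + z^(n - 1) * s[n] +
       if (n > 2) sum((z^(k - 1) + z2n / z^(k - 1)) * s[k]) else 0) /
      (1 - z2n)
  }
  for (k in 2:n) c_plus[k] <- s[k] + z * c_plus[k - 1]
  cc <- numeric(n)
  cc[n] <- (z / (z^2 - 1)) * (c_plus[n] + z * c_plus[n - 1])
  for (k in (n - 1):1) cc[k] <- z * (cc[k + 1] - c_plus[k])
  cc
}

# Dense evaluation matrix W (n_out x n_in): W %*% coef interpolates the
# cubic B-spline at continuous indices x (1-based), mirror boundary.
bspline_weights <- function(x, n_in) {
  n_out <- length(x)
  W <- matrix(0, n_out, n_in)
  i0 <- floor(x)
  t <- x - i0
  w <- cbind((1 - t)^3 / 6,
             (3 * t^3 - 6 * t^2 + 4) / 6,
             (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
             t^3 / 6)
  for (k in 0:3) {
    idx <- mirror_index(i0 - 1 + k, n_in)
    W[cbind(seq_len(n_out), idx)] <- W[cbind(seq_len(n_out), idx)] + w[, k + 1]
  }
  W
}

# Reflect an index into 1..n (whole-sample mirror).
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- (i - 1L) %% p
  i <- ifelse(i < 0, i + p, i)
  as.integer(ifelse(i >= n, p - i, i) + 1L)
}

# Apply a vector -> vector function along axis a of a 3D array.
apply_along <- function(arr, a, f) {
  perm <- c(a, setdiff(1:3, a))
  m <- aperm(arr, perm)
  d <- dim(m)
  m <- matrix(m, nrow = d[1])
  m <- apply(m, 2, f)
  dim(m) <- d
  aperm(m, order(perm))
}

# Multiply matrix W (n_out x n_a) into axis a of a 3D array.
tensor_mult <- function(arr, W, a) {
  perm <- c(a, setdiff(1:3, a))
  m <- aperm(arr, perm)
  d <- dim(m)
  m <- W %*% matrix(m, nrow = d[1])
  dim(m) <- c(nrow(W), d[2], d[3])
  aperm(m, order(perm))
}
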