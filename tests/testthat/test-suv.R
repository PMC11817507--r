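# SUL conversion and isotropic resampling.

test_that("lean body mass matches hand-computed values and rejects bad input", {
  # 9270*80/(6680+216*25) = 741600/12080; 9270*70/(8780+244*25) = 648900/14880
  expect_equal(lean_body_mass("male", 80, 25), 741600 / 12080, tolerance = 1e-12)
  expect_equal(lean_body_mass("female", 70, 25), 648900 / 14880, tolerance = 1e-12)
  expect_equal(round(lean_body_mass("male", 80, 25), 2), 61.39)
  expect_equal(round(lean_body_mass("female", 70, 25), 2), 43.61)
  expect_error(lean_body_mass("male", 0, 25), class = "petvasc_validation_error")
  expect_error(lean_body_mass("male", 80, -1), class = "petvasc_validation_error")
  expect_error(lean_body_mass("other", 80, 25), class = "petvasc_validation_error")
})

test_that("lean body mass is increasing in weight, decreasing in BMI", {
  for (sex in c("male", "female")) {
    w <- seq(45, 140, by = 5)
    expect_true(all(diff(vapply(w, function(x) lean_body_mass(sex, x, 27),
                                numeric(1))) > 0))
    b <- seq(17, 45, by = 2)
    expect_true(all(diff(vapply(b, function(x) lean_body_mass(sex, 80, x),
                                numeric(1))) < 0))
  }
})

test_that("SUL conversion implements activity * LBM / dose with units", {
  meta <- list(sex = "male", body_weight = 80, bmi = 25, injected_dose = 240)
  zero <- pet_volume(array(0, c(4, 4, 4)), c(2, 2, 2))
  expect_true(all(to_sul(zero, meta)$values == 0))

  # uniform activity equal to dose(Bq)/LBM(g) per mL -> SUL exactly 1
  lbm_g <- lean_body_mass("male", 80, 25) * 1000
  act <- 240e6 / lbm_g
  unif <- pet_volume(array(act, c(4, 4, 4)), c(2, 2, 2))
  expect_equal(unname(to_sul(unif, meta)$values[1, 1, 1]), 1, tolerance = 1e-12)

  # 5000 Bq/mL, male 80 kg BMI 25, 240 MBq -> 5000 * 61390.7 / 2.4e8
  v <- pet_volume(array(5000, c(2, 2, 2)), c(2, 2, 2))
  expect_equal(unname(to_sul(v, meta)$values[1]),
               5000 * lbm_g / 240e6, tolerance = 1e-12)
  expect_equal(round(unname(to_sul(v, meta)$values[1]), 3), 1.279)
})

test_that("SUL conversion is linear in activity and names missing fields", {
  meta <- list(sex = "female", body_weight = 62, bmi = 23, injected_dose = 190)
  set.seed(1)
  v <- pet_volume(array(runif(64, 0, 9000), c(4, 4, 4)), c(3.19, 3.19, 2))
  a <- 3.7
  va <- pet_volume(a * v$values, v$spacing)
  expect_equal(to_sul(va, meta)$values, a * to_sul(v, meta)$values,
               tolerance = 1e-12)
  expect_error(to_sul(v, list(sex = "female", bmi = 23, injected_dose = 190)),
               "body_weight", class = "petvasc_metadata_error")
})

test_that("resampling reproduces constants and linear ramps", {
  const <- pet_volume(array(4.2, c(8, 8, 8)), c(2, 2, 2))
  r <- resample_isotropic(const, 2)
  expect_equal(dim(r$values), c(8L, 8L, 8L))
  expect_equal(max(abs(r$values - 4.2)), 0, tolerance = 1e-9)

  # axial linear ramp at anisotropic spacing: cubic B-splines reproduce
  # polynomials exactly; mirror-boundary effects decay geometrically, so
  # compare well inside the volume
  d <- c(10, 10, 60); sp <- c(2, 2, 4)
  zc_in <- (seq_len(d[3]) - 0.5) * sp[3]
  ramp <- array(rep(2 + 0.5 * zc_in, each = d[1] * d[2]), d)
  r2 <- resample_isotropic(pet_volume(ramp, sp), 2)
  zc_out <- (seq_len(dim(r2$values)[3]) - 0.5) * 2
  interior <- 41:80
  err <- max(abs(sweep(r2$values[4:7, 4:7, interior, drop = FALSE], 3,
                       2 + 0.5 * zc_out[interior])))
  expect_lt(err, 1e-6)
})

test_that("resample there-and-back changes a smooth volume by < 1% RMS", {
  d <- c(16, 16, 24); sp <- c(3, 3, 3)
  x <- (seq_len(d[1]) - 0.5) * sp[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  smooth <- outer(outer(sin(x / 9), cos(y / 11)), sin(z / 8)) + 2
  v <- pet_volume(smooth, sp)
  back <- resample_isotropic(resample_isotropic(v, 2), 3)
  n <- pmin(dim(back$values), d)
  a <- back$values[1:n[1], 1:n[2], 1:n[3]]
  b <- smooth[1:n[1], 1:n[2], 1:n[3]]
  rms <- sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
  expect_lt(rms, 0.01)
})

test_that("mask resampling is nearest-neighbour and preserves labels", {
  p <- tiny_phantom_params()
  mask <- petvasc:::phantom_mask(p)
  r <- resample_isotropic(mask, 2)
  expect_s3_class(r, "segment_mask")
  expect_setequal(unique(as.vector(r$values)), 0:4)
  # every segment survives with roughly scaled voxel counts
  n_in <- tabulate(mask$values, 4)
  n_out <- tabulate(r$values, 4)
  scale <- prod(mask$spacing) / 8
  expect_true(all(abs(n_out - n_in * scale) / (n_in * scale) < 0.25))
})
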