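# Radiomic feature extraction: manifest contract, oracle equivalence of
# every texture matrix on small grids, limit conventions, invariances,
# and correlation pruning.

toy_roi_3x3 <- function() {
  # the 3x3x1 toy grid {1,1,2, 2,2,3, 3,3,3}
  vals <- array(c(1, 1, 2, 2, 2, 3, 3, 3, 3), c(3, 3, 1))
  list(vol = sul_volume(vals, c(1, 1, 1)),
       mask = array(TRUE, c(3, 3, 1)),
       arr = array(as.integer(vals), c(3, 3, 1)))
}

test_that("feature vector matches the 95-name manifest on a phantom segment", {
  tab <- baseline_table()
  fnames <- setdiff(names(tab), c("patient_id", "scan_id", "segment",
                                  "group", "calc_score", "scan_type"))
  expect_identical(fnames, feature_manifest())
  expect_true(all(vapply(tab[fnames], function(x) all(is.finite(x)),
                         logical(1))))
})

test_that("first-order entropy of the toy grid matches the hand-computed value", {
  toy <- toy_roi_3x3()
  fv <- extract_features(toy$vol, toy$mask,
                         settings = discretisation_settings(
                           bin_width = 1, min_roi_voxels = 5))
  p <- c(2, 3, 4) / 9
  expect_equal(unname(fv["fos_Entropy"]), -sum(p * log2(p)), tolerance = 1e-12)
  expect_equal(unname(fv["fos_Uniformity"]), sum(p^2), tolerance = 1e-12)
  expect_equal(unname(fv["SULmax"]), 3)
  expect_equal(unname(fv["SULmean"]), mean(toy$arr))
})

test_that("GLRLM of the toy grid matches exhaustive run enumeration", {
  toy <- toy_roi_3x3()
  roi <- petvasc:::roi_from_mask(toy$vol$values, toy$mask, 1)
  dirs <- petvasc:::neighbour_directions_13()
  glns <- numeric(nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    impl <- petvasc:::glrlm_matrix(roi, dirs[r, ])
    orac <- naive_glrlm(toy$arr, dirs[r, ], ng = 3)
    expect_equal(unname(impl), unname(orac))
    glns[r] <- sum(rowSums(orac)^2) / sum(orac)
  }
  fv <- extract_features(toy$vol, toy$mask,
                         settings = discretisation_settings(
                           bin_width = 1, min_roi_voxels = 5))
  expect_equal(unname(fv["glrlm_GrayLevelNonUniformity"]), mean(glns),
               tolerance = 1e-12)
})

test_that("texture matrices equal brute-force oracles on random ROIs", {
  dirs <- petvasc:::neighbour_directions_13()
  for (seed in c(11, 12, 13)) {
    arr <- random_toy_roi(seed)
    arr <- arr - min(arr, na.rm = TRUE) + 1L   # levels start at 1
    vals <- array(as.numeric(arr), dim(arr))
    vals[is.na(vals)] <- 0
    roi <- petvasc:::roi_from_mask(vals, !is.na(arr), 1)
    ng <- max(arr, na.rm = TRUE)
    for (r in seq_len(nrow(dirs))) {
      org <- naive_glcm(arr, dirs[r, ], ng)
      impl <- petvasc:::glcm_matrix(roi, dirs[r, ])
      if (is.null(org)) {
        expect_null(impl)
      } else {
        expect_equal(unname(impl), unname(org), tolerance = 1e-12)
      }
      expect_equal(unname(petvasc:::glrlm_matrix(roi, dirs[r, ])),
                   unname(naive_glrlm(arr, dirs[r, ], ng)))
    }
    expect_equal(unname(petvasc:::glszm_matrix(roi)),
                 unname(naive_glszm(arr, ng)))
    nb <- petvasc:::neighbour_stats(roi)
    dep <- nb$eq + 1L
    dmax <- max(dep)
    gldm_impl <- matrix(tabulate(roi$g + (dep - 1L) * ng, ng * dmax),
                        ng, dmax)
    expect_equal(unname(gldm_impl), unname(naive_gldm(arr, ng)))
  }
})

test_that("NGTDM features match formulas applied to the brute-force s/n vectors", {
  arr <- random_toy_roi(21)
  arr <- arr - min(arr, na.rm = TRUE) + 1L
  vals <- array(as.numeric(arr), dim(arr)); vals[is.na(vals)] <- 0
  roi <- petvasc:::roi_from_mask(vals, !is.na(arr), 1)
  impl <- petvasc:::ngtdm_features(roi)
  o <- naive_ngtdm(arr, max(arr, na.rm = TRUE))
  nvp <- sum(o$n); p_i <- o$n / nvp
  act <- which(p_i > 0); ngp <- length(act)
  coarse <- if (sum(p_i * o$s) > 0) 1 / sum(p_i * o$s) else 1e6
  contr <- (sum(outer(p_i[act], p_i[act]) * outer(act, act, `-`)^2) /
              (ngp * (ngp - 1))) * sum(o$s) / nvp
  busy <- sum(p_i * o$s) /
    sum(abs(outer(act * p_i[act], act * p_i[act], `-`)))
  v <- p_i[act] * o$s[act]
  compl <- sum(abs(outer(act, act, `-`)) * outer(v, v, `+`) /
                 outer(p_i[act], p_i[act], `+`)) / nvp
  stren <- sum(outer(p_i[act], p_i[act], `+`) * outer(act, act, `-`)^2) /
    sum(o$s)
  expect_equal(unname(impl),
               c(coarse, contr, busy, compl, stren), tolerance = 1e-10)
})

test_that("constant ROIs follow the documented limit conventions", {
  vol <- sul_volume(array(2.5, c(5, 5, 3)), c(2, 2, 2))
  mask <- array(TRUE, c(5, 5, 3))
  fv <- extract_features(vol, mask)
  expect_equal(unname(fv["SULmax"]), 2.5)
  expect_equal(unname(fv["SULmean"]), 2.5)
  expect_equal(unname(fv["fos_Variance"]), 0)
  expect_equal(unname(fv["fos_Skewness"]), 0)
  expect_equal(unname(fv["fos_Kurtosis"]), 0)
  expect_equal(unname(fv["fos_Entropy"]), 0)
  expect_true(all(is.finite(fv)))
})

test_that("degenerate ROIs raise a typed error", {
  vol <- sul_volume(array(1, c(4, 4, 4)), c(2, 2, 2))
  mask <- array(FALSE, c(4, 4, 4))
  mask[1:2, 1, 1] <- TRUE
  expect_error(extract_features(vol, mask),
               class = "petvasc_degenerate_roi")
})

test_that("features are invariant to ROI translation and discretisation anchors track the minimum", {
  set.seed(5)
  block <- array(runif(4 * 4 * 3, 1, 3), c(4, 4, 3))
  place <- function(at) {
    vals <- array(0, c(12, 12, 9))
    mask <- array(FALSE, c(12, 12, 9))
    vals[at[1]:(at[1] + 3), at[2]:(at[2] + 3), at[3]:(at[3] + 2)] <- block
    mask[at[1]:(at[1] + 3), at[2]:(at[2] + 3), at[3]:(at[3] + 2)] <- TRUE
    extract_features(sul_volume(vals, c(2, 2, 2)), mask)
  }
  expect_equal(place(c(1, 1, 1)), place(c(7, 5, 4)), tolerance = 1e-12)

  # adding a constant shifts intensity features, leaves texture unchanged
  vals <- array(0, c(8, 8, 5)); mask <- array(FALSE, c(8, 8, 5))
  vals[2:5, 2:5, 2:4] <- block; mask[2:5, 2:5, 2:4] <- TRUE
  f0 <- extract_features(sul_volume(vals, c(2, 2, 2)), mask)
  f1 <- extract_features(sul_volume(vals + 0.8 * mask, c(2, 2, 2)), mask)
  expect_equal(unname(f1["SULmean"] - f0["SULmean"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(f1["SULmax"] - f0["SULmax"]), 0.8, tolerance = 1e-12)
  texture <- grep("^(glcm|glrlm|glszm|ngtdm|gldm)_", names(f0), value = TRUE)
  expect_equal(f1[texture], f0[texture], tolerance = 1e-12)
})

test_that("correlation pruning follows the greedy rule", {
  set.seed(9)
  n <- 2000
  x1 <- rnorm(n)
  # target correlations r12 = r13 = 0.95, r23 = 0.85
  S <- matrix(c(1, .95, .95, .95, 1, .85, .95, .85, 1), 3)
  L <- chol(S)
  M <- matrix(rnorm(n * 3), n) %*% L
  colnames(M) <- c("a", "b", "c")
  out <- prune_correlated(M, threshold = 0.9)
  expect_identical(out$kept, "a")
  expect_identical(out$dropped, c("b", "c"))

  dup <- cbind(M[, 1, drop = FALSE], M[, 1, drop = FALSE])
  colnames(dup) <- c("f1", "f2")
  out2 <- prune_correlated(dup)
  expect_identical(out2$kept, "f1")
  expect_identical(out2$dropped, "f2")

  set.seed(10)
  ind <- matrix(rnorm(500 * 8), 500)
  colnames(ind) <- paste0("g", 1:8)
  out3 <- prune_correlated(ind)
  expect_length(out3$dropped, 0)

  cst <- cbind(M, konst = 1)
  expect_warning(out4 <- prune_correlated(cst), "zero-variance")
  expect_true("konst" %in% out4$kept)
})

test_that("pruning agrees with the brute-force oracle on random tables", {
  for (s in 1:50) {
    set.seed(s)
    n <- 60; p <- 12
    base <- matrix(rnorm(n * 4), n)
    M <- base[, sample(4, p, replace = TRUE)] + 0.6 * matrix(rnorm(n * p), n)
    colnames(M) <- sprintf("v%02d", 1:p)
    expect_identical(prune_correlated(M), brute_prune(M))
  }
})
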