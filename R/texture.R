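# Texture-matrix construction and per-family feature formulas over a
# discretised region of interest. Definitions follow the IBSI reference:
# grey-level co-occurrence (GLCM) and run-length (GLRLM) matrices are built
# per 3D direction (13 unique directions of the 26-neighbourhood) and the
# per-direction feature values averaged; size-zone (GLSZM), neighbouring
# grey-tone difference (NGTDM) and dependence (GLDM) matrices use the full
# 26-connected neighbourhood once.
#
# All functions take `roi`: a list with
#   g      - integer grey level (1..ng) per ROI voxel
#   coords - voxel coordinates (N x 3)
#   dim    - dimensions of the (cropped) grid
#   arr    - 3D array of grey levels, NA outside the ROI
#   ng     - number of grey levels

xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

# linear indices of coords shifted by direction d, NA when out of bounds
shift_linear <- function(coords, d, dm) {
  sc <- sweep(coords, 2, d, `+`)
  ok <- sc[, 1] >= 1 & sc[, 1] <= dm[1] &
        sc[, 2] >= 1 & sc[, 2] <= dm[2] &
        sc[, 3] >= 1 & sc[, 3] <= dm[3]
  lin <- rep(NA_integer_, nrow(sc))
  lin[ok] <- sc[ok, 1] + (sc[ok, 2] - 1L) * dm[1] +
    (sc[ok, 3] - 1L) * dm[1] * dm[2]
  lin
}

roi_from_mask <- function(values, mask_logical, bin_width) {
  idx <- which(mask_logical)
  coords <- arrayInd(idx, dim(mask_logical))
  # crop to the bounding box to keep shifted-index work small
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  dm <- as.integer(hi - lo + 1L)
  coords <- sweep(coords, 2, lo - 1L)
  x <- values[idx]
  g <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  ng <- max(g)
  arr <- array(NA_integer_, dm)
  arr[coords[, 1] + (coords[, 2] - 1L) * dm[1] +
        (coords[, 3] - 1L) * dm[1] * dm[2]] <- g
  list(x = x, g = g, coords = coords, dim = dm, arr = arr, ng = ng,
       n = length(idx))
}

# ---- GLCM ----------------------------------------------------------------

glcm_matrix <- function(roi, d) {
  lin2 <- shift_linear(roi$coords, d, roi$dim)
  g2 <- rep(NA_integer_, length(lin2))
  ok <- !is.na(lin2)
  g2[ok] <- roi$arr[lin2[ok]]
  ok <- ok & !is.na(g2)
  if (!any(ok)) return(NULL)
  ng <- roi$ng
  cnt <- tabulate(roi$g[ok] + (g2[ok] - 1L) * ng, nbins = ng * ng)
  P <- matrix(cnt, ng, ng)
  P <- P + t(P)                     # symmetric co-occurrence
  P / sum(P)
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mux <- sum(seq_len(ng) * px)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  # difference and sum marginals
  k_diff <- 0:(ng - 1)
  pd <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  ps <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * pd)
  hxy <- -sum(p * xlog2(p))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * xlog2(pxpy))
  hxy2 <- -sum(pxpy * xlog2(pxpy))
  hx <- -sum(px * xlog2(px))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0  # HX = HY for symmetric p
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sx > 0) (sum(i * j * p) - mux^2) / sx^2 else 1
  # maximal correlation coefficient via the Q matrix (levels with mass only)
  mcc <- {
    act <- px > 0
    if (sum(act) < 2) 1 else {
      psub <- p[act, act, drop = FALSE]
      psub <- psub / sum(psub)
      mcc_from(psub, rowSums(psub))
    }
  }
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mux)^4 * p),
    ClusterShade = sum((i + j - 2 * mux)^3 * p),
    ClusterTendency = sum((i + j - 2 * mux)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * xlog2(pd)),
    DifferenceVariance = sum((k_diff - da)^2 * pd),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * ps),
    SumEntropy = -sum(ps * xlog2(ps)),
    SumSquares = sum((i - mux)^2 * p))
}

# Q[i,j] = sum_k p(i,k) p(j,k) / (px_i px_k); MCC is the square root of its
# second-largest eigenvalue. Assumes symmetric p with strictly positive px.
mcc_from <- function(p, px) {
  Q <- sweep(p %*% t(p / px), 1, px, `/`)
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(ev[2], 0))
}

glcm_features <- function(roi) {
  dirs <- neighbour_directions_13()
  mats <- lapply(seq_len(nrow(dirs)), function(r) glcm_matrix(roi, dirs[r, ]))
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) == 0) mats <- list(matrix(1, 1, 1))
  rowMeans(vapply(mats, glcm_features_one, numeric(24)))
}

# ---- GLRLM ---------------------------------------------------------------

glrlm_matrix <- function(roi, d) {
  a0 <- which(d != 0)[1]
  t <- roi$coords[, a0] * sign(d[a0])
  key <- roi$coords - outer(t, d)     # line identifier (origin of the line)
  M <- 3 * max(roi$dim) + 3           # radix wide enough for signed digits
  keyid <- key[, 1] + key[, 2] * M + key[, 3] * M^2
  ord <- order(keyid, t)
  ks <- keyid[ord]; ts <- t[ord]; gs <- roi$g[ord]
  brk <- c(TRUE, ks[-1] != ks[-length(ks)] |
             ts[-1] != ts[-length(ts)] + 1L |
             gs[-1] != gs[-length(gs)])
  run_id <- cumsum(brk)
  run_len <- tabulate(run_id)
  run_g <- gs[brk]
  nr_max <- max(run_len)
  cnt <- tabulate(run_g + (run_len - 1L) * roi$ng, nbins = roi$ng * nr_max)
  matrix(cnt, roi$ng, nr_max)
}

# Shared formulas for level-by-size matrices (GLRLM runs, GLSZM zones).
level_size_features <- function(P, n_vox, names_map) {
  ns <- sum(P)
  i <- row(P); s <- col(P)
  p <- P / ns
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  ri <- rowSums(P); cs <- colSums(P)
  vals <- c(
    small = sum(P / col(P)^2) / ns,
    large = sum(P * col(P)^2) / ns,
    gln = sum(ri^2) / ns,
    glnn = sum(ri^2) / ns^2,
    sn = sum(cs^2) / ns,
    snn = sum(cs^2) / ns^2,
    pct = ns / n_vox,
    glv = sum((i - mu_i)^2 * p),
    sv = sum((s - mu_s)^2 * p),
    ent = -sum(p * xlog2(p)),
    lgl = sum(P / row(P)^2) / ns,
    hgl = sum(P * row(P)^2) / ns,
    sl = sum(P / (row(P)^2 * col(P)^2)) / ns,
    sh = sum(P * row(P)^2 / col(P)^2) / ns,
    ll = sum(P * col(P)^2 / row(P)^2) / ns,
    lh = sum(P * row(P)^2 * col(P)^2) / ns)
  stats::setNames(vals, names_map)
}

GLRLM_NAMES <- c("ShortRunEmphasis", "LongRunEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                 "RunPercentage", "GrayLevelVariance", "RunVariance",
                 "RunEntropy", "LowGrayLevelRunEmphasis",
                 "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                 "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                 "LongRunHighGrayLevelEmphasis")

GLSZM_NAMES <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                 "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                 "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                 "SmallAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis",
                 "LargeAreaHighGrayLevelEmphasis")

glrlm_features <- function(roi) {
  dirs <- neighbour_directions_13()
  feats <- vapply(seq_len(nrow(dirs)), function(r) {
    level_size_features(glrlm_matrix(roi, dirs[r, ]), roi$n, GLRLM_NAMES)
  }, numeric(16))
  rowMeans(feats)
}

# ---- GLSZM ---------------------------------------------------------------

glszm_matrix <- function(roi) {
  dirs <- neighbour_directions_13()
  n <- roi$n
  # voxel index within the ROI, by linear position in the cropped grid
  pos <- roi$coords[, 1] + (roi$coords[, 2] - 1L) * roi$dim[1] +
    (roi$coords[, 3] - 1L) * roi$dim[1] * roi$dim[2]
  roi_id <- rep(NA_integer_, prod(roi$dim))
  roi_id[pos] <- seq_len(n)
  edges <- lapply(seq_len(nrow(dirs)), function(r) {
    lin2 <- shift_linear(roi$coords, dirs[r, ], roi$dim)
    ok <- !is.na(lin2)
    nb <- rep(NA_integer_, n)
    nb[ok] <- roi_id[lin2[ok]]
    ok <- !is.na(nb) & roi$g == roi$g[pmax(nb, 1L)] & !is.na(nb)
    cbind(which(ok), nb[ok])
  })
  edges <- do.call(rbind, edges)
  gr <- igraph::make_graph(if (is.null(edges) || nrow(edges) == 0) integer(0)
                           else as.vector(t(edges)),
                           n = n, directed = FALSE)
  comp <- igraph::components(gr)
  zone_size <- comp$csize
  zone_g <- roi$g[match(seq_len(comp$no), comp$membership)]
  smax <- max(zone_size)
  cnt <- tabulate(zone_g + (zone_size - 1L) * roi$ng, nbins = roi$ng * smax)
  matrix(cnt, roi$ng, smax)
}

glszm_features <- function(roi) {
  level_size_features(glszm_matrix(roi), roi$n, GLSZM_NAMES)
}

# ---- neighbourhood sums shared by NGTDM and GLDM -------------------------

neighbour_stats <- function(roi) {
  dirs <- neighbour_directions_26()
  n <- roi$n
  sum_nb <- numeric(n); cnt_nb <- integer(n); eq_nb <- integer(n)
  for (r in seq_len(nrow(dirs))) {
    lin2 <- shift_linear(roi$coords, dirs[r, ], roi$dim)
    ok <- !is.na(lin2)
    g2 <- rep(NA_integer_, n)
    g2[ok] <- roi$arr[lin2[ok]]
    ok <- !is.na(g2)
    sum_nb[ok] <- sum_nb[ok] + g2[ok]
    cnt_nb[ok] <- cnt_nb[ok] + 1L
    eq_nb[ok] <- eq_nb[ok] + (g2[ok] == roi$g[ok])
  }
  list(sum = sum_nb, cnt = cnt_nb, eq = eq_nb)
}

ngtdm_features <- function(roi, nb = neighbour_stats(roi)) {
  valid <- nb$cnt > 0
  g <- roi$g[valid]
  abar <- nb$sum[valid] / nb$cnt[valid]
  nvp <- sum(valid)
  ng <- roi$ng
  n_i <- tabulate(g, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(abs(i - abar)[g == i]), numeric(1))
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) * outer(act, act, `-`)^2) /
       (ngp * (ngp - 1))) * (sum(s_i) / nvp)
  } else 0
  busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], `-`)))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  complexity <- if (ngp > 0) {
    v <- p_i[act] * s_i[act]
    sum(abs(outer(act, act, `-`)) * outer(v, v, `+`) /
          outer(p_i[act], p_i[act], `+`)) / nvp
  } else 0
  strength <- if (sum(s_i) > 0) {
    sum(outer(p_i[act], p_i[act], `+`) * outer(act, act, `-`)^2) / sum(s_i)
  } else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

GLDM_NAMES <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")

gldm_features <- function(roi, nb = neighbour_stats(roi)) {
  dep <- nb$eq + 1L     # dependence count includes the centre voxel
  dmax <- max(dep)
  cnt <- tabulate(roi$g + (dep - 1L) * roi$ng, nbins = roi$ng * dmax)
  P <- matrix(cnt, roi$ng, dmax)
  nz <- sum(P)
  p <- P / nz
  i <- row(P); d <- col(P)
  mu_i <- sum(i * p); mu_d <- sum(d * p)
  vals <- c(sum(P / d^2) / nz,
            sum(P * d^2) / nz,
            sum(rowSums(P)^2) / nz,
            sum(colSums(P)^2) / nz,
            sum(colSums(P)^2) / nz^2,
            sum((i - mu_i)^2 * p),
            sum((d - mu_d)^2 * p),
            -sum(p * xlog2(p)),
            sum(P / i^2) / nz,
            sum(P * i^2) / nz,
            sum(P / (i^2 * d^2)) / nz,
            sum(P * i^2 / d^2) / nz,
            sum(P * d^2 / i^2) / nz,
            sum(P * i^2 * d^2) / nz)
  stats::setNames(vals, GLDM_NAMES)
}
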