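# Independent brute-force oracles: naive, loop-based re-derivations of the
# texture matrices and decision rules, used to validate the vectorised
# implementations on small inputs. Deliberately written in the most direct
# style possible and kept free of any package internals.

in_roi <- function(arr, v) {
  all(v >= 1) && all(v <= dim(arr)) && !is.na(arr[v[1], v[2], v[3]])
}

# symmetric normalised co-occurrence matrix for one direction
naive_glcm <- function(arr, d, ng = max(arr, na.rm = TRUE)) {
  C <- matrix(0, ng, ng)
  dm <- dim(arr)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (is.na(arr[i, j, k])) next
    v2 <- c(i, j, k) + d
    if (in_roi(arr, v2)) {
      g1 <- arr[i, j, k]; g2 <- arr[v2[1], v2[2], v2[3]]
      C[g1, g2] <- C[g1, g2] + 1
    }
  }
  P <- C + t(C)
  if (sum(P) == 0) NULL else P / sum(P)
}

# run-length matrix for one direction by walking each run start
naive_glrlm <- function(arr, d, ng = max(arr, na.rm = TRUE)) {
  dm <- dim(arr)
  runs <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    v <- c(i, j, k)
    if (!in_roi(arr, v)) next
    g <- arr[i, j, k]
    prev <- v - d
    is_start <- !in_roi(arr, prev) || arr[prev[1], prev[2], prev[3]] != g
    if (!is_start) next
    len <- 0L
    w <- v
    while (in_roi(arr, w) && arr[w[1], w[2], w[3]] == g) {
      len <- len + 1L
      w <- w + d
    }
    runs[[length(runs) + 1L]] <- c(g, len)
  }
  rm_ <- do.call(rbind, runs)
  P <- matrix(0, ng, max(rm_[, 2]))
  for (r in seq_len(nrow(rm_))) {
    P[rm_[r, 1], rm_[r, 2]] <- P[rm_[r, 1], rm_[r, 2]] + 1
  }
  P
}

offsets26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
offsets26 <- offsets26[rowSums(abs(offsets26)) > 0, ]

# size-zone matrix by BFS flood fill over the 26-neighbourhood
naive_glszm <- function(arr, ng = max(arr, na.rm = TRUE)) {
  dm <- dim(arr)
  seen <- array(FALSE, dm)
  zones <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (is.na(arr[i, j, k]) || seen[i, j, k]) next
    g <- arr[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (r in seq_len(nrow(offsets26))) {
        w <- v + offsets26[r, ]
        if (in_roi(arr, w) && !seen[w[1], w[2], w[3]] &&
            arr[w[1], w[2], w[3]] == g) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  zm <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) P[zm[r, 1], zm[r, 2]] <- P[zm[r, 1], zm[r, 2]] + 1
  P
}

# dependence matrix: d = 1 + number of equal-level 26-neighbours
naive_gldm <- function(arr, ng = max(arr, na.rm = TRUE)) {
  dm <- dim(arr)
  deps <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (is.na(arr[i, j, k])) next
    g <- arr[i, j, k]
    dep <- 1L
    for (r in seq_len(nrow(offsets26))) {
      w <- c(i, j, k) + offsets26[r, ]
      if (in_roi(arr, w) && arr[w[1], w[2], w[3]] == g) dep <- dep + 1L
    }
    deps[[length(deps) + 1L]] <- c(g, dep)
  }
  dmat <- do.call(rbind, deps)
  P <- matrix(0, ng, max(dmat[, 2]))
  for (r in seq_len(nrow(dmat))) {
    P[dmat[r, 1], dmat[r, 2]] <- P[dmat[r, 1], dmat[r, 2]] + 1
  }
  P
}

# per-level NGTDM absolute-difference sums s_i and level counts n_i
naive_ngtdm <- function(arr, ng = max(arr, na.rm = TRUE)) {
  dm <- dim(arr)
  s <- numeric(ng); n <- integer(ng)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (is.na(arr[i, j, k])) next
    g <- arr[i, j, k]
    nb <- c()
    for (r in seq_len(nrow(offsets26))) {
      w <- c(i, j, k) + offsets26[r, ]
      if (in_roi(arr, w)) nb <- c(nb, arr[w[1], w[2], w[3]])
    }
    if (!length(nb)) next
    n[g] <- n[g] + 1L
    s[g] <- s[g] + abs(g - mean(nb))
  }
  list(s = s, n = n)
}

# exhaustive Youden search: evaluate J on a fine sweep of thresholds and
# return the maximum J (the threshold itself is checked via its J value)
brute_youden_J <- function(probs, active) {
  cand <- sort(unique(c(-Inf, Inf, probs - 1e-9, probs + 1e-9, probs)))
  max(vapply(cand, function(th) {
    mean(probs[active] >= th) + mean(probs[!active] < th) - 1
  }, numeric(1)))
}

youden_J_at <- function(th, probs, active) {
  mean(probs[active] >= th) + mean(probs[!active] < th) - 1
}

# greedy correlation pruning with explicitly hand-computed Pearson r
brute_prune <- function(mat, threshold = 0.9) {
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  kept <- integer(0)
  dropped <- integer(0)
  for (j in seq_len(ncol(mat))) {
    drop_j <- FALSE
    for (k in kept) {
      if (abs(pearson(mat[, j], mat[, k])) > threshold) { drop_j <- TRUE; break }
    }
    if (drop_j) dropped <- c(dropped, j) else kept <- c(kept, j)
  }
  list(kept = colnames(mat)[kept], dropped = colnames(mat)[dropped])
}

# small random discretised ROI on a grid, with a random non-cuboid mask
random_toy_roi <- function(seed, dm = c(6, 6, 4), ng = 4) {
  set.seed(seed)
  arr <- array(sample.int(ng, prod(dm), replace = TRUE), dm)
  keep <- array(runif(prod(dm)) < 0.7, dm)
  arr[!keep] <- NA_integer_
  if (all(is.na(arr))) arr[1, 1, 1] <- 1L
  arr
}
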