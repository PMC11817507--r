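# Scan-level aggregation, the Youden threshold and diagnostic reporting.

test_that("scan aggregation takes the maximum segment probability", {
  expect_equal(aggregate_scan(c(ascending = 0.45, descending = 0.75,
                                arch = 0.66, abdominal = 0.74)), 0.75)
  expect_equal(aggregate_scan(rep(0.5, 4)), 0.5)
  expect_equal(aggregate_scan(0.31), 0.31)
  expect_error(aggregate_scan(numeric(0)), class = "petvasc_validation_error")
  expect_error(aggregate_scan(c(0.2, 1.4)), class = "petvasc_validation_error")
})

test_that("aggregation is monotone in every segment probability", {
  set.seed(8)
  for (i in 1:50) {
    p <- runif(4)
    j <- sample(4, 1)
    q <- p; q[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_gte(aggregate_scan(q), aggregate_scan(p))
  }
})

test_that("the Youden cutoff solves the printed 4-point example and separable cases", {
  # probs (0.2-, 0.4+, 0.6-, 0.8+): max J = 0.5, ties resolved high -> 0.7
  th <- youden_cutoff(c(0.2, 0.4, 0.6, 0.8), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(th, 0.7)

  sep <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep, 0.5)  # midpoint of the separating gap, J = 1
  expect_equal(youden_J_at(sep, c(0.1, 0.2, 0.8, 0.9),
                           c(FALSE, FALSE, TRUE, TRUE)), 1)

  expect_error(youden_cutoff(c(0.2, 0.8), c(TRUE, TRUE)),
               class = "petvasc_validation_error")
})

test_that("the Youden cutoff matches exhaustive search on 200 random instances", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    probs <- round(runif(n), sample(c(1, 2, 3), 1))  # force ties sometimes
    active <- runif(n) < 0.5
    if (length(unique(active)) < 2) active[1:2] <- c(TRUE, FALSE)
    th <- youden_cutoff(probs, active)
    expect_equal(youden_J_at(th, probs, active),
                 brute_youden_J(probs, active), tolerance = 1e-12)
    # ties resolved high: no candidate threshold above th reaches max J
    u <- sort(unique(probs))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
    above <- c(mids[mids > th], if (is.finite(th) || th < Inf) Inf)
    jmax <- brute_youden_J(probs, active)
    for (cand in above) {
      expect_lt(youden_J_at(cand, probs, active), jmax - 1e-12)
    }
  }
})

test_that("Wilson intervals contain the point estimate and stay in [0, 1]", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    expect_true(ci[1] <= x / n + 1e-12 && ci[2] >= x / n - 1e-12)
  }
  expect_true(all(is.na(wilson_ci(0, 0))))
})

test_that("diagnostic reports reproduce the reconstructed follow-up confusion matrices", {
  # 19 scans, 7 active: tp 5, fp 1, fn 2, tn 11
  rep1 <- diagnostic_report(counts = c(tp = 5, fp = 1, fn = 2, tn = 11))
  expect_equal(round(rep1$ppv, 2), 0.83)
  expect_equal(round(rep1$npv, 2), 0.85)
  expect_equal(round(rep1$accuracy, 2), 0.84)
  expect_equal(round(rep1$ppv_ci, 2), c(0.44, 0.97))

  # clinical-report comparator: tp 4, fp 1, fn 3, tn 11
  rep2 <- diagnostic_report(counts = c(tp = 4, fp = 1, fn = 3, tn = 11))
  expect_equal(round(rep2$ppv, 2), 0.80)
  expect_equal(round(rep2$npv, 2), 0.79)
  expect_equal(round(rep2$accuracy, 2), 0.79)
})

test_that("diagnostic report handles perfect and degenerate inputs", {
  all_right <- diagnostic_report(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(is.na(all_right$npv))
  perfect <- diagnostic_report(c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                 TRUE, FALSE, TRUE, FALSE, FALSE),
                               c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                 TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$accuracy_ci[2], 1)
  expect_lt(perfect$accuracy_ci[1], 1)

  none_pos <- diagnostic_report(rep(FALSE, 6), c(TRUE, rep(FALSE, 5)))
  expect_true(is.na(none_pos$ppv))
  expect_true(all(is.na(none_pos$ppv_ci)))
})

test_that("per-scan decisions group segments and apply the threshold", {
  recs <- data.frame(
    scan_id = rep(c("s1", "s2"), each = 4),
    segment = rep(c("ascending", "arch", "descending", "abdominal"), 2))
  probs <- c(0.45, 0.66, 0.75, 0.74, 0.1, 0.2, 0.15, 0.05)
  dec <- scan_decisions(recs, probs, threshold = 0.7)
  expect_equal(nrow(dec), 2)
  expect_equal(dec$scan_prob[dec$scan_id == "s1"], 0.75)
  expect_equal(dec$call[dec$scan_id == "s1"], "active")
  expect_equal(dec$scan_prob[dec$scan_id == "s2"], 0.2)
  expect_equal(dec$call[dec$scan_id == "s2"], "inactive")
})
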