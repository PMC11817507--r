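# Model grid: enumeration, leakage-safe cross-validation, final-model
# selection and test-set scoring.

test_that("grid enumeration is the Cartesian product in deterministic order", {
  g <- enumerate_grid()
  expect_equal(nrow(g), 441)
  expect_equal(nrow(enumerate_grid("anova", 10, "random_forest")), 1)
  expect_equal(nrow(enumerate_grid(c("a", "b"), c(2, 4, 6),
                                   c("w", "x", "y", "z"))), 24)
  expect_false(any(duplicated(g$config_id)))
  expect_identical(enumerate_grid(), g)
  expect_error(enumerate_grid(character(0), 10, "rf"),
               class = "petvasc_validation_error")
})

test_that("cross-validation folds are patient-wise and group-stratified", {
  recs <- simulate_segment_records(10, 10, 10, seed = 4)
  folds <- petvasc:::make_patient_folds(recs, 5, seed = 1)
  # each patient in exactly one fold
  expect_setequal(names(folds), unique(recs$patient_id))
  # both groups spread over all folds (10 patients per group, 5 folds)
  for (f in 1:5) {
    pats <- names(folds)[folds == f]
    expect_setequal(unique(recs$group[recs$patient_id %in% pats]),
                    c("GCA", "ATHERO"))
  }
  expect_error(petvasc:::make_patient_folds(recs[1:8, ], 10, 1),
               class = "petvasc_validation_error")
})

test_that("a separable table is classified perfectly and reproducibly", {
  tab <- make_separable_table(n_patients = 20, delta = 3, seed = 1)
  cfg <- list(selector = "anova", n_features = 5L,
              classifier = "random_forest", config_id = "sep")
  r1 <- cross_validate(cfg, tab, n_folds = 5, seed = 3)
  expect_equal(r1$auc_mean, 1.0)
  r2 <- cross_validate(cfg, tab, n_folds = 5, seed = 3)
  expect_identical(r1$fold_aucs, r2$fold_aucs)
  expect_gte(r1$ppv_mean, 0.95)
  expect_gte(r1$npv_mean, 0.95)
})

test_that("every registered selector and classifier runs and separates the easy task", {
  tab <- make_separable_table(n_patients = 16, n_feat = 12, delta = 4,
                              seed = 2)
  for (sel in selector_registry()) {
    cfg <- list(selector = sel, n_features = 5L,
                classifier = "logistic", config_id = paste0(sel, "_lg"))
    r <- suppressWarnings(cross_validate(cfg, tab, n_folds = 4, seed = 1))
    expect_gte(r$auc_mean, 0.9)
  }
  for (cls in classifier_registry()) {
    cfg <- list(selector = "anova", n_features = 5L, classifier = cls,
                config_id = paste0("an_", cls))
    r <- suppressWarnings(cross_validate(cfg, tab, n_folds = 4, seed = 1))
    expect_gte(r$auc_mean, 0.9)
  }
})

fake_result <- function(id, auc, ppv, npv, k) {
  structure(list(config = list(selector = "s", n_features = k,
                               classifier = "c", config_id = id),
                 fold_aucs = rep(auc, 10), auc_mean = auc, auc_sd = 0,
                 ppv_mean = ppv, ppv_sd = 0, npv_mean = npv, npv_sd = 0,
                 models = list()), class = "grid_result")
}

test_that("final-model selection applies the documented tie-breaks", {
  single <- fake_result("only", 0.9, 0.8, 0.8, 10)
  expect_identical(select_final(list(single)), single)

  a <- fake_result("a", 0.9, 0.85, 0.75, 10)  # PPV+NPV = 1.6
  b <- fake_result("b", 0.9, 0.80, 0.70, 10)  # PPV+NPV = 1.5
  expect_identical(select_final(list(b, a))$config$config_id, "a")

  cs <- list(fake_result("k15", 0.9, 0.8, 0.8, 15),
             fake_result("k05", 0.9, 0.8, 0.8, 5),
             fake_result("k10", 0.9, 0.8, 0.8, 10))
  expect_equal(select_final(cs)$config$n_features, 5)
  expect_error(select_final(list()), class = "petvasc_validation_error")
})

test_that("test-set scoring demands disjoint patients and matches CV on separable data", {
  tab <- make_separable_table(n_patients = 24, delta = 3, seed = 5)
  ids <- unique(tab$patient_id)
  tr <- tab[tab$patient_id %in% ids[1:18], ]
  te <- tab[tab$patient_id %in% ids[19:24], ]
  cfg <- list(selector = "anova", n_features = 5L,
              classifier = "random_forest", config_id = "sep")
  res <- cross_validate(cfg, tr, n_folds = 5, seed = 2)
  perf <- fit_final_and_test(res, tr, te)
  expect_gte(perf$auc_mean, 0.99)
  expect_length(perf$probs, nrow(te))
  expect_true(all(perf$probs >= 0 & perf$probs <= 1))

  expect_error(fit_final_and_test(res, tr, tr[1:4, ]),
               class = "petvasc_leakage_error")
  expect_error(fit_final_and_test(res, tr, te[0, ]),
               class = "petvasc_validation_error")
})

test_that("capping n_features at the available columns warns but proceeds", {
  tab <- make_separable_table(n_patients = 12, n_feat = 8, delta = 3,
                              seed = 6)
  cfg <- list(selector = "correlation", n_features = 50L,
              classifier = "lda", config_id = "cap")
  expect_warning(r <- cross_validate(cfg, tab, n_folds = 4, seed = 1),
                 "capped")
  expect_gte(r$auc_mean, 0.9)
})
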