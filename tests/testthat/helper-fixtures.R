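# Shared fixtures, built once per test run and cached. The expensive ones
# (full phantom cohorts with feature extraction) are used by several test
# files; everything is seeded so the whole suite is reproducible.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small, fast phantom: coarse grid, vessel still fits
tiny_phantom_params <- function(n_gca = 2, n_athero = 2, ...) {
  phantom_params(n_gca = n_gca, n_athero = n_athero,
                 grid_shape = c(24L, 24L, 24L),
                 voxel_spacing = c(3.5, 3.5, 3.5), seed = 7L, ...)
}

# default-condition baseline cohort (20 + 20 patients) with features
baseline_table <- function() {
  fixture("baseline_table", function() {
    params <- phantom_params(seed = 42L)
    suppressWarnings(extract_cohort_features(generate_cohort(params)))
  })
}

# 25 + 25 patients -> 200 segments, for the label-permutation null
null_table <- function() {
  fixture("null_table", function() {
    params <- phantom_params(n_gca = 25, n_athero = 25, seed = 42L)
    suppressWarnings(extract_cohort_features(generate_cohort(params)))
  })
}

anova_rf_config <- function() {
  list(selector = "anova", n_features = 10L, classifier = "random_forest",
       config_id = "anova_k10_random_forest")
}

# the cross-validated reference model: ANOVA + 10 features + random forest
# on the calcification-filtered default cohort
trained_reference <- function() {
  fixture("trained_reference", function() {
    tab <- filter_calcified(baseline_table())
    pruned <- suppressWarnings(prune_correlated(tab))
    res <- suppressWarnings(cross_validate(anova_rf_config(), tab, seed = 5L,
                                           feature_names = pruned$kept))
    list(table = tab, pruned = pruned, result = res)
  })
}

# follow-up scan with one hot (active) segment, on the analysis grid
followup_hot_scan <- function() {
  fixture("followup_hot_scan", function() {
    params <- phantom_params(seed = 42L)
    scan <- generate_followup_scan(params, active = TRUE,
                                   active_segments = 3, seed = 77L)
    list(scan = scan,
         sul = resample_isotropic(to_sul(scan$pet, scan$meta), 2),
         mask = resample_isotropic(scan$mask, 2))
  })
}

# occlusion map of the hot follow-up scan under the reference model
reference_occlusion <- function() {
  fixture("reference_occlusion", function() {
    occlusion_map(followup_hot_scan()$sul, followup_hot_scan()$mask,
                  trained_reference()$result)
  })
}

# separable two-class table without any imaging: two Gaussian clouds
make_separable_table <- function(n_patients = 20, n_feat = 20, delta = 3,
                                 seed = 1) {
  set.seed(seed)
  groups <- rep(c("GCA", "ATHERO"), length.out = n_patients)
  ids <- sprintf("P%03d", seq_len(n_patients))
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    X <- matrix(rnorm(4 * n_feat), 4, n_feat)
    if (groups[i] == "GCA") X[, 1:5] <- X[, 1:5] + delta
    df <- data.frame(patient_id = ids[i], scan_id = paste0(ids[i], "_ba"),
                     segment = c("ascending", "arch", "descending",
                                 "abdominal"),
                     group = groups[i], calc_score = 0L,
                     scan_type = "baseline", stringsAsFactors = FALSE)
    cbind(df, as.data.frame(X))
  }))
  names(rows)[-(1:6)] <- sprintf("feat%02d", seq_len(n_feat))
  rownames(rows) <- NULL
  rows
}
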