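# The selector x feature-count x classifier model grid with patient-wise,
# group-stratified ten-fold cross-validation.
#
# Default registries hold seven univariate/embedded feature selectors and
# seven conventional classifiers; with nine candidate feature counts the
# default grid enumerates 7 x 9 x 7 = 441 configurations. Within every
# fold the selector is fitted on the fold-training rows only, the top-k
# features are passed to the classifier, and the fold-validation rows are
# scored; leakage of validation or test rows into selection or fitting is
# guarded by construction (and by the disjoint-patient assertion for the
# final test).

#' Default feature-selector registry
#'
#' Each selector scores features on the training rows and returns a
#' ranking: `anova` (one-way F statistic), `mutual_info` (histogram mutual
#' information with the class), `rfe` (recursive elimination driven by
#' linear-SVM weights), `l1` (order of entry along the lasso path),
#' `tree_importance` (random-forest Gini importance), `correlation`
#' (absolute point-biserial correlation), `chi2` (chi-squared statistic on
#' quartile-discretised features).
#'
#' @return Named character vector of selector names.
#' @export
selector_registry <- function() {
  c("anova", "mutual_info", "rfe", "l1", "tree_importance",
    "correlation", "chi2")
}

#' Default classifier registry
#'
#' `random_forest`, `logistic`, `svm_rbf`, `knn`, `naive_bayes`,
#' `gradient_boosting` (xgboost), `lda`.
#'
#' @return Character vector of classifier names.
#' @export
classifier_registry <- function() {
  c("random_forest", "logistic", "svm_rbf", "knn", "naive_bayes",
    "gradient_boosting", "lda")
}

#' Default candidate feature counts
#' @return Integer vector of length 9.
#' @export
feature_count_registry <- function() {
  c(2L, 4L, 6L, 8L, 10L, 15L, 20L, 25L, 30L)
}

#' Enumerate the model grid
#'
#' Cartesian product of the three registries in deterministic order
#' (classifier fastest, then feature count, then selector).
#'
#' @param selectors,feature_counts,classifiers Registry vectors.
#' @return A data frame of `model_config` rows: `selector`, `n_features`,
#'   `classifier`, `config_id`.
#' @export
enumerate_grid <- function(selectors = selector_registry(),
                           feature_counts = feature_count_registry(),
                           classifiers = classifier_registry()) {
  if (!length(selectors) || !length(feature_counts) || !length(classifiers)) {
    stop_petvasc("all three registries must be non-empty",
                 class = "petvasc_validation_error")
  }
  g <- expand.grid(classifier = classifiers,
                   n_features = as.integer(feature_counts),
                   selector = selectors,
                   stringsAsFactors = FALSE)[, c("selector", "n_features",
                                                 "classifier")]
  g$config_id <- sprintf("%s_k%02d_%s", g$selector, g$n_features,
                         g$classifier)
  g
}

# ---- selectors -----------------------------------------------------------

# All selectors: X numeric matrix (rows = segments), y factor with 2
# levels; return feature names ranked by decreasing importance.

rank_features <- function(selector, X, y, seed) {
  scores <- switch(selector,
    anova = apply(X, 2, function(f) {
      g <- split(f, y)
      n <- lengths(g); m <- vapply(g, mean, 0)
      gm <- mean(f)
      ssb <- sum(n * (m - gm)^2)
      ssw <- sum(vapply(seq_along(g), function(i) sum((g[[i]] - m[i])^2), 0))
      if (ssw <= 0) Inf else (ssb / 1) / (ssw / (length(f) - 2))
    }),
    mutual_info = apply(X, 2, mutual_info_score, y = y),
    correlation = abs(suppressWarnings(
      stats::cor(X, as.numeric(y) - 1)))[, 1],
    chi2 = apply(X, 2, function(f) {
      b <- cut(f, unique(stats::quantile(f, 0:4 / 4)), include.lowest = TRUE)
      if (nlevels(droplevels(b)) < 2) return(0)
      suppressWarnings(stats::chisq.test(table(b, y))$statistic)
    }),
    l1 = lasso_path_scores(X, y, seed),
    tree_importance = with_seed(seed, {
      rf <- randomForest::randomForest(X, y, ntree = 200)
      randomForest::importance(rf)[, 1]
    }),
    rfe = return(rfe_rank(X, y)),
    stop_petvasc(sprintf("unknown selector `%s`", selector),
                 class = "petvasc_validation_error"))
  scores[is.na(scores)] <- -Inf
  names(sort(scores, decreasing = TRUE))
}

mutual_info_score <- function(f, y, bins = 10L) {
  br <- unique(stats::quantile(f, seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(0)
  b <- cut(f, br, include.lowest = TRUE)
  joint <- table(b, y) / length(f)
  px <- rowSums(joint); py <- colSums(joint)
  e <- outer(px, py)
  sum(joint * xlog2(joint / ifelse(e > 0, e, 1)) * (joint > 0))
}

lasso_path_scores <- function(X, y, seed) {
  fit <- with_seed(seed, glmnet::glmnet(X, y, family = "binomial",
                                        standardize = TRUE, nlambda = 100))
  beta <- as.matrix(fit$beta)
  entry <- apply(beta != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  strength <- rowMeans(abs(beta))
  # earlier entry on the path ranks higher; mean |coef| breaks ties
  -(entry * 1e6 - strength)
}

# Recursive elimination with linear-SVM weights, dropping the weakest 20%
# per round; the elimination order (reversed) is the ranking.
rfe_rank <- function(X, y) {
  remaining <- colnames(X)
  eliminated <- character(0)
  while (length(remaining) > 1) {
    fit <- e1071::svm(X[, remaining, drop = FALSE], y, kernel = "linear",
                      scale = TRUE, cost = 1)
    w2 <- colSums((t(fit$coefs) %*% fit$SV)^2)[remaining]
    w2[is.na(w2)] <- 0
    n_drop <- max(1L, floor(0.2 * length(remaining)))
    drop_now <- names(sort(w2))[seq_len(n_drop)]
    eliminated <- c(drop_now, eliminated)
    remaining <- setdiff(remaining, drop_now)
  }
  c(remaining, eliminated)
}

# ---- classifiers ---------------------------------------------------------

# Fit on standardized training features; return an object with a
# predict_prob(newdata matrix) -> P(positive class) closure. The positive
# class is the first GROUP_LEVELS entry present ("GCA" / "active").

fit_classifier <- function(classifier, X, y, seed) {
  pos <- levels(y)[2]
  pred <- switch(classifier,
    random_forest = {
      fit <- with_seed(seed, randomForest::randomForest(X, y, ntree = 500))
      function(newX) stats::predict(fit, newX, type = "prob")[, pos]
    },
    logistic = {
      df <- data.frame(X, check.names = FALSE)
      fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                         family = stats::binomial()))
      function(newX) {
        suppressWarnings(stats::predict(fit,
          newdata = data.frame(newX, check.names = FALSE),
          type = "response"))
      }
    },
    svm_rbf = {
      fit <- with_seed(seed, e1071::svm(X, y, kernel = "radial",
                                        probability = TRUE, scale = FALSE))
      function(newX) {
        attr(stats::predict(fit, newX, probability = TRUE),
             "probabilities")[, pos]
      }
    },
    knn = {
      trainX <- X; trainy <- y
      function(newX) {
        cl <- class::knn(trainX, newX, trainy, k = 5, prob = TRUE)
        pr <- attr(cl, "prob")
        ifelse(cl == pos, pr, 1 - pr)
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(X, y)
      function(newX) stats::predict(fit, newX, type = "raw")[, pos]
    },
    gradient_boosting = {
      # xgboost encodes the second factor level as the positive class,
      # which matches `pos = levels(y)[2]`
      fit <- with_seed(seed, xgboost::xgboost(
        X, y, nrounds = 100, max_depth = 3, learning_rate = 0.1,
        nthreads = 1, verbosity = 0))
      function(newX) as.numeric(stats::predict(fit, newX))
    },
    lda = {
      fit <- suppressWarnings(MASS::lda(X, y))
      function(newX) stats::predict(fit, newX)$posterior[, pos]
    },
    stop_petvasc(sprintf("unknown classifier `%s`", classifier),
                 class = "petvasc_validation_error"))
  list(classifier = classifier, predict_prob = pred, positive = pos)
}

# z-scoring fitted on training rows; constant features get sd 1. The
# returned closure subsets new data to the fitted columns, so it can be
# applied to any table carrying at least those features.
standardizer <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  cols <- colnames(X)
  function(newX) {
    missing_cols <- setdiff(cols, colnames(newX))
    if (length(missing_cols)) {
      stop_petvasc(sprintf("features missing from new data: %s",
                           paste(missing_cols, collapse = ", ")),
                   class = "petvasc_validation_error")
    }
    sweep(sweep(newX[, cols, drop = FALSE], 2, mu), 2, sd_, `/`)
  }
}

# ---- cross-validation ----------------------------------------------------

# Patient-wise, group-stratified fold assignment: within each group,
# shuffled patients are dealt round-robin over folds.
make_patient_folds <- function(records, n_folds, seed) {
  pat <- unique(records[, c("patient_id", "group")])
  if (nrow(pat) < n_folds) {
    stop_petvasc(sprintf("need at least %d patients for %d-fold CV",
                         n_folds, n_folds), class = "petvasc_validation_error")
  }
  with_seed(seed, {
    fold_of <- integer(0)
    nms <- character(0)
    for (g in unique(pat$group)) {
      ids <- sample(pat$patient_id[pat$group == g])
      fold_of <- c(fold_of, ((seq_along(ids) - 1L) %% n_folds) + 1L)
      nms <- c(nms, ids)
    }
    stats::setNames(fold_of, nms)
  })
}

binary_metrics <- function(y, prob, pos, threshold = 0.5) {
  neg <- setdiff(levels(y), pos)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = prob, levels = c(neg, pos),
    direction = "<", quiet = TRUE)))
  call_pos <- prob >= threshold
  tp <- sum(call_pos & y == pos); fp <- sum(call_pos & y != pos)
  fn <- sum(!call_pos & y == pos); tn <- sum(!call_pos & y != pos)
  c(auc = auc,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Cross-validate one model configuration
#'
#' Ten-fold cross-validation with patient-wise, group-stratified folds. In
#' each fold, features are z-scored and the selector fitted on the
#' fold-training rows only; the classifier is fitted on the selected
#' top-`n_features` columns and scored on the fold-validation rows. PPV
#' and NPV use a probability threshold of 0.5 within CV.
#'
#' @param config One row of [enumerate_grid()] (or a list with `selector`,
#'   `n_features`, `classifier`).
#' @param table A feature table ([extract_cohort_features()]) restricted to
#'   the training patients.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling folds and stochastic fits.
#' @param feature_names Feature columns to use (defaults to all feature
#'   columns present, e.g. the kept set from [prune_correlated()]).
#' @return A `grid_result` list: `config`, `fold_aucs`, `auc_mean`,
#'   `auc_sd`, `ppv_mean`, `ppv_sd`, `npv_mean`, `npv_sd`, `models` (the
#'   per-fold fitted models for later test-set scoring).
#' @export
cross_validate <- function(config, table, n_folds = 10L, seed = 1L,
                           feature_names = NULL) {
  parts <- feature_table_parts(table)
  X_all <- parts$features
  if (!is.null(feature_names)) {
    X_all <- X_all[, feature_names, drop = FALSE]
  }
  y_all <- factor(parts$records$group,
                  levels = intersect(c("ATHERO", "GCA", "inactive", "active"),
                                     unique(parts$records$group)))
  k <- min(as.integer(config$n_features), ncol(X_all))
  if (k < config$n_features) {
    warning(sprintf("n_features capped at %d available features", k))
  }
  fold_of <- make_patient_folds(parts$records, n_folds, seed)
  row_fold <- fold_of[parts$records$patient_id]
  fold_metrics <- matrix(NA_real_, n_folds, 3,
                         dimnames = list(NULL, c("auc", "ppv", "npv")))
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- row_fold != f; va <- !tr
    if (length(unique(y_all[va])) < 2) {
      warning(sprintf("fold %d has a single class in validation; skipped", f))
      next
    }
    std <- standardizer(X_all[tr, , drop = FALSE])
    Xtr <- std(X_all[tr, , drop = FALSE])
    sel <- rank_features(config$selector, Xtr, y_all[tr],
                         seed = stage_seed(seed, paste0("sel", f)))[seq_len(k)]
    cls <- fit_classifier(config$classifier, Xtr[, sel, drop = FALSE],
                          y_all[tr], seed = stage_seed(seed, paste0("fit", f)))
    prob <- cls$predict_prob(std(X_all[va, , drop = FALSE])[, sel, drop = FALSE])
    fold_metrics[f, ] <- binary_metrics(y_all[va], prob, cls$positive)
    models[[f]] <- list(std = std, features = sel, cls = cls)
  }
  ok <- !is.na(fold_metrics[, "auc"])
  structure(list(
    config = as.list(config),
    fold_aucs = fold_metrics[, "auc"],
    auc_mean = mean(fold_metrics[ok, "auc"]),
    auc_sd = stats::sd(fold_metrics[ok, "auc"]),
    ppv_mean = mean(fold_metrics[ok, "ppv"], na.rm = TRUE),
    ppv_sd = stats::sd(fold_metrics[ok, "ppv"], na.rm = TRUE),
    npv_mean = mean(fold_metrics[ok, "npv"], na.rm = TRUE),
    npv_sd = stats::sd(fold_metrics[ok, "npv"], na.rm = TRUE),
    models = models
  ), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %s | AUC %.3f +/- %.3f, PPV %.3f, NPV %.3f\n",
              x$config$config_id %||% paste(x$config$selector,
                                            x$config$n_features,
                                            x$config$classifier),
              x$auc_mean, x$auc_sd, x$ppv_mean, x$npv_mean))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run cross-validation over a set of configurations
#'
#' @param grid Data frame from [enumerate_grid()].
#' @param table Training feature table.
#' @inheritParams cross_validate
#' @return A list of `grid_result` objects, one per grid row.
#' @export
run_grid <- function(grid, table, n_folds = 10L, seed = 1L,
                     feature_names = NULL) {
  lapply(seq_len(nrow(grid)), function(i) {
    cross_validate(grid[i, ], table, n_folds = n_folds, seed = seed,
                   feature_names = feature_names)
  })
}

#' Summarise grid results as a data frame
#' @param results List of `grid_result` objects.
#' @return One row per configuration with the CV metrics.
#' @export
grid_summary <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(config_id = r$config$config_id %||% NA_character_,
               selector = r$config$selector, n_features = r$config$n_features,
               classifier = r$config$classifier,
               auc_mean = r$auc_mean, auc_sd = r$auc_sd,
               ppv_mean = r$ppv_mean, ppv_sd = r$ppv_sd,
               npv_mean = r$npv_mean, npv_sd = r$npv_sd,
               stringsAsFactors = FALSE)
  }))
}

#' Pick the final model from grid results
#'
#' Ranks by mean CV AUC; ties are broken by PPV + NPV, then by fewer
#' features (parsimony), then lexicographically by configuration id, so the
#' choice is deterministic.
#'
#' @param results List of `grid_result` objects.
#' @return The winning `grid_result`.
#' @export
select_final <- function(results) {
  if (!length(results)) {
    stop_petvasc("no grid results to select from",
                 class = "petvasc_validation_error")
  }
  s <- grid_summary(results)
  ord <- order(-s$auc_mean,
               -(ifelse(is.na(s$ppv_mean), 0, s$ppv_mean) +
                   ifelse(is.na(s$npv_mean), 0, s$npv_mean)),
               s$n_features,
               s$config_id)
  results[[ord[1]]]
}

#' Score the untouched test set with the cross-validated final model
#'
#' Each of the per-fold fitted models scores the test table; test AUC, PPV
#' and NPV are reported as mean +/- SD over the fold models, and the
#' per-segment probability is the fold-model average. Patient overlap
#' between training and test tables is a hard error.
#'
#' @param result A `grid_result` from [cross_validate()] (with models).
#' @param train_table,test_table Feature tables with disjoint patients.
#' @return A list with `probs` (per-segment mean probability),
#'   `segment_records`, `auc_mean`, `auc_sd`, `ppv_mean`, `ppv_sd`,
#'   `npv_mean`, `npv_sd`.
#' @export
fit_final_and_test <- function(result, train_table, test_table) {
  if (nrow(test_table) == 0) {
    stop_petvasc("test table is empty", class = "petvasc_validation_error")
  }
  overlap <- intersect(unique(train_table$patient_id),
                       unique(test_table$patient_id))
  if (length(overlap)) {
    stop_petvasc(sprintf("patients appear in both train and test: %s",
                         paste(overlap, collapse = ", ")),
                 class = "petvasc_leakage_error")
  }
  parts <- feature_table_parts(test_table)
  models <- Filter(Negate(is.null), result$models)
  if (!length(models)) {
    stop_petvasc("grid result carries no fitted fold models",
                 class = "petvasc_validation_error")
  }
  probs <- vapply(models, function(m) {
    m$cls$predict_prob(m$std(parts$features)[, m$features, drop = FALSE])
  }, numeric(nrow(test_table)))
  probs <- matrix(probs, nrow = nrow(test_table))
  y <- factor(parts$records$group)
  pos <- models[[1]]$cls$positive
  has_both <- length(unique(parts$records$group)) == 2
  met <- if (has_both) {
    t(apply(probs, 2, function(pr) binary_metrics(y, pr, pos)))
  } else matrix(NA_real_, 1, 3, dimnames = list(NULL, c("auc", "ppv", "npv")))
  list(probs = rowMeans(probs),
       segment_records = parts$records,
       positive = pos,
       auc_mean = mean(met[, "auc"]), auc_sd = stats::sd(met[, "auc"]),
       ppv_mean = mean(met[, "ppv"], na.rm = TRUE),
       ppv_sd = stats::sd(met[, "ppv"], na.rm = TRUE),
       npv_mean = mean(met[, "npv"], na.rm = TRUE),
       npv_sd = stats::sd(met[, "npv"], na.rm = TRUE))
}

#' Predict per-segment probabilities with a fitted grid result
#'
#' Fold-model-averaged probability of the positive class for every row of
#' a feature table.
#'
#' @param result A `grid_result` with fitted fold models.
#' @param table A feature table.
#' @return Numeric vector of probabilities, one per row.
#' @export
predict_segments <- function(result, table) {
  parts <- feature_table_parts(table)
  models <- Filter(Negate(is.null), result$models)
  probs <- vapply(models, function(m) {
    m$cls$predict_prob(m$std(parts$features)[, m$features, drop = FALSE])
  }, numeric(nrow(table)))
  rowMeans(matrix(probs, nrow = nrow(table)))
}
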