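#' Paired per-chip standardization of a feature table
#'
#' Because the design is paired (every chip is recorded before and after the
#' drug), features are standardized against the chip's own baseline: for
#' each chip and feature, the mean and sample SD are computed from that
#' chip's *pre-drug* windows, and both conditions' windows are transformed
#' as `(x - mu) / sd`.  Post-drug values are thus expressed in units of the
#' chip's baseline variability, which preserves the paired relationship and
#' keeps chips with different absolute scales comparable.  A feature that is
#' constant in the baseline windows (`sd = 0`) is set to 0 with a warning.
#'
#' @param ft Feature table: a tibble with `chip_id`, `condition`,
#'   `window_index` and one numeric column per feature.
#' @param features Character vector of feature columns; defaults to all
#'   numeric non-key columns.
#' @return The feature table with standardized feature columns.
#' @export
paired_standardize <- function(ft, features = NULL) {
  ft <- as_tibble(ft)
  features <- features %||% setdiff(names(ft)[vapply(ft, is.numeric,
                                                     logical(1))],
                                    key_cols())
  assert_condition(ft$condition)
  pre_counts <- ft |>
    filter(.data$condition == "pre_drug") |>
    count(.data$chip_id)
  all_chips <- unique(ft$chip_id)
  short <- setdiff(all_chips, pre_counts$chip_id[pre_counts$n >= 2])
  if (length(short) > 0) {
    abort(paste0("chip(s) with fewer than 2 pre-drug windows: ",
                 paste(short, collapse = ", ")))
  }
  warned <- FALSE
  out <- ft |>
    group_by(.data$chip_id) |>
    group_modify(function(df, key) {
      pre <- df[df$condition == "pre_drug", , drop = FALSE]
      for (f in features) {
        mu <- mean(pre[[f]])
        sd_ <- stats::sd(pre[[f]])
        if (!is.finite(sd_) || sd_ == 0) {
          warned <<- TRUE
          df[[f]] <- 0
        } else {
          df[[f]] <- (df[[f]] - mu) / sd_
        }
      }
      df
    }) |>
    ungroup()
  if (warned) warn("feature(s) constant in pre-drug windows set to 0")
  out[, names(ft)]
}

#' The seven supported model families
#'
#' Random forest, gradient boosting, RBF-kernel SVM, k-nearest neighbours,
#' L2 logistic regression, Gaussian naive Bayes and a single-hidden-layer
#' perceptron.
#'
#' @return Character vector of model identifiers accepted by
#'   [grouped_loocv()] and [run_pipeline()].
#' @export
model_names <- function() c("rf", "xgboost", "svm", "knn", "lr", "nb", "mlp")

# Small fixed tuning grid per model family (searched by inner grouped CV).
model_grid <- function(model) {
  switch(model,
    svm = lapply(c(0.1, 1, 10), function(c_) list(cost = c_)),
    rf = lapply(c(0L, 8L), function(d) list(depth = d)),
    xgboost = lapply(c(3L, 6L), function(d) list(depth = d)),
    knn = lapply(c(3L, 5L, 9L), function(k) list(k = k)),
    lr = lapply(c(0.1, 0.01, 0.001), function(l) list(lambda = l)),
    nb = list(list()),
    mlp = list(list(decay = 0.01)),
    abort(paste0("unknown model: ", model))
  )
}

# Fit `model` on (x_train, y_train) and return decision scores for x_new
# (higher = more post-drug-like).  Scores are margins or probabilities,
# never hard labels.
fit_predict <- function(model, x_train, y_train, x_new, params = list(),
                        seed = 1L) {
  x_train <- as.matrix(x_train)
  x_new <- as.matrix(x_new)
  y_num <- as.numeric(y_train)
  yf <- factor(y_num, levels = c(0, 1))
  scores <- withr::with_seed(seed, switch(
    model,
    svm = {
      gamma <- 1 / (ncol(x_train) * max(mean(apply(x_train, 2, stats::var)),
                                        1e-12))
      fit <- e1071::svm(x_train, yf, kernel = "radial",
                        cost = params$cost %||% 1, gamma = gamma,
                        scale = FALSE)
      dv_new <- attr(stats::predict(fit, x_new, decision.values = TRUE),
                     "decision.values")[, 1]
      dv_tr <- attr(stats::predict(fit, x_train, decision.values = TRUE),
                    "decision.values")[, 1]
      # orient the margin so larger means class 1
      flip <- stats::cor(dv_tr, y_num)
      if (is.finite(flip) && flip < 0) -dv_new else dv_new
    },
    rf = {
      fit <- ranger::ranger(
        x = x_train, y = yf, num.trees = 500, probability = TRUE,
        max.depth = params$depth %||% 0, seed = seed, num.threads = 1
      )
      stats::predict(fit, data = x_new, num.threads = 1)$predictions[, "1"]
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x_train, label = y_num)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$depth %||% 6, eta = 0.1,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = 200, verbose = 0
      )
      stats::predict(fit, xgboost::xgb.DMatrix(x_new))
    },
    knn = {
      pred <- class::knn(x_train, x_new, cl = yf, k = params$k %||% 5,
                         prob = TRUE)
      p_win <- attr(pred, "prob")
      ifelse(pred == "1", p_win, 1 - p_win)
    },
    lr = {
      fit <- glmnet::glmnet(x_train, yf, family = "binomial", alpha = 0,
                            lambda = params$lambda %||% 0.01)
      as.numeric(stats::predict(fit, x_new, type = "response"))
    },
    nb = {
      fit <- e1071::naiveBayes(x_train, yf)
      nb_scores(fit, x_new)
    },
    mlp = {
      fit <- nnet::nnet(x_train, y_num, size = 100,
                        decay = params$decay %||% 0.01, maxit = 200,
                        entropy = TRUE, trace = FALSE, MaxNWts = 5000)
      as.numeric(stats::predict(fit, x_new))
    },
    abort(paste0("unknown model: ", model))
  ))
  as.numeric(scores)
}

# Vectorized posterior P(class 1 | x) from an e1071 Gaussian naive-Bayes
# fit.  predict.naiveBayes loops over rows in R, which is prohibitively
# slow for the large hybrid matrices SHAP sampling evaluates; this scores
# the same fitted tables with matrix operations.  Within-class SDs are
# floored at 1e-6 so features constant in a class stay finite.
nb_scores <- function(fit, x) {
  lp <- log(fit$apriori / sum(fit$apriori))
  ll <- matrix(rep(lp, each = nrow(x)), nrow(x), 2)
  for (j in seq_along(fit$tables)) {
    tb <- fit$tables[[j]]
    for (k in 1:2) {
      m <- tb[k, 1]
      s <- tb[k, 2]
      if (!is.finite(m)) next
      if (!is.finite(s) || s < 1e-6) s <- 1e-6
      ll[, k] <- ll[, k] + stats::dnorm(x[, j], m, s, log = TRUE)
    }
  }
  stats::plogis(ll[, 2] - ll[, 1])
}

# AUC of decision scores against 0/1 labels (larger score = class 1).
score_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                 levels = c(0, 1), quiet = TRUE)))
}

#' Bootstrap lower confidence bound of the cross-validation AUC
#'
#' Percentile bootstrap over the per-split AUCs: the splits are resampled
#' with replacement `n_boot` times, the mean AUC of each resample recorded,
#' and the `alpha / 2` quantile of those means returned.  Using the lower
#' bound of the 95% interval as the model score is deliberately
#' conservative: a model is only called discriminative when even the
#' pessimistic end of its AUC distribution is high.
#'
#' @param split_aucs Numeric vector of per-split AUCs.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alpha Two-sided miscoverage (default 0.05, i.e. the 2.5th
#'   percentile is returned).
#' @param seed Seed for the resampling.
#' @return The lower confidence bound, a single number.
#' @export
auc_lower_ci <- function(split_aucs, n_boot = 1000L, alpha = 0.05,
                         seed = 1L) {
  split_aucs <- split_aucs[!is.na(split_aucs)]
  if (length(split_aucs) == 0) abort("`split_aucs` is empty")
  if (length(split_aucs) == 1) return(split_aucs)
  n <- length(split_aucs)
  means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(split_aucs[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  as.numeric(stats::quantile(means, alpha / 2, type = 7, names = FALSE))
}

#' Grouped leave-one-chip-out cross-validated classification
#'
#' One outer split per chip: all windows (both conditions) of the held-out
#' chip form the validation set, every other chip's windows the training
#' set, so no chip ever contributes to both sides of a split (asserted on
#' every run).  Within each training set, hyperparameters are tuned by an
#' inner grouped leave-one-chip-out CV over a small fixed grid, maximizing
#' mean inner AUC.  Validation decision scores give one AUC per split; the
#' model's overall score is the bootstrap lower confidence bound of those
#' AUCs ([auc_lower_ci()]).  Optionally, sampled Shapley attributions are
#' computed for the post-drug validation windows of every split against a
#' background drawn from the training windows.
#'
#' @param ft Standardized feature table ([paired_standardize()]).
#' @param model One of `rf`, `xgboost`, `svm`, `knn`, `lr`, `nb`, `mlp`.
#' @param seed Master seed; per-split seeds are derived from it.
#' @param features Feature columns (default: all numeric non-key columns).
#' @param shap Compute per-split SHAP attributions (default `TRUE`).
#' @param shap_nperm Permutation draws per explained window (default 120;
#'   attributions are medianed over windows and splits, which smooths the
#'   sampling noise).
#' @param shap_background Maximum number of training rows used as the
#'   interventional background (default 64).
#' @param n_boot,alpha Passed to [auc_lower_ci()].
#' @param tune Run the inner tuning loop (default `TRUE`; when `FALSE` the
#'   first grid point is used).
#' @return A `cv_report` object: list with `model`, `splits` (tibble of
#'   chip, auc, chosen parameters), `auc_lower_ci`, `shap_split_medians`
#'   (splits x features matrix of median absolute attributions over
#'   post-drug validation windows), `ranking` (see [rank_features()]), and
#'   `seed`.
#' @export
grouped_loocv <- function(ft, model = model_names(), seed = 1L,
                          features = NULL, shap = TRUE, shap_nperm = 120L,
                          shap_background = 64L, n_boot = 1000L,
                          alpha = 0.05, tune = TRUE) {
  model <- match.arg(model)
  ft <- as_tibble(ft)
  assert_condition(ft$condition)
  features <- features %||% setdiff(names(ft)[vapply(ft, is.numeric,
                                                     logical(1))],
                                    key_cols())
  chips <- sort(unique(ft$chip_id))
  if (length(chips) < 3) abort("grouped LOO-CV needs at least 3 chips")
  x_all <- as.matrix(ft[, features])
  y_all <- as.numeric(ft$condition == "post_drug")
  grid <- model_grid(model)

  split_auc <- numeric(length(chips))
  split_par <- character(length(chips))
  shap_medians <- matrix(NA_real_, length(chips), length(features),
                         dimnames = list(chips, features))

  for (ci in seq_along(chips)) {
    chip <- chips[ci]
    val_idx <- which(ft$chip_id == chip)
    tr_idx <- which(ft$chip_id != chip)
    # leakage guard: chip sets of train and validation must be disjoint
    stopifnot(length(intersect(ft$chip_id[tr_idx], ft$chip_id[val_idx])) == 0)

    best <- grid[[1]]
    if (tune && length(grid) > 1) {
      inner_chips <- setdiff(chips, chip)
      mean_auc <- vapply(grid, function(params) {
        aucs <- vapply(inner_chips, function(ic) {
          in_tr <- which(ft$chip_id != chip & ft$chip_id != ic)
          in_val <- which(ft$chip_id == ic)
          sc <- fit_predict(model, x_all[in_tr, , drop = FALSE],
                            y_all[in_tr], x_all[in_val, , drop = FALSE],
                            params, seed = derive_seed(seed, model, chip, ic))
          score_auc(y_all[in_val], sc)
        }, numeric(1))
        mean(aucs, na.rm = TRUE)
      }, numeric(1))
      best <- grid[[which.max(mean_auc)]]
    }
    split_par[ci] <- paste(names(best), unlist(best), sep = "=",
                           collapse = ",")

    fit_seed <- derive_seed(seed, model, chip, "outer")
    scores <- fit_predict(model, x_all[tr_idx, , drop = FALSE],
                          y_all[tr_idx], x_all[val_idx, , drop = FALSE],
                          best, seed = fit_seed)
    split_auc[ci] <- score_auc(y_all[val_idx], scores)

    if (shap) {
      model_fn <- function(newx) {
        fit_predict(model, x_all[tr_idx, , drop = FALSE], y_all[tr_idx],
                    newx, best, seed = fit_seed)
      }
      bg <- x_all[tr_idx, , drop = FALSE]
      if (nrow(bg) > shap_background) {
        sel <- withr::with_seed(derive_seed(seed, model, chip, "bg"),
                                sample.int(nrow(bg), shap_background))
        bg <- bg[sel, , drop = FALSE]
      }
      class1 <- val_idx[y_all[val_idx] == 1]
      phi <- vapply(seq_along(class1), function(k) {
        shap_attribute(model_fn, x_all[class1[k], ], bg, mode = "sampled",
                       n_perm = shap_nperm,
                       seed = derive_seed(seed, model, chip, "shap", k))
      }, numeric(length(features)))
      shap_medians[ci, ] <- apply(abs(phi), 1, stats::median)
    }
  }

  direction <- vapply(features, function(f) {
    d <- mean(ft[[f]][y_all == 1]) - mean(ft[[f]][y_all == 0])
    if (!is.finite(d)) 0 else sign(d)
  }, numeric(1))

  report <- structure(list(
    model = model,
    splits = tibble(chip_id = chips, auc = split_auc, params = split_par),
    auc_lower_ci = auc_lower_ci(split_auc, n_boot = n_boot, alpha = alpha,
                                seed = derive_seed(seed, model, "boot")),
    shap_split_medians = if (shap) shap_medians else NULL,
    ranking = NULL,
    features = features,
    direction = direction,
    seed = seed
  ), class = "cv_report")
  if (shap) report$ranking <- rank_features(shap_medians, direction)
  report
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Grouped LOO-CV report —", x$model, "\n")
  cat("  splits:", nrow(x$splits), " mean AUC:",
      round(mean(x$splits$auc, na.rm = TRUE), 3),
      " lower-CI AUC:", round(x$auc_lower_ci, 3), "\n")
  if (!is.null(x$ranking)) {
    cat("  top features:",
        paste(utils::head(x$ranking$feature, 3), collapse = ", "), "\n")
  }
  invisible(x)
}
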