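test_that("paired standardization references each chip's pre-drug baseline", {
  ft <- tibble::tibble(
    chip_id = "c1",
    condition = rep(c("pre_drug", "post_drug"), each = 3),
    window_index = rep(0:2, 2),
    f = c(1, 2, 3, 4, 5, 6)
  )
  out <- paired_standardize(ft)
  expect_equal(out$f[out$condition == "pre_drug"], c(-1, 0, 1))
  expect_equal(out$f[out$condition == "post_drug"], c(2, 3, 4))

  ft$f[1:3] <- 5
  expect_warning(out2 <- paired_standardize(ft), "constant")
  expect_true(all(out2$f == 0))
})

test_that("standardization is local to each chip", {
  ft <- toy_feature_table(n_chips = 3, n_windows = 4, seed = 2)
  shifted <- ft |>
    dplyr::mutate(f1 = f1 + 100 * (chip_id == "chip2"))
  a <- paired_standardize(ft)
  b <- paired_standardize(shifted)
  expect_equal(b[b$chip_id != "chip2", ], a[a$chip_id != "chip2", ])
  # chip2's own standardization absorbs its constant shift entirely
  expect_equal(b$f1[b$chip_id == "chip2"], a$f1[a$chip_id == "chip2"],
               tolerance = 1e-12)
})

test_that("standardization requires two pre-drug windows per chip", {
  ft <- toy_feature_table(n_chips = 3, n_windows = 4, seed = 3)
  ft <- ft[!(ft$chip_id == "chip2" & ft$condition == "pre_drug" &
               ft$window_index > 0), ]
  expect_error(paired_standardize(ft), "chip2")
})

test_that("grouped LOO-CV makes one leakage-free split per chip", {
  ft <- paired_standardize(toy_feature_table(n_chips = 5, n_windows = 4,
                                             effect = 3, seed = 5))
  rep <- grouped_loocv(ft, "nb", seed = 1, shap = FALSE)
  expect_equal(nrow(rep$splits), 5)
  expect_setequal(rep$splits$chip_id, unique(ft$chip_id))
  expect_error(grouped_loocv(ft[ft$chip_id %in% c("chip1", "chip2"), ],
                             "nb", seed = 1), "3 chips")
  expect_error(grouped_loocv(ft, "not_a_model"))
})

test_that("a perfectly separating feature yields AUC 1 in every split", {
  ft <- toy_feature_table(n_chips = 4, n_windows = 4, seed = 7)
  ft$f1 <- as.numeric(ft$condition == "post_drug")  # the label itself
  for (model in c("svm", "nb", "lr", "knn", "rf")) {
    rep <- grouped_loocv(ft, model, seed = 2, shap = FALSE, tune = FALSE)
    expect_equal(rep$splits$auc, rep(1, 4))
    expect_equal(rep$auc_lower_ci, 1)
  }
})

test_that("labels shuffled within chips give chance-level mean AUC", {
  withr::local_seed(31)
  ft <- toy_feature_table(n_chips = 5, n_windows = 4, effect = 0, seed = 9)
  mean_aucs <- vapply(1:20, function(i) {
    shuffled <- ft |>
      dplyr::group_by(chip_id, condition) |>
      dplyr::mutate(window_index = sample(window_index)) |>
      dplyr::group_by(chip_id) |>
      dplyr::mutate(condition = sample(condition)) |>
      dplyr::ungroup()
    # re-pair so both labels exist per chip, then classify
    rep <- grouped_loocv(shuffled, "nb", seed = 100 + i, shap = FALSE,
                         tune = FALSE)
    mean(rep$splits$auc, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(mean_aucs), 0.35)
  expect_lt(mean(mean_aucs), 0.65)
})

test_that("every model family produces finite scores on both classes", {
  ft <- paired_standardize(toy_feature_table(n_chips = 4, n_windows = 5,
                                             effect = 1.5, seed = 11))
  x <- as.matrix(ft[, c("f1", "f2", "f3")])
  y <- as.numeric(ft$condition == "post_drug")
  for (model in model_names()) {
    sc <- fit_predict(model, x, y, x, model_grid(model)[[1]], seed = 3)
    expect_length(sc, nrow(x))
    expect_true(all(is.finite(sc)), info = model)
  }
})

test_that("vectorized naive-Bayes scores equal e1071's row-wise predictions", {
  withr::local_seed(29)
  x <- matrix(rnorm(120 * 5), 120, 5)
  y <- factor(rbinom(120, 1, 0.5), levels = c(0, 1))
  fit <- e1071::naiveBayes(x, y)
  xn <- matrix(rnorm(40 * 5), 40, 5)
  expect_equal(meadrug:::nb_scores(fit, xn),
               unname(predict(fit, xn, type = "raw")[, 2]),
               tolerance = 1e-12)
})

test_that("bootstrap lower CI handles degenerate and general inputs", {
  expect_equal(auc_lower_ci(rep(1, 9), seed = 1), 1)
  expect_equal(auc_lower_ci(rep(0.5, 9), seed = 1), 0.5)
  expect_error(auc_lower_ci(numeric()), "empty")

  splits <- c(0.6, 0.7, 0.8, 0.9, 1.0, 0.6, 0.7, 0.8, 0.9)
  got <- auc_lower_ci(splits, n_boot = 1000, alpha = 0.05, seed = 0)
  expect_equal(got, oracle_bootstrap_lower(splits, 1000, 0.05, 0),
               tolerance = 1e-12)
  # bounded by the observed split range
  withr::local_seed(17)
  for (i in 1:10) {
    v <- runif(9)
    lo <- auc_lower_ci(v, n_boot = 200, seed = i)
    expect_gte(lo, min(v))
    expect_lte(lo, max(v))
    expect_lte(lo, mean(v))
  }
})

test_that("tuning picks hyperparameters by inner grouped CV", {
  ft <- paired_standardize(toy_feature_table(n_chips = 4, n_windows = 4,
                                             effect = 2, seed = 13))
  rep <- grouped_loocv(ft, "knn", seed = 4, shap = FALSE, tune = TRUE)
  expect_true(all(grepl("^k=[359]$", rep$splits$params)))
})
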