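#' Linear mixed-model test of a drug effect on one feature
#'
#' Window-level feature values violate the independence assumption of
#' standard two-sample tests: windows from one chip are correlated (and
#' overlap when the segmentation overlaps).  The test therefore fits
#' `value ~ condition + (1 | chip_id)` by maximum likelihood — a fixed drug
#' effect plus a random intercept per chip absorbing intra-chip
#' variability — and compares it against the condition-free null via a
#' likelihood-ratio test.  All windows enter the model directly; nothing is
#' pre-averaged.
#'
#' @param ft Feature table with `chip_id`, `condition` and the feature
#'   column (standardized or raw; the p-value is invariant to affine
#'   rescaling).
#' @param feature Name of the feature column to test.
#' @return A one-row tibble: `feature`, `estimate` (fixed-effect coefficient
#'   of the post-drug condition), `p_value`, `code` (see
#'   [significance_code()]), `converged`.
#' @export
lmm_test <- function(ft, feature) {
  ft <- as_tibble(ft)
  assert_condition(ft$condition)
  if (!feature %in% names(ft)) abort(paste0("no feature column `", feature, "`"))
  if (length(unique(ft$chip_id)) < 3) abort("need at least 3 chips")
  dat <- tibble(
    value = ft[[feature]],
    condition = factor(ft$condition, levels = condition_levels()),
    chip_id = ft$chip_id
  )
  fail <- tibble(feature = feature, estimate = NA_real_, p_value = NA_real_,
                 code = NA_character_, converged = FALSE)
  if (!is.finite(stats::sd(dat$value)) || stats::sd(dat$value) == 0) {
    warn(paste0("feature `", feature, "` is constant: LMM not identifiable"))
    return(fail)
  }
  fit <- tryCatch({
    full <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ condition + (1 | chip_id), data = dat, REML = FALSE)
    ))
    null <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ 1 + (1 | chip_id), data = dat, REML = FALSE)
    ))
    lrt <- stats::anova(null, full)
    p <- lrt[["Pr(>Chisq)"]][2]
    # a zero LRT statistic gives p = 1; keep it inside (0, 1]
    p <- min(max(p, .Machine$double.xmin), 1)
    list(estimate = unname(lme4::fixef(full)["conditionpost_drug"]),
         p_value = p)
  }, error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$p_value)) {
    warn(paste0("LMM did not converge for feature `", feature, "`"))
    return(fail)
  }
  tibble(feature = feature, estimate = fit$estimate, p_value = fit$p_value,
         code = significance_code(fit$p_value), converged = TRUE)
}

#' Significance annotation for a p-value
#'
#' The five annotation bins: `ns` for `0.05 < p <= 1`, `*` for
#' `0.01 < p <= 0.05`, `**` for `0.001 < p <= 0.01`, `***` for
#' `1e-4 < p <= 1e-3` and `****` for `p <= 1e-4`.  Boundaries belong to the
#' stricter bin (`p = 0.05` is `*`).
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

#' LMM screen over all features
#'
#' Applies [lmm_test()] to every feature column and appends
#' Benjamini-Hochberg adjusted q-values as supplementary output (the
#' per-feature codes themselves are not multiplicity-adjusted).
#'
#' @inheritParams lmm_test
#' @param features Feature columns; default all numeric non-key columns.
#' @return Tibble with one row per feature.
#' @export
lmm_screen <- function(ft, features = NULL) {
  ft <- as_tibble(ft)
  features <- features %||% setdiff(names(ft)[vapply(ft, is.numeric,
                                                     logical(1))],
                                    key_cols())
  out <- purrr::map_dfr(features, function(f) lmm_test(ft, f))
  out$bh_q <- stats::p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value)
}

#' Feature-feature correlation matrix of one condition
#'
#' Pearson correlations between features over the windows of a single
#' condition — the standard multicollinearity check before interpreting
#' feature importances.  Zero-variance features yield zero rows/columns
#' with a warning; the diagonal is 1.
#'
#' @inheritParams lmm_screen
#' @param condition `"pre_drug"` or `"post_drug"`.
#' @return Symmetric correlation matrix (features x features).
#' @export
feature_correlation <- function(ft, condition = c("pre_drug", "post_drug"),
                                features = NULL) {
  condition <- match.arg(condition)
  ft <- as_tibble(ft)
  features <- features %||% setdiff(names(ft)[vapply(ft, is.numeric,
                                                     logical(1))],
                                    key_cols())
  if (length(features) < 2) abort("need at least 2 features")
  sub <- ft[ft$condition == condition, features, drop = FALSE]
  if (nrow(sub) < 3) abort("need at least 3 windows in the condition")
  m <- as.matrix(sub)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("zero-variance feature(s): ",
                paste(features[sds == 0], collapse = ", ")))
  }
  out <- suppressWarnings(stats::cor(m))
  out[!is.finite(out)] <- 0
  diag(out) <- 1
  out
}
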