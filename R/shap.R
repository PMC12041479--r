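#' Shapley-value attribution of one prediction
#'
#' Attributes a model's score for one instance to its features by Shapley
#' values: the weighted average, over feature subsets `S`, of the change in
#' the value function when the feature joins the coalition.  The value
#' function is the interventional expectation — features outside `S` are
#' replaced by rows of a background sample and the scores averaged:
#' `v(S) = mean_b f(x_S, b_notS)`.
#'
#' Two estimators are provided.  `exact` enumerates all `2^d` subsets
#' (feasible for `d <= 12`) and satisfies the efficiency, symmetry and
#' dummy axioms to numerical precision.  `sampled` averages over random
#' feature permutations; each permutation contributes a telescoping sum, so
#' additivity `sum(phi) = f(x) - mean_b f(b)` holds exactly for any number
#' of draws while individual attributions converge at rate
#' `1 / sqrt(n_perm)`.
#'
#' @param model_fn Function mapping a numeric matrix of instances to a
#'   numeric vector of scores.
#' @param instance Numeric vector, the instance to explain.
#' @param background Numeric matrix of background rows (same columns as
#'   `instance`).
#' @param mode `"sampled"` (default) or `"exact"`.
#' @param n_perm Number of permutation draws for the sampled mode
#'   (default 2000).
#' @param seed Seed for the permutation sampling.
#' @return Named numeric vector of attributions, one per feature.
#' @export
#' @examples
#' f <- function(x) 2 * x[, 1]
#' shap_attribute(f, c(3, 7), matrix(0, 1, 2), mode = "exact")
shap_attribute <- function(model_fn, instance, background,
                           mode = c("sampled", "exact"), n_perm = 2000L,
                           seed = 1L) {
  mode <- match.arg(mode)
  background <- as.matrix(background)
  d <- length(instance)
  if (ncol(background) != d) {
    abort("`background` must have one column per feature")
  }
  nb <- nrow(background)
  phi <- if (mode == "exact") {
    if (d > 12) {
      abort("exact mode supports at most 12 features; use mode = \"sampled\"")
    }
    shap_exact(model_fn, instance, background)
  } else {
    shap_sampled(model_fn, instance, background, n_perm, seed)
  }
  names(phi) <- colnames(background) %||% names(instance)
  phi
}

# mean model score with features in `mask` (logical) set to the instance
mask_values <- function(model_fn, instance, background, masks) {
  nb <- nrow(background)
  n_masks <- nrow(masks)
  x <- background[rep(seq_len(nb), times = n_masks), , drop = FALSE]
  for (m in seq_len(n_masks)) {
    on <- which(masks[m, ])
    if (length(on) > 0) {
      rows <- (m - 1L) * nb + seq_len(nb)
      x[rows, on] <- matrix(instance[on], nb, length(on), byrow = TRUE)
    }
  }
  scores <- model_fn(x)
  colMeans(matrix(scores, nrow = nb))
}

shap_exact <- function(model_fn, instance, background) {
  d <- length(instance)
  n_masks <- 2^d
  bits <- matrix(FALSE, n_masks, d)
  for (j in seq_len(d)) {
    bits[, j] <- bitwAnd(seq_len(n_masks) - 1L, bitwShiftL(1L, j - 1L)) > 0
  }
  # chunk the 2^d * nb evaluations to bound memory
  v <- numeric(n_masks)
  chunk <- max(1L, 4096L %/% max(1L, nrow(background)))
  idx <- seq_len(n_masks)
  for (grp in split(idx, ceiling(idx / chunk))) {
    v[grp] <- mask_values(model_fn, instance, background,
                          bits[grp, , drop = FALSE])
  }
  sizes <- rowSums(bits)
  # the full coalition never appears as an S in the sum; give it weight 0
  w <- ifelse(sizes < d,
              factorial(sizes) * factorial(pmax(d - sizes - 1, 0)) /
                factorial(d),
              0)
  phi <- numeric(d)
  mask_id <- seq_len(n_masks) - 1L
  for (j in seq_len(d)) {
    without <- !bits[, j]
    s_ids <- mask_id[without]
    with_ids <- s_ids + bitwShiftL(1L, j - 1L)
    phi[j] <- sum(w[without] * (v[with_ids + 1L] - v[s_ids + 1L]))
  }
  phi
}

shap_sampled <- function(model_fn, instance, background, n_perm, seed) {
  d <- length(instance)
  nb <- nrow(background)
  phi <- numeric(d)
  chunk <- max(1L, 20000L %/% ((d + 1L) * nb))
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      take <- min(chunk, n_perm - done)
      perms <- lapply(seq_len(take), function(i) sample.int(d))
      masks <- matrix(FALSE, take * (d + 1L), d)
      row <- 0L
      for (p in perms) {
        mask <- logical(d)
        row <- row + 1L  # empty coalition
        for (i in seq_len(d)) {
          mask[p[i]] <- TRUE
          masks[row + i, ] <- mask
        }
        row <- row + d
      }
      v <- mask_values(model_fn, instance, background, masks)
      for (k in seq_len(take)) {
        vv <- v[(k - 1L) * (d + 1L) + seq_len(d + 1L)]
        phi[perms[[k]]] <- phi[perms[[k]]] + diff(vv)
      }
      done <- done + take
    }
  })
  phi / n_perm
}

#' Rank features by median absolute SHAP attribution
#'
#' Aggregates per-split SHAP attributions into an importance ranking: for
#' each feature, the median across cross-validation splits of the median
#' absolute attribution over post-drug validation windows, plus the min and
#' max across splits and the direction of the feature's shift after the
#' drug (+1 increased, -1 decreased).
#'
#' @param shap_split_medians Splits-by-features matrix of median absolute
#'   attributions (e.g. from a `cv_report`), or a `cv_report` itself.
#' @param direction Optional named vector of shift signs per feature.
#' @return A tibble sorted by decreasing importance with columns `feature`,
#'   `median_abs_shap`, `min_abs_shap`, `max_abs_shap`, `direction`,
#'   `rank`.
#' @export
rank_features <- function(shap_split_medians, direction = NULL) {
  if (inherits(shap_split_medians, "cv_report")) {
    direction <- direction %||% shap_split_medians$direction
    shap_split_medians <- shap_split_medians$shap_split_medians
  }
  m <- as.matrix(shap_split_medians)
  if (nrow(m) < 1) abort("need at least one split")
  out <- tibble(
    feature = colnames(m) %||% paste0("f", seq_len(ncol(m))),
    median_abs_shap = unname(apply(m, 2, stats::median, na.rm = TRUE)),
    min_abs_shap = unname(apply(m, 2, min, na.rm = TRUE)),
    max_abs_shap = unname(apply(m, 2, max, na.rm = TRUE)),
    direction = if (is.null(direction)) NA_real_ else
      as.numeric(direction[colnames(m)])
  )
  out <- arrange(out, desc(.data$median_abs_shap))
  out$rank <- seq_len(nrow(out))
  out
}

#' Cross-model similarity of feature-importance vectors
#'
#' Pearson correlation between the median absolute SHAP vectors of several
#' fitted models, quantifying how similarly the models apportion importance
#' across features.
#'
#' @param reports A named list of `cv_report` objects (or of numeric
#'   importance vectors with identical names).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
model_similarity <- function(reports) {
  if (length(reports) < 2) abort("need at least 2 models")
  vecs <- lapply(reports, function(r) {
    if (inherits(r, "cv_report")) {
      stats::setNames(r$ranking$median_abs_shap, r$ranking$feature)
    } else {
      r
    }
  })
  feats <- sort(names(vecs[[1]]))
  for (v in vecs) {
    if (!identical(sort(names(v)), feats)) {
      abort("models have mismatched feature sets")
    }
  }
  mat <- vapply(vecs, function(v) v[feats], numeric(length(feats)))
  nm <- names(reports) %||% vapply(reports, function(r)
    if (inherits(r, "cv_report")) r$model else "model", character(1))
  colnames(mat) <- nm
  out <- suppressWarnings(stats::cor(mat))
  out[!is.finite(out)] <- 0
  diag(out) <- 1
  out
}
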