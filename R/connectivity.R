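#' Pairwise correlation of binned spike trains
#'
#' Builds the functional-connectivity matrix of one window: the chosen
#' pairwise statistic between every two electrode rows of the binary
#' occupancy matrix.  Rows with zero variance (silent or saturated
#' electrodes) get correlation 0 with all partners so they stay isolated
#' rather than propagating undefined values; the diagonal is forced to 1.
#'
#' Methods:
#' * `pearson` — product-moment correlation.  On 0/1 data this equals the
#'   phi coefficient of the 2x2 contingency table, which is how it is
#'   computed here (sparse cross-products, numerically exact).
#' * `spearman` — rank correlation.  The rank transform of a binary vector
#'   is affine in the vector, so on 0/1 data Spearman coincides with
#'   Pearson; non-binary input falls back to [stats::cor()].
#' * `canonical` — a sparse canonical-correlation statistic: each electrode
#'   is lag-embedded (lags `0..5` bins), the embeddings are whitened, and
#'   the first canonical correlation is found by power iteration with
#'   soft-thresholding (L1 penalty `lambda = 0.1`) of the canonical
#'   weights.  This keeps a genuinely multivariate statistic while staying
#'   pairwise; the result is in `[0, 1]`.
#'
#' @param binned Electrodes-by-bins matrix from [bin_binary()] (sparse or
#'   dense).
#' @param method `"pearson"`, `"spearman"` or `"canonical"`.
#' @param lags Integer lags for the canonical embedding.
#' @param lambda Soft-threshold penalty for the canonical weights.
#' @return A `conn_graph` object: list with `corr` (symmetric, unit
#'   diagonal), `method`, `node_ids` (electrode ids), and `adjacency`
#'   (`NULL` until [binarize()] is applied).
#' @export
correlate <- function(binned, method = c("pearson", "spearman", "canonical"),
                      lags = 0:5, lambda = 0.1) {
  method <- match.arg(method)
  m <- nrow(binned)
  if (is.null(m) || m < 2) abort("need at least 2 electrodes to correlate")
  node_ids <- rownames(binned) %||% as.character(seq_len(m) - 1L)

  if (method == "canonical") {
    corr <- corr_canonical(as.matrix(binned), lags = lags, lambda = lambda)
  } else {
    is_binary <- if (inherits(binned, "sparseMatrix")) {
      vals <- methods::as(Matrix::Matrix(binned, sparse = TRUE), "dMatrix")@x
      all(vals %in% c(0, 1))
    } else {
      all(binned %in% c(0, 1))
    }
    if (is_binary) {
      # phi coefficient == Pearson on 0/1 data; Spearman coincides too
      # because ranking a binary vector is an affine transformation.
      corr <- corr_phi(binned)
    } else {
      corr <- corr_dense(as.matrix(binned), method)
    }
  }
  dimnames(corr) <- list(node_ids, node_ids)
  structure(list(corr = corr, adjacency = NULL, method = method,
                 threshold = NA_real_, node_ids = node_ids),
            class = "conn_graph")
}

# Pearson correlation of binary rows via the phi coefficient.
corr_phi <- function(binned) {
  v <- methods::as(methods::as(Matrix::Matrix(binned, sparse = TRUE),
                               "dMatrix"), "CsparseMatrix")
  n <- ncol(v)
  r <- Matrix::rowSums(v)
  n11 <- as.matrix(Matrix::tcrossprod(v))
  num <- n * n11 - outer(r, r)
  var_ <- n * r - r^2  # n * variance * n, zero iff constant row
  den <- sqrt(outer(var_, var_))
  corr <- ifelse(den > 0, num / den, 0)
  corr[!is.finite(corr)] <- 0
  diag(corr) <- 1
  corr <- pmin(pmax(corr, -1), 1)
  (corr + t(corr)) / 2
}

corr_dense <- function(dense, method) {
  suppressWarnings(corr <- stats::cor(t(dense), method = method))
  corr[!is.finite(corr)] <- 0
  diag(corr) <- 1
  (corr + t(corr)) / 2
}

# First sparse canonical correlation between lag-embedded rows.
corr_canonical <- function(dense, lags = 0:5, lambda = 0.1, ridge = 1e-6,
                           max_iter = 50L) {
  m <- nrow(dense)
  n <- ncol(dense)
  L <- length(lags)
  if (n <= max(lags) + 2) abort("too few bins for the requested lags")
  nn <- n - max(lags)
  # stacked embedding: rows (electrode, lag), columns = usable bins
  emb <- matrix(0, m * L, nn)
  for (k in seq_along(lags)) {
    emb[(seq_len(m) - 1) * L + k, ] <-
      dense[, (1 + lags[k]):(nn + lags[k]), drop = FALSE]
  }
  emb <- emb - rowMeans(emb)
  cov_all <- tcrossprod(emb) / (nn - 1)
  corr <- diag(1, m)
  for (i in seq_len(m - 1)) {
    bi <- (i - 1) * L + seq_len(L)
    for (j in (i + 1):m) {
      bj <- (j - 1) * L + seq_len(L)
      r <- sparse_cca_first(cov_all[bi, bi], cov_all[bj, bj],
                            cov_all[bi, bj], lambda, ridge, max_iter)
      corr[i, j] <- corr[j, i] <- r
    }
  }
  corr
}

sparse_cca_first <- function(sxx, syy, sxy, lambda, ridge, max_iter) {
  if (sum(diag(sxx)) == 0 || sum(diag(syy)) == 0) return(0)
  wx <- tryCatch(solve(chol(sxx + ridge * diag(nrow(sxx)))),
                 error = function(e) NULL)
  wy <- tryCatch(solve(chol(syy + ridge * diag(nrow(syy)))),
                 error = function(e) NULL)
  if (is.null(wx) || is.null(wy)) return(0)
  k <- t(wx) %*% sxy %*% wy
  u <- rep(1 / sqrt(nrow(k)), nrow(k))
  v <- rep(1 / sqrt(ncol(k)), ncol(k))
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  for (it in seq_len(max_iter)) {
    u_new <- soft(k %*% v, lambda)
    if (sum(u_new^2) == 0) return(0)
    u_new <- u_new / sqrt(sum(u_new^2))
    v_new <- soft(crossprod(k, u_new), lambda)
    if (sum(v_new^2) == 0) return(0)
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(u_new - u), abs(v_new - v)) < 1e-8) {
      u <- u_new; v <- v_new
      break
    }
    u <- u_new; v <- v_new
  }
  r <- as.numeric(t(u) %*% k %*% v)
  min(max(abs(r), 0), 1)
}

#' Threshold a correlation matrix into a binary adjacency
#'
#' An undirected edge is drawn between two electrodes when their raw
#' (signed) correlation is at least `threshold`; strong negative
#' correlations therefore do not create edges, and self-loops are never
#' created.  Raising the threshold can only remove edges.
#'
#' @param x A `conn_graph` from [correlate()], or a bare correlation matrix.
#' @param threshold Edge threshold (default 0.5).
#' @return If `x` is a `conn_graph`, the same object with `adjacency` and
#'   `threshold` filled in; if a matrix, the binary adjacency matrix.
#' @export
binarize <- function(x, threshold = 0.5) {
  if (inherits(x, "conn_graph")) {
    x$adjacency <- binarize(x$corr, threshold)
    x$threshold <- threshold
    return(x)
  }
  adj <- (x >= threshold) * 1
  diag(adj) <- 0
  adj
}
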