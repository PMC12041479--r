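# Independent oracles used across the suite.  Everything here is written
# from first principles (loops, enumeration, closed forms) and never calls
# the implementation it checks.

# ---- random fixtures ------------------------------------------------------

rand_spike_set <- function(n_chips = 2, n_electrodes = 8, duration = 10,
                           max_spikes = 20) {
  rows <- list()
  for (ch in seq_len(n_chips)) {
    for (co in c("pre_drug", "post_drug")) {
      for (el in seq_len(n_electrodes) - 1L) {
        n <- sample(0:max_spikes, 1)
        if (n > 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            chip_id = paste0("chip", ch), condition = co, electrode = el,
            time_s = sort(round(runif(n, 0, duration), 6))
          )
        }
      }
    }
  }
  spike_tbl(dplyr::bind_rows(rows), duration_s = duration,
            n_electrodes = n_electrodes)
}

rand_er_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  a
}

# ---- graph oracles (pure-R BFS / enumeration) -----------------------------

bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer()
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

bfs_all_dist <- function(adj) {
  n <- nrow(adj)
  t(vapply(seq_len(n), function(s) bfs_dist(adj, s), numeric(n)))
}

oracle_components <- function(adj) {
  n <- nrow(adj)
  d <- bfs_all_dist(adj)
  memb <- rep(NA_integer_, n)
  k <- 0
  for (v in seq_len(n)) {
    if (is.na(memb[v])) {
      k <- k + 1
      memb[is.finite(d[v, ])] <- k
    }
  }
  memb
}

# distance measures over the largest connected component
oracle_distance_measures <- function(adj) {
  memb <- oracle_components(adj)
  sizes <- table(memb)
  big <- as.integer(names(sizes)[which.max(sizes)])
  nodes <- which(memb == big)
  if (length(nodes) < 2 || sum(adj) == 0) {
    return(list(apl = 0, diameter = 0, eccentricity = 0))
  }
  sub <- adj[nodes, nodes, drop = FALSE]
  d <- bfs_all_dist(sub)
  pair_d <- d[upper.tri(d)]
  list(apl = mean(pair_d), diameter = max(d),
       eccentricity = mean(apply(d, 1, max)))
}

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bfs_all_dist(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  tri <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k]) {
          tri <- tri + 1
        }
      }
    }
  }
  deg <- rowSums(adj)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(0)
  3 * tri / triples
}

oracle_k_core <- function(adj) {
  # iterative peeling: largest k with a subgraph of min degree >= k
  n <- nrow(adj)
  best <- 0
  for (k in seq_len(n)) {
    a <- adj
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(a[alive, alive, drop = FALSE])
      drop_idx <- which(deg < k)
      if (length(drop_idx) == 0) break
      alive[which(alive)[drop_idx]] <- FALSE
      if (!any(alive)) break
    }
    if (sum(alive) > 0) best <- k else break
  }
  best
}

oracle_assortativity <- function(adj) {
  deg <- rowSums(adj)
  xs <- ys <- numeric()
  n <- nrow(adj)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] == 1) {
        # both orientations of each edge
        xs <- c(xs, deg[i], deg[j])
        ys <- c(ys, deg[j], deg[i])
      }
    }
  }
  if (length(xs) < 2 || sd(xs) == 0 || sd(ys) == 0) return(0)
  oracle_pearson(xs, ys)
}

oracle_knn_mean <- function(adj) {
  deg <- rowSums(adj)
  vals <- vapply(seq_len(nrow(adj)), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) == 0) NA_real_ else mean(deg[nb])
  }, numeric(1))
  if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
}

oracle_betweenness_mean <- function(adj) {
  # path-counting betweenness via BFS shortest-path counts
  n <- nrow(adj)
  d <- bfs_all_dist(adj)
  sigma <- matrix(0, n, n)  # number of shortest s->t paths
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || is.infinite(d[s, t])) next
      preds <- which(adj[t, ] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  mean(bc)
}

# ---- scalar statistics ----------------------------------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_phi <- function(x, y) {
  # phi coefficient from the 2x2 contingency table of two binary vectors
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

oracle_bootstrap_lower <- function(values, n_boot, alpha, seed) {
  set.seed(seed)
  n <- length(values)
  means <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    means[i] <- mean(values[sample(n, n, replace = TRUE)])
  }
  # type-7 quantile, written out
  srt <- sort(means)
  h <- (n_boot - 1) * (alpha / 2) + 1
  lo <- floor(h)
  srt[lo] + (h - lo) * (srt[min(lo + 1, n_boot)] - srt[lo])
}

# brute-force Shapley values by direct subset enumeration with combn()
oracle_shap <- function(model_fn, instance, background) {
  d <- length(instance)
  v <- function(S) {
    x <- background
    if (length(S) > 0) {
      x[, S] <- matrix(instance[S], nrow(x), length(S), byrow = TRUE)
    }
    mean(model_fn(x))
  }
  phi <- numeric(d)
  for (j in seq_len(d)) {
    others <- setdiff(seq_len(d), j)
    for (s_size in 0:length(others)) {
      subsets <- if (s_size == 0) list(integer()) else
        utils::combn(others, s_size, simplify = FALSE)
      w <- factorial(s_size) * factorial(d - s_size - 1) / factorial(d)
      for (S in subsets) {
        phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
      }
    }
  }
  phi
}

# exhaustive sliding-window count by direct simulation
oracle_n_windows <- function(duration, window, overlap_pct) {
  step <- window * (1 - overlap_pct / 100)
  k <- 0
  while (k * step + window <= duration) k <- k + 1
  k
}

# feature table with a known structure for classification tests
toy_feature_table <- function(n_chips = 4, n_windows = 5, effect = 0,
                              seed = 1) {
  withr::with_seed(seed, {
    grid <- tidyr::crossing(
      chip_id = paste0("chip", seq_len(n_chips)),
      condition = c("pre_drug", "post_drug"),
      window_index = seq_len(n_windows) - 1L
    )
    chip_int <- rnorm(n_chips)
    names(chip_int) <- paste0("chip", seq_len(n_chips))
    grid |>
      dplyr::mutate(
        f1 = rnorm(dplyr::n()) + chip_int[chip_id] +
          effect * (condition == "post_drug"),
        f2 = rnorm(dplyr::n()),
        f3 = rnorm(dplyr::n())
      )
  })
}
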