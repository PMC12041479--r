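k_n <- function(n) matrix(1, n, n) - diag(n)
path_n <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}
star_n <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}
two_cliques_bridge <- function() {
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- k_n(4)
  a[5:8, 5:8] <- k_n(4)
  a[4, 5] <- a[5, 4] <- 1
  diag(a) <- 0
  a
}

test_that("closed forms hold on the complete graph K5", {
  f <- scalar_measures(k_n(5))
  expect_equal(f$density, 1)
  expect_equal(f$mean_degree, 4)
  expect_equal(f$smd, 16)
  expect_equal(f$complexity, 4)
  expect_equal(f$ed, 0)
  expect_equal(f$transitivity, 1)
  expect_equal(f$apl, 1)
  expect_equal(f$diameter, 1)
  expect_equal(f$eccentricity, 1)
  expect_equal(f$efficiency, 1)
  expect_equal(f$k_core, 4)
  expect_equal(f$bc, 0)
  expect_equal(f$assortativity, 0)  # undefined on regular graphs -> 0
  expect_equal(f$knn, 4)
  expect_equal(f$cc, 1)
  expect_equal(f$ec, 1)
})

test_that("closed forms hold on the path P4", {
  f <- scalar_measures(path_n(4))
  expect_equal(f$density, 0.5)
  expect_equal(f$mean_degree, 1.5)
  expect_equal(f$diameter, 3)
  expect_equal(f$apl, 10 / 6)
  expect_equal(f$efficiency, 13 / 18)
  expect_equal(f$bc, 1 / 3)
  expect_equal(f$transitivity, 0)
})

test_that("closed forms hold on the 5-node star", {
  f <- scalar_measures(star_n(5))
  expect_equal(f$smd, 4)
  expect_equal(f$complexity, 2.5)
  expect_equal(f$ed, -(0.8 * log2(0.8) + 0.2 * log2(0.2)))
  expect_equal(f$transitivity, 0)
  expect_equal(f$k_core, 1)
  expect_equal(f$diameter, 2)
})

test_that("measures agree with brute-force oracles on random graphs", {
  withr::local_seed(99)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    p <- sample(c(0.2, 0.5, 0.8), 1)
    adj <- rand_er_adjacency(n, p)
    f <- suppressWarnings(scalar_measures(adj))
    deg <- rowSums(adj)
    expect_equal(f$mean_degree, mean(deg))
    expect_equal(f$smd, mean(deg^2))
    if (mean(deg) > 0) expect_equal(f$complexity, f$smd / f$mean_degree)
    expect_equal(f$density, sum(adj) / (n * (n - 1)))
    expect_equal(f$transitivity, oracle_transitivity(adj), tolerance = 1e-12)
    dm <- oracle_distance_measures(adj)
    if (sum(adj) > 0) {
      expect_equal(f$apl, dm$apl, tolerance = 1e-12)
      expect_equal(f$diameter, dm$diameter)
      expect_equal(f$eccentricity, dm$eccentricity, tolerance = 1e-12)
    }
    expect_equal(f$efficiency, oracle_efficiency(adj), tolerance = 1e-12)
    expect_equal(f$k_core, oracle_k_core(adj))
    expect_equal(f$assortativity, oracle_assortativity(adj),
                 tolerance = 1e-10)
    expect_equal(f$knn, oracle_knn_mean(adj), tolerance = 1e-12)
    expect_equal(f$bc, oracle_betweenness_mean(adj), tolerance = 1e-10)
    pd <- as.numeric(table(deg)) / n
    expect_equal(f$ed, -sum(pd * log2(pd)), tolerance = 1e-12)
  }
})

test_that("degree-moment inequality and relabeling invariance hold", {
  withr::local_seed(41)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    adj <- rand_er_adjacency(n, 0.4)
    f <- suppressWarnings(scalar_measures(adj))
    expect_gte(f$smd - f$mean_degree^2, -1e-12)  # Jensen
    perm <- sample(n)
    f2 <- suppressWarnings(scalar_measures(adj[perm, perm]))
    expect_equal(unlist(f2), unlist(f), tolerance = 1e-10)
  }
  # equality iff regular
  expect_equal(scalar_measures(k_n(4))$smd, scalar_measures(k_n(4))$mean_degree^2)
})

test_that("degenerate graphs follow the stated conventions", {
  expect_error(scalar_measures(matrix(0, 1, 1)), "2 nodes")
  f <- suppressWarnings(scalar_measures(matrix(0, 4, 4)))
  expect_equal(f$apl, 0)
  expect_equal(f$diameter, 0)
  expect_equal(f$eccentricity, 0)
  expect_equal(f$efficiency, 0)
  expect_equal(f$mean_degree, 0)
  expect_equal(f$complexity, 0)
})

test_that("every community method recovers two bridged cliques", {
  adj <- two_cliques_bridge()
  for (method in community_methods()) {
    mem <- detect_communities(adj, method, seed = 7)
    expect_length(mem, 8)
    expect_length(unique(mem), 2)
    expect_length(unique(mem[1:4]), 1)
    expect_length(unique(mem[5:8]), 1)
    expect_false(mem[1] == mem[8])
  }
})

test_that("community detection handles edgeless and complete graphs", {
  mem0 <- detect_communities(matrix(0, 5, 5), "multilevel")
  expect_equal(sort(unique(mem0)), 1:5)  # singletons
  for (method in c("multilevel", "spanning_tree", "label_propagation")) {
    mem <- detect_communities(k_n(6), method, seed = 1)
    expect_length(unique(mem), 1)  # no division improves modularity
  }
  expect_error(detect_communities(k_n(4), "nonsense"))
})

test_that("community APL matches the induced-subgraph BFS oracle", {
  adj <- two_cliques_bridge()
  for (method in community_methods()) {
    expect_equal(community_apl(adj, method, seed = 3), 1)  # induced K4
  }
  expect_equal(community_apl(matrix(0, 4, 4), "multilevel"), 0)

  # two K3 cliques plus a 5-node pendant path on one clique
  a <- matrix(0, 11, 11)
  a[1:3, 1:3] <- k_n(3)
  a[4:6, 4:6] <- k_n(3)
  a[3, 4] <- a[4, 3] <- 1
  a[6, 7] <- a[7, 6] <- 1
  for (i in 7:10) a[i, i + 1] <- a[i + 1, i] <- 1
  diag(a) <- 0
  mem <- detect_communities(a, "multilevel", seed = 2)
  sizes <- table(mem)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  chosen <- big[which.min(vapply(big, function(cm) min(which(mem == cm)),
                                 numeric(1)))]
  nodes <- which(mem == chosen)
  sub <- a[nodes, nodes, drop = FALSE]
  memb_sub <- oracle_components(sub)
  comp_nodes <- which(memb_sub == as.integer(names(which.max(table(memb_sub)))))
  d <- bfs_all_dist(sub[comp_nodes, comp_nodes, drop = FALSE])
  expect_equal(community_apl(a, "multilevel", seed = 2),
               mean(d[upper.tri(d)]))
})

test_that("stochastic community methods are reproducible under a seed", {
  withr::local_seed(10)
  adj <- rand_er_adjacency(20, 0.25)
  for (method in c("infomap", "label_propagation", "spinglass")) {
    m1 <- detect_communities(adj, method, seed = 11)
    m2 <- detect_communities(adj, method, seed = 11)
    expect_identical(m1, m2)
  }
})

test_that("graph_features returns the full 25-feature panel", {
  withr::local_seed(12)
  adj <- rand_er_adjacency(10, 0.5)
  f <- graph_features(adj, seed = 4)
  expect_setequal(names(f), setdiff(feature_names(), "spike_contrast"))
  expect_true(all(vapply(f, is.numeric, logical(1))))
})
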