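adj_to_graph <- function(adjacency) {
  if (inherits(adjacency, "conn_graph")) adjacency <- adjacency$adjacency
  if (is.null(adjacency)) abort("no adjacency: call binarize() first")
  igraph::graph_from_adjacency_matrix(
    methods::as(as.matrix(adjacency), "matrix"),
    mode = "undirected", diag = FALSE
  )
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(g, keep)
}

#' Scalar complex-network measures of a binary graph
#'
#' Computes the 17 graph-level summaries used as classification features:
#' degree statistics (`mean_degree`, `smd` = second moment of the degree
#' distribution, `complexity` = `smd / mean_degree`, `ed` = Shannon entropy
#' of the degree distribution in bits), `density`, `transitivity` (global
#' clustering), distance-based measures (`apl`, `diameter`, `eccentricity`
#' over the largest connected component; `efficiency` over all ordered pairs
#' with `1/Inf = 0`), mean centralities (`bc` betweenness normalized by
#' `(n-1)(n-2)/2`, `cc` closeness, `ec` eigenvector and `hub_score`, both
#' max-normalized, `knn` mean average-neighbour degree), `k_core`
#' (degeneracy) and degree `assortativity` (0 when undefined, e.g. regular
#' graphs).  Per-node measures are reduced to the graph level by the
#' arithmetic mean (`reduce = "median"` switches to the median).
#'
#' @param adjacency Symmetric binary adjacency matrix (zero diagonal) or a
#'   binarized `conn_graph`.
#' @param reduce How per-node measures are collapsed: `"mean"` (default) or
#'   `"median"`.
#' @param ed_base Logarithm base of the degree-distribution entropy
#'   (default 2, i.e. bits).
#' @return Named list of the 17 measures.
#' @export
#' @examples
#' k5 <- matrix(1, 5, 5) - diag(5)
#' scalar_measures(k5)$density
scalar_measures <- function(adjacency, reduce = c("mean", "median"),
                            ed_base = 2) {
  reduce <- match.arg(reduce)
  red <- if (reduce == "mean") {
    function(x) if (all(is.na(x))) 0 else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) 0 else stats::median(x, na.rm = TRUE)
  }
  g <- adj_to_graph(adjacency)
  n <- igraph::vcount(g)
  if (n < 2) abort("graph must have at least 2 nodes")
  deg <- igraph::degree(g)
  mean_degree <- mean(deg)
  smd <- mean(deg^2)
  complexity <- if (mean_degree > 0) smd / mean_degree else 0
  p <- as.numeric(table(deg)) / n
  ed <- -sum(p * log(p, base = ed_base))
  trans <- igraph::transitivity(g, type = "global")
  if (!is.finite(trans)) trans <- 0

  if (igraph::ecount(g) == 0) {
    apl <- diameter <- ecc <- 0
  } else {
    sub <- largest_component(g)
    d <- igraph::distances(sub)
    if (nrow(d) > 1) {
      apl <- mean(d[upper.tri(d)])
      diameter <- max(d)
      ecc <- red(apply(d, 1, max))
    } else {
      apl <- diameter <- ecc <- 0
    }
  }

  bcv <- igraph::betweenness(g, normalized = n > 2)
  ccv <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  ccv[!is.finite(ccv)] <- 0
  # componentwise Perron vectors keep eigenvector centrality well-defined
  # (and node-relabeling invariant) on disconnected graphs; for undirected
  # graphs Kleinberg's hub score coincides with eigenvector centrality
  ecv <- eigen_centrality_componentwise(g)
  hubv <- ecv
  knnv <- if (igraph::ecount(g) == 0) rep(NA_real_, n) else
    suppressWarnings(igraph::knn(g)$knn)
  assort <- igraph::assortativity_degree(g)
  if (!is.finite(assort)) assort <- 0

  list(
    assortativity = assort,
    knn = red(knnv),
    apl = apl,
    bc = red(bcv),
    cc = red(ccv),
    complexity = complexity,
    density = igraph::edge_density(g),
    diameter = diameter,
    eccentricity = ecc,
    ec = red(ecv),
    efficiency = igraph::global_efficiency(g),
    ed = ed,
    hub_score = red(hubv),
    k_core = max(igraph::coreness(g)),
    mean_degree = mean_degree,
    smd = smd,
    transitivity = trans
  )
}

# Eigenvector centrality computed per connected component (Perron vector of
# each component's adjacency, non-negative by construction), max-normalized
# over the whole graph.  Unlike a global ARPACK solve this is deterministic
# and invariant under node relabeling even when components tie for the
# dominant eigenvalue.
eigen_centrality_componentwise <- function(g) {
  n <- igraph::vcount(g)
  v <- numeric(n)
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    nodes <- which(comp$membership == cid)
    if (length(nodes) < 2) next
    b <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, nodes), sparse = FALSE)
    if (sum(b) == 0) next
    e <- eigen(b, symmetric = TRUE)
    v[nodes] <- abs(e$vectors[, which.max(e$values)])
  }
  if (max(v) > 0) v <- v / max(v)
  v
}

community_methods <- function() {
  c("fastgreedy", "infomap", "leading_eigenvector", "label_propagation",
    "edge_betweenness", "spinglass", "multilevel", "spanning_tree")
}

# map feature column -> community method
community_feature_map <- function() {
  c(afc = "fastgreedy", aic = "infomap", alc = "leading_eigenvector",
    alpc = "label_propagation", aebc = "edge_betweenness",
    aspc = "spinglass", amc = "multilevel", asc = "spanning_tree")
}

#' Community detection on a binary graph
#'
#' Thin wrapper over the igraph community-detection algorithms plus a
#' spanning-tree divisive method: starting from a spanning forest, the
#' forest edge with the highest edge betweenness is removed iteratively and
#' the split sequence with maximal modularity (evaluated in the original
#' graph) is kept.  Stochastic methods (infomap, label propagation,
#' spinglass) are run under `seed` so results are reproducible; spinglass
#' requires a connected graph and is applied to the largest component, all
#' other nodes becoming singletons.  An edgeless graph yields singleton
#' communities for every method.
#'
#' @inheritParams scalar_measures
#' @param method One of `fastgreedy`, `infomap`, `leading_eigenvector`,
#'   `label_propagation`, `edge_betweenness`, `spinglass`, `multilevel`,
#'   `spanning_tree`.
#' @param seed Integer seed for the stochastic methods.
#' @return Integer membership vector (one community id per node).
#' @export
detect_communities <- function(adjacency, method = community_methods(),
                               seed = 1L) {
  method <- match.arg(method)
  g <- adj_to_graph(adjacency)
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) return(seq_len(n))
  # the whole dispatch runs under the seed: several igraph methods
  # (louvain's vertex order, infomap, label propagation, spinglass) draw
  # from R's RNG
  membership <- withr::with_seed(seed, switch(
    method,
    fastgreedy = igraph::membership(igraph::cluster_fast_greedy(g)),
    infomap = igraph::membership(igraph::cluster_infomap(g)),
    leading_eigenvector = tryCatch(
      igraph::membership(igraph::cluster_leading_eigen(g)),
      error = function(e) igraph::components(g)$membership
    ),
    label_propagation = igraph::membership(igraph::cluster_label_prop(g)),
    edge_betweenness = suppressWarnings(
      igraph::membership(igraph::cluster_edge_betweenness(g))),
    spinglass = spinglass_membership(g, seed),
    multilevel = igraph::membership(igraph::cluster_louvain(g)),
    spanning_tree = spanning_tree_membership(g)
  ))
  as.integer(membership)
}

spinglass_membership <- function(g, seed) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  membership <- rep(NA_integer_, igraph::vcount(g))
  sub_mem <- withr::with_seed(seed,
    igraph::membership(igraph::cluster_spinglass(sub)))
  membership[keep] <- as.integer(sub_mem)
  # remaining nodes become singletons
  free <- which(is.na(membership))
  if (length(free) > 0) {
    membership[free] <- max(membership, na.rm = TRUE) + seq_along(free)
  }
  membership
}

# Divisive spanning-forest method: remove the forest edge with highest
# betweenness, keep the split sequence with maximal modularity.
spanning_tree_membership <- function(g) {
  forest <- igraph::mst(g)
  best_mem <- igraph::components(forest)$membership
  best_mod <- igraph::modularity(g, best_mem)
  work <- forest
  while (igraph::ecount(work) > 0) {
    eb <- igraph::edge_betweenness(work)
    work <- igraph::delete_edges(work, which.max(eb))
    mem <- igraph::components(work)$membership
    mod <- igraph::modularity(g, mem)
    if (mod > best_mod) {
      best_mod <- mod
      best_mem <- mem
    }
  }
  as.integer(best_mem)
}

#' Average path length within the largest community
#'
#' Runs the requested community-detection method, takes the community with
#' the most nodes (ties broken toward the community containing the smallest
#' node index), and returns the average shortest path length of the largest
#' connected component of its induced subgraph.  A singleton or edgeless
#' community yields 0.  These are the 8 community features (AFC, AIC, ALC,
#' ALPC, AEBC, ASPC, AMC, ASC), one per method.
#'
#' @inheritParams detect_communities
#' @return A single non-negative number.
#' @export
community_apl <- function(adjacency, method = community_methods(),
                          seed = 1L) {
  method <- match.arg(method)
  g <- adj_to_graph(adjacency)
  membership <- detect_communities(adjacency, method, seed = seed)
  sizes <- table(membership)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  chosen <- big[which.min(vapply(big, function(cm) min(which(membership == cm)),
                                 numeric(1)))]
  nodes <- which(membership == chosen)
  if (length(nodes) < 2) return(0)
  sub <- igraph::induced_subgraph(g, nodes)
  if (igraph::ecount(sub) == 0) return(0)
  sub <- largest_component(sub)
  d <- igraph::distances(sub)
  if (nrow(d) < 2) return(0)
  mean(d[upper.tri(d)])
}

#' All 25 graph features of one window
#'
#' Convenience wrapper combining [scalar_measures()] with the 8
#' community-APL scalars.
#'
#' @inheritParams scalar_measures
#' @param seed Seed forwarded to the stochastic community methods.
#' @return Named list of 25 features.
#' @export
graph_features <- function(adjacency, seed = 1L, reduce = "mean") {
  out <- scalar_measures(adjacency, reduce = reduce)
  cmap <- community_feature_map()
  for (feat in names(cmap)) {
    out[[feat]] <- community_apl(adjacency, cmap[[feat]], seed = seed)
  }
  out
}
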