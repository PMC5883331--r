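#' Global topological metrics of a binary graph
#'
#' Clustering coefficient `Cp` (mean nodal clustering, triangles over
#' connected triples; nodes of degree < 2 contribute 0), characteristic path
#' length `Lp` (mean shortest path over reachable pairs), global efficiency
#' `Eglob` (mean inverse shortest path over all pairs, unreachable pairs
#' contributing 0), local efficiency `Eloc` (mean over nodes of the global
#' efficiency of the neighbour-induced subgraph), and degree assortativity
#' `a` (Pearson correlation of degrees over edge endpoints).
#'
#' @param graph a [binarize_density] result, logical adjacency matrix, or
#'   igraph object.
#' @return object of class `global_metrics`: list with `Cp`, `Lp`, `Eloc`,
#'   `Eglob`, `assortativity`, `n_nodes`, `n_edges`.
#' @export
global_metrics <- function(graph) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  cp <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  D <- igraph::distances(g)
  off <- upper_vec(D)
  lp <- mean(off[is.finite(off)])
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  eglob <- sum(inv) / (n * (n - 1))
  adj <- graph_adjacency(graph)
  eloc <- mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    Ds <- igraph::distances(sub)
    iv <- 1 / Ds
    diag(iv) <- 0
    iv[!is.finite(iv)] <- 0
    sum(iv) / (length(nb) * (length(nb) - 1))
  }, numeric(1)))
  a <- suppressWarnings(igraph::assortativity_degree(g))
  structure(list(Cp = mean(cp), Lp = lp, Eloc = eloc, Eglob = eglob,
                 assortativity = a, n_nodes = n,
                 n_edges = igraph::ecount(g)),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("Global metrics (%d nodes, %d edges):\n", x$n_nodes, x$n_edges))
  cat(sprintf("  Cp = %.4f  Lp = %.4f  Eloc = %.4f  Eglob = %.4f  a = %.4f\n",
              x$Cp, x$Lp, x$Eloc, x$Eglob, x$assortativity))
  invisible(x)
}

#' Degree-preserving rewired null ensemble
#'
#' Randomizes the graph by repeated double-edge swaps that preserve every
#' node's degree exactly (self-loops and multi-edges rejected; connectedness
#' is not enforced).
#'
#' @inheritParams global_metrics
#' @param n number of null graphs.
#' @param swaps_per_edge attempted swaps per edge per null.
#' @param seed integer seed; the ensemble is reproducible bitwise.
#' @return object of class `null_ensemble`: list with `graphs` (list of
#'   logical adjacency matrices), `n`, `swaps_per_edge`, `seed`.
#' @export
rewire_null <- function(graph, n = 1000L, swaps_per_edge = 10L, seed = 1L) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) < 2) stop("graph has fewer than 2 edges", call. = FALSE)
  niter <- igraph::ecount(g) * swaps_per_edge
  graphs <- with_seed(child_seed(seed, "rewire"), {
    lapply(seq_len(n), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
      as.matrix(igraph::as_adjacency_matrix(r)) > 0
    })
  })
  structure(list(graphs = graphs, n = n, swaps_per_edge = swaps_per_edge,
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Degree-preserving rewired ensemble:", x$n, "graphs,",
      x$swaps_per_edge, "swaps/edge, seed", x$seed, "\n")
  invisible(x)
}

#' Small-worldness
#'
#' `sigma = (Cp / <Cp_rand>) / (Lp / <Lp_rand>)`, with null means over a
#' degree-preserving rewired ensemble of the same graph. A small-world graph
#' combines greater-than-random clustering with near-random path length
#' (`sigma` substantially > 1).
#'
#' @inheritParams global_metrics
#' @param nulls a [rewire_null] ensemble of the same graph.
#' @return `sigma`, with attributes `Cp_rand` and `Lp_rand` (null means).
#' @export
small_worldness <- function(graph, nulls) {
  gm <- global_metrics(graph)
  null_gm <- vapply(nulls$graphs, function(a) {
    m <- global_metrics(a)
    c(m$Cp, m$Lp)
  }, numeric(2))
  sigma <- (gm$Cp / mean(null_gm[1, ])) / (gm$Lp / mean(null_gm[2, ]))
  attr(sigma, "Cp_rand") <- mean(null_gm[1, ])
  attr(sigma, "Lp_rand") <- mean(null_gm[2, ])
  sigma
}

#' Rich-club coefficient curve with rewired-null normalization
#'
#' For each degree threshold k, `phi(k)` is the edge density of the subgraph
#' induced by nodes of degree > k. The normalized coefficient is the ratio
#' of `phi(k)` to its mean over a degree-preserving rewired ensemble.
#'
#' @inheritParams small_worldness
#' @return object of class `rich_club_curve`: data frame with `k`, `n_nodes`
#'   (nodes of degree > k), `phi`, `phi_rand` (null mean), `null_sd`,
#'   `rho_norm` (`phi / phi_rand`, `NA` where `phi_rand` is 0).
#' @export
rich_club <- function(graph, nulls = NULL) {
  adj <- graph_adjacency(graph)
  deg <- colSums(adj)
  ks <- seq(0L, max(deg) - 1L)
  phi <- vapply(ks, function(k) rich_club_phi(adj, deg, k), numeric(1))
  nn <- vapply(ks, function(k) sum(deg > k), numeric(1))
  keep <- nn >= 2
  out <- data.frame(k = ks[keep], n_nodes = nn[keep], phi = phi[keep])
  if (!is.null(nulls)) {
    nv <- vapply(nulls$graphs, function(a) {
      d <- colSums(a)
      vapply(out$k, function(k) rich_club_phi(a, d, k), numeric(1))
    }, numeric(nrow(out)))
    nv <- matrix(nv, nrow = nrow(out))
    out$phi_rand <- rowMeans(nv)
    out$null_sd <- apply(nv, 1, stats::sd)
    out$rho_norm <- ifelse(out$phi_rand > 0, out$phi / out$phi_rand, NA_real_)
  }
  class(out) <- c("rich_club_curve", "data.frame")
  out
}

rich_club_phi <- function(adj, deg, k) {
  keep <- deg > k
  nk <- sum(keep)
  if (nk < 2) return(NA_real_)
  sum(adj[keep, keep]) / (nk * (nk - 1))
}

#' Nodal degree and Euclidean connection distance
#'
#' @inheritParams global_metrics
#' @param atlas a [make_atlas] atlas supplying centroids.
#' @param ids region ids corresponding to graph nodes (default: left
#'   hemisphere).
#' @return list with `nodes` (data frame: `region_id`, `degree`,
#'   `mean_distance` in mm, `NA` for isolated nodes) and `edges` (data
#'   frame: `i`, `j` as region ids, `distance` mm).
#' @export
degree_and_distance <- function(graph, atlas, ids = left_ids(atlas)) {
  adj <- graph_adjacency(graph)
  stopifnot(ncol(adj) == length(ids))
  d <- atlas_distances(atlas, ids)
  deg <- colSums(adj)
  dsum <- rowSums(adj * d)
  pairs <- pair_index(ncol(adj))
  on <- upper_vec(adj)
  edges <- data.frame(i = ids[pairs[on, "i"]], j = ids[pairs[on, "j"]],
                      distance = upper_vec(d)[on])
  nodes <- data.frame(region_id = ids, degree = deg,
                      mean_distance = ifelse(deg > 0, dsum / deg, NA_real_))
  list(nodes = nodes, edges = edges)
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (k_is / k_i)^2` over modules s, the diversity of a
#' node's inter-modular connections: 0 for a provincial node whose
#' neighbours share its module, approaching 1 for edges spread evenly over
#' many modules. Isolated nodes get 0.
#'
#' @inheritParams global_metrics
#' @param partition a `partition` or label vector covering all nodes.
#' @return numeric vector of participation coefficients.
#' @export
participation_coefficient <- function(graph, partition) {
  adj <- graph_adjacency(graph)
  lab <- module_labels(partition)
  stopifnot(length(lab) == ncol(adj))
  deg <- colSums(adj)
  kis <- rowsum(adj * 1, lab)              # modules x nodes counts
  p <- 1 - colSums((t(t(kis) / pmax(deg, 1)))^2)
  p[deg == 0] <- 0
  stats::setNames(p, colnames(adj))
}
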