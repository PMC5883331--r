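#' Modularity of a partition
#'
#' Directly evaluates the Newman-Girvan modularity with a
#' Reichardt-Bornholdt resolution parameter on a (possibly weighted)
#' undirected graph:
#' `Q = (1/2m) * sum_ij (A_ij - gamma * k_i k_j / 2m) * delta(s_i, s_j)`,
#' with `m` the total edge weight, `k` the (weighted) degrees. This is the
#' standard `1/(2m)` normalization used by the common Louvain
#' implementations.
#'
#' @param graph a `binary_graph`, symmetric weight matrix, or igraph object.
#' @param labels module labels (integer vector over nodes, or a `partition`).
#' @param gamma resolution parameter (gamma > 1 favours more, smaller
#'   modules).
#' @return the modularity value.
#' @export
modularity_q <- function(graph, labels, gamma = 1) {
  W <- weight_matrix(graph)
  lab <- module_labels(labels)
  stopifnot(length(lab) == ncol(W))
  m2 <- sum(W)
  if (m2 <= 0) stop("graph has no edges", call. = FALSE)
  k <- rowSums(W)
  w_c <- vapply(split(seq_along(lab), lab),
                function(ix) sum(W[ix, ix, drop = FALSE]), numeric(1))
  k_c <- vapply(split(k, lab), sum, numeric(1))
  sum(w_c / m2 - gamma * (k_c / m2)^2)
}

weight_matrix <- function(graph) {
  if (inherits(graph, "binary_graph")) {
    W <- graph$adjacency * 1
  } else if (igraph::is_igraph(graph)) {
    W <- as.matrix(igraph::as_adjacency_matrix(graph, attr =
      if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL))
  } else {
    W <- as.matrix(graph)
  }
  stop_if_not_symmetric(W, "graph weight")
  diag(W) <- 0
  W
}

module_labels <- function(x) {
  if (inherits(x, "partition")) return(x$labels)
  lab <- as.integer(as.factor(x))
  stats::setNames(lab, names(x))
}

# Renumber module ids 1..k by descending size (ties: smallest original id).
relabel_by_size <- function(lab) {
  tab <- sort(table(lab), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  stats::setNames(as.integer(map[as.character(lab)]), names(lab))
}

new_partition <- function(labels, graph, gamma, method,
                          convergence_warning = FALSE) {
  labels <- relabel_by_size(labels)
  structure(list(labels = labels, sizes = tabulate(labels),
                 Q = modularity_q(graph, labels, gamma), gamma = gamma,
                 method = method, convergence_warning = convergence_warning),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition (%s, gamma = %g): %d modules, Q = %.4f\n",
              x$method, x$gamma, length(x$sizes), x$Q))
  cat("  sizes:", paste(x$sizes, collapse = " "), "\n")
  if (isTRUE(x$convergence_warning))
    cat("  warning: consensus did not converge\n")
  invisible(x)
}

#' Louvain community detection with local refinement
#'
#' Greedy Louvain modularity maximization (resolution `gamma`), followed by
#' a deterministic single-node-move hill climb that relocates nodes while
#' any move increases modularity. The refinement removes most of the
#' run-to-run variability of plain Louvain on small graphs and guarantees a
#' node-move local optimum.
#'
#' @inheritParams modularity_q
#' @param gamma resolution parameter.
#' @param seed integer seed (Louvain is stochastic).
#' @param refine apply the node-move hill climb (default TRUE).
#' @return object of class `partition`: `labels` (module ids, 1..k by
#'   descending size), `sizes`, `Q` (modularity on the input graph at
#'   `gamma`), `gamma`, `method`.
#' @export
louvain_partition <- function(graph, gamma = 1, seed = 1L, refine = TRUE) {
  W <- weight_matrix(graph)
  if (sum(W) <= 0) stop("cannot partition an edgeless graph", call. = FALSE)
  lab <- with_seed(child_seed(seed, "louvain"), louvain_once(W, gamma))
  if (refine) lab <- refine_partition(W, lab, gamma)
  names(lab) <- colnames(W)
  new_partition(lab, W, gamma, "louvain")
}

louvain_once <- function(W, gamma) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  as.integer(igraph::membership(igraph::cluster_louvain(g, resolution = gamma)))
}

# Single-node-move hill climb on modularity; deterministic given its input.
refine_partition <- function(W, lab, gamma, max_sweeps = 100L) {
  n <- ncol(W)
  m2 <- sum(W)
  k <- rowSums(W)
  lab <- as.integer(as.factor(lab))
  K <- vapply(split(k, lab), sum, numeric(1))
  K <- unname(K[order(as.integer(names(K)))])
  free <- integer(0)                    # recycled empty module ids
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      a <- lab[i]
      w_to <- rowsum(W[, i], lab)       # weight from i into each module
      mods <- as.integer(rownames(w_to))
      w_ia0 <- w_to[match(a, mods)]
      w_ia <- if (is.na(w_ia0)) 0 else w_ia0
      ## candidate targets: modules i touches, plus a fresh empty module
      cand <- mods[w_to > 0]
      cand <- cand[cand != a]
      empty_id <- if (length(free)) free[1] else length(K) + 1L
      cand <- c(cand, empty_id)
      w_ib <- w_to[match(cand, mods)]
      w_ib[is.na(w_ib)] <- 0
      K_b <- ifelse(cand <= length(K), K[pmin(cand, length(K))], 0)
      dQ <- 2 * (w_ib - w_ia) / m2 -
        2 * gamma * k[i] * (K_b - (K[a] - k[i])) / m2^2
      best <- which.max(dQ)
      if (dQ[best] > 1e-12) {
        b <- cand[best]
        if (b > length(K)) K <- c(K, 0)
        K[a] <- K[a] - k[i]
        K[b] <- K[b] + k[i]
        lab[i] <- b
        if (!any(lab == a)) free <- union(free, a)
        free <- setdiff(free, b)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.integer(as.factor(lab))
}

#' Consensus clustering over repeated Louvain runs
#'
#' Runs Louvain `runs` times, builds the co-assignment (consensus) matrix
#' `M` counting how often each node pair lands in the same module, and
#' re-clusters `M / runs` as a weighted graph with the same algorithm,
#' iterating until every run of an iteration returns the identical
#' partition (up to label permutation) or `max_iter` iterations.
#'
#' @inheritParams louvain_partition
#' @param runs Louvain repetitions per iteration.
#' @param max_iter consensus iterations before giving up.
#' @return a `partition` (with `Q` evaluated on the original graph and a
#'   `convergence_warning` flag), with attribute `consensus` (the final
#'   co-assignment count matrix of the first iteration) and `iterations`.
#' @export
consensus_partition <- function(graph, gamma = 1, runs = 1000L, seed = 1L,
                                max_iter = 10L) {
  W0 <- weight_matrix(graph)
  if (sum(W0) <= 0) stop("cannot partition an edgeless graph", call. = FALSE)
  n <- ncol(W0)
  W <- W0
  first_M <- NULL
  converged <- FALSE
  lab <- NULL
  it <- 0L
  with_seed(child_seed(seed, "consensus"), {
    for (it in seq_len(max_iter)) {
      labs <- matrix(0L, n, runs)
      for (r in seq_len(runs)) {
        l <- louvain_once(W, gamma)
        labs[, r] <- refine_partition(W, l, gamma)
      }
      canon <- apply(labs, 2, canonical_labels)
      if (all(canon[, 1] == canon)) {
        lab <- labs[, 1]
        converged <- TRUE
        break
      }
      M <- matrix(0, n, n)
      for (r in seq_len(runs)) {
        same <- outer(labs[, r], labs[, r], `==`)
        M <- M + same
      }
      if (is.null(first_M)) first_M <- M
      W <- M / runs
      diag(W) <- 0
      lab <- labs[, 1]
    }
  })
  names(lab) <- colnames(W0)
  p <- new_partition(lab, W0, gamma, "consensus-louvain",
                     convergence_warning = !converged)
  attr(p, "consensus") <- first_M
  attr(p, "iterations") <- it
  p
}

# Canonical form: modules renumbered by first appearance, so two labelings
# that differ only by a permutation of ids compare equal.
canonical_labels <- function(lab) {
  match(lab, unique(lab))
}
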