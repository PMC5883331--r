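#' Inter-regional Pearson correlation network
#'
#' Builds a weighted network whose edge weights are Pearson correlations
#' between columns of an observations x regions data matrix: the structural
#' covariance network (SCN) when rows are subjects and entries are regional
#' cortical thickness, or the transcriptional brain network (TBN) when the
#' input is the transpose of a regions x genes expression matrix.
#'
#' @param data observations x regions numeric matrix (>= 3 rows).
#' @param kind label stored with the network, e.g. `"SCN"` or `"TBN"`.
#' @param covariates optional data frame / matrix of per-observation nuisance
#'   covariates (e.g. age) residualized out of every column before
#'   correlating.
#' @return object of class `weighted_network`: list with `weights` (symmetric
#'   correlation matrix, unit diagonal; rows/columns of zero-variance regions
#'   are `NA`), `kind`, and `n_obs`.
#' @export
pearson_network <- function(data, kind = "SCN", covariates = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 3) stop("need at least 3 observations per pair", call. = FALSE)
  if (!is.null(covariates)) {
    x <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    data <- stats::lm.fit(x, data)$residuals
  }
  sds <- apply(data, 2, stats::sd)
  w <- suppressWarnings(stats::cor(data))
  if (any(sds == 0)) {
    flat <- which(sds == 0)
    w[flat, ] <- NA_real_
    w[, flat] <- NA_real_
    warning(length(flat), " zero-variance region(s); correlations set to NA",
            call. = FALSE)
  }
  diag(w) <- 1
  structure(list(weights = w, kind = kind, n_obs = nrow(data)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- ncol(x$weights)
  r <- upper_vec(x$weights)
  cat(sprintf("%s weighted network: %d regions, %d observations\n",
              x$kind, n, x$n_obs))
  cat(sprintf("  off-diagonal r: mean %.3f, range [%.3f, %.3f], %d NA\n",
              mean(r, na.rm = TRUE), min(r, na.rm = TRUE),
              max(r, na.rm = TRUE), sum(is.na(r))))
  invisible(x)
}

#' Density-threshold a weighted network into a binary graph
#'
#' Retains exactly `floor(density * N(N-1)/2)` of the most strongly positive
#' weights as edges. Ties at the cut are resolved by larger weight, then by
#' smaller (i, j) pair order. Negative or zero weights are never admitted as
#' edges, whatever the requested density.
#'
#' @param network a [pearson_network] result, or a bare symmetric weight
#'   matrix.
#' @param density target connection density in (0, 1].
#' @return object of class `binary_graph`: list with `adjacency` (symmetric
#'   logical matrix), `density`, `edge_count`, and `kind`.
#' @export
binarize_density <- function(network, density = 0.10) {
  w <- if (inherits(network, "weighted_network")) network$weights else network
  kind <- if (inherits(network, "weighted_network")) network$kind else "graph"
  stop_if_not_symmetric(w, "weight")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  n <- ncol(w)
  n_pairs <- n * (n - 1L) / 2L
  m <- floor(density * n_pairs)
  pairs <- pair_index(n)
  wt <- upper_vec(w)
  pos <- which(!is.na(wt) & wt > 0)
  if (length(pos) < m) {
    stop(sprintf(
      "not enough positive weights to reach density %.3g: need %d edges, %d available",
      density, m, length(pos)), call. = FALSE)
  }
  keep <- pos[order(-wt[pos], pairs[pos, "i"], pairs[pos, "j"])][seq_len(m)]
  adj <- matrix(FALSE, n, n, dimnames = dimnames(w))
  adj[pairs[keep, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  structure(list(adjacency = adj, density = density, edge_count = m,
                 kind = kind),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary %s graph: %d nodes, %d edges (density %.3g)\n",
              x$kind, ncol(x$adjacency), x$edge_count, x$density))
  invisible(x)
}

# Coerce a binary_graph / logical adjacency to igraph.
as_igraph <- function(graph) {
  adj <- graph_adjacency(graph)
  igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
}

graph_adjacency <- function(graph) {
  if (inherits(graph, "binary_graph")) return(graph$adjacency)
  if (igraph::is_igraph(graph)) {
    return(as.matrix(igraph::as_adjacency_matrix(graph)) > 0)
  }
  if (is.matrix(graph)) return(graph != 0 & !is.na(graph))
  stop("cannot interpret graph argument", call. = FALSE)
}
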