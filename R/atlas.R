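#' Build a synthetic cortical parcellation atlas
#'
#' Constructs an idealized hemisphere: points are sampled on a half-ellipsoid
#' shell (left hemisphere, `x <= 0`), partitioned into `n_regions` parcels by
#' k-means (a centroidal Voronoi tessellation of the shell), and mirrored to
#' the right hemisphere by flipping the sign of the first coordinate. The
#' spatial-adjacency relation links parcels whose point clouds touch
#' (nearest-neighbour contact on the shell, i.e. Voronoi/Delaunay neighbours),
#' and seven cytoarchitectonic classes are grown as contiguous patches from
#' well-separated seed parcels.
#'
#' The geometry is deliberately schematic: downstream analysis consumes only
#' centroids, Euclidean distances, spatial adjacency and surface point clouds,
#' none of which require a folded cortical surface.
#'
#' @param n_regions number of left-hemisphere parcels (>= 14, so that seven
#'   contiguous classes of at least two parcels each can be formed). A
#'   brain-like atlas uses 152.
#' @param seed integer seed; the atlas is a deterministic function of
#'   `(n_regions, seed)`.
#' @param points_per_region average number of shell points retained per parcel
#'   as its `surface_points`.
#' @param axes semi-axes of the ellipsoid in mm (left-right, posterior-
#'   anterior, inferior-superior).
#' @return an object of class `parcel_atlas`: a list with `regions` (data
#'   frame: `region_id`, `x`, `y`, `z`, `hemisphere`, `ve_class`), `adjacency`
#'   (symmetric logical matrix over all regions, no cross-hemisphere links),
#'   `surface_points` (list of n x 3 matrices), and `resolution` (the point
#'   cloud spacing in mm, used by sample assignment as the containment
#'   radius).
#' @export
make_atlas <- function(n_regions, seed = 1L, points_per_region = 60L,
                       axes = c(65, 85, 60)) {
  if (n_regions < 14) {
    stop("n_regions too small to form seven contiguous cytoarchitectonic ",
         "classes: need at least 14 parcels", call. = FALSE)
  }
  with_seed(child_seed(seed, "atlas"), {
    m <- n_regions * points_per_region
    ## uniform directions, folded onto the left (x <= 0) half, scaled to shell
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u[, 1] <- -abs(u[, 1])
    pts <- sweep(u, 2, axes, `*`)

    km <- suppressWarnings(
      stats::kmeans(pts, centers = n_regions, iter.max = 100, nstart = 2)
    )
    cent <- km$centers
    lab <- km$cluster

    nn <- knn_chunked(pts, k = 6L)
    h <- stats::median(nn$dist[, 1])

    adj_l <- matrix(FALSE, n_regions, n_regions)
    for (k in seq_len(ncol(nn$idx))) {
      a <- lab
      b <- lab[nn$idx[, k]]
      keep <- a != b
      adj_l[cbind(a[keep], b[keep])] <- TRUE
    }
    adj_l <- adj_l | t(adj_l)
    diag(adj_l) <- FALSE
    adj_l <- connect_components(adj_l, cent)

    ve <- grow_classes(adj_l, cent, n_classes = 7L)

    sp <- split.data.frame(pts, lab)
    sp <- lapply(sp, function(p) {
      if (nrow(p) > points_per_region) p[seq_len(points_per_region), , drop = FALSE] else p
    })

    n2 <- 2L * n_regions
    regions <- data.frame(
      region_id = seq_len(n2),
      x = c(cent[, 1], -cent[, 1]),
      y = c(cent[, 2], cent[, 2]),
      z = c(cent[, 3], cent[, 3]),
      hemisphere = rep(c("L", "R"), each = n_regions),
      ve_class = c(ve, ve)
    )
    adjacency <- matrix(FALSE, n2, n2)
    adjacency[seq_len(n_regions), seq_len(n_regions)] <- adj_l
    adjacency[n_regions + seq_len(n_regions), n_regions + seq_len(n_regions)] <- adj_l
    mirror <- function(p) { p[, 1] <- -p[, 1]; p }
    surface_points <- c(unname(sp), lapply(unname(sp), mirror))

    structure(
      list(regions = regions, adjacency = adjacency,
           surface_points = surface_points, resolution = h, axes = axes),
      class = "parcel_atlas")
  })
}

# k nearest neighbours among rows of pts, computed in row chunks to bound
# memory; returns indices and distances, each m x k.
knn_chunked <- function(pts, k = 6L, chunk = 500L) {
  m <- nrow(pts)
  sq <- rowSums(pts^2)
  idx <- matrix(0L, m, k)
  dst <- matrix(0, m, k)
  for (start in seq(1L, m, by = chunk)) {
    rows <- start:min(start + chunk - 1L, m)
    d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(pts[rows, , drop = FALSE], pts)
    d2[cbind(seq_along(rows), rows)] <- Inf
    for (kk in seq_len(k)) {
      j <- max.col(-d2, ties.method = "first")
      idx[rows, kk] <- j
      dst[rows, kk] <- sqrt(pmax(d2[cbind(seq_along(rows), j)], 0))
      d2[cbind(seq_along(rows), j)] <- Inf
    }
  }
  list(idx = idx, dist = dst)
}

# Ensure the within-hemisphere adjacency graph is connected by linking the
# nearest parcel pair across components (rarely needed for dense shells).
connect_components <- function(adj, cent) {
  repeat {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no == 1L) return(adj)
    a <- which(comp$membership == 1L)
    b <- which(comp$membership != 1L)
    d <- outer(rowSums(cent[a, , drop = FALSE]^2),
               rowSums(cent[b, , drop = FALSE]^2), `+`) -
      2 * tcrossprod(cent[a, , drop = FALSE], cent[b, , drop = FALSE])
    w <- which(d == min(d), arr.ind = TRUE)[1, ]
    adj[a[w[1]], b[w[2]]] <- adj[b[w[2]], a[w[1]]] <- TRUE
  }
}

# Assign 7 contiguous cytoarchitectonic classes: seeds by farthest-point
# sampling on centroids, then multi-source growth along the adjacency graph,
# always claiming the unassigned neighbour closest to its seed.
grow_classes <- function(adj, cent, n_classes = 7L) {
  n <- nrow(cent)
  seeds <- integer(n_classes)
  seeds[1] <- sample.int(n, 1L)
  d_all <- euclid_matrix(cent)
  for (c in 2:n_classes) {
    dmin <- apply(d_all[, seeds[seq_len(c - 1L)], drop = FALSE], 1, min)
    seeds[c] <- which.max(dmin)
  }
  cls <- rep(NA_integer_, n)
  cls[seeds] <- seq_len(n_classes)
  while (anyNA(cls)) {
    progressed <- FALSE
    for (c in seq_len(n_classes)) {
      members <- which(cls == c)
      nb <- which(is.na(cls) & apply(adj[, members, drop = FALSE], 1, any))
      if (length(nb)) {
        cls[nb[which.min(d_all[nb, seeds[c]])]] <- c
        progressed <- TRUE
      }
    }
    if (!progressed) { # isolated leftovers: attach to nearest assigned class
      left <- which(is.na(cls))
      for (i in left) cls[i] <- cls[which(!is.na(cls))[which.min(d_all[i, !is.na(cls)])]]
    }
  }
  cls
}

#' @export
print.parcel_atlas <- function(x, ...) {
  nl <- sum(x$regions$hemisphere == "L")
  cat("Synthetic cortical atlas:", nl, "left +", nl, "mirrored right parcels\n")
  cat("  spatial adjacency:", sum(x$adjacency) / 2, "links;",
      "point-cloud resolution", round(x$resolution, 2), "mm\n")
  cat("  von Economo class sizes (L):",
      paste(tabulate(x$regions$ve_class[x$regions$hemisphere == "L"], 7),
            collapse = " "), "\n")
  invisible(x)
}

#' Region ids of the left hemisphere of an atlas
#' @param atlas a `parcel_atlas`
#' @return integer vector of region ids
#' @export
left_ids <- function(atlas) {
  atlas$regions$region_id[atlas$regions$hemisphere == "L"]
}

#' Centroid Euclidean distance matrix (mm) for a set of regions
#' @param atlas a `parcel_atlas`
#' @param ids region ids (default: left hemisphere)
#' @return symmetric matrix of distances in mm
#' @export
atlas_distances <- function(atlas, ids = left_ids(atlas)) {
  xyz <- as.matrix(atlas$regions[match(ids, atlas$regions$region_id),
                                 c("x", "y", "z")])
  d <- euclid_matrix(xyz)
  dimnames(d) <- list(ids, ids)
  d
}
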