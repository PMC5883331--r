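#' Spatially contiguous module-permutation null
#'
#' Generates pseudo-random partitions of the parcellation that preserve the
#' number of modules, the exact multiset of module sizes, and the spatial
#' contiguity of every module, for permutation inference on within-module
#' statistics. Each draw re-seeds the modules at random parcels (largest
#' module first) and grows each module over the spatial-adjacency graph,
#' repeatedly claiming the unclaimed neighbour closest (Euclidean) to the
#' module's running centroid, until the source size is reached. Draws in
#' which some module cannot reach its size (the unclaimed set became
#' disconnected) are rejected and resampled.
#'
#' @param partition a [partition] object, or a bare integer vector of module
#'   labels; every source module must be contiguous on the atlas adjacency.
#' @param atlas a [make_atlas] atlas; labels are over its left hemisphere (or
#'   over `ids`).
#' @param n number of null partitions.
#' @param seed integer seed.
#' @param ids region ids the labels refer to; defaults to the left hemisphere.
#' @param max_rejections total rejected draws tolerated before aborting.
#' @return object of class `null_partition_set`: list with `labels` (an
#'   n_regions x n integer matrix, one column per draw), `n`, `seed`,
#'   `n_rejected`, and `sizes` (the preserved size multiset).
#' @export
permute_modules <- function(partition, atlas, n = 1000L, seed = 1L,
                            ids = left_ids(atlas), max_rejections = 500L * n) {
  labels <- module_labels(partition)
  idx <- match(ids, atlas$regions$region_id)
  stopifnot(length(labels) == length(ids), !anyNA(idx))
  adj <- atlas$adjacency[idx, idx, drop = FALSE]
  xyz <- as.matrix(atlas$regions[idx, c("x", "y", "z")])

  bad <- !vapply(split(seq_along(labels), labels), function(m) {
    is_contiguous(adj, m)
  }, logical(1))
  if (any(bad)) {
    stop("source modules not spatially contiguous: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }

  sizes <- sort(tabulate(labels), decreasing = TRUE)
  nbrs <- apply(adj, 1, which, simplify = FALSE)
  out <- matrix(NA_integer_, length(labels), n)
  rejected <- 0L
  with_seed(child_seed(seed, "spatial_null"), {
    for (d in seq_len(n)) {
      repeat {
        draw <- grow_partition_once(adj, xyz, sizes, nbrs)
        if (!is.null(draw)) break
        rejected <- rejected + 1L
        if (rejected > max_rejections) {
          stop(sprintf(
            "spatial null rejection budget exhausted: %d rejections for %d accepted draws",
            rejected, d - 1L), call. = FALSE)
        }
      }
      out[, d] <- draw
    }
  })
  structure(list(labels = out, n = n, seed = seed, n_rejected = rejected,
                 sizes = sizes),
            class = "null_partition_set")
}

# One seeded-growth attempt; returns a label vector (modules numbered in the
# order grown, largest first) or NULL if any module got stuck. Neighbour
# lists and an incrementally maintained frontier keep each claim O(degree).
grow_partition_once <- function(adj, xyz, sizes, nbrs = NULL) {
  n <- nrow(adj)
  if (is.null(nbrs)) nbrs <- apply(adj, 1, which, simplify = FALSE)
  lab <- rep(NA_integer_, n)
  for (m in seq_along(sizes)) {
    unclaimed <- which(is.na(lab))
    if (!length(unclaimed)) return(NULL)
    s <- unclaimed[sample.int(length(unclaimed), 1L)]
    lab[s] <- m
    size <- 1L
    ctr_sum <- xyz[s, ]
    frontier <- nbrs[[s]][is.na(lab[nbrs[[s]]])]
    while (size < sizes[m]) {
      if (!length(frontier)) return(NULL)
      ctr <- ctr_sum / size
      d2 <- (xyz[frontier, 1] - ctr[1])^2 + (xyz[frontier, 2] - ctr[2])^2 +
        (xyz[frontier, 3] - ctr[3])^2
      pick <- frontier[which.min(d2)]
      lab[pick] <- m
      size <- size + 1L
      ctr_sum <- ctr_sum + xyz[pick, ]
      add <- nbrs[[pick]]
      frontier <- c(frontier[frontier != pick], add[is.na(lab[add])])
      frontier <- frontier[!duplicated(frontier)]
    }
  }
  if (anyNA(lab)) NULL else lab
}

# TRUE iff the induced subgraph on `members` is connected.
is_contiguous <- function(adj, members) {
  if (length(members) <= 1L) return(TRUE)
  sub <- adj[members, members, drop = FALSE]
  seen <- c(1L, integer(0))
  frontier <- 1L
  reached <- rep(FALSE, length(members))
  reached[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(!reached & apply(sub[, frontier, drop = FALSE], 1, any))
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

# Grow a contiguous partition with given sizes (used for planted truth);
# retries growth until it succeeds.
grow_contiguous_partition <- function(atlas, sizes, seed,
                                      ids = left_ids(atlas), tries = 5000L) {
  idx <- match(ids, atlas$regions$region_id)
  adj <- atlas$adjacency[idx, idx, drop = FALSE]
  xyz <- as.matrix(atlas$regions[idx, c("x", "y", "z")])
  with_seed(child_seed(seed, "planted_partition"), {
    for (t in seq_len(tries)) {
      lab <- grow_partition_once(adj, xyz, sort(sizes, decreasing = TRUE))
      if (!is.null(lab)) return(stats::setNames(lab, ids))
    }
    stop("could not grow a contiguous planted partition", call. = FALSE)
  })
}

#' @export
print.null_partition_set <- function(x, ...) {
  cat("Spatially contiguous null partitions:", x$n, "draws over",
      nrow(x$labels), "regions\n")
  cat("  module sizes preserved:", paste(x$sizes, collapse = " "),
      "| rejected draws:", x$n_rejected, "\n")
  invisible(x)
}
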