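# Independent brute-force implementations used as oracles. These deliberately
# share no code with the package: plain double loops and BFS.

oracle_bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ])) {
          if (D[s, v] > d) {
            D[s, v] <- d
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in nb) for (b in nb) if (a < b && adj[a, b]) links <- links + 1
    2 * links / (k * (k - 1))
  })
}

oracle_global_metrics <- function(adj) {
  n <- nrow(adj)
  D <- oracle_bfs_distances(adj)
  off <- D[upper.tri(D)]
  lp <- mean(off[is.finite(off)])
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  eglob <- sum(inv) / (n * (n - 1))
  eloc <- mean(sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    Ds <- oracle_bfs_distances(sub)
    iv <- 1 / Ds
    diag(iv) <- 0
    iv[!is.finite(iv)] <- 0
    sum(iv) / (length(nb) * (length(nb) - 1))
  }))
  deg <- rowSums(adj)
  ends <- which(adj, arr.ind = TRUE)      # both directions of every edge
  a <- suppressWarnings(stats::cor(deg[ends[, 1]], deg[ends[, 2]]))
  list(Cp = mean(oracle_clustering(adj)), Lp = lp, Eloc = eloc,
       Eglob = eglob, assortativity = a)
}

oracle_rich_club <- function(adj, k) {
  deg <- rowSums(adj)
  keep <- which(deg > k)
  if (length(keep) < 2) return(NA_real_)
  e <- 0
  for (a in keep) for (b in keep) if (a < b && adj[a, b]) e <- e + 1
  2 * e / (length(keep) * (length(keep) - 1))
}

oracle_participation <- function(adj, lab) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    k <- sum(adj[i, ])
    if (k == 0) return(0)
    1 - sum(sapply(unique(lab), function(s) {
      (sum(adj[i, ] & lab == s) / k)^2
    }))
  })
}

oracle_modularity <- function(adj, lab, gamma = 1) {
  W <- adj * 1
  diag(W) <- 0
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (lab[i] == lab[j]) q <- q + W[i, j] - gamma * k[i] * k[j] / m2
  }
  q / m2
}

# All set partitions of 1..n as label vectors (restricted growth strings).
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxlab + 1)) {
      rec(c(prefix, l), max(maxlab, l))
    }
  }
  rec(integer(0), 0L)
  out
}

oracle_connected <- function(adj, members) {
  if (length(members) <= 1) return(TRUE)
  sub <- adj[members, members, drop = FALSE]
  seen <- 1L
  repeat {
    nxt <- unique(c(seen, which(apply(sub[, seen, drop = FALSE], 1, any))))
    if (length(nxt) == length(seen)) break
    seen <- nxt
  }
  length(seen) == length(members)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
  adj <- adj | t(adj)
  adj
}

# Ensure a graph has at least one edge per node (avoids degenerate oracle
# cases in randomized sweeps where they are not the point of the test).
random_connected_graph <- function(n, p, seed) {
  adj <- random_graph(n, p, seed)
  for (i in which(rowSums(adj) == 0)) {
    j <- if (i == 1) 2L else i - 1L
    adj[i, j] <- adj[j, i] <- TRUE
  }
  adj
}

as_bg <- function(adj) {
  structure(list(adjacency = adj, density = mean(adj[upper.tri(adj)]),
                 edge_count = sum(adj[upper.tri(adj)]), kind = "fixture"),
            class = "binary_graph")
}

# Tiny hand-made atlas: `k` square parcels side by side in the z = 0 plane,
# each parcel a 5 x 5 grid of surface points with 1 mm spacing; resolution 0
# so assignment distances are exact. Parcels are mirrored to the right
# hemisphere like the generator's atlases.
toy_atlas <- function(k = 4, spacing = 10) {
  grid <- as.matrix(expand.grid(x = -(0:4), y = 0:4, z = 0))
  sp <- lapply(seq_len(k), function(i) {
    g <- grid
    g[, 2] <- g[, 2] + (i - 1) * spacing
    g
  })
  cent <- t(sapply(sp, colMeans))
  adj <- abs(outer(seq_len(k), seq_len(k), `-`)) == 1
  regions <- data.frame(
    region_id = seq_len(2 * k),
    x = c(cent[, 1], -cent[, 1]), y = rep(cent[, 2], 2),
    z = rep(cent[, 3], 2),
    hemisphere = rep(c("L", "R"), each = k),
    ve_class = rep(rep_len(1:7, k), 2))
  adjacency <- matrix(FALSE, 2 * k, 2 * k)
  adjacency[seq_len(k), seq_len(k)] <- adj
  adjacency[k + seq_len(k), k + seq_len(k)] <- adj
  mirror <- function(p) { p[, 1] <- -p[, 1]; p }
  structure(list(regions = regions, adjacency = adjacency,
                 surface_points = c(sp, lapply(sp, mirror)),
                 resolution = 0, axes = c(65, 85, 60)),
            class = "parcel_atlas")
}

# Shared medium atlas built once per test run.
shared_atlas_60 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_atlas(60, seed = 7)
    cache
  }
})
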