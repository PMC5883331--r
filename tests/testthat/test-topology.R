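test_that("closed-form metrics hold on the complete graph and the star", {
  k5 <- matrix(TRUE, 5, 5); diag(k5) <- FALSE
  m <- global_metrics(as_bg(k5))
  expect_equal(m$Cp, 1)
  expect_equal(m$Lp, 1)
  expect_equal(m$Eglob, 1)

  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  ms <- global_metrics(as_bg(star))
  expect_equal(ms$Cp, 0)
  expect_equal(ms$Lp, 1.6)              # 4 pairs at 1, 6 pairs at 2
})

test_that("global and nodal metrics match brute-force oracles on random graphs", {
  for (s in 1:8) {
    n <- sample(10:30, 1)
    adj <- random_connected_graph(n, stats::runif(1, 0.15, 0.5), seed = s)
    m <- global_metrics(as_bg(adj))
    o <- oracle_global_metrics(adj)
    for (f in c("Cp", "Lp", "Eloc", "Eglob")) {
      expect_equal(m[[f]], o[[f]], tolerance = 1e-10, label = paste(f, s))
    }
    if (is.finite(o$assortativity)) {
      expect_equal(m$assortativity, o$assortativity, tolerance = 1e-10)
    }
    set.seed(s)
    lab <- sample(1:3, n, replace = TRUE)
    expect_equal(unname(participation_coefficient(as_bg(adj), lab)),
                 oracle_participation(adj, lab), tolerance = 1e-10)
  }
})

test_that("relabeling nodes permutes nodal metrics and leaves global metrics unchanged", {
  adj <- random_connected_graph(18, 0.3, seed = 21)
  set.seed(22)
  perm <- sample(18)
  padj <- adj[perm, perm]
  m1 <- global_metrics(as_bg(adj))
  m2 <- global_metrics(as_bg(padj))
  expect_equal(m1[c("Cp", "Lp", "Eloc", "Eglob", "assortativity")],
               m2[c("Cp", "Lp", "Eloc", "Eglob", "assortativity")],
               tolerance = 1e-12)
  lab <- rep(1:3, each = 6)
  p1 <- participation_coefficient(as_bg(adj), lab)
  p2 <- participation_coefficient(as_bg(padj), lab[perm])
  expect_equal(unname(p2), unname(p1)[perm], tolerance = 1e-12)
})

test_that("rewiring preserves degree sequences, is rigid on triangles, and is reproducible", {
  adj <- random_connected_graph(30, 0.2, seed = 31)
  nulls <- rewire_null(as_bg(adj), n = 20, seed = 1)
  for (g in nulls$graphs) {
    expect_identical(sort(colSums(g)), sort(colSums(adj)))
  }
  expect_identical(rewire_null(as_bg(adj), n = 5, seed = 9)$graphs,
                   rewire_null(as_bg(adj), n = 5, seed = 9)$graphs)

  k3 <- matrix(TRUE, 3, 3); diag(k3) <- FALSE
  n3 <- rewire_null(as_bg(k3), n = 5, seed = 2)
  for (g in n3$graphs) expect_identical(unname(g), unname(k3))
})

test_that("small-worldness self-normalizes and detects the ring lattice", {
  adj <- random_connected_graph(24, 0.3, seed = 41)
  self_null <- structure(list(graphs = replicate(10, adj, simplify = FALSE),
                              n = 10, swaps_per_edge = 0, seed = 0),
                         class = "null_ensemble")
  expect_equal(as.numeric(small_worldness(as_bg(adj), self_null)), 1,
               tolerance = 1e-12)

  ## ring lattice n = 50, k = 4: clustered but long paths
  n <- 50
  ring <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (o in 1:2) {
    j <- ((i - 1 + o) %% n) + 1
    ring[i, j] <- ring[j, i] <- TRUE
  }
  nulls <- rewire_null(as_bg(ring), n = 30, seed = 3)
  expect_gt(as.numeric(small_worldness(as_bg(ring), nulls)), 1.5)

  ## a dense random graph is its own rewiring class: sigma near 1
  dense <- random_connected_graph(40, 0.5, seed = 42)
  nulls_d <- rewire_null(as_bg(dense), n = 30, seed = 4)
  sig <- as.numeric(small_worldness(as_bg(dense), nulls_d))
  expect_lt(abs(sig - 1), 0.1)
})

test_that("rich-club coefficients match direct subgraph counting and null expectations", {
  k6 <- matrix(TRUE, 6, 6); diag(k6) <- FALSE
  rc <- rich_club(as_bg(k6))
  expect_true(all(rc$phi == 1))

  ## hand-built 8-node graph with a dense high-degree core
  adj <- matrix(FALSE, 8, 8)
  core <- combn(1:4, 2)
  for (c in seq_len(ncol(core))) adj[core[1, c], core[2, c]] <- TRUE
  adj[1, 5] <- adj[2, 6] <- adj[3, 7] <- adj[4, 8] <- adj[5, 6] <- TRUE
  adj <- adj | t(adj)
  rc8 <- rich_club(as_bg(adj))
  for (r in seq_len(nrow(rc8))) {
    expect_equal(rc8$phi[r], oracle_rich_club(adj, rc8$k[r]),
                 tolerance = 1e-12)
  }
  ## phi non-decreasing in k when the high-degree core is a clique
  expect_true(all(diff(rc8$phi) >= -1e-12))

  ## Erdos-Renyi: normalized coefficient within 3 null sd of 1
  er <- random_connected_graph(40, 0.25, seed = 51)
  rc_er <- rich_club(as_bg(er), rewire_null(as_bg(er), n = 50, seed = 5))
  ok <- rc_er$n_nodes >= 10 & rc_er$null_sd > 0
  expect_true(all(abs(rc_er$phi[ok] - rc_er$phi_rand[ok]) <=
                    3 * rc_er$null_sd[ok] + 1e-12))
})

test_that("connection distances come from centroid geometry", {
  at <- toy_atlas(k = 2)
  ## override centroids for an exact 3-4-5 triangle
  at$regions$x[1:2] <- c(0, 3)
  at$regions$y[1:2] <- c(0, 4)
  at$regions$z[1:2] <- 0
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  dd <- degree_and_distance(as_bg(adj), at, ids = 1:2)
  expect_equal(dd$edges$distance, 5)
  expect_equal(dd$nodes$mean_distance, c(5, 5))

  ## hub at mean of {2, 4, 6}
  at4 <- toy_atlas(k = 4)
  at4$regions$x[1:4] <- 0
  at4$regions$y[1:4] <- c(0, 2, 4, 6)
  at4$regions$z[1:4] <- 0
  hub <- matrix(FALSE, 4, 4)
  hub[1, 2:4] <- hub[2:4, 1] <- TRUE
  dd4 <- degree_and_distance(as_bg(hub), at4, ids = 1:4)
  expect_equal(dd4$nodes$mean_distance[1], 4)

  ## full synthetic graph: distance table equals a brute-force double loop
  a <- shared_atlas_60()
  w <- pearson_network(simulate_thickness(a, sim_config("compact", seed = 3)))
  g <- binarize_density(w, 0.1)
  dd60 <- degree_and_distance(g, a)
  ids <- left_ids(a)
  xyz <- as.matrix(a$regions[match(ids, a$regions$region_id), c("x", "y", "z")])
  for (r in sample(nrow(dd60$edges), 40)) {
    i <- match(dd60$edges$i[r], ids); j <- match(dd60$edges$j[r], ids)
    expect_equal(dd60$edges$distance[r], sqrt(sum((xyz[i, ] - xyz[j, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("participation coefficient closed forms hold", {
  ## all neighbours in own module
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2:4] <- adj[2:4, 1] <- TRUE
  expect_equal(unname(participation_coefficient(as_bg(adj), rep(1, 4))),
               rep(0, 4))
  ## degree-4 node with two neighbours in each of two modules
  adj5 <- matrix(FALSE, 5, 5)
  adj5[1, 2:5] <- adj5[2:5, 1] <- TRUE
  lab <- c(1, 1, 1, 2, 2)
  expect_equal(unname(participation_coefficient(as_bg(adj5), lab))[1], 0.5)
})
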