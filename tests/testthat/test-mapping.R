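test_that("probe selection keeps the highest-mean probe and breaks ties lexicographically", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                       gene_symbol = c("A", "B", "B", "C", NA))
  expr <- rbind(c(1.0, 2.0, 4.0, 7.1, 9.0),
                c(3.0, 3.0, 1.0, 3.2, 9.0))
  colnames(expr) <- probes$probe_id
  map <- select_probe_per_gene(probes, expr)
  expect_identical(unname(map["A"]), "p1")      # singleton
  expect_identical(unname(map["B"]), "p2")      # 2.5 vs 2.5: lexicographic tie
  expect_identical(unname(map["C"]), "p4")      # plain maximum
  expect_equal(attr(map, "n_unannotated"), 1L)

  expr2 <- expr
  expr2[, "p3"] <- c(10, 10)
  expect_identical(unname(select_probe_per_gene(probes, expr2)["B"]), "p3")
})

test_that("reflection flips right-hemisphere x, preserves left samples and counts", {
  s <- data.frame(sample_id = sprintf("s%d", 1:14),
                  x = c(rep(-5.5, 10), 12.0, 3.25, 8.0, 1.0),
                  y = -5.0, z = 30.0,
                  hemisphere = c(rep("L", 10), rep("R", 4)))
  out <- reflect_right_hemisphere(s)
  expect_equal(nrow(out), 14)
  expect_true(all(out$hemisphere == "L"))
  expect_identical(out[1:10, ], s[1:10, ])      # left rows bitwise untouched
  expect_equal(out$x[11], -12.0)
  expect_equal(out$y[11], -5.0)
  ## involution on coordinates
  twice <- reflect_right_hemisphere(out)
  expect_identical(twice$x, out$x)
})

test_that("parcel assignment honours containment, the 2 mm tolerance, and conservation", {
  at <- toy_atlas(k = 4)
  ## region 2 surface spans y in [10, 14]; place samples on / near it
  s <- data.frame(
    sample_id = c("on", "near", "far", "noncort"),
    x = c(-2, -2, -2, -2),
    y = c(12, 12, 12, 12),
    z = c(0, 1.5, 2.5, 0),
    hemisphere = "L",
    cortical_flag = c(TRUE, TRUE, TRUE, FALSE))
  asn <- assign_samples_to_parcels(s, at, tolerance_mm = 2)
  expect_equal(asn$region_id[asn$sample_id == "on"], 2L)
  expect_equal(asn$region_id[asn$sample_id == "near"], 2L)
  expect_true(is.na(asn$region_id[asn$sample_id == "far"]))
  expect_true(is.na(asn$region_id[asn$sample_id == "noncort"]))
  cnt <- attr(asn, "counts")
  expect_equal(unname(cnt["n_assigned"] + cnt["n_dropped_tolerance"] +
                        cnt["n_noncortical"]), unname(cnt["n_input"]))
})

test_that("assignment fraction matches an independent brute-force nearest-point search", {
  a <- shared_atlas_60()
  cfg <- sim_config("compact", seed = 13)
  ex <- simulate_expression(a, cfg)
  refl <- reflect_right_hemisphere(ex$samples)
  asn <- assign_samples_to_parcels(refl, a, tolerance_mm = 2)

  ids <- left_ids(a)
  xyz <- as.matrix(refl[, c("x", "y", "z")])
  brute <- sapply(seq_len(nrow(refl)), function(s) {
    if (!refl$cortical_flag[s]) return(NA_integer_)
    dmin <- Inf; rbest <- NA_integer_
    for (rid in ids) {
      sp <- a$surface_points[[match(rid, a$regions$region_id)]]
      dd <- min(sqrt(colSums((t(sp) - xyz[s, ])^2)))
      if (dd < dmin) { dmin <- dd; rbest <- rid }
    }
    if (max(0, dmin - a$resolution) <= 2) rbest else NA_integer_
  })
  expect_equal(asn$region_id, brute)
})

test_that("aggregation takes medians, interpolates empty parcels, and ignores donor scale", {
  at <- toy_atlas(k = 3)
  probes <- data.frame(probe_id = c("pG", "pH"), gene_symbol = c("G", "H"))
  gm <- select_probe_per_gene(probes, matrix(1, 1, 2,
                                             dimnames = list("s0", c("pG", "pH"))))
  ## one donor: region 1 gets asymmetric values; region 2 empty; region 3 sampled
  s <- data.frame(sample_id = sprintf("s%d", 1:6), donor_id = "D1",
                  x = -2, y = c(2, 2, 2, 22, 22, 22), z = 0,
                  hemisphere = "L", cortical_flag = TRUE)
  expr <- cbind(pG = c(-1, 0, 4, 1, 2, 3), pH = c(5, 6, 7, 8, 9, 10))
  rownames(expr) <- s$sample_id
  asn <- assign_samples_to_parcels(s, at)
  expect_equal(asn$region_id, c(1L, 1L, 1L, 3L, 3L, 3L))

  rex <- aggregate_regional_expression(s, expr, gm, asn, at)
  ## within-donor z then median: region 1 median of z{-1,0,4} is z(0)
  z <- scale(expr[, "pG"])
  expect_equal(unname(rex$values["1", "G"]), unname(stats::median(z[1:3])))
  ## empty region 2 interpolated as the mean of regions 1 and 3
  expect_true(rex$interpolated[2])
  expect_equal(unname(rex$values["2", "G"]),
               mean(rex$values[c("1", "3"), "G"]))
  expect_equal(rex$n_samples, c(3L, 0L, 3L))

  ## per-donor affine rescaling of the raw scale changes nothing
  s2 <- s; s2$donor_id <- c(rep("D1", 3), rep("D2", 3))
  expr_shifted <- expr
  expr_shifted[4:6, ] <- expr[4:6, ] * 7 + 100
  r1 <- aggregate_regional_expression(s2, expr, gm, asn, at)
  r2 <- aggregate_regional_expression(s2, expr_shifted, gm, asn, at)
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("a parcel without samples or sampled neighbours cannot be interpolated", {
  at <- toy_atlas(k = 3)
  probes <- data.frame(probe_id = "pG", gene_symbol = "G")
  gm <- stats::setNames("pG", "G")
  ## only region 1 sampled: region 3 has no sampled neighbour (chain 1-2-3)
  s <- data.frame(sample_id = "s1", donor_id = "D1", x = -2, y = 2, z = 0,
                  hemisphere = "L", cortical_flag = TRUE)
  expr <- matrix(1, 1, 1, dimnames = list("s1", "pG"))
  asn <- assign_samples_to_parcels(s, at)
  expect_error(aggregate_regional_expression(s, expr, gm, asn, at),
               "cannot interpolate")
})
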