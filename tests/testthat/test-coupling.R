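test_that("edge tables enumerate unordered pairs with oracle-checked distances", {
  at <- toy_atlas(k = 5)
  set.seed(1)
  w <- matrix(stats::rnorm(25), 5, 5)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  cx <- matrix(stats::runif(25, -1, 1), 5, 5)
  cx <- (cx + t(cx)) / 2
  diag(cx) <- 1
  et <- build_edge_table(w, list(genome = cx), at, density = 0.3, ids = 1:5)
  expect_equal(nrow(et), 10)

  xyz <- as.matrix(at$regions[1:5, c("x", "y", "z")])
  for (r in seq_len(nrow(et))) {
    expect_equal(et$distance[r],
                 sqrt(sum((xyz[et$i[r], ] - xyz[et$j[r], ])^2)),
                 tolerance = 1e-12)
    expect_equal(et$scn_weight[r], w[et$i[r], et$j[r]])
  }

  bad <- w; bad[1, 2] <- bad[1, 2] + 0.5   # break symmetry
  expect_error(build_edge_table(bad, list(genome = cx), at, ids = 1:5),
               "symmetric")
})

test_that("distance decay fits identify their own generating form", {
  set.seed(2)
  d <- stats::runif(400, 5, 120)
  y_lin <- 2 - 0.01 * d
  fl <- distance_decay_fit(y_lin, d, "linear")
  fe <- distance_decay_fit(y_lin, d, "exponential")
  expect_equal(fl$r_squared, 1, tolerance = 1e-10)
  expect_lt(fl$aic, fe$aic)

  y_exp <- exp(-d / 30)
  fe2 <- distance_decay_fit(y_exp, d, "exponential")
  expect_equal(fe2$r_squared, 1, tolerance = 1e-8)
  expect_equal(unname(fe2$coefficients["lambda"]), 30, tolerance = 1e-3)

  ## noisy exponential: correct model wins the AIC comparison in most seeds
  wins <- sum(sapply(1:5, function(s) {
    set.seed(s)
    dd <- stats::runif(500, 5, 120)
    yy <- exp(-dd / 30) + stats::rnorm(500, 0, 0.05)
    distance_decay_fit(yy, dd, "exponential")$aic <
      distance_decay_fit(yy, dd, "linear")$aic
  }))
  expect_gte(wins, 4)
})

test_that("partial correlation is exact on identities and recovers planted coupling", {
  set.seed(3)
  ctrl <- stats::rnorm(300)
  x <- 2 * ctrl + stats::rnorm(300)
  f <- partial_edge_correlation(x, x, ctrl)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  ## planted partial correlation 0.3 beyond the control
  set.seed(4)
  n <- 1000
  ctrl <- stats::rnorm(n)
  common <- stats::rnorm(n)
  x <- ctrl + sqrt(0.3) * common + sqrt(0.7) * stats::rnorm(n)
  y <- -0.5 * ctrl + sqrt(0.3) * common + sqrt(0.7) * stats::rnorm(n)
  fp <- partial_edge_correlation(x, y, ctrl)
  expect_lt(abs(unname(fp$coefficients["r"]) - 0.3), 0.06)
})

test_that("partial-correlation p-values are calibrated when both sides are pure control", {
  ps <- sapply(1:200, function(s) {
    set.seed(s)
    ctrl <- stats::rnorm(120)
    x <- ctrl + stats::rnorm(120)
    y <- 2 * ctrl + stats::rnorm(120)
    partial_edge_correlation(x, y, ctrl)$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.045)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the within-module test matches a double-loop oracle and handles flat input", {
  a <- shared_atlas_60()
  lab <- transcortex:::grow_contiguous_partition(a, c(20, 20, 20), seed = 5)
  ns <- permute_modules(lab, a, n = 99, seed = 6)
  set.seed(7)
  cx <- matrix(stats::rnorm(3600), 60, 60)
  cx <- (cx + t(cx)) / 2
  diag(cx) <- 1
  res <- intramodule_coexpression_test(cx, lab, ns)
  acc <- 0; cnt <- 0
  for (i in 1:59) for (j in (i + 1):60) {
    if (lab[i] == lab[j]) { acc <- acc + cx[i, j]; cnt <- cnt + 1 }
  }
  expect_equal(res$observed, acc / cnt, tolerance = 1e-12)
  expect_equal(res$p_value, (1 + sum(res$null >= res$observed)) / 100)
  expect_gt(res$p_value, 0)

  flat <- matrix(0.4, 60, 60); diag(flat) <- 1
  res_flat <- intramodule_coexpression_test(flat, lab, ns)
  expect_equal(res_flat$p_value, 1)
  expect_true(all(res_flat$null == res_flat$observed))
})

test_that("gene-set indices are averaged z-profiles with zero cortical mean", {
  vals <- cbind(gA = c(1, 2, 3, 4), gB = c(10, 30, 20, 40), gC = c(0, 0, 1, 0))
  rownames(vals) <- 1:4
  rex <- transcortex:::new_regional_expression(vals, rep(1L, 4), rep(FALSE, 4))
  idx1 <- gene_set_index(rex, "gA")
  expect_equal(unname(idx1), as.numeric(scale(vals[, "gA"])))

  idx3 <- gene_set_index(rex, c("gA", "gB", "gC"))
  hand <- rowMeans(cbind(scale(vals[, "gA"]), scale(vals[, "gB"]),
                         scale(vals[, "gC"])))
  expect_equal(unname(idx3), unname(hand), tolerance = 1e-12)
  expect_lt(abs(mean(idx3)), 1e-10)
  expect_message(gene_set_index(rex, c("gA", "missing")), "absent")
})

test_that("the degenerate all-gene set reproduces whole-genome coupling in the screen", {
  a <- shared_atlas_60()
  cfg <- sim_config("compact", seed = 8)
  rex <- simulate_regional_expression(a, cfg)
  th <- simulate_thickness(a, cfg)
  scn <- pearson_network(th)$weights
  d <- atlas_distances(a)
  set.seed(9)
  sets <- c(list(all = colnames(rex$values)),
            lapply(stats::setNames(1:5, paste0("S", 1:5)),
                   function(i) sample(colnames(rex$values), 12)))
  sc <- set_coexpression_screen(rex, sets, scn, d)
  whole <- stats::cor(transcortex:::upper_vec(coexpression_matrix(rex)),
                      transcortex:::upper_vec(scn))
  expect_equal(sc$r[sc$set == "all"], whole, tolerance = 1e-12)

  ## every reported per-set statistic equals a from-scratch recomputation
  for (nm in paste0("S", 1:5)) {
    cx <- stats::cor(t(rex$values[, sets[[nm]]]))
    r <- stats::cor(cx[upper.tri(cx)], scn[upper.tri(scn)])
    expect_equal(sc$r_squared[sc$set == nm], r^2, tolerance = 1e-12)
  }
})

test_that("nested F arithmetic matches a hand-rolled RSS computation", {
  set.seed(10)
  n <- 20
  d <- stats::runif(n, 10, 100)
  b <- stats::rnorm(n)
  aa <- stats::rnorm(n)
  y <- 0.3 * b + 0.5 * aa + stats::rnorm(n, 0, 0.3)
  out <- nested_coupling_F(y, aa, b, d)

  res <- function(v) stats::residuals(stats::lm(v ~ log(d)))
  yr <- res(y); ar <- res(aa); br <- res(b)
  rss0 <- sum(stats::residuals(stats::lm(yr ~ br))^2)
  rss1 <- sum(stats::residuals(stats::lm(yr ~ br + ar))^2)
  f_hand <- (rss0 - rss1) / (rss1 / (n - 3))
  expect_equal(out$F, f_hand, tolerance = 1e-10)
  expect_equal(out$df2, n - 3)

  ## no added variance when the competing sets coincide
  same <- nested_coupling_F(y, b, b, d)
  expect_equal(same$F, 0, tolerance = 1e-9)
})

test_that("edge/non-edge contrasts match group means and guard degenerate splits", {
  at <- toy_atlas(k = 5)
  set.seed(11)
  w <- matrix(stats::runif(25, 0.1, 1), 5, 5)
  w <- (w + t(w)) / 2; diag(w) <- 1
  cx <- matrix(stats::rnorm(25), 5, 5); cx <- (cx + t(cx)) / 2; diag(cx) <- 1
  et <- build_edge_table(w, list(genome = cx), at, density = 0.4, ids = 1:5)
  out <- edge_nonedge_contrast(et)
  expect_equal(out$edge_mean, mean(et$coexpr_genome[et$is_edge]))
  expect_equal(out$nonedge_mean, mean(et$coexpr_genome[!et$is_edge]))

  et_full <- build_edge_table(w, list(genome = cx), at, density = 1, ids = 1:5)
  expect_error(edge_nonedge_contrast(et_full), "nonempty")
})

test_that("class tests flag planted over-expression and wire BH correction correctly", {
  classes <- rep(1:7, each = 10)
  expect_true(all(class_expression_test(rep(0, 70), classes)$p_value == 1))

  set.seed(12)
  idx <- stats::rnorm(70, 0, 0.3)
  idx[classes == 1] <- idx[classes == 1] + 1
  res <- class_expression_test(idx, classes)
  expect_lt(res$p_adjusted[res$class == 1], 0.05)
  expect_equal(res$direction[res$class == 1], "over")
  expect_equal(res$p_adjusted, stats::p.adjust(res$p_value, "BH"))
})

test_that("variance partition adds up for orthogonal predictors and solves exactly", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  stopifnot(abs(sum(x1 * x2)) < 1e-12)
  y <- 0.8 * x1 + 0.4 * x2 + 0        # deterministic, orthogonal design
  vp <- variance_partition(y, x1, x2, rep(0, n))
  expect_equal(vp$combined, vp$distance + vp$set_coexpr, tolerance = 1e-8)
  expect_equal(vp$combined, 1, tolerance = 1e-12)

  set.seed(13)
  ld <- stats::rnorm(50)
  cx <- stats::rnorm(50)
  cls <- rep(0:1, 25)
  y2 <- 0.5 * ld - 0.3 * cx + stats::rnorm(50, 0, 0.5)
  vp2 <- variance_partition(y2, ld, cx, cls)
  X <- cbind(1, ld, cx)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  rss <- sum((y2 - X %*% beta)^2)
  expect_equal(vp2$combined, 1 - rss / sum((y2 - mean(y2))^2),
               tolerance = 1e-10)
})
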