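#' Edge table of paired region-pair quantities
#'
#' One row per unordered region pair, carrying structural covariance,
#' whole-genome (and per-set) co-expression, Euclidean distance, and the
#' edge/non-edge flag at a given density: the substrate of all coupling
#' statistics.
#'
#' @param scn a [pearson_network] of kind SCN (or bare symmetric matrix).
#' @param coexpr named list of co-expression matrices (must include
#'   `genome`; any further entries become `coexpr_<name>` columns).
#' @param atlas a [make_atlas] atlas.
#' @param density density at which `is_edge` is evaluated.
#' @param ids region ids (default left hemisphere), shared by all matrices.
#' @return data frame of class `edge_table` with columns `i`, `j`,
#'   `scn_weight`, `coexpr_genome`, `coexpr_*`, `distance`, `is_edge`.
#' @export
build_edge_table <- function(scn, coexpr, atlas, density = 0.10,
                             ids = left_ids(atlas)) {
  w <- if (inherits(scn, "weighted_network")) scn$weights else scn
  stop_if_not_symmetric(w, "scn weight")
  stopifnot(is.list(coexpr), "genome" %in% names(coexpr))
  n <- ncol(w)
  stopifnot(length(ids) == n)
  for (m in coexpr) {
    stop_if_not_symmetric(m, "co-expression")
    stopifnot(ncol(m) == n)
  }
  pairs <- pair_index(n)
  d <- atlas_distances(atlas, ids)
  bg <- binarize_density(w, density)
  out <- data.frame(i = ids[pairs[, "i"]], j = ids[pairs[, "j"]],
                    scn_weight = upper_vec(w))
  for (nm in names(coexpr)) out[[paste0("coexpr_", nm)]] <- upper_vec(coexpr[[nm]])
  out$distance <- upper_vec(d)
  out$is_edge <- upper_vec(bg$adjacency)
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Co-expression matrix from regional expression
#'
#' Pearson correlation between regional expression profiles, optionally
#' restricted to a gene set.
#'
#' @param rex a `regional_expression`.
#' @param genes optional character vector restricting the profile to a gene
#'   set (>= 2 genes must be present).
#' @return symmetric regions x regions correlation matrix.
#' @export
coexpression_matrix <- function(rex, genes = NULL) {
  v <- rex$values
  if (!is.null(genes)) {
    present <- intersect(genes, colnames(v))
    if (length(present) < 2) {
      stop("fewer than 2 genes of the set present in the expression matrix",
           call. = FALSE)
    }
    v <- v[, present, drop = FALSE]
  }
  stats::cor(t(v))
}

new_coupling_fit <- function(form, coefficients, r_squared, aic, df_residual,
                             p_value, n) {
  structure(list(form = form, coefficients = coefficients,
                 r_squared = r_squared, aic = aic,
                 df_residual = df_residual, p_value = p_value, n = n),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("Coupling fit (%s, n = %d): R^2 = %.4f, AIC = %.2f, p = %.3g\n",
              x$form, x$n, x$r_squared, x$aic, x$p_value))
  co <- paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
              collapse = ", ")
  cat(" ", co, "\n")
  invisible(x)
}

# Gaussian-likelihood AIC up to the constant: n*log(RSS/n) + 2k.
aic_rss <- function(rss, n, k) n * log(rss / n) + 2 * k

#' Distance-decay model fit with AIC
#'
#' Fits a region-pair quantity (structural covariance or co-expression) as
#' a function of inter-regional Euclidean distance, either linearly
#' (`y = b0 + b1 d`) or exponentially (`y = a exp(-d / lambda)`), by least
#' squares; the exponential decay length is profiled over a multistart grid
#' and polished by golden-section search. AIC (Gaussian form,
#' `n log(RSS/n) + 2k`) supports selecting between the two forms.
#'
#' @param y numeric response per region pair.
#' @param distance Euclidean distance per pair (mm).
#' @param form `"linear"` or `"exponential"`.
#' @param lambda_grid multistart grid of decay lengths (mm).
#' @return a `coupling_fit` (coefficients, `r_squared`, `aic`, p-value of
#'   the slope for the linear form).
#' @export
distance_decay_fit <- function(y, distance,
                               form = c("linear", "exponential"),
                               lambda_grid = c(5, 10, 20, 30, 50, 80, 120)) {
  form <- match.arg(form)
  ok <- is.finite(y) & is.finite(distance)
  y <- y[ok]; d <- distance[ok]
  n <- length(y)
  if (n < 10) stop("need at least 10 pairs", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (form == "linear") {
    fit <- stats::lm(y ~ d)
    rss <- sum(fit$residuals^2)
    pv <- suppressWarnings(summary(fit))$coefficients["d", 4]
    return(new_coupling_fit(
      "linear", c(intercept = unname(stats::coef(fit)[1]),
                  slope = unname(stats::coef(fit)[2])),
      1 - rss / tss, aic_rss(rss, n, 2L), n - 2L, pv, n))
  }
  ## exponential: alpha profiled analytically for fixed lambda
  rss_lambda <- function(l) {
    x <- exp(-d / l)
    alpha <- sum(x * y) / sum(x * x)
    sum((y - alpha * x)^2)
  }
  r <- vapply(lambda_grid, rss_lambda, numeric(1))
  best <- which.min(r)
  lo <- lambda_grid[max(1L, best - 1L)]
  hi <- lambda_grid[min(length(lambda_grid), best + 1L)]
  opt <- stats::optimize(rss_lambda, c(lo * 0.5, hi * 1.5))
  lambda <- opt$minimum
  x <- exp(-d / lambda)
  alpha <- sum(x * y) / sum(x * x)
  rss <- opt$objective
  new_coupling_fit(
    "exponential", c(alpha = alpha, lambda = lambda),
    1 - rss / tss, aic_rss(rss, n, 2L), n - 2L, NA_real_, n)
}

#' Partial correlation between two edge-wise quantities
#'
#' Residualizes `x` and `y` on a control variable (typically log distance),
#' then reports the Pearson correlation of the residuals, its squared value,
#' and a t-distribution p-value with `n - 3` degrees of freedom.
#'
#' @param x,y numeric vectors per region pair.
#' @param control nuisance vector (e.g. `log(distance)`).
#' @return a `coupling_fit` with coefficients `r` (partial correlation).
#' @export
partial_edge_correlation <- function(x, y, control) {
  ok <- is.finite(x) & is.finite(y) & is.finite(control)
  x <- x[ok]; y <- y[ok]; control <- control[ok]
  n <- length(x)
  rx <- stats::lm.fit(cbind(1, control), x)$residuals
  ry <- stats::lm.fit(cbind(1, control), y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tval <- r * sqrt(df / (1 - r^2))
  pv <- 2 * stats::pt(-abs(tval), df)
  rss <- sum((ry - r * stats::sd(ry) / stats::sd(rx) * rx)^2)
  new_coupling_fit("partial", c(r = r), r^2, aic_rss(rss, n, 3L), df, pv, n)
}

#' Within-module co-expression against the spatially contiguous null
#'
#' The observed statistic is the mean co-expression over all unordered
#' region pairs sharing a module (or cytoarchitectonic class); the null
#' distribution re-evaluates it on spatially contiguous permuted partitions
#' that preserve the number and sizes of modules. Rejection uses the 95th
#' percentile of the null; the permutation p-value uses the
#' `(1 + #{null >= observed}) / (1 + n)` convention and can never be 0.
#'
#' @param coexpr symmetric co-expression matrix.
#' @param labels module or class labels over the same regions.
#' @param null_set a [permute_modules] null set over the same atlas (for
#'   class labels, built from the class partition with the same machinery).
#' @return object of class `module_coexpr_test`: `observed`, `null`
#'   (vector), `q95`, `p_value`, `significant`.
#' @export
intramodule_coexpression_test <- function(coexpr, labels, null_set) {
  stop_if_not_symmetric(coexpr, "co-expression")
  lab <- module_labels(labels)
  stopifnot(length(lab) == ncol(coexpr),
            nrow(null_set$labels) == ncol(coexpr))
  obs <- within_group_mean(coexpr, lab)
  null <- apply(null_set$labels, 2, function(l) within_group_mean(coexpr, l))
  q95 <- stats::quantile(null, 0.95, names = FALSE)
  p <- (1 + sum(null >= obs)) / (1 + length(null))
  structure(list(observed = obs, null = null, q95 = q95, p_value = p,
                 significant = obs > q95),
            class = "module_coexpr_test")
}

within_group_mean <- function(m, lab) {
  same <- outer(lab, lab, `==`) & upper.tri(m)
  mean(m[same])
}

#' @export
print.module_coexpr_test <- function(x, ...) {
  cat(sprintf(
    "Within-module co-expression: observed %.4f vs null 95th pct %.4f (p = %.4g)\n",
    x$observed, x$q95, x$p_value))
  invisible(x)
}

#' Gene-set expression index
#'
#' Z-scores each set gene across regions and averages the z-profiles,
#' giving one index value per region (e.g. the HSE expression index).
#'
#' @param rex a `regional_expression`.
#' @param genes character vector of set gene symbols (missing genes are
#'   dropped with a message).
#' @return numeric per-region index (mean z across set genes).
#' @export
gene_set_index <- function(rex, genes) {
  present <- intersect(genes, colnames(rex$values))
  if (!length(present)) stop("no set genes present", call. = FALSE)
  if (length(present) < length(genes)) {
    message(length(genes) - length(present), " set gene(s) absent from the ",
            "expression matrix")
  }
  z <- scale(rex$values[, present, drop = FALSE])
  stats::setNames(rowMeans(z), rownames(rex$values))
}

#' Screen gene sets for co-expression coupling with structural covariance
#'
#' For every gene set, restricts the co-expression matrix to the set's
#' genes and correlates its region-pair values with structural covariance,
#' both raw and after residualizing log distance from each side.
#'
#' @param rex a `regional_expression`.
#' @param gene_sets named list of gene symbol vectors (e.g. [read_gmt]).
#' @param scn_weights symmetric structural covariance matrix.
#' @param distance region-pair distance matrix (mm).
#' @param min_genes sets with fewer present genes are skipped.
#' @return data frame of class `set_screen` (one row per retained set):
#'   `set`, `n_genes`, `r`, `r_squared`, `partial_r_squared`, and ranks
#'   `rank_r2` / `rank_partial_r2` (1 = strongest coupling).
#' @export
set_coexpression_screen <- function(rex, gene_sets, scn_weights, distance,
                                    min_genes = 2L) {
  stop_if_not_symmetric(scn_weights, "scn weight")
  scn_v <- upper_vec(scn_weights)
  ld <- log(upper_vec(distance))
  rows <- lapply(names(gene_sets), function(nm) {
    present <- intersect(gene_sets[[nm]], colnames(rex$values))
    if (length(present) < min_genes) return(NULL)
    cx <- upper_vec(coexpression_matrix(rex, present))
    pr <- partial_edge_correlation(cx, scn_v, ld)
    data.frame(set = nm, n_genes = length(present),
               r = stats::cor(cx, scn_v),
               r_squared = stats::cor(cx, scn_v)^2,
               partial_r_squared = pr$r_squared)
  })
  out <- do.call(rbind, rows)
  out$rank_r2 <- rank(-out$r_squared, ties.method = "min")
  out$rank_partial_r2 <- rank(-out$partial_r_squared, ties.method = "min")
  class(out) <- c("set_screen", "data.frame")
  out
}

#' Nested F-test: does set co-expression add coupling beyond a reference?
#'
#' All variables are residualized on log distance; the F statistic compares
#' the residual sum of squares of `scn ~ B` against `scn ~ B + A`
#' (df1 = 1, df2 = n - 3), testing whether co-expression `A` (e.g. the HSE
#' set) explains structural covariance beyond co-expression `B` (e.g. the
#' whole genome), after the shared distance constraint.
#'
#' @param scn_weight structural covariance per pair.
#' @param coexpr_a,coexpr_b competing co-expression values per pair.
#' @param distance Euclidean distance per pair (mm).
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
nested_coupling_F <- function(scn_weight, coexpr_a, coexpr_b, distance) {
  ld <- log(distance)
  res <- function(v) stats::lm.fit(cbind(1, ld), v)$residuals
  y <- res(scn_weight); a <- res(coexpr_a); b <- res(coexpr_b)
  n <- length(y)
  rss0 <- sum(stats::lm.fit(cbind(1, b), y)$residuals^2)
  rss1 <- sum(stats::lm.fit(cbind(1, b, a), y)$residuals^2)
  df2 <- n - 3L
  Fstat <- ((rss0 - rss1) / 1) / (rss1 / df2)
  list(F = Fstat, df1 = 1L, df2 = df2,
       p_value = stats::pf(Fstat, 1, df2, lower.tail = FALSE))
}

#' Mean co-expression at edges versus non-edges
#'
#' @param edge_table an [build_edge_table] result.
#' @param column co-expression column to contrast (default whole genome).
#' @return list with `edge_mean`, `nonedge_mean`, `difference`, and a Welch
#'   two-sample comparison (`t`, `p_value`), reported descriptively.
#' @export
edge_nonedge_contrast <- function(edge_table, column = "coexpr_genome") {
  stopifnot(column %in% names(edge_table))
  v <- edge_table[[column]]
  e <- edge_table$is_edge
  if (!any(e) || all(e)) {
    stop("both edge and non-edge groups must be nonempty", call. = FALSE)
  }
  tt <- stats::t.test(v[e], v[!e])
  list(edge_mean = mean(v[e]), nonedge_mean = mean(v[!e]),
       difference = mean(v[e]) - mean(v[!e]),
       t = unname(tt$statistic), p_value = tt$p.value)
}

#' Per-class expression test of a gene-set index
#'
#' One-sample two-sided t-test of the regional index against 0 within each
#' cytoarchitectonic class (the index is z-based, so the whole-cortex mean
#' is ~0), with Benjamini-Hochberg correction across classes.
#'
#' @param index per-region index (e.g. [gene_set_index]).
#' @param classes per-region class labels (e.g. `ve_class`).
#' @param min_regions classes with fewer regions are skipped.
#' @return data frame: `class`, `n`, `mean`, `t`, `p_value`, `p_adjusted`,
#'   `direction`.
#' @export
class_expression_test <- function(index, classes, min_regions = 2L) {
  stopifnot(length(index) == length(classes))
  cls <- sort(unique(classes))
  rows <- lapply(cls, function(c) {
    v <- index[classes == c]
    if (length(v) < min_regions) return(NULL)
    if (stats::sd(v) < .Machine$double.eps) {
      ## degenerate constant index: no evidence against the null
      return(data.frame(class = c, n = length(v), mean = mean(v),
                        t = 0, p_value = 1))
    }
    tt <- stats::t.test(v, mu = 0)
    data.frame(class = c, n = length(v), mean = mean(v),
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$mean > 0, "over", "under")
  out
}

#' Variance partition of structural covariance
#'
#' Ordinary least squares R-squared of structural covariance on each
#' predictor alone (log distance, a gene-set co-expression, same-class
#' co-membership) and on log distance plus the co-expression jointly.
#'
#' @param scn_weight structural covariance per pair.
#' @param log_distance log Euclidean distance per pair.
#' @param set_coexpr gene-set co-expression per pair (e.g. HSE).
#' @param class_comembership logical/0-1 same-class indicator per pair.
#' @return list of R-squared values: `distance`, `set_coexpr`, `class`,
#'   `combined` (distance + set co-expression).
#' @export
variance_partition <- function(scn_weight, log_distance, set_coexpr,
                               class_comembership) {
  r2 <- function(fit, y) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  y <- scn_weight
  list(
    distance = r2(stats::lm.fit(cbind(1, log_distance), y), y),
    set_coexpr = r2(stats::lm.fit(cbind(1, set_coexpr), y), y),
    class = r2(stats::lm.fit(cbind(1, as.numeric(class_comembership)), y), y),
    combined = r2(stats::lm.fit(cbind(1, log_distance, set_coexpr), y), y))
}
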