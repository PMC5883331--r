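#' Select one probe per gene by highest mean expression
#'
#' For genes measured by multiple microarray probes, keeps the probe with
#' the highest average expression across all (cortical) samples. Probes
#' without a gene annotation are excluded first; exact ties are broken by
#' the lexicographically smaller probe id.
#'
#' @param probes data frame with columns `probe_id` (unique) and
#'   `gene_symbol` (`NA` for unannotated probes).
#' @param expr samples x probes numeric matrix with probe ids as column
#'   names.
#' @return named character vector mapping gene symbol to selected probe id,
#'   with attribute `n_unannotated` (probes dropped for missing symbols).
#' @export
select_probe_per_gene <- function(probes, expr) {
  stopifnot(!anyDuplicated(probes$probe_id),
            all(probes$probe_id %in% colnames(expr)))
  ann <- probes[!is.na(probes$gene_symbol), , drop = FALSE]
  means <- colMeans(expr[, ann$probe_id, drop = FALSE])
  ord <- order(ann$gene_symbol, -means, ann$probe_id)
  first <- !duplicated(ann$gene_symbol[ord])
  map <- stats::setNames(ann$probe_id[ord][first], ann$gene_symbol[ord][first])
  attr(map, "n_unannotated") <- nrow(probes) - nrow(ann)
  map
}

#' Reflect right-hemisphere samples onto the left hemisphere
#'
#' Mirrors every right-hemisphere sample to its contralateral position by
#' flipping the sign of the first (left-right) coordinate, and relabels it
#' `L`; left-hemisphere samples are untouched. Used to increase the sample
#' density of the analysed hemisphere before parcel assignment.
#'
#' @param samples data frame with columns `x`, `y`, `z`, `hemisphere`.
#' @return the data frame with all rows in the left hemisphere.
#' @export
reflect_right_hemisphere <- function(samples) {
  require_columns(samples, c("x", "y", "z", "hemisphere"), "sample table")
  r <- samples$hemisphere == "R"
  samples$x[r] <- -samples$x[r]
  samples$hemisphere[r] <- "L"
  samples
}

#' Assign expression samples to parcels with a sub-cortical tolerance
#'
#' Each cortical sample is assigned to the parcel whose surface contains it;
#' samples just outside the cortical surface (typically mis-registered into
#' the subjacent white matter) are assigned to the nearest parcel surface if
#' within `tolerance_mm`, and dropped otherwise. Containment is judged at
#' the atlas point-cloud resolution: the distance to a parcel surface is the
#' distance to its nearest surface point minus `atlas$resolution`, floored
#' at zero. Ties go to the smaller distance, then the smaller region id.
#' Non-cortical samples are dropped up front.
#'
#' @param samples data frame (`sample_id`, `x`, `y`, `z`, `hemisphere`,
#'   `cortical_flag`), already reflected to the left hemisphere.
#' @param atlas a [make_atlas] atlas with surface points.
#' @param tolerance_mm assignment tolerance beyond the parcel surface (mm).
#' @return data frame (`sample_id`, `region_id`, `distance`) with `NA`
#'   region for dropped samples, and attribute `counts`:
#'   `c(n_input, n_assigned, n_dropped_tolerance, n_noncortical)`.
#' @export
assign_samples_to_parcels <- function(samples, atlas, tolerance_mm = 2) {
  if (is.null(atlas$surface_points)) {
    stop("atlas has no surface points; cannot assign samples", call. = FALSE)
  }
  require_columns(samples,
                  c("sample_id", "x", "y", "z", "hemisphere", "cortical_flag"),
                  "sample table")
  if (any(samples$hemisphere != "L")) {
    stop("samples must be reflected to the left hemisphere first ",
         "(see reflect_right_hemisphere)", call. = FALSE)
  }
  ids <- left_ids(atlas)
  cort <- samples$cortical_flag
  xyz <- as.matrix(samples[, c("x", "y", "z")])
  n_s <- nrow(samples)
  best_d <- rep(Inf, n_s)
  best_r <- rep(NA_integer_, n_s)
  for (rid in ids) {
    sp <- atlas$surface_points[[match(rid, atlas$regions$region_id)]]
    d2 <- outer(rowSums(xyz^2), rowSums(sp^2), `+`) - 2 * tcrossprod(xyz, sp)
    dmin <- sqrt(pmax(apply(d2, 1, min), 0))
    upd <- dmin < best_d                # strict: ties keep smaller region id
    best_d[upd] <- dmin[upd]
    best_r[upd] <- rid
  }
  d_surf <- pmax(0, best_d - atlas$resolution)
  ok <- cort & d_surf <= tolerance_mm
  out <- data.frame(sample_id = samples$sample_id,
                    region_id = ifelse(ok, best_r, NA_integer_),
                    distance = d_surf)
  attr(out, "counts") <- c(n_input = n_s, n_assigned = sum(ok),
                           n_dropped_tolerance = sum(cort & !ok),
                           n_noncortical = sum(!cort))
  out
}

new_regional_expression <- function(values, n_samples, interpolated) {
  structure(list(values = values, n_samples = n_samples,
                 interpolated = interpolated),
            class = "regional_expression")
}

#' @export
print.regional_expression <- function(x, ...) {
  cat(sprintf("Regional expression: %d regions x %d genes\n",
              nrow(x$values), ncol(x$values)))
  if (!all(is.na(x$n_samples)))
    cat(sprintf("  samples per region: median %d, %d interpolated parcel(s)\n",
                stats::median(x$n_samples, na.rm = TRUE), sum(x$interpolated)))
  invisible(x)
}

#' Aggregate assigned samples to a regions x genes expression matrix
#'
#' Probe expression is collapsed to genes via `gene_map`, z-normalized per
#' gene within each donor across that donor's assigned cortical samples
#' (making donors with different microarray scales commensurable), pooled
#' over donors (ipsilateral plus reflected contralateral samples), and
#' summarized per parcel as the median across pooled samples. Parcels with
#' no assigned sample are filled with the mean of their spatially adjacent
#' sampled parcels and flagged as interpolated.
#'
#' @param samples sample data frame (must include `sample_id`, `donor_id`).
#' @param expr samples x probes matrix (row names = sample ids).
#' @param gene_map gene -> probe map from [select_probe_per_gene].
#' @param assignment result of [assign_samples_to_parcels].
#' @param atlas a [make_atlas] atlas (supplies adjacency for interpolation).
#' @return a `regional_expression` object over the left hemisphere: `values`
#'   (regions x genes), `n_samples`, `interpolated`.
#' @export
aggregate_regional_expression <- function(samples, expr, gene_map,
                                          assignment, atlas) {
  ids <- left_ids(atlas)
  keep <- !is.na(assignment$region_id)
  if (!any(keep)) stop("no assigned samples", call. = FALSE)
  sid <- assignment$sample_id[keep]
  region <- assignment$region_id[keep]
  donor <- samples$donor_id[match(sid, samples$sample_id)]
  G <- expr[match(sid, rownames(expr)), gene_map, drop = FALSE]
  colnames(G) <- names(gene_map)

  for (d in unique(donor)) {
    rows <- donor == d
    mu <- colMeans(G[rows, , drop = FALSE])
    sd <- apply(G[rows, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    G[rows, ] <- sweep(sweep(G[rows, , drop = FALSE], 2, mu), 2, sd, `/`)
  }

  vals <- matrix(NA_real_, length(ids), ncol(G),
                 dimnames = list(ids, colnames(G)))
  n_samp <- integer(length(ids))
  for (k in seq_along(ids)) {
    rows <- region == ids[k]
    n_samp[k] <- sum(rows)
    if (n_samp[k] > 0) {
      vals[k, ] <- apply(G[rows, , drop = FALSE], 2, stats::median)
    }
  }
  interpolated <- n_samp == 0
  if (any(interpolated)) {
    idx <- match(ids, atlas$regions$region_id)
    adj <- atlas$adjacency[idx, idx, drop = FALSE]
    for (k in which(interpolated)) {
      nb <- which(adj[k, ] & n_samp > 0)
      if (!length(nb)) {
        stop("region ", ids[k],
             " has no samples and no sampled neighbours; cannot interpolate",
             call. = FALSE)
      }
      vals[k, ] <- colMeans(vals[nb, , drop = FALSE])
    }
  }
  new_regional_expression(vals, n_samp, interpolated)
}

#' One-step mapping from simulated donors to regional expression
#'
#' Convenience wrapper chaining probe selection, hemisphere reflection,
#' parcel assignment and aggregation on a [simulate_cortex] bundle.
#'
#' @param sim a `cortex_simulation`.
#' @param tolerance_mm assignment tolerance (mm).
#' @return a `regional_expression` object, with the assignment counts as
#'   attribute `mapping_counts`.
#' @export
map_expression <- function(sim, tolerance_mm = 2) {
  cortical <- sim$samples$cortical_flag
  gene_map <- select_probe_per_gene(sim$probes,
                                    sim$expr[cortical, , drop = FALSE])
  refl <- reflect_right_hemisphere(sim$samples)
  asn <- assign_samples_to_parcels(refl, sim$atlas, tolerance_mm)
  rex <- aggregate_regional_expression(refl, sim$expr, gene_map, asn,
                                       sim$atlas)
  attr(rex, "mapping_counts") <- attr(asn, "counts")
  rex
}
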