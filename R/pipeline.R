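#' Run the full coupling pipeline end to end
#'
#' Chains expression mapping, network construction, graph topology with
#' rewired nulls, consensus community detection, the spatially contiguous
#' permutation null, and the coupling statistics, over a grid of connection
#' densities and modularity resolutions, and returns a single nested report.
#'
#' @param sim a [simulate_cortex] bundle (or any list with the same fields).
#' @param densities connection densities to analyse.
#' @param gammas Louvain resolution parameters.
#' @param n_rewire rewired nulls per graph for topology normalization.
#' @param n_spatial spatially contiguous null partitions per test.
#' @param consensus_runs Louvain repetitions per consensus.
#' @param gene_sets named list of gene sets; defaults to the packaged HSE
#'   set.
#' @param seed master seed for all stochastic stages.
#' @param out_dir if non-NULL, the report is also written as
#'   `report.json` under this directory.
#' @return a nested list report (class `pipeline_report`) with elements
#'   `config`, `mapping`, and one entry per density carrying topology,
#'   communities per gamma, null tests and coupling statistics.
#' @export
run_pipeline <- function(sim, densities = c(0.05, 0.10, 0.15),
                         gammas = c(1, 2), n_rewire = 1000L,
                         n_spatial = 1000L, consensus_runs = 1000L,
                         gene_sets = list(HSE = hse_genes()),
                         seed = 1L, out_dir = NULL) {
  atlas <- sim$atlas
  ids <- left_ids(atlas)
  rex <- map_expression(sim)
  scn <- pearson_network(sim$thickness, kind = "SCN")
  coexpr_genome <- coexpression_matrix(rex)
  coexpr_sets <- lapply(gene_sets, function(g) coexpression_matrix(rex, g))
  tbn <- structure(list(weights = coexpr_genome, kind = "TBN",
                        n_obs = ncol(rex$values)),
                   class = "weighted_network")
  d <- atlas_distances(atlas, ids)
  ve <- atlas$regions$ve_class[match(ids, atlas$regions$region_id)]

  report <- list(
    config = list(densities = densities, gammas = gammas, seed = seed,
                  n_rewire = n_rewire, n_spatial = n_spatial,
                  consensus_runs = consensus_runs,
                  preset = sim$config$preset, sim_seed = sim$config$seed),
    mapping = as.list(attr(rex, "mapping_counts")),
    densities = list())

  first_set <- names(gene_sets)[1]
  for (rho in densities) {
    key <- sprintf("%.2f", rho)
    scn_g <- binarize_density(scn, rho)
    tbn_g <- binarize_density(tbn, rho)
    nulls_scn <- rewire_null(scn_g, n = n_rewire,
                             seed = child_seed(seed, paste0("scnnull", key)))
    nulls_tbn <- rewire_null(tbn_g, n = n_rewire,
                             seed = child_seed(seed, paste0("tbnnull", key)))
    entry <- list(
      scn = c(unclass(global_metrics(scn_g)),
              sigma = as.numeric(small_worldness(scn_g, nulls_scn))),
      tbn = c(unclass(global_metrics(tbn_g)),
              sigma = as.numeric(small_worldness(tbn_g, nulls_tbn))),
      rich_club_scn = rich_club(scn_g, nulls_scn),
      rich_club_tbn = rich_club(tbn_g, nulls_tbn),
      gamma = list())

    et <- build_edge_table(scn, c(list(genome = coexpr_genome), coexpr_sets),
                           atlas, density = rho, ids = ids)
    set_col <- paste0("coexpr_", first_set)
    entry$coupling <- list(
      scn_distance = list(
        linear = unclass(distance_decay_fit(et$scn_weight, et$distance, "linear")),
        exponential = unclass(distance_decay_fit(et$scn_weight, et$distance, "exponential"))),
      coexpr_distance = list(
        linear = unclass(distance_decay_fit(et$coexpr_genome, et$distance, "linear")),
        exponential = unclass(distance_decay_fit(et$coexpr_genome, et$distance, "exponential"))),
      genome_r_squared = stats::cor(et$scn_weight, et$coexpr_genome)^2,
      genome_partial = unclass(partial_edge_correlation(
        et$coexpr_genome, et$scn_weight, log(et$distance))),
      set_r_squared = stats::cor(et$scn_weight, et[[set_col]])^2,
      nested_F = nested_coupling_F(et$scn_weight, et[[set_col]],
                                   et$coexpr_genome, et$distance),
      edge_contrast_genome = edge_nonedge_contrast(et, "coexpr_genome"),
      edge_contrast_set = edge_nonedge_contrast(et, set_col),
      variance_partition = variance_partition(
        et$scn_weight, log(et$distance), et[[set_col]],
        ve[match(et$i, ids)] == ve[match(et$j, ids)]))

    for (g in gammas) {
      gkey <- sprintf("%g", g)
      part_scn <- consensus_partition(scn_g, gamma = g, runs = consensus_runs,
                                      seed = child_seed(seed, paste0("scn", key, gkey)))
      part_tbn <- consensus_partition(tbn_g, gamma = g, runs = consensus_runs,
                                      seed = child_seed(seed, paste0("tbn", key, gkey)))
      nulls_sp <- permute_modules(part_scn, atlas, n = n_spatial,
                                  seed = child_seed(seed, paste0("sp", key, gkey)))
      intra <- intramodule_coexpression_test(coexpr_genome, part_scn, nulls_sp)
      intra_set <- intramodule_coexpression_test(coexpr_sets[[first_set]],
                                                 part_scn, nulls_sp)
      pc <- participation_coefficient(scn_g, part_scn)
      entry$gamma[[gkey]] <- list(
        scn_modules = length(part_scn$sizes), scn_Q = part_scn$Q,
        scn_sizes = part_scn$sizes,
        tbn_modules = length(part_tbn$sizes), tbn_Q = part_tbn$Q,
        intramodule_genome = intra[c("observed", "q95", "p_value", "significant")],
        intramodule_set = intra_set[c("observed", "q95", "p_value", "significant")],
        participation_mean = mean(pc),
        spatial_null_rejected = nulls_sp$n_rejected)
    }

    ## von Economo classes with the same null machinery (gamma-independent)
    nulls_ve <- permute_modules(ve, atlas, n = n_spatial,
                                seed = child_seed(seed, paste0("ve", key)))
    entry$ve_class <- list(
      intraclass_genome = intramodule_coexpression_test(
        coexpr_genome, ve, nulls_ve)[c("observed", "q95", "p_value", "significant")])
    report$densities[[key]] <- entry
  }

  ## density-independent nodal analyses at the middle density
  rho0 <- densities[ceiling(length(densities) / 2)]
  scn_g0 <- binarize_density(scn, rho0)
  idx <- gene_set_index(rex, gene_sets[[first_set]])
  dd <- degree_and_distance(scn_g0, atlas, ids)
  fit_deg <- stats::lm(idx ~ dd$nodes$degree)
  report$index <- list(
    set = first_set,
    class_test = class_expression_test(idx, ve),
    degree_r_squared = summary(fit_deg)$r.squared,
    degree_distance_r_squared = summary(
      stats::lm(dd$nodes$degree ~ dd$nodes$mean_distance))$r.squared)

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(strip_classes(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report | densities:", paste(names(x$densities), collapse = " "),
      "| seed:", x$config$seed, "\n")
  for (key in names(x$densities)) {
    e <- x$densities[[key]]
    cat(sprintf(
      "  rho=%s  SCN: Cp %.3f Lp %.2f sigma %.2f | genome R2 %.3f | F(HSE>genome) %.1f\n",
      key, e$scn$Cp, e$scn$Lp, e$scn$sigma,
      e$coupling$genome_r_squared, e$coupling$nested_F$F))
    for (g in names(e$gamma)) {
      eg <- e$gamma[[g]]
      cat(sprintf(
        "    gamma=%s: %d SCN modules (Q=%.3f), intra-module p=%.3g\n",
        g, eg$scn_modules, eg$scn_Q, eg$intramodule_genome$p_value))
    }
  }
  invisible(x)
}
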