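#' Simulation configuration
#'
#' Assembles the parameters of the synthetic cortex generator. The
#' `"full"` preset mirrors the study conditions the pipeline is designed
#' for: a 152-parcel left hemisphere, 296 subjects' cortical thickness with
#' planted modular covariance and exponential distance decay, six expression
#' donors (two sampled bilaterally) with spatially autocorrelated gene
#' profiles, multiple probes per gene, uneven per-parcel sampling with one
#' deliberately empty parcel, and a 19-gene planted set whose regional
#' profile tracks the degree of the planted covariance graph. The
#' `"compact"` preset is a 60-parcel, 4-module reduction used for fast
#' statistical experiments.
#'
#' @param preset `"full"` or `"compact"`.
#' @param seed master integer seed; every stage derives its own stream from
#'   it, so adding a stage does not perturb the others.
#' @param ... named overrides of any default listed below.
#' @return a list of class `sim_config`.
#' @details Fields: `n_regions`, `n_subjects`, `n_genes`, `n_donors`,
#'   `samples_per_donor`, `n_modules`, `module_effect` (within-module
#'   correlation increment), `base_corr` (amplitude of the exponential
#'   distance decay), `decay_length` (mm), `coupled_set_size`,
#'   `coupling_strength` (0..1; 0 fully decouples expression from the planted
#'   partition and degree), `expr_module_amp`, `expr_signal_frac` (share of
#'   each background gene's regional variance carried by the shared
#'   spatial/module field rather than by gene-specific variation),
#'   `noise_sd`, `probe_noise`, `probe_counts`, `frac_unannotated`,
#'   `frac_far`, `frac_noncortical`, `frac_right`, `n_bilateral_donors`,
#'   `sampling_concentration` (gamma shape controlling how uneven per-parcel
#'   sample counts are), `age_effect` (0 = no age covariate).
#' @export
sim_config <- function(preset = c("full", "compact"), seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_regions = 152L, n_subjects = 296L, n_genes = 400L,
    n_donors = 6L, samples_per_donor = 250L,
    n_modules = 9L, module_effect = 0.5, base_corr = 0.45, decay_length = 30,
    coupled_set_size = 19L, coupling_strength = 0.7, expr_module_amp = 0.5,
    expr_signal_frac = 0.15,
    noise_sd = 0.2, probe_noise = 0.1, probe_counts = 1:3,
    frac_unannotated = 0.03, frac_far = 0.04, frac_noncortical = 0.05,
    frac_right = 0.4, n_bilateral_donors = 2L, sampling_concentration = 1.2,
    age_effect = 0, seed = as.integer(seed), preset = preset
  )
  if (preset == "compact") {
    cfg[c("n_regions", "n_subjects", "n_genes", "n_modules",
          "samples_per_donor")] <- list(60L, 200L, 200L, 4L, 120L)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  counts <- c("n_regions", "n_subjects", "n_genes", "n_donors",
              "samples_per_donor", "n_modules", "coupled_set_size")
  stopifnot(all(unlist(cfg[counts]) >= 1),
            cfg$coupling_strength >= 0, cfg$coupling_strength <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Project a correlation matrix to the nearest positive semi-definite one
#'
#' Eigenvalue clipping followed by re-normalization to unit diagonal. The
#' relative Frobenius-norm change is recorded; if it exceeds `max_change`
#' the target structure is considered infeasible and an error is thrown.
#'
#' @param C symmetric matrix with unit diagonal.
#' @param eps floor applied to eigenvalues.
#' @param max_change maximum tolerated relative Frobenius change.
#' @return PSD correlation matrix with attribute `frobenius_change`.
#' @export
nearest_psd_correlation <- function(C, eps = 1e-7, max_change = 0.10) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= eps) {
    attr(C, "frobenius_change") <- 0
    return(C)
  }
  v <- pmax(e$values, eps)
  B <- e$vectors %*% (v * t(e$vectors))
  B <- stats::cov2cor(B)
  change <- norm(B - C, "F") / norm(C, "F")
  if (change > max_change) {
    stop(sprintf(
      "requested correlation structure is far from PSD (relative change %.3f > %.2f)",
      change, max_change), call. = FALSE)
  }
  attr(B, "frobenius_change") <- change
  B
}

# Deterministic planted structure shared by the thickness and expression
# generators: contiguous planted partition, target thickness correlation
# (distance decay + within-module increment, PSD-projected), and the degree
# of the planted covariance graph at 10% density.
planted_structure <- function(atlas, config) {
  ids <- left_ids(atlas)
  n <- length(ids)
  sizes <- rep(n %/% config$n_modules, config$n_modules)
  sizes[seq_len(n %% config$n_modules)] <- sizes[seq_len(n %% config$n_modules)] + 1L
  partition <- grow_contiguous_partition(atlas, sizes, config$seed, ids = ids)
  d <- atlas_distances(atlas, ids)
  C <- config$base_corr * exp(-d / config$decay_length)
  same <- outer(partition, partition, `==`)
  C[same] <- C[same] + config$module_effect
  diag(C) <- 1
  C <- nearest_psd_correlation(C)
  ## degree of the planted covariance graph; degenerate targets (all
  ## off-diagonal mass ~0, e.g. decoupled configs) get a flat degree field
  n_pairs <- n * (n - 1) / 2
  if (sum(C[upper.tri(C)] > 0) >= floor(0.10 * n_pairs)) {
    deg <- colSums(binarize_density(C, 0.10)$adjacency)
  } else {
    deg <- rep(0L, n)
  }
  zdeg <- if (stats::sd(deg) > 0) as.numeric(scale(deg)) else rep(0, n)
  list(ids = ids, partition = partition, C = C,
       degree = stats::setNames(deg, ids), zdeg = zdeg)
}

#' Simulate cortical thickness with planted modular covariance
#'
#' Rows (subjects) are independent draws from a multivariate normal whose
#' correlation combines an exponential distance decay with a within-module
#' increment over a planted contiguous partition, projected to the nearest
#' PSD correlation. An optional linear age effect can be added.
#'
#' @param atlas a [make_atlas] atlas.
#' @param config a [sim_config].
#' @param planted optional precomputed planted structure (internal reuse).
#' @return subjects x regions matrix (columns named by left-hemisphere region
#'   id) with attributes `partition` (planted labels) and `ages` (if an age
#'   effect is on).
#' @export
simulate_thickness <- function(atlas, config, planted = NULL) {
  if (is.null(planted)) planted <- planted_structure(atlas, config)
  n <- length(planted$ids)
  with_seed(child_seed(config$seed, "thickness"), {
    mu <- 2.5 + stats::rnorm(n, 0, 0.25)
    X <- MASS::mvrnorm(config$n_subjects, mu = rep(0, n), Sigma = planted$C)
    X <- sweep(0.15 * X, 2, mu, `+`)
    ages <- NULL
    if (config$age_effect != 0) {
      ages <- stats::runif(config$n_subjects, 14, 25)
      X <- X + config$age_effect * as.numeric(scale(ages))
    }
    dimnames(X) <- list(sprintf("subj%03d", seq_len(config$n_subjects)),
                        planted$ids)
    attr(X, "partition") <- planted$partition
    attr(X, "ages") <- ages
    X
  })
}

# Regional gene profiles: spatially autocorrelated fields with an optional
# module component, plus the planted coupled set tracking covariance-graph
# degree. Deterministic given the config seed.
simulate_regional_profiles <- function(atlas, config, planted) {
  ids <- planted$ids
  n <- length(ids)
  d <- atlas_distances(atlas, ids)
  S <- exp(-d / config$decay_length)
  amp <- config$coupling_strength * config$expr_module_amp
  if (amp > 0) {
    same <- outer(planted$partition, planted$partition, `==`)
    S[same] <- S[same] + amp
    diag(S) <- 1
  }
  S <- nearest_psd_correlation(S, max_change = 0.25)
  with_seed(child_seed(config$seed, "profiles"), {
    ## each background gene mixes the shared spatial/module field with a
    ## gene-specific idiosyncratic profile: with hundreds of genes the shared
    ## field does not average out of co-expression, so the signal fraction
    ## sets how strongly whole-genome co-expression tracks the planted
    ## covariance structure
    f <- config$expr_signal_frac
    U <- sqrt(f) * MASS::mvrnorm(config$n_genes, mu = rep(0, n), Sigma = S) +
      sqrt(1 - f) * matrix(stats::rnorm(config$n_genes * n), config$n_genes, n)
    k <- config$coupled_set_size
    cs <- config$coupling_strength
    coupled_rows <- config$n_genes - k + seq_len(k)
    a <- stats::rnorm(k, 1, 0.3)
    ## the coupled set is a coherent, co-regulated set: its mean profile is a
    ## noisy affine function of planted covariance-graph degree, and its
    ## residual gene-to-gene variation carries the full shared field
    ## (signal fraction 1), unlike background genes
    field <- MASS::mvrnorm(k, mu = rep(0, n), Sigma = S)
    U[coupled_rows, ] <- cs * (a %o% planted$zdeg) + sqrt(1 - cs^2) * field
    coupled_names <- if (k == 19L) hse_genes() else sprintf("CPL%03d", seq_len(k))
    genes <- c(sprintf("G%04d", seq_len(config$n_genes - k)), coupled_names)
    dimnames(U) <- list(genes, ids)
    list(U = U, genes = genes, coupled_genes = coupled_names)
  })
}

#' Simulate regional expression directly (perfect mapping shortcut)
#'
#' Returns the generator's regional gene profiles as a ready-made
#' `regional_expression` object, bypassing sample scattering and
#' parcel assignment. Intended for statistical experiments (power,
#' calibration) where the mapping stage is not under study.
#'
#' @inheritParams simulate_thickness
#' @return a `regional_expression` object (regions x genes).
#' @export
simulate_regional_expression <- function(atlas, config, planted = NULL) {
  if (is.null(planted)) planted <- planted_structure(atlas, config)
  prof <- simulate_regional_profiles(atlas, config, planted)
  new_regional_expression(t(prof$U),
                          n_samples = rep(NA_integer_, length(planted$ids)),
                          interpolated = rep(FALSE, length(planted$ids)))
}

#' Simulate donor expression samples and probes
#'
#' Emulates a post-mortem microarray survey: per donor, samples are scattered
#' at region surfaces and displaced into the subjacent tissue (most within
#' the 2 mm assignment tolerance, a few beyond it, a few flagged
#' non-cortical); two donors also contribute right-hemisphere samples; one
#' parcel is deliberately left without samples; each gene is measured by
#' 1..k probes with distinct offsets; donors differ by an affine scale/shift
#' removed later by within-donor normalization.
#'
#' @inheritParams simulate_thickness
#' @return list with `samples` (data frame: `sample_id`, `donor_id`, `x`,
#'   `y`, `z`, `hemisphere`, `cortical_flag`), `expr` (samples x probes
#'   matrix), `probes` (data frame: `probe_id`, `gene_symbol`; unannotated
#'   probes have `NA` symbol), and `truth` (true region, far flag, coupled
#'   genes, planted partition and degree, empty region).
#' @export
simulate_expression <- function(atlas, config, planted = NULL) {
  if (is.null(planted)) planted <- planted_structure(atlas, config)
  prof <- simulate_regional_profiles(atlas, config, planted)
  ids <- planted$ids
  nL <- length(ids)
  h <- atlas$resolution
  empty_region <- ids[ceiling(nL / 2)]

  with_seed(child_seed(config$seed, "samples"), {
    w <- stats::rgamma(nL, shape = config$sampling_concentration)
    w[ids == empty_region] <- 0

    donor_tabs <- vector("list", config$n_donors)
    for (dn in seq_len(config$n_donors)) {
      ns <- config$samples_per_donor
      reg <- sample(seq_len(nL), ns, replace = TRUE, prob = w)
      bilateral <- dn <= config$n_bilateral_donors
      right <- bilateral & stats::runif(ns) < config$frac_right
      far <- stats::runif(ns) < config$frac_far
      noncort <- stats::runif(ns) < config$frac_noncortical
      depth <- ifelse(far, stats::runif(ns, h + 2.6, h + 6),
                      abs(stats::rnorm(ns, 0, 0.9)))
      xyz <- matrix(0, ns, 3)
      for (s in seq_len(ns)) {
        rid <- reg[s] + if (right[s]) nL else 0L
        sp <- atlas$surface_points[[rid]]
        p <- sp[sample.int(nrow(sp), 1L), ]
        nrm <- p / atlas$axes^2
        nrm <- nrm / sqrt(sum(nrm^2))
        xyz[s, ] <- p - depth[s] * nrm
      }
      donor_tabs[[dn]] <- data.frame(
        donor_id = sprintf("D%d", dn), region = reg, right = right,
        far = far, noncort = noncort,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }
    tab <- do.call(rbind, donor_tabs)
    ns_all <- nrow(tab)
    tab$sample_id <- sprintf("S%04d", seq_len(ns_all))

    ## probe table: 1..k probes per gene plus a fringe of unannotated probes
    n_probes_g <- sample(config$probe_counts, config$n_genes, replace = TRUE)
    gene_of_probe <- rep(seq_len(config$n_genes), n_probes_g)
    offsets <- stats::rnorm(length(gene_of_probe), 0, 1.5)
    n_un <- round(config$frac_unannotated * length(gene_of_probe))
    probes <- data.frame(
      probe_id = sprintf("P%05d", seq_len(length(gene_of_probe) + n_un)),
      gene_symbol = c(prof$genes[gene_of_probe], rep(NA_character_, n_un)))

    ## per-sample gene values: regional profile + noise, donor affine
    base_g <- stats::runif(config$n_genes, 4, 10)
    scale_d <- exp(stats::rnorm(config$n_donors, 0, 0.15))
    shift_d <- stats::rnorm(config$n_donors, 0, 1)
    didx <- as.integer(factor(tab$donor_id,
                              levels = sprintf("D%d", seq_len(config$n_donors))))
    G <- prof$U[, tab$region, drop = FALSE] +
      matrix(stats::rnorm(config$n_genes * ns_all, 0, config$noise_sd),
             config$n_genes, ns_all)
    G <- base_g + sweep(G, 2, scale_d[didx], `*`)
    G <- sweep(G, 2, shift_d[didx], `+`)

    expr <- t(G[gene_of_probe, , drop = FALSE] + offsets +
                matrix(stats::rnorm(length(gene_of_probe) * ns_all, 0,
                                    config$probe_noise),
                       length(gene_of_probe), ns_all))
    if (n_un > 0) {
      expr <- cbind(expr, matrix(stats::rnorm(ns_all * n_un, 6, 2), ns_all, n_un))
    }
    dimnames(expr) <- list(tab$sample_id, probes$probe_id)

    samples <- data.frame(
      sample_id = tab$sample_id, donor_id = tab$donor_id,
      x = tab$x, y = tab$y, z = tab$z,
      hemisphere = ifelse(tab$right, "R", "L"),
      cortical_flag = !tab$noncort)
    truth <- list(
      sample_region = stats::setNames(ids[tab$region] + ifelse(tab$right, nL, 0L),
                                      tab$sample_id),
      sample_far = stats::setNames(tab$far, tab$sample_id),
      partition = planted$partition, degree = planted$degree,
      coupled_genes = prof$coupled_genes, empty_region = empty_region)
    list(samples = samples, expr = expr, probes = probes, truth = truth)
  })
}

#' Run the full synthetic cortex generator
#'
#' @param config a [sim_config].
#' @return object of class `cortex_simulation`: list with `atlas`,
#'   `thickness`, `samples`, `expr`, `probes`, `truth` (planted partition,
#'   planted degree, coupled gene set, per-sample true region, empty parcel)
#'   and `config`.
#' @export
simulate_cortex <- function(config = sim_config()) {
  atlas <- make_atlas(config$n_regions, seed = config$seed)
  planted <- planted_structure(atlas, config)
  thickness <- simulate_thickness(atlas, config, planted)
  ex <- simulate_expression(atlas, config, planted)
  structure(list(atlas = atlas, thickness = thickness, samples = ex$samples,
                 expr = ex$expr, probes = ex$probes, truth = ex$truth,
                 config = config),
            class = "cortex_simulation")
}

#' @export
print.cortex_simulation <- function(x, ...) {
  cat("Synthetic cortex bundle (preset:", x$config$preset, ")\n")
  cat(sprintf("  %d L parcels, %d subjects, %d genes (%d-gene coupled set), %d donor samples\n",
              x$config$n_regions, nrow(x$thickness), x$config$n_genes,
              length(x$truth$coupled_genes), nrow(x$samples)))
  cat("  planted modules:", length(unique(x$truth$partition)),
      "| empty parcel:", x$truth$empty_region, "\n")
  invisible(x)
}

#' Write a simulation bundle as plain-text tables
#'
#' Writes `regions.tsv`, `adjacency.tsv` (edge list), `thickness.tsv`,
#' `samples.tsv`, `probes.tsv`, `expression.tsv` and `truth.json` under
#' `dir`.
#'
#' @param sim a [simulate_cortex] bundle.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(sim$atlas$regions, "regions.tsv")
  ed <- which(sim$atlas$adjacency & upper.tri(sim$atlas$adjacency), arr.ind = TRUE)
  w(data.frame(region_i = ed[, 1], region_j = ed[, 2]), "adjacency.tsv")
  w(data.frame(subject = rownames(sim$thickness), sim$thickness,
               check.names = FALSE), "thickness.tsv")
  w(sim$samples, "samples.tsv")
  w(sim$probes, "probes.tsv")
  w(data.frame(sample_id = rownames(sim$expr), sim$expr, check.names = FALSE),
    "expression.tsv")
  jsonlite::write_json(
    list(partition = as.list(sim$truth$partition),
         coupled_genes = sim$truth$coupled_genes,
         empty_region = sim$truth$empty_region,
         seed = sim$config$seed, preset = sim$config$preset),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
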