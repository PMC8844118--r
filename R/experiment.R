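#' Configuration of the full factorial experiment
#'
#' Bundles every dial of the end-to-end virtual-ecologist run: the synthetic
#' climate generator, the species presets, the sampling design, the fold and
#' learner sets, and the discrimination gates. The reference configuration
#' (2 dataset versions x 3 grid resolutions x 50 samples x 4 algorithms x 2
#' fold assignments) yields 2400 fitted models per species; tests and the
#' worked examples run a reduced smoke configuration.
#'
#' @param generator a [generator_config()].
#' @param species character vector of [species_preset()] names.
#' @param resolutions integer aggregation factors relative to the generated
#'   grid; 1 = native resolution (default `c(1, 2, 4)`, three resolutions).
#' @param n_samples presence-absence samples per species (default 50).
#' @param n_points points per sample (default 300).
#' @param algorithms learner tags (default all four).
#' @param n_fold_assignments checkerboard assignments (fixed at 2:
#'   primary + complement).
#' @param auc_min,tss_min inclusive retention gates (defaults 0.7, 0.4).
#' @param n_sac_samples samples used for the full-data residual correlograms
#'   (default 3; the block size is a per-species property, not per-sample).
#' @param sac_class_width correlogram distance-class width, km.
#' @param n_pred_sim_sets,n_pred_sim_pixels predicted-simulated r sampling
#'   design (sets x pixels per set).
#' @param master_seed master seed; every stage derives sub-seeds from it.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              species = c("alpine", "mediterranean",
                                          "generalist", "restricted"),
                              resolutions = c(1, 2, 4),
                              n_samples = 50L, n_points = 300L,
                              algorithms = c("glm", "gam", "gbm", "rf"),
                              n_fold_assignments = 2L,
                              auc_min = 0.7, tss_min = 0.4,
                              n_sac_samples = 3L, sac_class_width = 100,
                              n_pred_sim_sets = 10L, n_pred_sim_pixels = 1000L,
                              master_seed = 1L) {
  stopifnot(n_samples >= 1, n_points >= 10, length(algorithms) >= 1,
            n_fold_assignments == 2L, auc_min >= 0, auc_min <= 1,
            tss_min >= -1, tss_min <= 1)
  structure(list(generator = generator, species = species,
                 resolutions = resolutions, n_samples = as.integer(n_samples),
                 n_points = as.integer(n_points), algorithms = algorithms,
                 n_fold_assignments = 2L, auc_min = auc_min, tss_min = tss_min,
                 n_sac_samples = as.integer(n_sac_samples),
                 sac_class_width = sac_class_width,
                 n_pred_sim_sets = as.integer(n_pred_sim_sets),
                 n_pred_sim_pixels = as.integer(n_pred_sim_pixels),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror [experiment_config()]; a `generator` mapping mirrors
#' [generator_config()].
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) y$generator <- do.call(generator_config, y$generator)
  do.call(experiment_config, y)
}

#' Number of habitat-suitability models fitted per species
#'
#' `versions x resolutions x samples x algorithms x fold assignments`; the
#' reference configuration gives 2400.
#'
#' @param config an [experiment_config()].
#' @return integer count per species.
#' @export
count_fits <- function(config) {
  2L * length(config$resolutions) * config$n_samples *
    length(config$algorithms) * config$n_fold_assignments
}

# Fit/evaluate all algorithms for one sample under both checkerboard
# assignments; returns metrics rows and the retained fitted models.
fit_sample_models <- function(sample, stack, designs, config) {
  pts <- sample$points
  xv <- extract_values(stack, pts$x, pts$y)
  metrics <- list(); models <- list(); aucs <- numeric(0)
  for (design in designs) {
    fold <- assign_points_to_folds(pts, design)
    tr <- fold == 1L; te <- fold == 2L
    ok <- length(unique(pts$label[tr])) == 2 && length(unique(pts$label[te])) == 2
    for (alg in config$algorithms) {
      row <- data.frame(sample_id = sample$sample_id, algorithm = alg,
                        assignment_id = design$assignment_id,
                        rmse = NA_real_, auc = NA_real_, tss = NA_real_,
                        tss_threshold = NA_real_, retained = FALSE,
                        fitted = FALSE)
      if (ok) {
        seed_fit <- derive_seed(config$master_seed, "fit", sample$species_tag,
                                stack$version_tag, stack$resolution_tag,
                                sample$sample_id, alg, design$assignment_id)
        fit <- tryCatch(fit_hsm(alg, xv[tr, , drop = FALSE], pts$label[tr],
                                seed = seed_fit),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          ev <- evaluate_hsm(fit, xv[te, , drop = FALSE], pts$label[te])
          row$rmse <- ev$rmse; row$auc <- ev$auc; row$tss <- ev$tss
          row$tss_threshold <- ev$tss_threshold
          row$fitted <- TRUE
          row$retained <- ev$auc >= config$auc_min && ev$tss >= config$tss_min
          if (row$retained) {
            models[[length(models) + 1L]] <- fit
            aucs <- c(aucs, ev$auc)
          }
        }
      }
      metrics[[length(metrics) + 1L]] <- row
    }
  }
  list(metrics = do.call(rbind, metrics), models = models, aucs = aucs)
}

#' Desk-scale smoke configuration
#'
#' A reduced configuration for fast end-to-end runs and examples: a 60 x 60
#' synthetic grid, two species archetypes (one response-curve, one PCA
#' niche), two dataset versions, two resolutions, 5 samples of 300 points,
#' all four learners and both fold assignments — 160 fitted models per
#' species.
#'
#' @param master_seed master seed.
#' @param species species presets (default `c("alpine", "mediterranean")`).
#' @return an [experiment_config()].
#' @export
smoke_config <- function(master_seed = 1L,
                         species = c("alpine", "mediterranean")) {
  experiment_config(
    generator = generator_config(n_rows = 60, n_cols = 60,
                                 gcms = "gcm1", timeframes = "2050",
                                 seed = derive_seed(master_seed, "generator")),
    species = species, resolutions = c(1, 2), n_samples = 5L, n_points = 300L,
    n_sac_samples = 2L, n_pred_sim_sets = 10L, n_pred_sim_pixels = 1000L,
    master_seed = master_seed)
}

#' Run the full virtual-ecologist experiment
#'
#' Executes the pipeline end to end for every species x version x resolution
#' combination: generate the paired climate versions (+ future variants),
#' simulate each species on version A at the native resolution, draw
#' presence-absence samples, estimate the spatial-autocorrelation range from
#' full-data residual correlograms and build checkerboard folds, fit and
#' gate all learners, build AUC-weighted ensembles, compute standardized
#' permutation importance, project ensembles under current and future
#' conditions, and derive mismatch diagnostics (between-version differences,
#' predicted-simulated r) plus factor-importance tables.
#'
#' All tabular outputs are written as CSV under `out_dir` (grids as ASCII
#' rasters when `write_grids = TRUE`), and a JSON manifest records the
#' configuration digest, per-stage seeds, file paths and model counts.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and returns results in memory only.
#' @param write_grids also write median/difference grids as `.asc` files.
#' @param verbose print one progress line per species x version x resolution.
#' @return invisibly, a list with `metrics`, `importance`, `block_sizes`,
#'   `mismatch` (per-context summaries), `pred_sim`, `future_diff`,
#'   `factor_importance`, `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, write_grids = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- config$generator
  clim <- generate_climate_pair(gen)
  # resolution variants per version (factor 1 = native)
  stacks <- list()
  for (res in config$resolutions) {
    for (v in c("A", "B")) {
      s <- clim[[v]]
      if (res > 1) s <- aggregate_resolution(s, res)
      s$resolution_tag <- paste0("res", res)
      stacks[[paste(v, res, sep = "_")]] <- s
    }
  }
  native_a <- stacks[["A_1"]]

  metrics_all <- list(); imp_all <- list(); block_sizes <- list()
  mismatch_rows <- list(); pred_sim_rows <- list(); future_rows <- list()
  median_grids <- list()

  for (sp_name in config$species) {
    preset <- species_preset(sp_name)
    hs <- simulate_suitability(native_a, preset,
                               seed = derive_seed(config$master_seed, "hs", sp_name))
    prob <- occurrence_probability(hs$values, preset$conversion)
    pa <- realize_presence_absence(prob, seed = derive_seed(config$master_seed,
                                                            "pa", sp_name))
    samples <- sample_presabs(pa, hs$spec, strategy = preset$sampling$strategy,
                              buffer_km = preset$sampling$buffer_km %||% 120,
                              n_points = config$n_points,
                              n_samples = config$n_samples,
                              detection_prob = preset$conversion$detection_prob,
                              seed = derive_seed(config$master_seed, "sampling", sp_name),
                              species_tag = sp_name)
    # SAC range from full-data residual correlograms on the native-resolution
    # version-A stack (block size is a per-species property)
    sac <- c()
    for (i in seq_len(min(config$n_sac_samples, length(samples)))) {
      res_i <- tryCatch(
        full_data_residuals(samples[[i]], native_a,
                            seed = derive_seed(config$master_seed, "sac", sp_name, i)),
        error = function(e) NULL)
      if (is.null(res_i)) next
      for (alg in names(res_i)) {
        cg <- build_correlogram(res_i[[alg]]$residual,
                                res_i[[alg]][, c("x", "y")],
                                class_width = config$sac_class_width)
        sac <- c(sac, suppressWarnings(estimate_sac_range(cg)))
      }
    }
    if (length(sac) == 0) sac <- config$sac_class_width
    bs <- choose_block_size(sac)
    block_sizes[[sp_name]] <- bs

    for (res in config$resolutions) {
      for (v in c("A", "B")) {
        stack <- stacks[[paste(v, res, sep = "_")]]
        designs <- checkerboard_folds(stack$spec, bs)
        ensembles <- list()
        for (smp in samples) {
          fr <- fit_sample_models(smp, stack, designs, config)
          fr$metrics$species_tag <- sp_name
          fr$metrics$version_tag <- v
          fr$metrics$resolution_tag <- stack$resolution_tag
          metrics_all[[length(metrics_all) + 1L]] <- fr$metrics
          if (length(fr$models) >= 1) {
            ens <- ensemble_wmean(fr$models, fr$aucs)
            ensembles[[as.character(smp$sample_id)]] <- ens
            xv <- extract_values(stack, smp$points$x, smp$points$y)
            imp <- permutation_importance(ens, xv,
              seed = derive_seed(config$master_seed, "imp", sp_name, v, res,
                                 smp$sample_id))
            imp$species_tag <- sp_name; imp$version_tag <- v
            imp$resolution_tag <- stack$resolution_tag
            imp$sample_id <- smp$sample_id
            imp_all[[length(imp_all) + 1L]] <- imp
          }
        }
        if (verbose)
          message(sprintf("%s %s res%d: %d/%d samples with retained models",
                          sp_name, v, res, length(ensembles), length(samples)))
        if (length(ensembles) == 0) next
        ps <- project_models(ensembles, stack)
        med <- median_projection(ps)
        median_grids[[paste(sp_name, v, res, "current", sep = "_")]] <-
          list(median = med, spec = stack$spec, species = sp_name,
               version = v, res = res, n_samples = length(ensembles))
        # predicted-simulated r needs the simulated probability on this geometry
        prob_here <- if (res == 1) prob else {
          pr_stack <- climate_stack(hs$spec, list(p = prob))
          aggregate_resolution(pr_stack, res)$values$p
        }
        r <- predicted_simulated_r(med, prob_here, stack$spec,
                                   n_pixels = config$n_pred_sim_pixels,
                                   n_sets = config$n_pred_sim_sets,
                                   seed = derive_seed(config$master_seed,
                                                      "psr", sp_name, v, res))
        pred_sim_rows[[length(pred_sim_rows) + 1L]] <- data.frame(
          species_tag = sp_name, version_tag = v,
          resolution_tag = stack$resolution_tag, set = seq_along(r), response = r)
        # future projections
        for (nm in names(clim$future)) {
          parts <- strsplit(nm, "_")[[1]]
          if (parts[1] != v) next
          fut <- clim$future[[nm]]
          if (res > 1) fut <- aggregate_resolution(fut, res)
          fut$resolution_tag <- paste0("res", res)
          med_f <- median_projection(project_models(ensembles, fut))
          median_grids[[paste(sp_name, v, res, parts[2], parts[3], parts[4],
                              sep = "_")]] <-
            list(median = med_f, spec = fut$spec, species = sp_name,
                 version = v, res = res, scenario = parts[2], gcm = parts[3],
                 timeframe = parts[4], n_samples = length(ensembles))
        }
      }
      # between-version mismatch at this resolution (current + future)
      key_a <- paste(sp_name, "A", res, "current", sep = "_")
      key_b <- paste(sp_name, "B", res, "current", sep = "_")
      if (!is.null(median_grids[[key_a]]) && !is.null(median_grids[[key_b]])) {
        dg <- version_difference(median_grids[[key_b]]$median,
                                 median_grids[[key_a]]$median)
        spec_r <- median_grids[[key_a]]$spec
        mismatch_rows[[length(mismatch_rows) + 1L]] <- data.frame(
          species_tag = sp_name, resolution_tag = paste0("res", res),
          scenario_tag = "current", gcm_tag = NA_character_,
          timeframe_tag = "current",
          median_abs_diff = stats::median(abs(dg[!spec_r$mask])),
          mean_diff = mean(dg[!spec_r$mask]))
        if (write_grids && !is.null(out_dir))
          write_ascii_grid(dg, spec_r,
                           file.path(out_dir, sprintf("diff_%s_res%d_current.asc",
                                                      sp_name, res)))
      }
      for (nm in names(clim$future)) {
        parts <- strsplit(nm, "_")[[1]]
        if (parts[1] != "A") next
        ka <- paste(sp_name, "A", res, parts[2], parts[3], parts[4], sep = "_")
        kb <- paste(sp_name, "B", res, parts[2], parts[3], parts[4], sep = "_")
        if (is.null(median_grids[[ka]]) || is.null(median_grids[[kb]])) next
        dg <- version_difference(median_grids[[kb]]$median,
                                 median_grids[[ka]]$median)
        spec_r <- median_grids[[ka]]$spec
        dsamp <- sample_future_differences(dg, spec_r,
          n_pixels = min(config$n_pred_sim_pixels, sum(!spec_r$mask)),
          seed = derive_seed(config$master_seed, "fdiff", sp_name, res, nm))
        future_rows[[length(future_rows) + 1L]] <- data.frame(
          species_tag = sp_name, resolution_tag = paste0("res", res),
          scenario_tag = parts[2], gcm_tag = parts[3], timeframe_tag = parts[4],
          response = dsamp)
        mismatch_rows[[length(mismatch_rows) + 1L]] <- data.frame(
          species_tag = sp_name, resolution_tag = paste0("res", res),
          scenario_tag = parts[2], gcm_tag = parts[3], timeframe_tag = parts[4],
          median_abs_diff = stats::median(abs(dg[!spec_r$mask])),
          mean_diff = mean(dg[!spec_r$mask]))
      }
    }
  }

  metrics <- do.call(rbind, metrics_all)
  importance <- if (length(imp_all)) do.call(rbind, imp_all) else NULL
  pred_sim <- if (length(pred_sim_rows)) do.call(rbind, pred_sim_rows) else NULL
  future_diff <- if (length(future_rows)) do.call(rbind, future_rows) else NULL
  mismatch <- if (length(mismatch_rows)) do.call(rbind, mismatch_rows) else NULL

  # factor importance on the three response kinds, where enough structure exists
  fi <- list()
  if (!is.null(pred_sim) && length(unique(pred_sim$species_tag)) >= 2) {
    tab <- assemble_outcomes(data.frame(response = pred_sim$response,
                                        species_tag = pred_sim$species_tag,
                                        version_tag = pred_sim$version_tag,
                                        resolution_tag = pred_sim$resolution_tag))
    if (nrow(tab) >= 50)
      fi$pred_sim_r <- rf_factor_importance(tab, seed = derive_seed(
        config$master_seed, "fi_psr"))
  }
  if (!is.null(future_diff) && nrow(future_diff) >= 50) {
    tab <- tryCatch(assemble_outcomes(future_diff), warning = function(w)
      suppressWarnings(assemble_outcomes(future_diff)))
    if (length(attr(tab, "factors")) >= 1)
      fi$future_diff <- rf_factor_importance(tab, seed = derive_seed(
        config$master_seed, "fi_fd"))
  }
  if (!is.null(importance) && nrow(importance) >= 50) {
    tab <- suppressWarnings(assemble_outcomes(data.frame(
      response = importance$std_imp, species_tag = importance$species_tag,
      version_tag = importance$version_tag,
      resolution_tag = importance$resolution_tag)))
    if (length(attr(tab, "factors")) >= 1)
      fi$std_imp <- rf_factor_importance(tab, seed = derive_seed(
        config$master_seed, "fi_si"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hsmismatch")),
    master_seed = config$master_seed,
    n_species = length(config$species),
    count_fits_per_species = count_fits(config),
    models_fitted = sum(metrics$fitted),
    models_retained = sum(metrics$retained),
    block_sizes_km = block_sizes,
    files = character(0))

  if (!is.null(out_dir)) {
    paths <- c(metrics = file.path(out_dir, "metrics.csv"),
               importance = file.path(out_dir, "importance.csv"),
               mismatch = file.path(out_dir, "mismatch.csv"),
               pred_sim = file.path(out_dir, "predicted_simulated_r.csv"),
               future_diff = file.path(out_dir, "future_differences.csv"))
    utils::write.csv(metrics, paths["metrics"], row.names = FALSE)
    if (!is.null(importance)) utils::write.csv(importance, paths["importance"], row.names = FALSE)
    if (!is.null(mismatch)) utils::write.csv(mismatch, paths["mismatch"], row.names = FALSE)
    if (!is.null(pred_sim)) utils::write.csv(pred_sim, paths["pred_sim"], row.names = FALSE)
    if (!is.null(future_diff)) utils::write.csv(future_diff, paths["future_diff"], row.names = FALSE)
    for (nm in names(fi))
      utils::write.csv(fi[[nm]], file.path(out_dir, paste0("factor_importance_",
                                                           nm, ".csv")),
                       row.names = FALSE)
    manifest$files <- unname(paths[file.exists(paths)])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(metrics = metrics, importance = importance,
                 block_sizes = block_sizes, mismatch = mismatch,
                 pred_sim = pred_sim, future_diff = future_diff,
                 factor_importance = fi, median_grids = median_grids,
                 manifest = manifest))
}
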