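#!/usr/bin/env Rscript
# Stage 3 — spatial blocking: fit full-data smoother/boosting models per
# archetype, build residual Moran's I correlograms, estimate the spatial
# autocorrelation (SAC) range, and choose the checkerboard block size
# (max SAC range + 100 km).
#
# Writes results/blocking/: correlograms_<species>.csv, block_sizes.csv,
# blocks_<species>.csv (both fold assignments).

library(hsmismatch)

out <- "results/blocking"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930L

clim <- generate_climate_pair(generator_config(seed = seed))
stack_a <- clim$A

sizes <- NULL
for (nm in c("alpine", "mediterranean", "generalist", "restricted")) {
  preset <- species_preset(nm)
  hs <- simulate_suitability(stack_a, preset, seed = derive_seed(seed, "hs", nm))
  prob <- occurrence_probability(hs$values, preset$conversion)
  pa <- realize_presence_absence(prob, seed = derive_seed(seed, "pa", nm))
  samples <- sample_presabs(pa, hs$spec, strategy = preset$sampling$strategy,
                            buffer_km = ifelse(is.na(preset$sampling$buffer_km),
                                               120, preset$sampling$buffer_km),
                            n_points = 300, n_samples = 3,
                            detection_prob = preset$conversion$detection_prob,
                            seed = derive_seed(seed, "sampling", nm),
                            species_tag = nm)
  cgs <- NULL; ranges <- c()
  for (smp in samples) {
    res <- tryCatch(full_data_residuals(smp, stack_a,
                                        seed = derive_seed(seed, "sac", nm,
                                                           smp$sample_id)),
                    error = function(e) NULL)
    if (is.null(res)) next
    for (alg in names(res)) {
      cg <- build_correlogram(res[[alg]]$residual, res[[alg]][, c("x", "y")],
                              class_width = 100)
      ranges <- c(ranges, suppressWarnings(estimate_sac_range(cg)))
      cg$algorithm <- alg; cg$sample_id <- smp$sample_id
      cgs <- rbind(cgs, cg)
    }
  }
  write.csv(cgs, file.path(out, paste0("correlograms_", nm, ".csv")),
            row.names = FALSE)
  bs <- choose_block_size(ranges)
  sizes <- rbind(sizes, data.frame(species = nm, max_sac_range_km = max(ranges),
                                   block_size_km = bs))
  message(sprintf("%-14s SAC ranges %s km -> block size %d km", nm,
                  paste(sort(unique(ranges)), collapse = "/"), bs))
  designs <- checkerboard_folds(stack_a$spec, bs)
  blocks <- do.call(rbind, lapply(designs, function(d)
    cbind(d$blocks, assignment_id = d$assignment_id)))
  write.csv(blocks, file.path(out, paste0("blocks_", nm, ".csv")),
            row.names = FALSE)
}
write.csv(sizes, file.path(out, "block_sizes.csv"), row.names = FALSE)
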