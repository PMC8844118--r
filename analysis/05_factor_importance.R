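#!/usr/bin/env Rscript
# Stage 5 — importance of the experimental factors: random-forest regression
# (1000 trees, permutation importance n = 5) of the modeling outcomes on the
# experiment factors, for each of the three response kinds.
#
# Reads results/experiment/ (stage 4); writes results/factors/.

library(hsmismatch)

inp <- "results/experiment"
out <- "results/factors"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930L

stopifnot(file.exists(file.path(inp, "predicted_simulated_r.csv")))
psr <- read.csv(file.path(inp, "predicted_simulated_r.csv"))
fd <- read.csv(file.path(inp, "future_differences.csv"))
imp <- read.csv(file.path(inp, "importance.csv"))

run_fi <- function(df, label) {
  tab <- suppressWarnings(assemble_outcomes(df))
  fi <- rf_factor_importance(tab, n_trees = 1000, n_perm = 5,
                             seed = derive_seed(seed, "fi", label))
  fi$response_kind <- label
  message(label, ":")
  for (i in order(-fi$mean_importance))
    message(sprintf("  %-16s %5.1f%% (sd %.1f)", fi$factor[i],
                    fi$mean_importance[i], fi$sd_importance[i]))
  fi
}

fi_all <- rbind(
  run_fi(data.frame(response = psr$response, species_tag = psr$species_tag,
                    version_tag = psr$version_tag,
                    resolution_tag = psr$resolution_tag), "pred_sim_r"),
  run_fi(fd, "future_diff"),
  run_fi(data.frame(response = imp$std_imp, species_tag = imp$species_tag,
                    version_tag = imp$version_tag,
                    resolution_tag = imp$resolution_tag), "std_imp"))
write.csv(fi_all, file.path(out, "factor_importance.csv"), row.names = FALSE)
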