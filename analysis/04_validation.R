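#!/usr/bin/env Rscript

# Reduced-size versions of the package's validation experiments, for a
# quick interactive look; the full-size runs live in the test suite and
# scripts/acceptance.R.

suppressMessages(library(cfosnet))
seed <- 20260920L

bo <- experiment_betweenness_oracle(n_graphs = 100, seed = seed)
cat(sprintf("betweenness vs enumeration: %d/%d graphs agree (max |diff| %.2g)\n",
            bo$n_agree, bo$n_graphs, bo$max_abs_diff))

hr <- experiment_hub_recovery(n_reps = 25, seed = seed + 1L)
cat(sprintf("planted hub recovered as unique hub in both groups: %.0f%% of %d runs\n",
            100 * hr$rate, hr$n_reps))

t1 <- experiment_region_type1(n_reps = 200, seed = seed + 2L)
cat(sprintf("region model type-I error (alpha 0.05): %.3f over %d null fits\n",
            t1$rejection_rate, t1$n_fitted))

lr <- experiment_lfc_recovery(n_reps = 100, seed = seed + 3L)
cat(sprintf("treatment lfc -0.7 recovered with mean estimate %.3f (bias %+.3f)\n",
            lr$mean_estimate, lr$bias))

cd <- experiment_connected_detection(n_reps = 50, seed = seed + 4L)
cat(sprintf("anatomically supported coupling detected in %.0f%% of %d runs\n",
            100 * cd$detection_rate, cd$n_reps))

dt <- experiment_determinism(seed = seed + 5L)
cat(sprintf("pipeline determinism: %d files, %d byte mismatches\n",
            dt$n_files, dt$n_mismatched))
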