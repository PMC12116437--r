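#!/usr/bin/env Rscript

# Simulates the reference synthetic study: 10 control vs 11 prenatally
# treated subjects from 14 litters, 36 regions, with reduced activation
# (log fold change -0.4) in the reward/social-behavior regions and an
# Erdos-Renyi anatomical connectome. Writes the study bundle under
# results/synthetic_study/.

suppressMessages(library(cfosnet))

seed <- 20260920L
regions <- cfos_regions()
net <- cfos_network_map()
lfc <- setNames(ifelse(net$network %in% c("MRS", "MRS_SBN", "SBN"),
                       -0.4, 0), net$region)

# anatomical connectome first, so the latent co-activation can be
# supported on it (direct connections couple activation)
adj <- generate_anatomical_connectome(regions, edge_density = 0.3,
                                      seed = seed + 1L)

cfg <- study_config(
  regions = regions,
  treatment_log_fold_change = lfc,
  latent_scale = 1.0,
  nb_dispersion = 20,
  latent_corr = latent_corr_from_adjacency(adj, rho = 0.2),
  seed = seed
)

files <- simulate_study_files(cfg, "results/synthetic_study",
                              adjacency = adj)
counts <- files$counts_data

cat("Simulated study written to results/synthetic_study/\n")
cat(sprintf("  subjects: %d (%s)\n", length(unique(counts$subject_id)),
            paste(sprintf("%s n=%d", names(table(unique(
              counts[, c("subject_id", "group")])$group)),
              table(unique(counts[, c("subject_id", "group")])$group)),
              collapse = ", ")))
cat(sprintf("  regions: %d, records: %d, total cells counted: %d\n",
            length(unique(counts$region)), nrow(counts),
            sum(counts$count)))
cat(sprintf("  litters: %d; anatomical edges: %d\n",
            length(unique(counts$litter_id)),
            sum(files$adjacency_data) / 2))
cat("  treated regions (true lfc -0.4):",
    sum(lfc < 0), "of", length(regions), "\n")
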