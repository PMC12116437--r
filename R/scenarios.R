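# Canonical simulation scenarios. Each returns the study conditions of
# one validation experiment; the experiment functions in
# experiments.R consume them. Parameters were fixed once by an a-priori
# design analysis (see the methods vignette) and are not tuning knobs.

#' Planted-hub recovery scenario
#'
#' Full-size study (10 + 11 subjects, 14 litters, 36 regions) in which
#' one region is the latent activation hub: every region correlates 0.9
#' with it (one shared factor, so 0.81 between the others), and the
#' anatomical connectome is the pure star around the hub
#' (`edge_density = 0` with a planted hub). Uniform 0.5 mm^2 ROI
#' sections, two slides per region, latent scale 1 so the latent signal
#' dominates counting noise (dispersion 20), litter SD 0.2.
#'
#' @param seed Integer seed.
#' @param hub Hub region label.
#' @return List with `config` (a [study_config()]) and `adjacency`.
#' @export
scenario_hub_recovery <- function(seed = 1L, hub = "IPN") {
  regions <- cfos_regions()
  cfg <- study_config(
    regions = regions,
    region_area = setNames(rep(0.5, length(regions)), regions),
    litter_sd = 0.2,
    nb_dispersion = 20,
    latent_scale = 1.0,
    latent_corr = latent_corr_hub(regions, hub, hub_r = 0.9),
    planted_hub = hub,
    seed = seed
  )
  adj <- generate_anatomical_connectome(regions, edge_density = 0,
                                        planted_hub = hub,
                                        seed = seed + 1L)
  list(config = cfg, adjacency = adj)
}

#' Single-region activation scenario
#'
#' Study-scale conditions for calibrating the per-region
#' negative-binomial mixed model: 10 + 11 subjects in 14 litters
#' (treatment at the litter level), one region of 0.5 mm^2 sections on
#' two slides, baseline 100 cells/mm^2, litter SD 0.3, dispersion 10.
#' With one region the latent activation term is redundant with the NB
#' dispersion (the model's individual-level noise), so it is switched
#' off.
#'
#' @param seed Integer seed.
#' @param lfc True treatment log fold change (0 for null simulations).
#' @return A [study_config()].
#' @export
scenario_single_region <- function(seed = 1L, lfc = 0) {
  study_config(
    regions = "ROI",
    region_area = c(ROI = 0.5),
    treatment_log_fold_change = c(ROI = lfc),
    litter_sd = 0.3,
    nb_dispersion = 10,
    latent_scale = 0,
    seed = seed
  )
}

#' Anatomically supported correlation scenario
#'
#' Latent correlation placed only on anatomically connected pairs:
#' the adjacency is Erdos-Renyi at density 0.3 over the 36 regions and
#' the latent correlation is `I + rho * A` with `rho` capped for
#' positive definiteness (realized value carried as an attribute,
#' ~0.15 at this density). Low counting noise (dispersion 50, latent
#' scale 1.5, no litter effect) so the comparison isolates the
#' anatomical structure.
#'
#' @param seed Integer seed.
#' @param rho Target latent correlation on connected pairs.
#' @param edge_density Anatomical edge density.
#' @return List with `config` and `adjacency`.
#' @export
scenario_adjacency_coupled <- function(seed = 1L, rho = 0.2,
                                       edge_density = 0.3) {
  regions <- cfos_regions()
  adj <- generate_anatomical_connectome(regions, edge_density,
                                        seed = seed + 1L)
  cfg <- study_config(
    regions = regions,
    region_area = setNames(rep(0.5, length(regions)), regions),
    litter_sd = 0,
    nb_dispersion = 50,
    latent_scale = 1.5,
    latent_corr = latent_corr_from_adjacency(adj, rho = rho),
    seed = seed
  )
  list(config = cfg, adjacency = adj)
}
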