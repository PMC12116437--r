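#' Generate a stand-in anatomical connectome
#'
#' Produces a symmetric binary region adjacency standing in for an
#' axonal-tract connectome. Without a planted hub the graph is
#' Erdos-Renyi at `edge_density`; with a planted hub that region is
#' additionally wired to every other region (so `edge_density = 0`
#' yields a pure star around the hub).
#'
#' @param regions Region labels.
#' @param edge_density Probability of an edge between two (non-hub)
#'   regions. Must lie in (0, 1), or in \[0, 1) when a hub is planted.
#' @param planted_hub Optional region label to wire to all others.
#' @param seed Integer seed.
#' @return Symmetric 0/1 matrix with zero diagonal and region dimnames.
#' @export
generate_anatomical_connectome <- function(regions, edge_density,
                                           planted_hub = NULL,
                                           seed = 1L) {
  regions <- as.character(regions)
  nr <- length(regions)
  if (!is.null(planted_hub) && !(planted_hub %in% regions))
    stop("generate_anatomical_connectome: unknown planted_hub label '",
         planted_hub, "'")
  lo_ok <- if (is.null(planted_hub)) edge_density > 0 else edge_density >= 0
  if (!lo_ok || edge_density >= 1)
    stop("generate_anatomical_connectome: edge_density ", edge_density,
         " outside the valid range",
         if (is.null(planted_hub)) " (0, 1)" else " [0, 1)")
  set.seed(as.integer(seed))
  adj <- matrix(0L, nr, nr, dimnames = list(regions, regions))
  if (edge_density > 0) {
    adj[upper.tri(adj)] <- rbinom(nr * (nr - 1L) / 2L, 1L, edge_density)
    adj <- adj + t(adj)
  }
  if (!is.null(planted_hub)) {
    adj[planted_hub, ] <- 1L
    adj[, planted_hub] <- 1L
  }
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  adj
}

# Deterministic litter layout: litters split between groups in
# proportion to group sizes (treatment acts on the dam, so litters are
# nested in groups); subjects dealt round-robin over their group's
# litters.
litter_layout <- function(cfg) {
  n1 <- cfg$n_per_group[[cfg$group_labels[1]]]
  n2 <- cfg$n_per_group[[cfg$group_labels[2]]]
  nl1 <- max(1L, min(cfg$n_litters - 1L,
                     as.integer(round(cfg$n_litters * n1 / (n1 + n2)))))
  nl2 <- cfg$n_litters - nl1
  if (nl1 > n1 || nl2 > n2)
    stop("study_config: litters cannot outnumber subjects within a group")
  litter_ids <- sprintf("L%02d", seq_len(cfg$n_litters))
  list(
    litters = setNames(list(litter_ids[seq_len(nl1)],
                            litter_ids[nl1 + seq_len(nl2)]),
                       cfg$group_labels),
    litter_ids = litter_ids
  )
}

#' Simulate a complete two-group c-Fos study
#'
#' Draws, for each subject, a litter random intercept (shared within a
#' litter), a latent correlated activation vector for the subject's
#' group, and per-region negative-binomial total counts with mean
#' `exp(baseline + lfc * treated + litter + latent_scale * z) * area`,
#' where `area` is the summed ROI area over both hemispheres and all
#' slides. Totals are split multinomially (equal probabilities) over
#' hemisphere-by-slide records, so per-record counts sum exactly to the
#' drawn total.
#'
#' @param cfg A [study_config()].
#' @return List with `counts` (long-format count table: subject_id,
#'   group, litter_id, region, hemisphere, slide_index, count,
#'   area_mm2) and `truth` (class `simulation_truth`: planted hub,
#'   latent correlations, per-region true log fold change, realized
#'   litter intercepts, seed).
#' @export
generate_study <- function(cfg) {
  validate_study_config(cfg)
  set.seed(cfg$seed)
  lay <- litter_layout(cfg)
  nr <- length(cfg$regions)
  litter_b <- setNames(rnorm(cfg$n_litters, 0, cfg$litter_sd),
                       lay$litter_ids)

  n_slides <- as.integer(cfg$slides_per_region)
  rec_per_region <- 2L * n_slides
  rec_per_subject <- sum(rec_per_region)
  n_subj <- sum(cfg$n_per_group)
  n_rec <- n_subj * rec_per_subject

  # per-subject record template (region/hemisphere/slide layout)
  tmpl_region <- rep(cfg$regions, rec_per_region)
  tmpl_hemi <- unlist(lapply(n_slides, function(s) rep(c("left", "right"), s)),
                      use.names = FALSE)
  tmpl_slide <- unlist(lapply(n_slides, function(s) rep(seq_len(s) - 1L,
                                                        each = 2L)),
                       use.names = FALSE)
  tmpl_area <- rep(as.numeric(cfg$region_area), rec_per_region)

  col_subject <- character(n_rec)
  col_group <- character(n_rec)
  col_litter <- character(n_rec)
  col_count <- integer(n_rec)

  subj_no <- 0L
  for (g in cfg$group_labels) {
    ng <- cfg$n_per_group[[g]]
    treated <- as.numeric(g == cfg$group_labels[2])
    sigma <- cfg$latent_corr[[g]]
    z <- MASS::mvrnorm(ng, mu = rep(0, nr), Sigma = sigma)
    z <- matrix(z, nrow = ng, ncol = nr)
    glitters <- rep(lay$litters[[g]], length.out = ng)
    for (s in seq_len(ng)) {
      subj_no <- subj_no + 1L
      lid <- glitters[s]
      log_mu <- cfg$baseline_log_density +
        treated * cfg$treatment_log_fold_change +
        litter_b[[lid]] + cfg$latent_scale * z[s, ]
      a_tot <- rec_per_region * as.numeric(cfg$region_area)
      mu <- exp(as.numeric(log_mu)) * a_tot
      totals <- if (is.finite(cfg$nb_dispersion)) {
        rnbinom(nr, mu = mu, size = cfg$nb_dispersion)
      } else {
        stats::rpois(nr, mu)
      }
      parts <- unlist(lapply(seq_len(nr), function(r) {
        as.integer(rmultinom(1L, totals[r], rep(1, rec_per_region[r])))
      }), use.names = FALSE)
      idx <- (subj_no - 1L) * rec_per_subject + seq_len(rec_per_subject)
      col_subject[idx] <- sprintf("S%02d", subj_no)
      col_group[idx] <- g
      col_litter[idx] <- lid
      col_count[idx] <- parts
    }
  }
  counts <- data.frame(
    subject_id = col_subject,
    group = col_group,
    litter_id = col_litter,
    region = rep(tmpl_region, n_subj),
    hemisphere = rep(tmpl_hemi, n_subj),
    slide_index = rep(tmpl_slide, n_subj),
    count = col_count,
    area_mm2 = rep(tmpl_area, n_subj),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    planted_hub = cfg$planted_hub,
    latent_corr = cfg$latent_corr,
    treatment_log_fold_change = cfg$treatment_log_fold_change,
    litter_intercepts = data.frame(
      litter_id = lay$litter_ids,
      group = rep(cfg$group_labels,
                  vapply(lay$litters, length, 1L)[cfg$group_labels]),
      intercept = unname(litter_b),
      stringsAsFactors = FALSE
    ),
    seed = cfg$seed
  ), class = "simulation_truth")
  list(counts = counts, truth = truth)
}
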