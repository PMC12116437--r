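#' Default brain-region panel
#'
#' The 36 region-of-interest acronyms used throughout the package
#' defaults: mesolimbic reward system, social behavior network, their
#' overlap, stress-regulating nuclei, autism-associated regions and
#' vegetative control regions.
#'
#' @return Character vector of 36 region acronyms.
#' @export
cfos_regions <- function() {
  c("CPU", "NAcc", "VP", "blAMY", "dCA2", "vCA1", "vCA3", "VTA", "ACC",
    "LS", "BNST",
    "mPOA", "lPOA", "VMH", "meAMY", "dmPAG", "dlPAG",
    "IF", "ZI", "mHb", "lHb", "PVT", "IPN", "LHA", "caAMY", "bmAMY",
    "lPAG", "vPAG", "RSC", "dCA1", "dCA3",
    "dGD", "vGD", "DMH", "ARC", "EW")
}

#' Default network membership map
#'
#' Maps each default region to its a-priori functional network:
#' mesolimbic reward system (MRS), social behavior network (SBN), the
#' MRS/SBN overlap, stress-regulating nuclei, autism-associated regions,
#' and control regions.
#'
#' @return Data frame with columns `region` and `network`.
#' @export
cfos_network_map <- function() {
  data.frame(
    region = cfos_regions(),
    network = c(rep("MRS", 9),
                rep("MRS_SBN", 2),
                rep("SBN", 6),
                rep("stress", 9),
                rep("autism", 5),
                rep("control", 5)),
    stringsAsFactors = FALSE
  )
}

#' Construct a synthetic study configuration
#'
#' Defines the generative model of a two-group prenatal-exposure c-Fos
#' study: subjects nested in litters (treatment is assigned at the
#' litter level, as in a prenatal valproic-acid design), a log-scale
#' litter random intercept, a latent multivariate-normal activation
#' vector with a per-group correlation matrix entering the log mean, and
#' negative-binomial counts (variance mu + mu^2/dispersion) with total
#' ROI area as multiplier, split multinomially over hemispheres and
#' slides.
#'
#' @param regions Character vector of region labels.
#' @param n_per_group Named integer vector, subjects per group.
#' @param group_labels Two group labels; first is the reference
#'   (control) group.
#' @param n_litters Total number of litters across both groups.
#' @param region_area Named numeric vector: ROI area (mm^2) of one
#'   hemisphere section on one slide, per region. Default spans
#'   0.12-1.5 mm^2, typical of subcortical nuclei through cortical ROIs.
#' @param baseline_log_density Named numeric vector: log cells/mm^2 in
#'   the reference group. Default log(100) everywhere.
#' @param treatment_log_fold_change Named numeric vector: additive
#'   log-scale treatment effect on density. Default 0.
#' @param litter_sd SD of the litter random intercept (log scale).
#' @param nb_dispersion Negative-binomial size parameter; variance is
#'   mu + mu^2/nb_dispersion. `Inf` gives Poisson counts.
#' @param latent_scale Multiplier of the latent correlated activation
#'   vector on the log-mean scale.
#' @param latent_corr List with one correlation matrix per group label
#'   (region x region, symmetric, unit diagonal, positive
#'   semidefinite), or a single matrix used for both groups. Default
#'   identity.
#' @param slides_per_region Named integer vector of slides per region.
#' @param planted_hub Optional region label recorded in the simulation
#'   truth as the intended hub.
#' @param seed Integer seed; mandatory, drives all randomness.
#' @return Object of class `study_config`.
#' @export
study_config <- function(regions = cfos_regions(),
                         n_per_group = c(CTR = 10, VPA = 11),
                         group_labels = c("CTR", "VPA"),
                         n_litters = 14,
                         region_area = NULL,
                         baseline_log_density = NULL,
                         treatment_log_fold_change = NULL,
                         litter_sd = 0.3,
                         nb_dispersion = 10,
                         latent_scale = 0.3,
                         latent_corr = NULL,
                         slides_per_region = NULL,
                         planted_hub = NULL,
                         seed = 1L) {
  regions <- as.character(regions)
  nr <- length(regions)
  if (is.null(names(n_per_group))) names(n_per_group) <- group_labels
  if (is.null(region_area)) {
    region_area <- setNames(round(exp(seq(log(0.12), log(1.5),
                                          length.out = nr)), 4), regions)
  }
  if (is.null(baseline_log_density)) {
    baseline_log_density <- setNames(rep(log(100), nr), regions)
  }
  if (is.null(treatment_log_fold_change)) {
    treatment_log_fold_change <- setNames(rep(0, nr), regions)
  }
  if (is.null(slides_per_region)) {
    slides_per_region <- setNames(rep(2L, nr), regions)
  }
  if (is.null(latent_corr)) latent_corr <- diag(nr)
  if (is.matrix(latent_corr)) {
    latent_corr <- setNames(list(latent_corr, latent_corr), group_labels)
  }
  latent_corr <- lapply(latent_corr, function(m) {
    if (is.null(rownames(m))) dimnames(m) <- list(regions, regions)
    m
  })
  cfg <- structure(list(
    regions = regions,
    n_per_group = n_per_group,
    group_labels = group_labels,
    n_litters = as.integer(n_litters),
    region_area = region_area[regions],
    baseline_log_density = baseline_log_density[regions],
    treatment_log_fold_change = treatment_log_fold_change[regions],
    litter_sd = litter_sd,
    nb_dispersion = nb_dispersion,
    latent_scale = latent_scale,
    latent_corr = latent_corr,
    slides_per_region = slides_per_region[regions],
    planted_hub = planted_hub,
    seed = as.integer(seed)
  ), class = "study_config")
  validate_study_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' Checks positivity of areas and dispersion, group bookkeeping, litter
#' count, and that each group's latent correlation matrix is symmetric
#' with unit diagonal and positive semidefinite.
#'
#' @param cfg A `study_config`.
#' @return The config, invisibly, or an error.
#' @export
validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  if (length(cfg$group_labels) != 2L)
    stop("study_config: exactly two group labels are required")
  if (!all(names(cfg$n_per_group) %in% cfg$group_labels))
    stop("study_config: n_per_group names must match group_labels")
  if (any(cfg$n_per_group < 1L))
    stop("study_config: each group needs at least one subject")
  if (any(is.na(cfg$region_area)) || any(cfg$region_area <= 0))
    stop("study_config: region areas must be positive for every region")
  if (cfg$litter_sd < 0) stop("study_config: litter_sd must be nonnegative")
  if (cfg$nb_dispersion <= 0)
    stop("study_config: nb_dispersion must be positive")
  if (cfg$n_litters > sum(cfg$n_per_group))
    stop("study_config: more litters than subjects")
  if (cfg$n_litters < 2L)
    stop("study_config: at least two litters are required")
  if (any(cfg$slides_per_region < 1L))
    stop("study_config: slides_per_region must be >= 1")
  if (!is.null(cfg$planted_hub) && !(cfg$planted_hub %in% cfg$regions))
    stop("study_config: planted_hub '", cfg$planted_hub,
         "' is not among the configured regions")
  for (g in names(cfg$latent_corr)) {
    m <- cfg$latent_corr[[g]]
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop("latent_corr[", g, "] is not symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8)
      stop("latent_corr[", g, "] does not have a unit diagonal")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("latent_corr[", g, "] is not positive semidefinite ",
           "(smallest eigenvalue ", format(min(ev)), ")")
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> ", length(x$regions), " regions; ",
      paste(sprintf("%s n=%d", names(x$n_per_group), x$n_per_group),
            collapse = ", "),
      "; ", x$n_litters, " litters; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' One-factor latent correlation routed through a hub region
#'
#' Builds the region correlation matrix in which every region correlates
#' `hub_r` with the hub; all other pairwise correlations are the induced
#' `hub_r^2` (the correlation "flows through" the hub as a single shared
#' factor). Positive semidefinite by construction.
#'
#' @param regions Region labels.
#' @param hub Hub region label.
#' @param hub_r Latent correlation between the hub and every other
#'   region.
#' @return Correlation matrix with dimnames.
#' @export
latent_corr_hub <- function(regions, hub, hub_r = 0.9) {
  if (!(hub %in% regions)) stop("unknown hub region '", hub, "'")
  nr <- length(regions)
  m <- matrix(hub_r^2, nr, nr, dimnames = list(regions, regions))
  m[hub, ] <- hub_r
  m[, hub] <- hub_r
  diag(m) <- 1
  m
}

#' Latent correlation supported on an anatomical adjacency
#'
#' Builds `I + rho * A` over the region set, with `rho` capped so the
#' matrix stays positive definite (`rho <= shrink / |lambda_min(A)|`).
#' Anatomically unconnected pairs have zero latent correlation; the
#' realized `rho` is returned as an attribute.
#'
#' @param adj Symmetric binary adjacency with region dimnames.
#' @param rho Target correlation on connected pairs.
#' @param shrink Positive-definiteness safety factor in (0, 1).
#' @return Correlation matrix with attribute `rho`.
#' @export
latent_corr_from_adjacency <- function(adj, rho = 0.2, shrink = 0.95) {
  A <- as.matrix(adj)
  lam_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  rho_use <- if (lam_min < 0) min(rho, shrink / abs(lam_min)) else rho
  m <- diag(nrow(A)) + rho_use * A
  dimnames(m) <- dimnames(A)
  attr(m, "rho") <- rho_use
  m
}
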