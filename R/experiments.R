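# Seeded validation experiments. Each re-runs a pipeline component on
# freshly simulated data under the scenarios in scenarios.R and
# summarizes recovery/calibration. Used by the test suite, the
# analysis drivers and scripts/acceptance.R.

rep_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Betweenness versus exhaustive enumeration
#'
#' Draws random undirected graphs (2-8 nodes, edge probability 0.1-0.9)
#' and compares [betweenness_centrality()] with the enumeration oracle
#' [betweenness_reference()].
#'
#' @param n_graphs Number of random graphs.
#' @param seed Integer seed.
#' @param tol Agreement tolerance (exact up to floating-point
#'   round-off in the path fractions).
#' @return List: `n_graphs`, `n_agree`, `max_abs_diff`.
#' @export
experiment_betweenness_oracle <- function(n_graphs = 200, seed = 1L,
                                          tol = 1e-9) {
  set.seed(as.integer(seed))
  max_diff <- 0
  n_agree <- 0L
  for (i in seq_len(n_graphs)) {
    n <- sample(2:8, 1)
    p_edge <- runif(1, 0.1, 0.9)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1L, p_edge)
    adj <- adj + t(adj)
    dimnames(adj) <- list(as.character(seq_len(n)),
                          as.character(seq_len(n)))
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    got <- betweenness_centrality(ig)
    want <- betweenness_reference(adj)
    d <- max(abs(got[names(want)] - want))
    max_diff <- max(max_diff, d)
    if (d <= tol) n_agree <- n_agree + 1L
  }
  list(n_graphs = n_graphs, n_agree = n_agree, max_abs_diff = max_diff)
}

# Network-reconstruction arm of the pipeline for one simulated study:
# density -> per-group correlation -> anatomical mask -> thresholds ->
# centralities -> hubs.
reconstruct_networks <- function(counts, adj, r2_min = 0.7,
                                 p_max = 0.05, hub_quantile = 0.8,
                                 hub_rule = "both") {
  dens <- compute_density(counts)
  out <- list()
  for (g in unique(counts$group)) {
    cm <- suppressWarnings(correlation_matrix(dens, group = g))
    fg <- threshold_edges(mask_anatomical(cm, adj), r2_min, p_max)
    # degenerate replicates (edgeless graphs) legitimately yield empty
    # hub sets; the per-replicate score already accounts for them
    ct <- suppressWarnings(
      centrality_table(fg, hub_quantile = hub_quantile,
                       hub_rule = hub_rule))
    out[[g]] <- list(graph = fg, centrality = ct,
                     hubs = ct$region[ct$is_hub])
  }
  out
}

#' Planted-hub recovery experiment
#'
#' Runs the end-to-end network-reconstruction arm on replicates of
#' [scenario_hub_recovery()] and scores a replicate as recovered when
#' the planted region is the unique hub (conjunctive rule) in both
#' group graphs.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param hub Planted hub label.
#' @return List: `rate` (both-group recovery fraction), `per_group`
#'   rates, `n_reps`.
#' @export
experiment_hub_recovery <- function(n_reps = 100, seed = 1L,
                                    hub = "IPN") {
  seeds <- rep_seeds(seed, n_reps)
  per_rep <- matrix(NA, n_reps, 2)
  for (i in seq_len(n_reps)) {
    sc <- scenario_hub_recovery(seeds[i], hub = hub)
    sim <- generate_study(sc$config)
    nets <- reconstruct_networks(sim$counts, sc$adjacency)
    if (i == 1L) colnames(per_rep) <- names(nets)
    per_rep[i, ] <- vapply(nets, function(x) identical(x$hubs, hub), TRUE)
  }
  list(rate = mean(per_rep[, 1] & per_rep[, 2]),
       per_group = colMeans(per_rep), n_reps = n_reps)
}

#' Type-I error of the per-region model
#'
#' Replicated null simulations ([scenario_single_region()] with zero
#' treatment effect); each replicate is fitted with
#' [fit_region_model()] and the likelihood-ratio p-value recorded.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param alpha Nominal level.
#' @return List: `rejection_rate`, `n_fitted`, `n_failed`, `p` vector.
#' @export
experiment_region_type1 <- function(n_reps = 1000, seed = 1L,
                                    alpha = 0.05) {
  seeds <- rep_seeds(seed, n_reps)
  p <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    sim <- generate_study(scenario_single_region(seeds[i], lfc = 0))
    fit <- tryCatch(fit_region_model(sim$counts),
                    error = function(e) NULL)
    if (!is.null(fit)) p[i] <- fit$p
  }
  ok <- !is.na(p)
  list(rejection_rate = mean(p[ok] < alpha), n_fitted = sum(ok),
       n_failed = sum(!ok), p = p)
}

#' Treatment-effect recovery of the per-region model
#'
#' Replicated simulations at a known treatment log fold change; the
#' mean bias of the fitted effect is reported.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param lfc True treatment log fold change.
#' @return List: `mean_estimate`, `bias`, `true_lfc`, `n_fitted`,
#'   `estimates`.
#' @export
experiment_lfc_recovery <- function(n_reps = 500, seed = 1L,
                                    lfc = -0.7) {
  seeds <- rep_seeds(seed, n_reps)
  est <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    sim <- generate_study(scenario_single_region(seeds[i], lfc = lfc))
    fit <- tryCatch(fit_region_model(sim$counts),
                    error = function(e) NULL)
    if (!is.null(fit)) est[i] <- fit$estimate
  }
  ok <- !is.na(est)
  list(mean_estimate = mean(est[ok]), bias = mean(est[ok]) - lfc,
       true_lfc = lfc, n_fitted = sum(ok), estimates = est)
}

#' Connected-versus-unconnected correlation detection
#'
#' Replicates of [scenario_adjacency_coupled()]; per replicate the
#' first group's correlation matrix is compared between anatomically
#' connected and unconnected pairs. With `shuffle = TRUE` the adjacency
#' is randomly relabeled before the comparison, breaking the
#' correspondence and yielding a null distribution of p-values.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param shuffle Shuffle the adjacency labels (null control).
#' @return List: `detection_rate` (positive t and p < 0.05), `t`, `p`
#'   vectors, `n_reps`.
#' @export
experiment_connected_detection <- function(n_reps = 200, seed = 1L,
                                           shuffle = FALSE) {
  seeds <- rep_seeds(seed, n_reps)
  tval <- pval <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    sc <- scenario_adjacency_coupled(seeds[i])
    sim <- generate_study(sc$config)
    dens <- compute_density(sim$counts)
    g1 <- sc$config$group_labels[1]
    cm <- suppressWarnings(correlation_matrix(dens, group = g1))
    adj <- sc$adjacency
    if (shuffle) {
      set.seed(seeds[i] + 1L)
      perm <- sample(nrow(adj))
      adj <- adj[perm, perm]
      dimnames(adj) <- dimnames(sc$adjacency)
    }
    res <- compare_connected_unconnected(cm, adj)
    tval[i] <- res$t
    pval[i] <- res$p
  }
  list(detection_rate = mean(tval > 0 & pval < 0.05),
       t = tval, p = pval, n_reps = n_reps)
}

#' Threshold monotonicity and mask containment
#'
#' On random correlation matrices (independent-noise studies), verifies
#' that raising `r2_min` or lowering `p_max` never adds edges and that
#' the masked-then-thresholded edge set is contained in the unmasked
#' one.
#'
#' @param n_reps Number of random studies.
#' @param seed Integer seed.
#' @return List: `n_reps`, `monotonicity_violations`,
#'   `containment_violations`.
#' @export
experiment_threshold_properties <- function(n_reps = 50, seed = 1L) {
  set.seed(as.integer(seed))
  edge_key <- function(g) paste(g$edges$region_a, g$edges$region_b)
  mono_bad <- 0L
  contain_bad <- 0L
  for (i in seq_len(n_reps)) {
    nreg <- sample(6:12, 1)
    nsub <- sample(8:15, 1)
    m <- matrix(rnorm(nsub * nreg), nsub, nreg,
                dimnames = list(NULL, paste0("R", seq_len(nreg))))
    # occasional strong couplings so some edges exist
    for (j in seq_len(max(1, nreg %/% 3))) {
      a <- sample(nreg, 2)
      m[, a[2]] <- m[, a[1]] + rnorm(nsub, sd = runif(1, 0.05, 0.6))
    }
    cm <- suppressWarnings(correlation_matrix(m))
    adj <- generate_anatomical_connectome(colnames(m), runif(1, 0.2, 0.8),
                                          seed = sample.int(1e6, 1))
    r2_grid <- sort(runif(4, 0.1, 0.95))
    p_grid <- sort(runif(4, 0.01, 0.5))
    for (pm in p_grid) {
      sizes <- vapply(r2_grid, function(r2)
        nrow(threshold_edges(cm, r2, pm)$edges), 0L)
      if (any(diff(sizes) > 0)) mono_bad <- mono_bad + 1L
    }
    for (r2 in r2_grid) {
      sizes <- vapply(p_grid, function(pm)
        nrow(threshold_edges(cm, r2, pm)$edges), 0L)
      if (any(diff(sizes) < 0)) mono_bad <- mono_bad + 1L
    }
    plain <- threshold_edges(cm, 0.4, 0.05)
    masked <- threshold_edges(mask_anatomical(cm, adj), 0.4, 0.05)
    if (!all(edge_key(masked) %in% edge_key(plain)))
      contain_bad <- contain_bad + 1L
  }
  list(n_reps = n_reps, monotonicity_violations = mono_bad,
       containment_violations = contain_bad)
}

#' Degree handshake property
#'
#' On random functional graphs, checks that the degree sum equals twice
#' the edge count.
#'
#' @param n_reps Number of random graphs.
#' @param seed Integer seed.
#' @return List: `n_reps`, `violations`.
#' @export
experiment_degree_handshake <- function(n_reps = 100, seed = 1L) {
  set.seed(as.integer(seed))
  bad <- 0L
  for (i in seq_len(n_reps)) {
    nreg <- sample(5:15, 1)
    nsub <- sample(6:12, 1)
    m <- matrix(rnorm(nsub * nreg), nsub, nreg,
                dimnames = list(NULL, paste0("R", seq_len(nreg))))
    for (j in seq_len(nreg %/% 2)) {
      a <- sample(nreg, 2)
      m[, a[2]] <- m[, a[1]] + rnorm(nsub, sd = 0.2)
    }
    cm <- suppressWarnings(correlation_matrix(m))
    g <- threshold_edges(cm, runif(1, 0.2, 0.8), 0.1)
    if (sum(degree_centrality(g)) != 2L * nrow(g$edges)) bad <- bad + 1L
  }
  list(n_reps = n_reps, violations = bad)
}

#' Byte-level determinism of the pipeline
#'
#' Simulates a small study and runs the full pipeline twice from the
#' same inputs and settings, comparing every output file byte for byte
#' (MD5).
#'
#' @param seed Integer seed.
#' @param work_dir Scratch directory (a temporary directory by
#'   default).
#' @return List: `n_files`, `n_mismatched`, `identical`.
#' @export
experiment_determinism <- function(seed = 1L, work_dir = tempfile()) {
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  regions <- cfos_regions()[1:12]
  cfg <- study_config(regions = regions,
                      n_per_group = c(CTR = 6, VPA = 6),
                      n_litters = 6,
                      latent_scale = 0.5,
                      seed = seed)
  sim_dir <- file.path(work_dir, "sim")
  files <- simulate_study_files(cfg, sim_dir, edge_density = 0.4)
  run_once <- function(out) {
    pc <- pipeline_config(files$counts, files$adjacency,
                          out_dir = out,
                          fit_activation_models = FALSE, seed = seed)
    suppressMessages(run_pipeline(pc))
    out
  }
  d1 <- run_once(file.path(work_dir, "run1"))
  d2 <- run_once(file.path(work_dir, "run2"))
  f1 <- sort(list.files(d1))
  f2 <- sort(list.files(d2))
  if (!identical(f1, f2))
    return(list(n_files = length(union(f1, f2)), n_mismatched = NA,
                identical = FALSE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  n_bad <- sum(unname(h1) != unname(h2))
  list(n_files = length(f1), n_mismatched = n_bad,
       identical = n_bad == 0L)
}
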