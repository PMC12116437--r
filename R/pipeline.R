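#' Construct a pipeline configuration
#'
#' Bundles the input paths and analysis settings of one end-to-end run:
#' density aggregation, per-region and network activation models,
#' group-wise anatomically masked correlation networks and hub
#' analysis.
#'
#' @param counts_path Long-format count table CSV.
#' @param adjacency_path Labeled 0/1 anatomical adjacency CSV.
#' @param network_map_path Optional two-column (region, network) CSV.
#' @param out_dir Output directory (created if absent).
#' @param r2_min,p_max Functional edge thresholds.
#' @param hub_quantile,hub_rule Hub classification settings.
#' @param adjust Multiplicity method for region p-values.
#' @param connected_value Pairwise value compared between anatomically
#'   connected and unconnected pairs.
#' @param fit_activation_models Set `FALSE` to skip the (relatively
#'   slow) negative-binomial mixed models and run only the network
#'   reconstruction arm.
#' @param seed Integer seed recorded in the manifest (the pipeline
#'   itself is deterministic given its inputs).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path, adjacency_path,
                            network_map_path = NULL,
                            out_dir = "results",
                            r2_min = 0.7, p_max = 0.05,
                            hub_quantile = 0.8,
                            hub_rule = c("both", "sum"),
                            adjust = c("holm", "bh"),
                            connected_value = "r",
                            fit_activation_models = TRUE,
                            seed = 1L) {
  hub_rule <- match.arg(hub_rule)
  adjust <- match.arg(adjust)
  if (r2_min < 0 || r2_min > 1 || p_max <= 0 || p_max > 1 ||
      hub_quantile <= 0 || hub_quantile >= 1)
    stop("pipeline_config: threshold out of range")
  structure(list(
    counts_path = counts_path, adjacency_path = adjacency_path,
    network_map_path = network_map_path, out_dir = out_dir,
    r2_min = r2_min, p_max = p_max, hub_quantile = hub_quantile,
    hub_rule = hub_rule, adjust = adjust,
    connected_value = connected_value,
    fit_activation_models = isTRUE(fit_activation_models),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

stage <- function(name, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    }),
    warning = function(w) {
      message("pipeline stage [", name, "] warning: ",
              conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
}

#' Run the full c-Fos connectome pipeline
#'
#' Executes density aggregation, the per-region activation scan (and
#' pooled network models when a membership map is given), per-group
#' correlation matrices, anatomical masking, edge thresholding,
#' centrality and hub analysis, and the between-group degree
#' comparison. All declared outputs plus a machine-readable run
#' manifest are written under `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a result bundle: density table, region stats,
#'   network stats, per-group correlation matrices, functional graphs,
#'   centrality tables, hub sets, connected-vs-unconnected and degree
#'   comparison tests, and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (p in c(cfg$counts_path, cfg$adjacency_path, cfg$network_map_path)) {
    if (!is.null(p) && !file.exists(p))
      stop("pipeline configuration error: input file not found: ", p)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, paste0(...))

  counts <- stage("read", read_count_table(cfg$counts_path))
  adj <- stage("read", read_adjacency(cfg$adjacency_path))
  net_map <- if (!is.null(cfg$network_map_path)) {
    stage("read", read.csv(cfg$network_map_path, stringsAsFactors = FALSE))
  }

  dens <- stage("density", compute_density(counts))
  write_density_table(dens, out("density.csv"))

  region_stats <- NULL
  network_stats <- NULL
  if (cfg$fit_activation_models) {
    region_stats <- stage("activation_stats",
                          region_scan(counts, adjust = cfg$adjust))
    write_csv_precise(region_stats, out("region_stats.csv"))
    if (!is.null(net_map)) {
      nets <- split(net_map$region, net_map$network)
      nets <- nets[vapply(nets, length, 1L) >= 2L]
      network_stats <- do.call(rbind, lapply(names(nets), function(nm) {
        fit <- stage("activation_stats",
                     fit_network_model(counts, regions = nets[[nm]],
                                       label = nm))
        data.frame(network = nm, chi2 = fit$chi2, df = fit$df,
                   n_obs = fit$n_obs, p = fit$p, lfc = fit$estimate,
                   stringsAsFactors = FALSE)
      }))
      write_csv_precise(network_stats, out("network_stats.csv"))
    }
  }

  groups <- unique(counts$group)
  corr <- list(); graphs <- list(); centr <- list(); hubs <- list()
  conn_tests <- list(); masked_pairs <- list(); dropped_regions <- list()
  for (g in groups) {
    cm <- stage("connectome", correlation_matrix(dens, group = g))
    corr[[g]] <- cm
    write_correlation_matrices(cm, out("correlation_", g))
    conn_tests[[g]] <- stage("connectome",
                             compare_connected_unconnected(
                               cm, adj, value = cfg$connected_value))
    masked <- stage("connectome", mask_anatomical(cm, adj))
    ut <- upper.tri(cm$r)
    masked_pairs[[g]] <- sum(!is.na(cm$r[ut]) & is.na(masked$r[ut]))
    dropped_regions[[g]] <- cm$regions[apply(is.na(cm$r), 1, all)]
    fg <- stage("connectome",
                threshold_edges(masked, r2_min = cfg$r2_min,
                                p_max = cfg$p_max))
    graphs[[g]] <- fg
    write_edge_list(fg, out("edges_", g, ".csv"),
                    graphml_path = out("graph_", g, ".graphml"))
    ct <- stage("network_analysis",
                centrality_table(fg, hub_quantile = cfg$hub_quantile,
                                 hub_rule = cfg$hub_rule))
    centr[[g]] <- ct
    hubs[[g]] <- ct$region[ct$is_hub]
    write_csv_precise(as.data.frame(ct), out("centrality_", g, ".csv"))
  }

  degree_cmp <- if (length(groups) == 2L) {
    stage("network_analysis",
          compare_degree_distributions(centr[[groups[1]]],
                                       centr[[groups[2]]]))
  }
  report <- list(
    hubs = hubs,
    edge_counts = lapply(graphs, function(g) nrow(g$edges)),
    anatomically_masked_pairs = masked_pairs,
    zero_variance_regions = dropped_regions,
    connected_vs_unconnected = conn_tests,
    degree_comparison = degree_cmp
  )
  jsonlite::write_json(report, out("network_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  manifest <- list(
    package = "cfosnet",
    version = as.character(packageVersion("cfosnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = list(counts = cfg$counts_path,
                  adjacency = cfg$adjacency_path,
                  network_map = cfg$network_map_path),
    settings = cfg[c("r2_min", "p_max", "hub_quantile", "hub_rule",
                     "adjust", "connected_value",
                     "fit_activation_models")],
    seed = cfg$seed,
    outputs = list.files(cfg$out_dir)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(density = dens, region_stats = region_stats,
                 network_stats = network_stats, correlations = corr,
                 graphs = graphs, centrality = centr, hubs = hubs,
                 connected_vs_unconnected = conn_tests,
                 degree_comparison = degree_cmp, manifest = manifest))
}

#' Simulate a study and write its files
#'
#' Wraps the synthetic-data generator: writes the count table, the
#' anatomical adjacency, the study config (YAML) and a ground-truth
#' record (JSON) into `out_dir`.
#'
#' @param cfg A [study_config()].
#' @param out_dir Output directory.
#' @param adjacency Optional precomputed adjacency; by default an
#'   Erdos-Renyi connectome at `edge_density` (with the config's
#'   planted hub wired to all regions, if set).
#' @param edge_density Edge density for the default adjacency.
#' @return Invisibly, list of written paths plus the simulated objects.
#' @export
simulate_study_files <- function(cfg, out_dir, adjacency = NULL,
                                 edge_density = 0.3) {
  validate_study_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_study(cfg)
  if (is.null(adjacency)) {
    adjacency <- generate_anatomical_connectome(
      cfg$regions, edge_density, planted_hub = cfg$planted_hub,
      seed = cfg$seed + 1L)
  }
  paths <- list(
    counts = file.path(out_dir, "counts.csv"),
    adjacency = file.path(out_dir, "adjacency.csv"),
    config = file.path(out_dir, "study_config.yaml"),
    truth = file.path(out_dir, "truth.json")
  )
  write_count_table(sim$counts, paths$counts)
  write_adjacency(adjacency, paths$adjacency)
  write_study_config(cfg, paths$config)
  truth <- sim$truth
  jsonlite::write_json(
    list(planted_hub = truth$planted_hub,
         treatment_log_fold_change = as.list(truth$treatment_log_fold_change),
         litter_intercepts = truth$litter_intercepts,
         seed = truth$seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")
  invisible(c(paths, list(counts_data = sim$counts, truth_data = truth,
                          adjacency_data = adjacency)))
}
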