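# All tabular output is plain CSV. Numeric columns are written with
# %.17g so that write -> read round-trips doubles exactly.

format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      s <- rep(NA_character_, length(x))
      ok <- !is.na(x)
      long <- sprintf("%.17g", x[ok])
      short <- sprintf("%.15g", x[ok])
      use_short <- as.numeric(short) == x[ok]
      s[ok] <- ifelse(use_short, short, long)
      df[[j]] <- s
    }
  }
  df
}

write_csv_precise <- function(df, path) {
  write.csv(format_full_precision(df), path, row.names = FALSE,
            quote = FALSE, na = "NA")
  invisible(path)
}

#' Write / read a long-format count table
#'
#' Columns: subject_id, group, litter_id, region, hemisphere,
#' slide_index, count, area_mm2. Doubles round-trip exactly.
#'
#' @param counts Count table data frame.
#' @param path File path (CSV).
#' @return `write_count_table` the path invisibly; `read_count_table`
#'   the count table.
#' @export
write_count_table <- function(counts, path) {
  write_csv_precise(counts, path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character",
                                group = "character",
                                litter_id = "character",
                                region = "character",
                                hemisphere = "character",
                                slide_index = "integer",
                                count = "integer",
                                area_mm2 = "numeric"))
  df
}

#' Write / read a labeled anatomical adjacency matrix
#'
#' Square 0/1 CSV with a leading `region` label column and region
#' column headers.
#'
#' @param adj Binary matrix with region dimnames.
#' @param path File path (CSV).
#' @return `write_adjacency` the path invisibly; `read_adjacency` an
#'   integer matrix with dimnames.
#' @export
write_adjacency <- function(adj, path) {
  df <- data.frame(region = rownames(adj), adj, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$region
  if (!identical(rownames(m), colnames(m)))
    stop("read_adjacency: row and column labels differ in ", path)
  m
}

#' Write / read a density table
#'
#' Subjects as rows; `subject_id`, `group`, `litter_id` metadata
#' columns followed by one density column per region.
#'
#' @param dens A `density_table`.
#' @param path File path (CSV).
#' @return `write_density_table` the path invisibly;
#'   `read_density_table` a `density_table`.
#' @export
write_density_table <- function(dens, path) {
  write_csv_precise(as.data.frame(dens), path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  regions <- setdiff(names(df), c("subject_id", "group", "litter_id"))
  structure(df, regions = regions,
            class = c("density_table", "data.frame"))
}

#' Write the three matrices of a correlation matrix object
#'
#' Writes `<prefix>_r.csv`, `<prefix>_signed_r2.csv`, `<prefix>_p.csv`
#' and `<prefix>_n_pairs.csv`, each a labeled square CSV.
#'
#' @param corr A `correlation_matrix`.
#' @param prefix Path prefix (directory + file stem).
#' @return Character vector of the written paths, invisibly.
#' @export
write_correlation_matrices <- function(corr, prefix) {
  paths <- character(0)
  for (nm in c("r", "signed_r2", "p", "n_pairs")) {
    m <- corr[[nm]]
    df <- data.frame(region = rownames(m), as.data.frame(m, optional = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    path <- paste0(prefix, "_", nm, ".csv")
    write_csv_precise(df, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Export a functional graph
#'
#' Writes the edge list (region_a, region_b, sign, weight, r) as CSV
#' and, optionally, the graph as GraphML.
#'
#' @param g A `functional_graph`.
#' @param path Edge-list CSV path.
#' @param graphml_path Optional GraphML path.
#' @return The edge-list path, invisibly.
#' @export
write_edge_list <- function(g, path, graphml_path = NULL) {
  write_csv_precise(g$edges, path)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(g), graphml_path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_list
#' @param regions Node set of the graph (edge lists do not carry
#'   isolated nodes).
#' @param group Group label.
#' @export
read_edge_list <- function(path, regions, group = NA_character_) {
  edges <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(region_a = "character",
                                   region_b = "character",
                                   sign = "character",
                                   weight = "numeric", r = "numeric"))
  structure(list(regions = regions, edges = edges, group = group,
                 thresholds = NULL),
            class = "functional_graph")
}

#' Write / read a study configuration as YAML
#'
#' Latent correlation matrices are stored row-wise under their group
#' labels. The seed is mandatory.
#'
#' @param cfg A `study_config`.
#' @param path YAML file path.
#' @return `write_study_config` the path invisibly; `read_study_config`
#'   a validated `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  num_str <- function(x) {
    s <- sprintf("%.17g", x)
    short <- sprintf("%.15g", x)
    ok <- as.numeric(short) == x
    s[ok] <- short[ok]
    s
  }
  lst <- unclass(cfg)
  lst$latent_corr <- lapply(lst$latent_corr, function(m) {
    lapply(seq_len(nrow(m)), function(i) num_str(unname(m[i, ])))
  })
  lst$n_per_group <- as.list(lst$n_per_group)
  for (nm in c("region_area", "baseline_log_density",
               "treatment_log_fold_change")) {
    lst[[nm]] <- as.list(setNames(num_str(lst[[nm]]), names(lst[[nm]])))
  }
  lst$slides_per_region <- as.list(lst$slides_per_region)
  for (nm in c("litter_sd", "nb_dispersion", "latent_scale")) {
    lst[[nm]] <- num_str(lst[[nm]])
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (is.null(lst$seed)) stop("read_study_config: seed is mandatory in ", path)
  regions <- as.character(lst$regions)
  lc <- lapply(lst$latent_corr, function(rows) {
    m <- do.call(rbind, lapply(rows, as.numeric))
    dimnames(m) <- list(regions, regions)
    m
  })
  num_vec <- function(x) {
    v <- unlist(x)
    setNames(as.numeric(v), names(v))
  }
  study_config(
    regions = regions,
    n_per_group = num_vec(lst$n_per_group),
    group_labels = as.character(lst$group_labels),
    n_litters = lst$n_litters,
    region_area = num_vec(lst$region_area),
    baseline_log_density = num_vec(lst$baseline_log_density),
    treatment_log_fold_change = num_vec(lst$treatment_log_fold_change),
    litter_sd = as.numeric(lst$litter_sd),
    nb_dispersion = as.numeric(lst$nb_dispersion),
    latent_scale = as.numeric(lst$latent_scale),
    latent_corr = lc,
    slides_per_region = unlist(lst$slides_per_region),
    planted_hub = lst$planted_hub,
    seed = lst$seed
  )
}
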