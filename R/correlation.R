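#' Group-wise Pearson correlation matrices of regional densities
#'
#' All pairwise Pearson correlations between regional density profiles
#' across the subjects of one group, using pairwise-complete
#' observations. p-values come from the two-sided t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` df, where `n` is
#' the per-pair complete sample size. The signed R-squared
#' (`sign(r) * r^2`) preserves the direction of negative couplings
#' while thresholds compare magnitudes. Pairs with fewer than
#' `min_pairs` complete observations, and zero-variance regions, are
#' set to `NA` (with a warning for the latter).
#'
#' @param dens A `density_table`, or a numeric subjects-x-regions
#'   matrix.
#' @param group Group label to subset (required for a `density_table`
#'   containing both groups).
#' @param min_pairs Minimum pairwise-complete sample size.
#' @return Object of class `correlation_matrix`: list of matrices `r`,
#'   `signed_r2`, `p`, `n_pairs`, plus `group` and `regions`.
#' @export
correlation_matrix <- function(dens, group = NULL, min_pairs = 3L) {
  m <- if (is.matrix(dens)) dens else density_matrix(dens, group = group)
  regions <- colnames(m)
  nr <- ncol(m)
  zero_var <- vapply(seq_len(nr), function(j) {
    v <- m[, j][!is.na(m[, j])]
    length(v) < 2L || stats::sd(v) == 0
  }, TRUE)
  if (any(zero_var)) {
    warning("correlation_matrix: zero-variance or empty region(s) ",
            paste(regions[zero_var], collapse = ", "),
            "; their rows/columns are set to NA")
  }
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(m))
  storage.mode(n_pairs) <- "integer"
  too_few <- n_pairs < min_pairs
  r[too_few] <- NA_real_
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- ifelse(zero_var, NA_real_, 1)
  tt <- r * sqrt(pmax(n_pairs - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), pmax(n_pairs - 2, 1))
  diag(p) <- NA_real_
  structure(list(
    r = r,
    signed_r2 = sign(r) * r^2,
    p = p,
    n_pairs = n_pairs,
    group = if (is.null(group)) NA_character_ else group,
    regions = regions
  ), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> group ", x$group, ": ", length(x$regions),
      " regions, ", sum(!is.na(x$r[upper.tri(x$r)])),
      " defined pairs\n", sep = "")
  invisible(x)
}

#' Mask a correlation matrix with an anatomical adjacency
#'
#' Restricts candidate functional connections to region pairs with
#' documented anatomical connectivity: entries where the (OR-
#' symmetrized) adjacency is zero are set to `NA` in `r`, `signed_r2`
#' and `p`. Labels are matched by name; any mismatch is an error
#' listing the asymmetric difference.
#'
#' @param corr A `correlation_matrix`.
#' @param adj Square binary matrix with region dimnames.
#' @return The masked `correlation_matrix` (attribute `masked = TRUE`).
#' @export
mask_anatomical <- function(corr, adj) {
  stopifnot(inherits(corr, "correlation_matrix"))
  adj_regions <- rownames(adj)
  extra <- setdiff(adj_regions, corr$regions)
  missing_regions <- setdiff(corr$regions, adj_regions)
  if (length(extra) || length(missing_regions))
    stop("mask_anatomical: region label mismatch; only in adjacency: {",
         paste(extra, collapse = ", "), "}; only in correlation: {",
         paste(missing_regions, collapse = ", "), "}")
  a <- as.matrix(adj)[corr$regions, corr$regions]
  a <- (a + t(a)) > 0  # symmetrize a possibly directed source by OR
  keep <- a | diag(TRUE, length(corr$regions))
  for (nm in c("r", "signed_r2", "p")) corr[[nm]][!keep] <- NA_real_
  attr(corr, "masked") <- TRUE
  corr
}

#' Threshold a correlation matrix into a functional graph
#'
#' An undirected edge is drawn between two regions iff the pair is
#' unmasked, `|signed R2| > r2_min` and `p < p_max` (both strict, so
#' ties at the thresholds are excluded). Edge sign records the
#' direction of the underlying correlation; weight is `|signed R2|`.
#'
#' @param corr A `correlation_matrix` (typically anatomically masked).
#' @param r2_min Strength threshold on `|signed R2|`.
#' @param p_max Significance threshold.
#' @return Object of class `functional_graph`: region node set, edge
#'   data frame (region_a, region_b, sign, weight, r), group label.
#' @export
threshold_edges <- function(corr, r2_min = 0.7, p_max = 0.05) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (r2_min < 0 || r2_min > 1 || p_max <= 0 || p_max > 1)
    stop("threshold_edges: thresholds out of range")
  sr2 <- corr$signed_r2
  p <- corr$p
  idx <- which(upper.tri(sr2) & !is.na(sr2) & !is.na(p) &
                 abs(sr2) > r2_min & p < p_max, arr.ind = TRUE)
  edges <- data.frame(
    region_a = corr$regions[idx[, 1]],
    region_b = corr$regions[idx[, 2]],
    sign = ifelse(sr2[idx] >= 0, "+", "-"),
    weight = abs(sr2[idx]),
    r = corr$r[idx],
    stringsAsFactors = FALSE
  )
  structure(list(regions = corr$regions, edges = edges,
                 group = corr$group,
                 thresholds = c(r2_min = r2_min, p_max = p_max)),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat("<functional_graph> group ", x$group, ": ", length(x$regions),
      " regions, ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "-"), " negative)\n", sep = "")
  invisible(x)
}

#' Convert a functional graph to an igraph object
#'
#' All regions are kept as vertices (isolated regions included).
#'
#' @param g A `functional_graph`.
#' @return An undirected `igraph` graph with `sign` and `weight` edge
#'   attributes.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  igraph::graph_from_data_frame(
    g$edges[, c("region_a", "region_b", "sign", "weight")],
    directed = FALSE,
    vertices = data.frame(name = g$regions, stringsAsFactors = FALSE)
  )
}

#' Do anatomically connected pairs correlate more strongly?
#'
#' Welch two-sample t-test comparing the correlation values of
#' anatomically connected versus unconnected region pairs (upper
#' triangle, NA pairs dropped). The comparison value is the Pearson r
#' by default; signed R-squared or |r| can be selected.
#'
#' @param corr An unmasked `correlation_matrix`.
#' @param adj Anatomical adjacency with matching region labels.
#' @param value Which pairwise value to compare.
#' @param alternative Passed to [t.test()]; default two-sided.
#' @return List with `t`, `df`, `p`, group means and pair counts.
#' @export
compare_connected_unconnected <- function(corr, adj,
                                          value = c("r", "signed_r2",
                                                    "abs_r"),
                                          alternative = "two.sided") {
  stopifnot(inherits(corr, "correlation_matrix"))
  value <- match.arg(value)
  a <- as.matrix(adj)[corr$regions, corr$regions]
  a <- (a + t(a)) > 0
  v <- switch(value, r = corr$r, signed_r2 = corr$signed_r2,
              abs_r = abs(corr$r))
  ut <- upper.tri(v)
  keep <- ut & !is.na(v)
  conn <- v[keep & a]
  unconn <- v[keep & !a]
  if (!length(conn) || !length(unconn))
    stop("compare_connected_unconnected: one of the pair classes is empty")
  tt <- t.test(conn, unconn, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_connected = mean(conn), mean_unconnected = mean(unconn),
       n_connected = length(conn), n_unconnected = length(unconn))
}
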