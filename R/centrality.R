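#' Degree centrality of a functional graph
#'
#' Number of incident edges per region; edge signs are ignored.
#' Isolated regions get 0.
#'
#' @param g A `functional_graph` or an `igraph` graph.
#' @return Named integer vector over all regions.
#' @export
degree_centrality <- function(g) {
  ig <- if (inherits(g, "functional_graph")) as_igraph(g) else g
  deg <- igraph::degree(ig, loops = FALSE)
  setNames(as.integer(deg), igraph::V(ig)$name)
}

#' Betweenness centrality of a functional graph
#'
#' For each node v, the sum over unordered pairs of distinct other
#' nodes (u, w) of the fraction of shortest u-w paths passing through
#' v. Unweighted, undirected; each unordered pair is counted once;
#' pairs with no connecting path contribute 0; endpoints are excluded
#' from their own pair terms. Edge signs are ignored.
#'
#' @param g A `functional_graph` or an `igraph` graph.
#' @return Named numeric vector over all regions.
#' @export
betweenness_centrality <- function(g) {
  ig <- if (inherits(g, "functional_graph")) as_igraph(g) else g
  btw <- igraph::betweenness(ig, directed = FALSE, weights = NA,
                             normalized = FALSE)
  setNames(as.numeric(btw), igraph::V(ig)$name)
}

#' Centrality table of one group's functional graph
#'
#' Degree and betweenness per region, together with each region's rank
#' quantile (the fraction of regions with a value no larger than its
#' own) and the hub flag from [classify_hubs()].
#'
#' @param g A `functional_graph`.
#' @param hub_quantile Quantile cutoff for hub classification.
#' @param hub_rule `"both"` (conjunctive, default) or `"sum"`.
#' @return Object of class `centrality_table` (a data frame): region,
#'   degree, betweenness, degree_q, betweenness_q, is_hub; attribute
#'   `group`.
#' @export
centrality_table <- function(g, hub_quantile = 0.8,
                             hub_rule = c("both", "sum")) {
  hub_rule <- match.arg(hub_rule)
  deg <- degree_centrality(g)
  btw <- betweenness_centrality(g)
  tab <- data.frame(
    region = names(deg),
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    degree_q = ecdf(deg)(deg),
    betweenness_q = ecdf(btw)(btw),
    stringsAsFactors = FALSE
  )
  hubs <- classify_hubs(tab, hub_quantile = hub_quantile, rule = hub_rule)
  tab$is_hub <- tab$region %in% hubs
  structure(tab, group = if (inherits(g, "functional_graph")) g$group else NA,
            class = c("centrality_table", "data.frame"))
}

#' Classify hub regions by centrality quantiles
#'
#' Default conjunctive rule: a region is a hub iff its degree strictly
#' exceeds the `hub_quantile` quantile of all degrees AND its
#' betweenness strictly exceeds the same quantile of all betweenness
#' values (linear-interpolation quantiles, R type 7). The alternative
#' `"sum"` rule rescales each centrality to \[0, 1\], sums them, and
#' requires the sum to strictly exceed its own `hub_quantile` quantile.
#' With all-equal centralities no node strictly exceeds the quantile
#' and the hub set is empty (with a warning).
#'
#' @param centr A `centrality_table` (or data frame with `region`,
#'   `degree`, `betweenness`).
#' @param hub_quantile Quantile cutoff, default 0.8.
#' @param rule `"both"` or `"sum"`.
#' @return Character vector of hub region labels.
#' @export
classify_hubs <- function(centr, hub_quantile = 0.8,
                          rule = c("both", "sum")) {
  rule <- match.arg(rule)
  if (!nrow(centr)) stop("classify_hubs: empty centrality table")
  deg <- centr$degree
  btw <- centr$betweenness
  if (rule == "both") {
    hubs <- centr$region[deg > quantile(deg, hub_quantile, type = 7) &
                           btw > quantile(btw, hub_quantile, type = 7)]
  } else {
    rescale01 <- function(x) {
      rng <- range(x)
      if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
    }
    s <- rescale01(deg) + rescale01(btw)
    hubs <- centr$region[s > quantile(s, hub_quantile, type = 7)]
  }
  if (!length(hubs) && length(unique(deg)) == 1L &&
      length(unique(btw)) == 1L)
    warning("classify_hubs: all centralities equal; empty hub set")
  hubs
}

#' Compare degree distributions of two functional graphs
#'
#' Wilcoxon rank-sum (Mann-Whitney) test on the per-region degree
#' values of two graphs. W is the rank-sum statistic of the first
#' sample (as conventionally reported); the two-sided p-value uses the
#' tie-corrected normal approximation.
#'
#' @param a,b `centrality_table`s (or data frames with a `degree`
#'   column), typically one per experimental group.
#' @param value Column to compare (default `"degree"`; `"betweenness"`
#'   also meaningful).
#' @return List with `W`, `p` and the two sample sizes.
#' @export
compare_degree_distributions <- function(a, b, value = "degree") {
  x <- a[[value]]
  y <- b[[value]]
  if (!length(x) || !length(y))
    stop("compare_degree_distributions: empty centrality table")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value,
       n_a = length(x), n_b = length(y))
}
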