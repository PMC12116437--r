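#' Enumeration-based betweenness reference
#'
#' Computes betweenness by exhaustively enumerating every shortest path
#' between every unordered pair of nodes (breadth-first distances, then
#' recursive path enumeration) and crediting each interior node its
#' fraction of the pair's paths. Written without any graph library, it
#' serves as the independent oracle for validating
#' [betweenness_centrality()] on small graphs; cost grows rapidly with
#' size, so keep graphs below ~10 nodes.
#'
#' @param adj Symmetric 0/1 adjacency matrix (zero diagonal).
#' @return Numeric betweenness vector, one entry per node.
#' @export
betweenness_reference <- function(adj) {
  n <- nrow(adj)
  nodes <- seq_len(n)
  nb <- lapply(nodes, function(i) which(adj[i, ] > 0))
  dist_from <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[is.infinite(d[nxt])]
      if (length(nxt)) d[nxt] <- d[frontier[1]] + 1
      frontier <- nxt
    }
    d
  }
  D <- t(vapply(nodes, dist_from, numeric(n)))
  enum_paths <- function(u, w) {
    if (u == w) return(list(u))
    res <- list()
    for (v in nb[[u]]) {
      if (is.finite(D[v, w]) && D[v, w] == D[u, w] - 1) {
        for (p in enum_paths(v, w)) res[[length(res) + 1L]] <- c(u, p)
      }
    }
    res
  }
  btw <- numeric(n)
  for (u in nodes) {
    for (w in nodes) {
      if (u < w && is.finite(D[u, w]) && D[u, w] >= 2) {
        paths <- enum_paths(u, w)
        sigma <- length(paths)
        inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
        tb <- table(inner)
        idx <- as.integer(names(tb))
        btw[idx] <- btw[idx] + as.numeric(tb) / sigma
      }
    }
  }
  if (!is.null(rownames(adj))) names(btw) <- rownames(adj)
  btw
}
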