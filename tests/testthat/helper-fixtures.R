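# Shared fixtures, built in code.

# Minimal long-format count table: one subject/region/slide unless
# overridden. Args are vectors recycled against each other.
make_records <- function(subject_id = "S01", group = "CTR",
                         litter_id = "L01", region = "A",
                         hemisphere = c("left", "right"),
                         slide_index = 0L, count = c(50L, 30L),
                         area_mm2 = 0.5) {
  data.frame(subject_id = subject_id, group = group,
             litter_id = litter_id, region = region,
             hemisphere = hemisphere, slide_index = slide_index,
             count = count, area_mm2 = area_mm2,
             stringsAsFactors = FALSE)
}

# Hand-built functional graph from an edge matrix (two columns of
# region labels).
make_graph <- function(regions, edges, group = "CTR") {
  ed <- if (is.null(edges) || !nrow(edges)) {
    data.frame(region_a = character(), region_b = character(),
               sign = character(), weight = numeric(), r = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(region_a = edges[, 1], region_b = edges[, 2],
               sign = "+", weight = 0.8, r = 0.9,
               stringsAsFactors = FALSE)
  }
  structure(list(regions = regions, edges = ed, group = group,
                 thresholds = c(r2_min = 0.7, p_max = 0.05)),
            class = "functional_graph")
}

# Hand-built correlation_matrix object with prescribed signed_r2 and p
# entries (symmetric fill from the upper triangle).
make_corr <- function(regions, signed_r2, p, group = "CTR") {
  sym <- function(m) {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(regions, regions)
    m
  }
  sr2 <- sym(signed_r2)
  structure(list(r = sign(sr2) * sqrt(abs(sr2)),
                 signed_r2 = sr2, p = sym(p),
                 n_pairs = matrix(10L, length(regions), length(regions),
                                  dimnames = list(regions, regions)),
                 group = group, regions = regions),
            class = "correlation_matrix")
}
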