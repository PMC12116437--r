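test_that("degree centrality matches hand-counted graphs", {
  tri <- make_graph(c("A", "B", "C"),
                    cbind(c("A", "B", "C"), c("B", "C", "A")))
  expect_equal(degree_centrality(tri),
               c(A = 2L, B = 2L, C = 2L))

  star <- make_graph(c("hub", paste0("L", 1:5)),
                     cbind("hub", paste0("L", 1:5)))
  deg <- degree_centrality(star)
  expect_identical(deg[["hub"]], 5L)
  expect_true(all(deg[paste0("L", 1:5)] == 1L))
  expect_identical(sum(deg), 2L * 5L)

  iso <- make_graph(c("A", "B", "C"), cbind("A", "B"))
  expect_identical(degree_centrality(iso)[["C"]], 0L)
})

test_that("betweenness matches hand-derived values on canonical graphs", {
  path3 <- make_graph(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  expect_equal(betweenness_centrality(path3),
               c(A = 0, B = 1, C = 0))

  star <- make_graph(c("hub", paste0("L", 1:5)),
                     cbind("hub", paste0("L", 1:5)))
  expect_equal(betweenness_centrality(star)[["hub"]], choose(5, 2))

  ring4 <- make_graph(c("A", "B", "C", "D"),
                      cbind(c("A", "B", "C", "D"), c("B", "C", "D", "A")))
  expect_equal(betweenness_centrality(ring4),
               c(A = 0.5, B = 0.5, C = 0.5, D = 0.5))
})

test_that("betweenness agrees with exhaustive path enumeration", {
  res <- experiment_betweenness_oracle(n_graphs = 60, seed = 61)
  expect_identical(res$n_agree, 60L)
  expect_lt(res$max_abs_diff, 1e-9)
})

test_that("hub classification follows the strict dual-quantile rule", {
  star <- make_graph(c("hub", paste0("L", 1:5)),
                     cbind("hub", paste0("L", 1:5)))
  ct <- centrality_table(star)
  expect_identical(ct$region[ct$is_hub], "hub")
  expect_true(all(ct$degree_q[ct$is_hub] > 0.8))
  expect_true(all(ct$betweenness_q[ct$is_hub] > 0.8))

  ring <- make_graph(c("A", "B", "C", "D"),
                     cbind(c("A", "B", "C", "D"), c("B", "C", "D", "A")))
  expect_identical(suppressWarnings(classify_hubs(centrality_table(ring))),
                   character(0))

  empty <- make_graph(c("A", "B", "C"), NULL)
  ct_empty <- suppressWarnings(centrality_table(empty))
  expect_warning(hubs <- classify_hubs(ct_empty),
                 "all centralities equal")
  expect_identical(hubs, character(0))

  # planted top node beats everyone under both rules; runners-up are
  # tied so the strict 80th-percentile exceedance singles out the top
  tab <- data.frame(region = paste0("R", 1:10),
                    degree = c(20L, 6L, 6L, 5L, 4L, 3L, 2L, 2L, 1L, 1L),
                    betweenness = c(50, 10, 10, 8, 6, 4, 2, 2, 1, 1),
                    stringsAsFactors = FALSE)
  expect_identical(classify_hubs(tab, rule = "both"), "R1")
  expect_identical(classify_hubs(tab, rule = "sum"), "R1")
  # brute-force check of the conjunctive rule
  manual <- tab$region[tab$degree > quantile(tab$degree, 0.8) &
                         tab$betweenness > quantile(tab$betweenness, 0.8)]
  expect_identical(classify_hubs(tab, rule = "both"), manual)
})

test_that("adding an edge never lowers a degree", {
  set.seed(11)
  regs <- paste0("R", 1:8)
  for (i in 1:20) {
    n_e <- sample(0:10, 1)
    pairs <- t(replicate(n_e + 1, sample(regs, 2)))
    pairs <- pairs[!duplicated(paste(pmin(pairs[, 1], pairs[, 2]),
                                     pmax(pairs[, 1], pairs[, 2]))), ,
                   drop = FALSE]
    if (nrow(pairs) < 2) next
    g_small <- make_graph(regs, pairs[-nrow(pairs), , drop = FALSE])
    g_big <- make_graph(regs, pairs)
    expect_true(all(degree_centrality(g_big) >=
                      degree_centrality(g_small)))
  }
})

test_that("degree distributions compare by rank-sum as expected", {
  a <- data.frame(degree = c(3L, 5L, 2L, 7L, 4L, 6L, 1L, 8L))
  res_same <- compare_degree_distributions(a, a)
  expect_gt(res_same$p, 0.9)

  b <- data.frame(degree = a$degree + 10L)
  res_shift <- compare_degree_distributions(a, b)
  expect_lt(res_shift$p, 0.001)
  # W is the Mann-Whitney statistic of the first sample: no wins
  expect_equal(res_shift$W, 0)

  set.seed(12)
  null_p <- replicate(200, {
    pool <- sample(0:15, 20, replace = TRUE)
    idx <- sample(20, 10)
    compare_degree_distributions(data.frame(degree = pool[idx]),
                                 data.frame(degree = pool[-idx]))$p
  })
  expect_gt(mean(null_p < 0.05), 0.005)
  expect_lt(mean(null_p < 0.05), 0.12)
  expect_gt(mean(null_p), 0.35)
  expect_lt(mean(null_p), 0.65)
})
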