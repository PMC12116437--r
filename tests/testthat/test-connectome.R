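test_that("perfect linear dependence gives |signed R2| = 1", {
  set.seed(4)
  a <- rnorm(10, 100, 20)
  m <- cbind(A = a, B = 2 * a, C = -a + 0.0, D = rnorm(10, 100, 20))
  cm <- correlation_matrix(m)
  expect_equal(cm$r["A", "B"], 1)
  expect_equal(cm$signed_r2["A", "B"], 1)
  expect_equal(cm$signed_r2["A", "C"], -1)
  expect_lt(cm$p["A", "B"], 1e-10)
  # symmetry and bounds
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$signed_r2, t(cm$signed_r2))
  expect_true(all(abs(cm$signed_r2) <= 1, na.rm = TRUE))
  expect_equal(abs(cm$signed_r2), cm$r^2)
})

test_that("independent regions trip the 5% threshold at the nominal rate", {
  set.seed(5)
  hits <- 0L; total <- 0L
  for (i in 1:150) {
    m <- matrix(rnorm(10 * 6), 10, 6,
                dimnames = list(NULL, paste0("R", 1:6)))
    cm <- correlation_matrix(m)
    ut <- upper.tri(cm$p)
    hits <- hits + sum(cm$p[ut] < 0.05)
    total <- total + sum(ut)
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
})

test_that("pairwise-complete correlations honor missing data and
           zero-variance columns", {
  set.seed(6)
  m <- matrix(rnorm(12 * 4, 100, 10), 12, 4,
              dimnames = list(NULL, c("A", "B", "C", "Z")))
  m[1:3, "B"] <- NA
  m[, "Z"] <- 5
  expect_warning(cm <- correlation_matrix(m), "zero-variance")
  expect_identical(cm$n_pairs["A", "B"], 9L)
  expect_identical(cm$n_pairs["A", "C"], 12L)
  expect_true(all(is.na(cm$r["Z", ])))
  expect_equal(cm$r["A", "B"],
               cor(m[, "A"], m[, "B"], use = "complete.obs"))
  # too few complete pairs -> NA
  m2 <- m[, c("A", "B", "C")]
  m2[1:10, "B"] <- NA
  expect_warning(cm2 <- correlation_matrix(m2), NA)
  expect_true(is.na(cm2$r["A", "B"]))
})

test_that("anatomical masking keeps only adjacent pairs and checks labels", {
  set.seed(7)
  m <- matrix(rnorm(10 * 4, 100, 10), 10, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  cm <- correlation_matrix(m)

  ones <- matrix(1L, 4, 4, dimnames = list(colnames(m), colnames(m)))
  diag(ones) <- 0L
  masked_id <- mask_anatomical(cm, ones)
  expect_equal(masked_id$r, cm$r)

  zeros <- ones * 0L
  masked_zero <- mask_anatomical(cm, zeros)
  expect_true(all(is.na(masked_zero$r[upper.tri(masked_zero$r)])))
  expect_identical(nrow(threshold_edges(masked_zero, 0.1, 0.9)$edges), 0L)

  wrong <- ones
  rownames(wrong) <- colnames(wrong) <- c("A", "B", "C", "X")
  expect_error(mask_anatomical(cm, wrong), "only in adjacency: \\{X\\}")

  # a directed source adjacency is OR-symmetrized
  dir_adj <- zeros
  dir_adj["A", "B"] <- 1L
  masked_dir <- mask_anatomical(cm, dir_adj)
  expect_false(is.na(masked_dir$r["B", "A"]))
})

test_that("edge thresholds are strict on both criteria and keep signs", {
  regs <- c("A", "B", "C", "D")
  sr2 <- matrix(0, 4, 4)
  p <- matrix(1, 4, 4)
  sr2[1, 2] <- 0.71; p[1, 2] <- 0.04   # passes both
  sr2[1, 3] <- 0.90; p[1, 3] <- 0.06   # fails p
  sr2[1, 4] <- -0.75; p[1, 4] <- 0.01  # negative, passes
  sr2[2, 3] <- 0.70; p[2, 3] <- 0.05   # exactly at thresholds: excluded
  cm <- make_corr(regs, sr2, p)
  g <- threshold_edges(cm, r2_min = 0.7, p_max = 0.05)
  key <- paste(g$edges$region_a, g$edges$region_b)
  expect_setequal(key, c("A B", "A D"))
  expect_identical(g$edges$sign[key == "A B"], "+")
  expect_identical(g$edges$sign[key == "A D"], "-")
  expect_equal(g$edges$weight[key == "A D"], 0.75)
})

test_that("mask-then-threshold equals threshold-then-intersect", {
  set.seed(8)
  cfg <- study_config(regions = cfos_regions()[1:10],
                      n_per_group = c(CTR = 8, VPA = 8), n_litters = 6,
                      latent_scale = 0.8, nb_dispersion = 30, seed = 51)
  dens <- compute_density(generate_study(cfg)$counts)
  cm <- correlation_matrix(dens, group = "CTR")
  adj <- generate_anatomical_connectome(cfos_regions()[1:10], 0.5,
                                        seed = 52)
  a <- threshold_edges(mask_anatomical(cm, adj), 0.3, 0.1)
  b <- threshold_edges(cm, 0.3, 0.1)
  b_kept <- b$edges[adj[cbind(b$edges$region_a, b$edges$region_b)] == 1, ]
  rownames(b_kept) <- NULL
  expect_equal(a$edges, b_kept)
})

test_that("connected pairs separate cleanly in the Welch comparison", {
  set.seed(9)
  regs <- paste0("R", 1:8)
  sr2 <- matrix(0, 8, 8)
  p <- matrix(0.5, 8, 8)
  adj <- matrix(0L, 8, 8, dimnames = list(regs, regs))
  adj[1, 2] <- adj[2, 3] <- adj[3, 4] <- adj[5, 6] <- 1L
  adj <- adj + t(adj)
  r <- matrix(rnorm(64, 0, 0.02), 8, 8)
  r[adj == 1] <- 0.9 + rnorm(sum(adj == 1), 0, 0.02)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 1
  cm <- make_corr(regs, sign(r) * r^2, p)
  cm$r <- r
  dimnames(cm$r) <- list(regs, regs)
  res <- compare_connected_unconnected(cm, adj)
  expect_gt(res$t, 10)
  expect_lt(res$p, 1e-4)
  expect_identical(res$n_connected, 4L)
  expect_identical(res$n_unconnected, 24L)

  empty <- adj * 0L
  expect_error(compare_connected_unconnected(cm, empty), "empty")
})
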