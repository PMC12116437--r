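test_that("Holm adjustment reproduces hand-computed step-down values", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.5), 0.5)
  expect_equal(adjust_pvalues(rep(0.01, 5)), rep(0.05, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- adjust_pvalues(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= 0))
    # BH alternative never exceeds Holm
    expect_true(all(adjust_pvalues(p, "bh") <= adj + 1e-12))
  }
})

test_that("Cohen's d matches hand computations and its invariances", {
  expect_equal(cohens_d(c(0, 1, 2), c(-1, 0, 1)), 1)
  expect_equal(cohens_d(c(0, 2), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "two observations")

  set.seed(2)
  a <- rnorm(8); b <- rnorm(9, 1)
  expect_equal(cohens_d(a, b, signed = TRUE),
               -cohens_d(b, a, signed = TRUE))
  expect_equal(cohens_d(3 * a + 2, 3 * b + 2), cohens_d(a, b))
})

test_that("paired Wilcoxon matches the tie-corrected normal approximation", {
  x <- 1:10
  res <- paired_wilcoxon(x + 1, x)
  # all differences equal: maximal |Z| for n = 10 under full ties
  expect_equal(res$Z, 27.5 / sqrt(96.25 - (1000 - 10) / 48))
  expect_lt(res$p, 0.01)

  expect_warning(r0 <- paired_wilcoxon(x, x), "zero")
  expect_true(r0$degenerate)

  set.seed(3)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  r1 <- paired_wilcoxon(a, b)
  perm <- sample(12)
  r2 <- paired_wilcoxon(a[perm], b[perm])
  expect_equal(abs(r1$Z), abs(r2$Z))
  expect_equal(r1$p, r2$p)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(r1$p, ref$p.value)
  expect_error(paired_wilcoxon(1:3, 2:4), "5 pairs")
})

test_that("region model recovers a strong effect with correct direction
           and is invariant to common area rescaling", {
  sim <- generate_study(scenario_single_region(17, lfc = -1.5))
  fit <- fit_region_model(sim$counts)
  expect_identical(fit$df, 1L)
  expect_lt(fit$p, 0.05)
  expect_identical(fit$direction, "CTR_higher")
  expect_lt(abs(fit$estimate + 1.5), 0.8)

  doubled <- sim$counts
  doubled$area_mm2 <- doubled$area_mm2 * 2
  fit2 <- fit_region_model(doubled)
  expect_equal(fit2$chi2, fit$chi2, tolerance = 1e-4)
  expect_equal(fit2$estimate, fit$estimate, tolerance = 1e-4)
})

test_that("degenerate and invalid region fits are flagged", {
  rec <- generate_study(scenario_single_region(5))$counts
  rec$count[rec$group == "VPA"] <- 0L
  expect_warning(fit <- fit_region_model(rec), "all-zero")
  expect_true(fit$degenerate)
  expect_identical(fit$direction, "none")

  two_regions <- rbind(make_records(region = "A"),
                       make_records(region = "B"))
  expect_error(fit_region_model(two_regions), "exactly one region")
})

test_that("single-region network model reduces to the region model", {
  sim <- generate_study(scenario_single_region(23, lfc = -0.5))
  rfit <- fit_region_model(sim$counts)
  nfit <- fit_network_model(sim$counts, label = "solo")
  expect_equal(nfit$chi2, rfit$chi2, tolerance = 1e-5)
  expect_equal(nfit$estimate, rfit$estimate, tolerance = 1e-5)
  expect_identical(nfit$df, 1L)
})

test_that("pooled network model detects a uniform treatment effect", {
  regs <- cfos_regions()[1:6]
  cfg <- study_config(regions = regs,
                      treatment_log_fold_change = setNames(rep(-0.8, 6),
                                                           regs),
                      latent_scale = 0.2, seed = 41)
  sim <- generate_study(cfg)
  fit <- fit_network_model(sim$counts, regions = regs, label = "MRS")
  expect_identical(fit$df, 1L)
  expect_lt(fit$p, 0.05)
  expect_lt(fit$estimate, 0)
  expect_error(fit_network_model(sim$counts, regions = c(regs, "NOPE")),
               "absent")
})

test_that("region scan applies Holm across regions and screens Cohen's d", {
  regs <- cfos_regions()[1:4]
  cfg <- study_config(regions = regs,
                      treatment_log_fold_change = setNames(c(-1.2, 0, 0, 0),
                                                           regs),
                      latent_scale = 0.2, seed = 43)
  sim <- generate_study(cfg)
  scan <- region_scan(sim$counts)
  expect_identical(scan$region, regs)
  expect_true(all(scan$p_adjusted >= scan$p, na.rm = TRUE))
  expect_equal(scan$p_adjusted, adjust_pvalues(scan$p))
  in_band <- !is.na(scan$p) & scan$p > 0.05 & scan$p < 0.1
  expect_identical(is.na(scan$cohens_d), !in_band)
})
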