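test_that("anatomical connectome respects the planted hub and determinism", {
  regs <- c("IPN", "VTA", "LS", "ZI", "ARC")
  adj <- generate_anatomical_connectome(regs, 0.4, planted_hub = "IPN",
                                        seed = 11)
  expect_true(all(adj["IPN", setdiff(regs, "IPN")] == 1L))
  expect_true(all(adj[setdiff(regs, "IPN"), "IPN"] == 1L))
  expect_identical(diag(adj), setNames(rep(0L, 5), regs))
  expect_identical(adj, t(adj))

  a1 <- generate_anatomical_connectome(cfos_regions(), 0.3, seed = 99)
  a2 <- generate_anatomical_connectome(cfos_regions(), 0.3, seed = 99)
  expect_identical(a1, a2)

  expect_error(generate_anatomical_connectome(regs, 0.4,
                                              planted_hub = "NOPE"),
               "planted_hub")
  expect_error(generate_anatomical_connectome(regs, 0), "edge_density")
  expect_error(generate_anatomical_connectome(regs, 1, planted_hub = "IPN"),
               "edge_density")
  # density 0 is allowed when a hub is planted: pure star
  star <- generate_anatomical_connectome(regs, 0, planted_hub = "IPN",
                                         seed = 1)
  expect_identical(sum(star), 8L)
})

test_that("generated studies are reproducible and structurally complete", {
  cfg <- study_config(regions = cfos_regions()[1:6],
                      n_per_group = c(CTR = 5, VPA = 5), n_litters = 6,
                      seed = 123)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$counts, s2$counts)
  # 10 subjects x 6 regions x 2 hemispheres x 2 slides
  expect_identical(nrow(s1$counts), 10L * 6L * 2L * 2L)
  expect_true(all(s1$counts$count >= 0))
  key <- with(s1$counts, paste(subject_id, region, hemisphere, slide_index))
  expect_identical(anyDuplicated(key), 0L)
  # litters never straddle groups (treatment acts on the dam)
  lg <- unique(s1$counts[, c("litter_id", "group")])
  expect_identical(anyDuplicated(lg$litter_id), 0L)

  s3 <- generate_study(study_config(regions = cfos_regions()[1:6],
                                    n_per_group = c(CTR = 5, VPA = 5),
                                    n_litters = 6, seed = 124))
  expect_false(identical(s1$counts$count, s3$counts$count))
  expect_identical(names(s1$counts), names(s3$counts))
})

test_that("noise-free generator matches the closed-form Poisson mean", {
  # litter_sd = 0, infinite dispersion, latent_scale = 0:
  # counts are Poisson with mean exp(baseline) * total area
  cfg <- study_config(regions = "A", n_per_group = c(CTR = 250, VPA = 250),
                      n_litters = 2, region_area = c(A = 0.5),
                      litter_sd = 0, nb_dispersion = Inf, latent_scale = 0,
                      seed = 7)
  sim <- generate_study(cfg)
  totals <- tapply(sim$counts$count, sim$counts$subject_id, sum)
  mu <- exp(log(100)) * (2 * 2 * 0.5)
  se <- sqrt(mu / length(totals))
  expect_lt(abs(mean(totals) - mu), 3 * se)
  # Poisson-like: variance within sampling error of the mean
  expect_lt(var(totals), 1.5 * mu)
})

test_that("finite dispersion produces overdispersion beyond Poisson", {
  cfg <- study_config(regions = "A", n_per_group = c(CTR = 250, VPA = 250),
                      n_litters = 2, region_area = c(A = 0.5),
                      litter_sd = 0, nb_dispersion = 5, latent_scale = 0,
                      seed = 8)
  sim <- generate_study(cfg)
  totals <- tapply(sim$counts$count, sim$counts$subject_id, sum)
  mu <- exp(log(100)) * 2
  # NB variance mu + mu^2/5 = 8200 >> mu
  expect_gt(var(totals), 3 * mu)
  expect_lt(abs(var(totals) / (mu + mu^2 / 5) - 1), 0.5)
})

test_that("latent correlation propagates to density correlations", {
  regs <- c("A", "B")
  lc <- matrix(c(1, 0.95, 0.95, 1), 2, 2, dimnames = list(regs, regs))
  cfg <- study_config(regions = regs, n_per_group = c(CTR = 250, VPA = 250),
                      n_litters = 2,
                      region_area = c(A = 0.5, B = 0.5),
                      litter_sd = 0, nb_dispersion = 50, latent_scale = 1.5,
                      latent_corr = lc, seed = 9)
  sim <- generate_study(cfg)
  dens <- compute_density(sim$counts)
  m <- density_matrix(dens, group = "CTR")
  expect_gt(cor(m[, "A"], m[, "B"]), 0.7)
})

test_that("multinomial hemisphere/slide split conserves subject totals", {
  cfg <- study_config(regions = cfos_regions()[1:4],
                      n_per_group = c(CTR = 4, VPA = 4), n_litters = 4,
                      seed = 21)
  sim <- generate_study(cfg)
  by_rec <- tapply(sim$counts$count,
                   paste(sim$counts$subject_id, sim$counts$region), sum)
  expect_true(all(by_rec == round(by_rec)))
  expect_true(all(by_rec >= 0))
  # hemisphere split is symmetric in expectation
  h <- tapply(sim$counts$count, sim$counts$hemisphere, sum)
  expect_lt(abs(h[["left"]] - h[["right"]]) / sum(h), 0.05)
})

test_that("invalid configurations are rejected with labeled errors", {
  regs <- c("A", "B")
  bad <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(regs, regs))
  expect_error(study_config(regions = regs, latent_corr = bad,
                            region_area = c(A = 1, B = 1),
                            n_per_group = c(CTR = 5, VPA = 5),
                            n_litters = 4, seed = 1),
               "positive semidefinite")
  expect_error(study_config(regions = regs,
                            region_area = c(A = 1, B = 1),
                            n_per_group = c(CTR = 2, VPA = 2),
                            n_litters = 10, seed = 1),
               "litters")
  expect_error(study_config(regions = regs,
                            region_area = c(A = -1, B = 1),
                            n_per_group = c(CTR = 5, VPA = 5),
                            n_litters = 4, seed = 1),
               "area")
  expect_error(study_config(regions = regs,
                            region_area = c(A = 1, B = 1),
                            n_per_group = c(CTR = 5, VPA = 5),
                            n_litters = 4, planted_hub = "Z", seed = 1),
               "planted_hub")
})
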