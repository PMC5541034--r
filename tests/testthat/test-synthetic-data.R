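test_that("config validation names the offending field", {
  expect_error(sim_config(time_points_h = c(0, 2, 2)), "time_points_h")
  expect_error(sim_config(depth_range = c(0, 10)), "depth_range")
  expect_error(sim_config(planted_blocks = list(list(taxa = 1:3, rho = 1))),
               "rho")
  expect_error(sim_config(n_taxa = 4,
                          planted_blocks = list(list(taxa = 3:6, rho = .5))),
               "n_taxa")
  expect_error(sim_config(effect_sizes = list(list(factor = "ph", taxa = 1,
                                                   logfc = 1))),
               "factor")
})

test_that("same config and seed give bit-identical output", {
  cfg <- tiny_config(seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$metadata, b$metadata)
  expect_identical(simulate_enrichment(cfg, noise_sd = 0.01),
                   simulate_enrichment(cfg, noise_sd = 0.01))
  cov1 <- simulate_covariates(cfg, a$truth)
  cov2 <- simulate_covariates(cfg, b$truth)
  expect_identical(cov1, cov2)
  expect_identical(simulate_spectra(cfg, a$truth)$values,
                   simulate_spectra(cfg, b$truth)$values)
})

test_that("counts respect depth_range and the canonical 11,265 depth", {
  cfg <- tiny_config(seed = 5)
  s <- simulate_counts(cfg)
  tot <- rowSums(s$counts)
  expect_true(all(tot >= 800 & tot <= 1200))
  expect_true(all(unclass(s$counts) >= 0))

  cfg2 <- sim_config(n_taxa = 15, depth_range = c(11265, 11265),
                     time_points_h = c(0, 2), n_replicates = 2, seed = 3)
  s2 <- simulate_counts(cfg2)
  expect_true(all(rowSums(s2$counts) == 11265))
})

test_that("planted positive block induces strong latent Spearman correlation", {
  # 2 forage x 2 vitE x 4 reps x 4 times = 64 samples
  cfg <- sim_config(n_taxa = 20, time_points_h = c(0, 2, 4, 8),
                    depth_range = c(1000, 1000),
                    planted_blocks = list(list(taxa = 1:5, rho = 0.9,
                                               sign = "+")),
                    seed = 9)
  s <- simulate_counts(cfg)
  z <- s$truth$latent
  expect_gt(cor(z[, 1], z[, 2], method = "spearman"), 0.5)
})

test_that("planted correlations converge to rho (Monte Carlo, n >= 500)", {
  cfg <- sim_config(n_taxa = 12, n_replicates = 32,
                    time_points_h = c(0, 2, 4, 8),
                    depth_range = c(1000, 1000),
                    planted_blocks = list(
                      list(taxa = 1:3, rho = 0.8, sign = "+"),
                      list(taxa = 4:6, rho = 0.7, sign = "-")),
                    seed = 21)
  s <- simulate_counts(cfg)          # 512 samples
  z <- s$truth$latent
  expect_lt(abs(cor(z[, 1], z[, 2]) - 0.8), 0.1)
  expect_lt(abs(cor(z[, 4], z[, 5]) - (-0.7)), 0.1)
  # sign pattern: taxa 4,6 share loading sign inside the negative block
  expect_lt(abs(cor(z[, 4], z[, 6]) - 0.7), 0.1)
})

test_that("planted edge list matches block structure", {
  cfg <- sim_config(n_taxa = 8,
                    planted_blocks = list(list(taxa = 1:3, rho = .9,
                                               sign = "-")),
                    seed = 1)
  s <- simulate_counts(cfg)
  pe <- s$truth$planted_edges
  expect_equal(nrow(pe), 3)
  # alternating loadings: (1,2) and (2,3) negative, (1,3) positive
  expect_equal(pe$sign[pe$a == "g__Genus001" & pe$b == "g__Genus002"], "-")
  expect_equal(pe$sign[pe$a == "g__Genus001" & pe$b == "g__Genus003"], "+")
})

test_that("enrichment tracks m(t): noiseless products and paper trajectories", {
  cfg <- sim_config(seed = 2)
  enr <- simulate_enrichment(cfg, sab_enrichment = 0.5, noise_sd = 0)
  g1 <- enr[enr$vessel == "GRAm.V1", ]
  g1 <- g1[order(g1$time_h), ]
  # m defaults: GRA (0, .16, .28, .42, ., .61) at 0/2/4/8/24/48 h
  expect_equal(g1$residue_e[g1$time_h == 48], 0.61 * 0.5)
  expect_equal(g1$residue_e[g1$time_h == 0], 0)
  expect_equal(g1$residue_e[g1$time_h %in% c(2, 4, 8)] / 0.5,
               c(0.16, 0.28, 0.42))
  h1 <- enr[enr$vessel == "HAYm.V1", ]
  expect_equal(h1$residue_e[h1$time_h %in% c(2, 4, 8)] / 0.5,
               c(0.09, 0.14, 0.17))
  expect_error(simulate_enrichment(cfg, sab_enrichment = 0), "sab")
  expect_error(simulate_enrichment(cfg, nh3_enrichment = -1), "nh3")
})

test_that("covariates equal baselines at zero coupling/noise; couplings carry sign", {
  cfg <- sim_config(n_taxa = 10, time_points_h = c(0, 2, 4, 8),
                    depth_range = c(1000, 1000), seed = 4)
  s <- simulate_counts(cfg)           # 64 samples
  cov0 <- simulate_covariates(cfg, s$truth, noise_sd = 0)
  cov0b <- simulate_covariates(cfg, s$truth, noise_sd = 0)
  expect_identical(cov0, cov0b)
  # baseline: same time -> same value
  sp <- split(cov0$lactate, s$metadata$time_h[match(cov0$sample_id,
                                                    s$metadata$sample_id)])
  expect_true(all(vapply(sp, function(v) diff(range(v)) < 1e-12, TRUE)))
  covk <- simulate_covariates(cfg, s$truth, noise_sd = 0,
                              couplings = list(list(covariate = "lactate",
                                                    taxon = 3, weight = 1)))
  r <- cor(covk$lactate - cov0$lactate, s$truth$latent[covk$sample_id, 3])
  expect_gt(r, 0.99)
  expect_gt(cor(covk$lactate, s$truth$latent[covk$sample_id, 3]), 0)
})

test_that("spectra: identical under zero effects, forage effect peaks where planted", {
  flat <- list(GRA = list(type = "anchors", t = c(0, 48), m = c(0, 0)),
               HAY = list(type = "anchors", t = c(0, 48), m = c(0, 0)))
  cfg <- sim_config(n_taxa = 5, time_points_h = c(0, 8),
                    colonization_params = flat, seed = 6)
  s <- simulate_counts(cfg)
  sp0 <- simulate_spectra(cfg, s$truth, noise_sd = 0)
  expect_true(all(abs(sp0$values - sp0$values[, 1]) < 1e-12))

  spf <- simulate_spectra(cfg, s$truth, noise_sd = 0,
                          peak_effects = list(list(factor = "forage",
                                                   wavenumber = 1030,
                                                   delta = 0.3)))
  md <- design_md <- s$metadata
  gra <- rowMeans(spf$values[, md$forage == "GRA"])
  hay <- rowMeans(spf$values[, md$forage == "HAY"])
  expect_equal(spf$wavenumber[which.max(gra - hay)], 1030, tolerance = 4)
})

test_that("write_simulation round-trips through the interchange formats", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(n_replicates = 2, seed = 8)
  paths <- write_simulation(cfg, dir)
  expect_true(all(file.exists(paths)))
  ct <- read_counts(paths["counts"])
  sim <- simulate_counts(cfg)
  expect_identical(unclass(ct), unclass(sim$counts))
  spc <- read_spectra(paths["spectra"])
  expect_equal(length(spc$samples), nrow(sim$metadata))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$true_m$GRA, sim$truth$true_m$GRA)
})
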