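test_that("one-factor Euclidean pseudo-F equals classical ANOVA F", {
  y <- 1:6
  md <- two_group_md(3)
  d <- euclid_d(matrix(y, dimnames = list(md$sample_id, NULL)))
  res <- permanova(d, md, "grp", n_perm = 99, seed = 1)
  expect_equal(res$pseudo_F[1], 13.5, tolerance = 1e-10)
  expect_equal(res$pseudo_F[1], anova_F(y, md$grp), tolerance = 1e-10)
})

test_that("pseudo-F equals ANOVA F on random univariate data (oracle sweep)", {
  set.seed(2)
  for (i in 1:25) {
    n_per <- sample(3:6, 1)
    y <- rnorm(2 * n_per, mean = rep(c(0, runif(1, 0, 2)), each = n_per))
    md <- two_group_md(n_per)
    d <- euclid_d(matrix(y, dimnames = list(md$sample_id, NULL)))
    res <- permanova(d, md, "grp", n_perm = 99, seed = i)
    expect_equal(res$pseudo_F[1], anova_F(y, md$grp), tolerance = 1e-8)
  }
})

test_that("permanova agrees with vegan::adonis2 on multivariate data", {
  skip_if_not_installed("vegan")
  set.seed(4)
  X <- matrix(rpois(12 * 6, 20), 12)
  md <- data.frame(sample_id = paste0("S", 1:12),
                   grp = rep(c("A", "B", "C"), each = 4),
                   blk = rep(c("x", "y"), 6), stringsAsFactors = FALSE)
  rownames(X) <- md$sample_id
  d <- bray_curtis(toy_counts(X, samples = md$sample_id))
  res <- permanova(d, md, c("grp", "blk"), n_perm = 199, seed = 1)
  ad <- vegan::adonis2(as.dist(unclass(d)) ~ grp + blk, data = md,
                       permutations = 199, by = "terms")
  expect_equal(res$SS[1:2], ad$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$pseudo_F[1:2], ad$F[1:2], tolerance = 1e-8)
})

test_that("SS additivity and term df bookkeeping", {
  set.seed(6)
  cfg <- tiny_config(n_replicates = 2, seed = 3)
  s <- simulate_counts(cfg)
  d <- bray_curtis(s$counts)
  res <- permanova(d, s$metadata,
                   c("forage", "vitE", "time_h", "forage:vitE"),
                   n_perm = 99, seed = 9)
  k <- nrow(res)
  expect_equal(sum(res$SS[1:(k - 1)]), res$SS[k], tolerance = 1e-9)
  expect_equal(sum(res$df[1:(k - 1)]), res$df[k])
  expect_true(all(res$SS >= -1e-12))
})

test_that("degenerate data (all samples identical) is flagged", {
  X <- matrix(5, 6, 3, dimnames = list(paste0("S", 1:6), NULL))
  d <- euclid_d(X)
  md <- two_group_md(3)
  res <- permanova(d, md, "grp", n_perm = 99, seed = 1)
  expect_true(attr(res, "degenerate"))
})

test_that("exact enumeration p matches Monte-Carlo p within binomial error", {
  set.seed(8)
  y <- c(0.2, 1.4, 0.9, 3.1, 2.7, 3.3)
  md <- two_group_md(3)
  d <- euclid_d(matrix(y, dimnames = list(md$sample_id, NULL)))
  pe <- permanova(d, md, "grp", exact = TRUE)$p_perm[1]
  pm <- permanova(d, md, "grp", n_perm = 999, seed = 5)$p_perm[1]
  expect_lt(abs(pe - pm), 3 * sqrt(pe * (1 - pe) / 999) + 2e-3)
})

test_that("singular designs and exhausted residual df raise errors", {
  md <- two_group_md(3)
  md$dup <- md$grp
  d <- euclid_d(matrix(rnorm(6), dimnames = list(md$sample_id, NULL)))
  expect_error(permanova(d, md, c("grp", "dup"), n_perm = 99), "aliased")
  md$id <- paste0("L", 1:6)
  expect_error(permanova(d, md, "id", n_perm = 99), "residual")
})

test_that("restricted (within-stratum) permutations stay within blocks", {
  p <- make_perms(6, 50, seed = 2, strata = rep(c("a", "b"), each = 3))
  expect_true(all(p[, 1:3] %in% 1:3) && all(p[, 4:6] %in% 4:6))
})

test_that("stratum_effect: whole data set equals one-factor permanova", {
  cfg <- tiny_config(n_replicates = 2, seed = 12)
  s <- simulate_counts(cfg)
  d <- bray_curtis(s$counts)
  a <- stratum_effect(d, s$metadata, "forage", n_perm = 99, seed = 3)
  b <- permanova(d, s$metadata, "forage", n_perm = 99, seed = 3)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_error(stratum_effect(d, s$metadata, "forage",
                              stratum = list(column = "forage", value = "GRA"),
                              n_perm = 99), "levels")
})

test_that("stratum-limited forage effect is detected early, not late", {
  cfg <- sim_config(n_taxa = 25, time_points_h = c(2, 48),
                    depth_range = c(4000, 4000),
                    effect_sizes = list(list(factor = "forage", taxa = 1:6,
                                             logfc = 2.5, times = 2)),
                    seed = 19)
  s <- simulate_counts(cfg)
  d <- bray_curtis(s$counts, normalize = "relative")
  early <- stratum_effect(d, s$metadata, "forage",
                          stratum = list(column = "time_h", value = 2),
                          n_perm = 199, seed = 4)
  late <- stratum_effect(d, s$metadata, "forage",
                         stratum = list(column = "time_h", value = 48),
                         n_perm = 199, seed = 4)
  expect_lt(early$p_perm[1], 0.05)
  expect_gt(late$p_perm[1], 0.05)
})

test_that("cca: indicator basis recovers CA inertia; guards fire", {
  set.seed(21)
  X <- matrix(rpois(6 * 8, 15) + 1L, 6)
  ct <- toy_counts(X)
  # site indicator basis spans the whole site space
  env <- diag(6)[, 1:5]
  colnames(env) <- paste0("e", 1:5)
  res <- cca(ct, env)
  expect_equal(res$constrained_inertia, res$total_inertia, tolerance = 1e-10)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_true(all(res$eigenvalues >= -1e-12))

  env2 <- cbind(a = rnorm(6), b = rnorm(6))
  env2 <- cbind(env2, dup = env2[, "a"])
  expect_error(cca(ct, env2), "collinear")
  expect_error(cca(ct, cbind(cst = rep(1, 6))), "constant")
  expect_error(cca(ct, matrix(rnorm(36), 6)), "more env columns")

  res2 <- cca(ct, env2[, 1:2])
  expect_lte(res2$constrained_inertia, res2$total_inertia + 1e-12)
  # site WA scores are weighted averages of taxon scores
  P <- X / sum(X)
  wa <- diag(1 / rowSums(P)) %*% P %*% res2$taxon_scores
  expect_equal(unname(res2$site_wa), unname(wa), tolerance = 1e-10)
})

test_that("cca matches vegan's eigenvalues and inertia", {
  skip_if_not_installed("vegan")
  set.seed(22)
  X <- matrix(rpois(10 * 12, 10) + 1L, 10)
  env <- data.frame(a = rnorm(10), b = runif(10))
  res <- cca(toy_counts(X), env)
  vg <- vegan::cca(X ~ a + b, data = env)
  expect_equal(res$constrained_inertia, sum(vg$CCA$eig), tolerance = 1e-8)
  expect_equal(unname(res$eigenvalues), unname(vg$CCA$eig), tolerance = 1e-8)
  expect_equal(res$total_inertia, vg$tot.chi, tolerance = 1e-8)
})

test_that("env_significance: generating gradient significant, p floor respected", {
  set.seed(23)
  n <- 16
  grad <- seq(-2, 2, length.out = n)
  lam <- exp(outer(grad, seq(-1.5, 1.5, length.out = 10), function(g, o)
    -(g - o)^2) * 1.5 + 3)
  X <- matrix(rpois(length(lam), lam), n)
  colnames(X) <- paste0("t", 1:10)
  ct <- toy_counts(X)
  env <- data.frame(gradient = grad, junk = rnorm(n))
  res <- env_significance(ct, env, n_perm = 999, seed = 3)
  expect_lte(res$p[res$variable == "gradient"], 0.01)
  expect_gte(min(res$p), 1 / 1000)
  res99 <- env_significance(ct, env, n_perm = 99, seed = 3)
  expect_gte(min(res99$p), 1 / 100)
  expect_error(env_significance(ct, env, n_perm = 20), "n_perm")
})

test_that("pcoa: round trip, simplex, duplicates, guards", {
  set.seed(24)
  X <- matrix(rnorm(14), 7, 2, dimnames = list(paste0("S", 1:7), NULL))
  res <- pcoa(euclid_d(X))
  expect_lt(procrustes_error(X, res$scores[, 1:2]), 1e-8)
  expect_false(res$negative)

  # equidistant points: simplex with equal positive eigenvalues
  m <- matrix(0.5, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  diag(m) <- 0
  r2 <- pcoa(dist_matrix(m))
  pos <- r2$eigenvalues[r2$eigenvalues > 1e-10]
  expect_equal(length(pos), 3)
  expect_lt(diff(range(pos)), 1e-10)

  X2 <- rbind(X, X[1, , drop = FALSE])
  rownames(X2) <- paste0("S", 1:8)
  r3 <- pcoa(euclid_d(X2))
  expect_equal(r3$scores["S8", ], r3$scores["S1", ], tolerance = 1e-8)

  expect_error(pcoa(dist_matrix(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("a", "b"))))), "3")
})

test_that("pcoa agrees with ape::pcoa eigenvalues", {
  set.seed(25)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("S", 1:10), NULL))
  d <- euclid_d(X)
  res <- pcoa(d)
  ref <- ape::pcoa(as.dist(unclass(d)))
  k <- length(ref$values$Eigenvalues)
  expect_equal(res$eigenvalues[1:k], ref$values$Eigenvalues, tolerance = 1e-8)
})
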