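test_that("subsample_gamma collapses when sampling everything", {
  set.seed(111)
  inc <- matrix(rbinom(40, 1, 0.5), 4, 10,
                dimnames = list(paste0("s", 1:4), paste0("sp", 1:10)))
  cm <- toy_cm(inc, habitat = c("forest", "forest", "savannah", "savannah"))
  gs <- subsample_gamma(cm, group_sizes = c(forest = 2, savannah = 2),
                        n_draws = 50, facet = "taxonomic", seed = 1)
  expect_equal(gs$sd, 0)
  expect_equal(gs$min, gs$median)
  expect_equal(gs$max, gs$median)
  expect_equal(gs$median, sum(colSums(inc) > 0))
})

test_that("subsample_gamma matches exhaustive enumeration on 2-choose-1", {
  inc <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0), 2, 4,
                dimnames = list(c("s1", "s2"), paste0("sp", 1:4)))
  cm <- toy_cm(inc, habitat = c("forest", "forest"))
  g <- subsample_gamma(cm, group_sizes = c(forest = 1), n_draws = 400,
                       facet = "taxonomic", seed = 2)
  enum <- unname(sort(rowSums(inc)))  # the only two possible gammas
  expect_equal(g$min, enum[1])
  expect_equal(g$max, enum[2])
  expect_true(g$median %in% c(enum, mean(enum)))
  # seed reproducibility
  g2 <- subsample_gamma(cm, group_sizes = c(forest = 1), n_draws = 400,
                        facet = "taxonomic", seed = 2)
  expect_identical(g$values, g2$values)
  expect_error(subsample_gamma(cm, group_sizes = c(forest = 5), n_draws = 5,
                               facet = "taxonomic"), "requested")
})

test_that("subsampled gamma never exceeds the fully pooled gamma", {
  ds <- simulate_dataset(sim_config(seed = 13))
  phy <- ds$phy
  cm <- ds$cm
  full <- assemblage_diversity(cm, NULL, phy,
                               cm$site_ids[cm$habitat != "farmland"])
  for (facet in c("taxonomic", "phylogenetic")) {
    g <- subsample_gamma(cm, NULL, phy, c(forest = 7, savannah = 8),
                         n_draws = 100, facet = facet, seed = 3)
    ref <- if (facet == "taxonomic") full$richness else full$pd
    expect_lte(g$median, ref)
    expect_lte(g$max, ref)
  }
})

test_that("exact accumulation reproduces the hand case and vegan oracle", {
  # 2 sites, X in both, Y in one: S(1) = 1.5, S(2) = 2
  inc <- matrix(c(1, 1, 1, 0), 2, 2,
                dimnames = list(c("s1", "s2"), c("X", "Y")))
  cm <- toy_cm(inc)
  ac <- accumulation_curve(cm, mode = "exact")
  expect_equal(ac$expected_richness, c(1.5, 2))

  skip_if_not_installed("vegan")
  set.seed(121)
  inc2 <- matrix(rbinom(8 * 15, 1, 0.35), 8, 15,
                 dimnames = list(paste0("s", 1:8), paste0("sp", 1:15)))
  cm2 <- toy_cm(inc2)
  ours <- accumulation_curve(cm2, mode = "exact")$expected_richness
  ref <- vegan::specaccum(inc2, method = "exact")$richness
  expect_equal(ours, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("accumulation curves are monotone, concave, end at pooled richness", {
  set.seed(131)
  for (r in 1:5) {
    inc <- matrix(rbinom(60, 1, runif(1, 0.2, 0.7)), 6, 10,
                  dimnames = list(paste0("s", 1:6), paste0("sp", 1:10)))
    cm <- toy_cm(inc)
    ac <- accumulation_curve(cm, mode = "exact")
    expect_true(all(diff(ac$expected_richness) >= -1e-12))
    expect_true(all(diff(diff(ac$expected_richness)) <= 1e-12))
    expect_equal(ac$expected_richness[6], sum(colSums(inc) > 0))
  }
})

test_that("permutation accumulation converges to the exact curve", {
  set.seed(141)
  inc <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12,
                dimnames = list(paste0("s", 1:8), paste0("sp", 1:12)))
  cm <- toy_cm(inc)
  ex <- accumulation_curve(cm, mode = "exact")
  pm <- accumulation_curve(cm, mode = "permutation", n_perm = 10000,
                           seed = 5)
  expect_lt(max(abs(ex$expected_richness - pm$expected_richness)), 0.05)
  expect_true(all(is.finite(pm$sd)))
})

test_that("elevation filter keeps exactly the sites at or below threshold", {
  inc <- matrix(1, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B")))
  cm <- toy_cm(inc, habitat = rep("forest", 4),
               elevation = c(1800, 2400, 2600, 3000))
  f <- elevation_filter(cm, 2500)
  expect_identical(f$site_ids, c("s1", "s2"))
  expect_identical(elevation_filter(cm, 4000)$site_ids, cm$site_ids)
  expect_error(elevation_filter(cm, 1000), "every site")
  cm_noelev <- toy_cm(inc)
  expect_error(elevation_filter(cm_noelev, 2500), "elevation")
})

test_that("compare_groups reproduces the closed-form Welch t", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  ct <- compare_groups(x, y)
  # Welch: t = -1 / sqrt(2 * var/4), var = 5/3 -> t = -1.095445, df = 6
  expect_equal(ct$t, -1 / sqrt(2 * (5 / 3) / 4), tolerance = 1e-6)
  expect_equal(ct$df, 6, tolerance = 1e-9)
  expect_equal(unname(ct$median), c(2.5, 3.5))
  expect_equal(unname(ct$iqr), c(1.5, 1.5))

  ct0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ct0$t, 0)
  expect_equal(ct0$p, 1)
  sep <- compare_groups(c(1, 1.001, 0.999), c(1001, 1001.001, 1000.999))
  expect_lt(sep$p, 1e-6)
  expect_error(compare_groups(c(1, 1), c(1, 1)), "constant")
  expect_error(compare_groups(1, c(1, 2)), "at least two")
  expect_warning(compare_groups(x, y, values_are_pairwise = TRUE),
                 "not independent")
})

test_that("permutation_contrast detects a clear beta difference", {
  set.seed(151)
  inc <- rbind(matrix(rbinom(5 * 20, 1, 0.3), 5, 20),
               matrix(rep(rbinom(20, 1, 0.7), 5), 5, byrow = TRUE))
  dimnames(inc) <- list(paste0("s", 1:10), paste0("sp", 1:20))
  cm <- toy_cm(inc, habitat = rep(c("forest", "farmland"), each = 5))
  bm <- beta_matrix(cm, "taxonomic")
  groups <- setNames(cm$habitat, cm$site_ids)
  pc <- permutation_contrast(bm, groups, n_perm = 199, seed = 6)
  expect_gt(pc$observed, 0)
  expect_lt(pc$p, 0.05)
})

test_that("facet_correlation matches the closed-form OLS solution", {
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  fc <- facet_correlation(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)   # normal equations
  resid <- y - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(fc$slope, beta[2], tolerance = 1e-10)
  expect_equal(fc$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fc$r_squared, r2, tolerance = 1e-10)

  expect_equal(facet_correlation(x, 2 * x + 1)$r_squared, 1)
  # orthogonal residual construction -> R^2 = 0
  y0 <- c(1, -1, 0, 1, -1); y0 <- y0 - mean(y0)
  y0 <- y0 - x * sum(y0 * (x - mean(x))) / sum((x - mean(x))^2)
  expect_lt(facet_correlation(x, y0)$r_squared, 1e-20)
  expect_error(facet_correlation(rep(1, 5), y), "variance")
})
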