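test_that("yule trees have the requested tips and are seed-deterministic", {
  phy <- simulate_phylogeny(5, seed = 1)
  expect_identical(length(phy$tip.label), 5L)
  expect_true(all(phy$edge.length > 0))
  expect_identical(ape::write.tree(simulate_phylogeny(5, seed = 1)),
                   ape::write.tree(phy))
  expect_false(identical(ape::write.tree(simulate_phylogeny(5, seed = 2)),
                         ape::write.tree(phy)))
  expect_error(simulate_phylogeny(1), "at least 2")
})

test_that("yule total length matches the closed-form expectation", {
  # epochs k = 2..n each add Exp(k b)-distributed time on k lineages:
  # E[L] = (n-1)/b, Var[L] = (n-1)/b^2
  n <- 40; b <- 1; reps <- 200
  L <- vapply(seq_len(reps), function(i)
    sum(simulate_phylogeny(n, b, seed = 5000 + i)$edge.length), 0)
  expect_lt(abs(mean(L) - (n - 1) / b), 3 * sqrt((n - 1) / b^2 / reps))
})

test_that("trait evolution honours kinds, rates, and seeds", {
  phy <- simulate_phylogeny(20, seed = 9)
  schema <- list(list(name = "svl", kind = "continuous", rate = 0, root = 40),
                 list(name = "mh", kind = "categorical",
                      levels = c("a", "b", "c"), rate = 0.5))
  tt <- simulate_traits(phy, schema, seed = 2)
  expect_true(all(tt$data$svl == 40))        # zero-rate limit
  expect_true(all(tt$data$mh %in% c("a", "b", "c")))
  tt2 <- simulate_traits(phy, schema, seed = 2)
  expect_identical(tt2$data, tt$data)
  expect_error(simulate_traits(phy, list(list(name = "x", kind = "fuzzy"))),
               "unknown trait kind")
})

test_that("brownian tip variance scales with tree depth", {
  # contrasts of a BM trait are iid N(0, rate): mean squared PIC ~ rate,
  # and squared PICs are uncorrelated with node height
  phy <- simulate_phylogeny(15, seed = 33)
  rate <- 2
  schema <- list(list(name = "x", kind = "continuous", rate = rate, root = 0))
  msq <- replicate(60, {
    tt <- simulate_traits(phy, schema,
                          seed = sample.int(1e6, 1))
    x <- setNames(tt$data$x, tt$species_ids)
    mean(ape::pic(x, phy)^2)
  })
  # 60 x 13 contrasts: chi-square mean concentrates near the rate
  expect_lt(abs(mean(msq) - rate) / rate, 0.15)
})

test_that("community generator produces the stated habitat structure", {
  cfg <- sim_config(seed = 3)
  ds <- simulate_dataset(cfg)
  expect_identical(length(ds$cm$site_ids), 37L)
  expect_identical(as.vector(table(ds$cm$habitat)[c("forest", "savannah",
                                                    "farmland")]),
                   c(11L, 11L, 15L))
  expect_identical(length(ds$cm$species_ids), 42L)
  expect_length(validate_dataset(ds$cm, ds$tt, ds$phy, ds$grid)$errors, 0)
  expect_identical(length(ds$truth$pools$farmland), 19L)
  expect_identical(length(ds$truth$pools$exclusive), 3L)

  # determinism of the full bundle
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds2$cm$incidence, ds$cm$incidence)
  expect_identical(ds2$grid$incidence, ds$grid$incidence)
  expect_identical(ds2$tt$data, ds$tt$data)
})

test_that("homogenization level h drives farmland structure", {
  phy <- simulate_phylogeny(45, seed = 4)
  # h = 1: every farmland row identical -> all pairwise taxonomic beta 0
  cfg1 <- sim_config(homogenization_h = 1, seed = 5)
  cm1 <- simulate_communities(cfg1, phy, seed = 8)
  farm <- cm1$site_ids[cm1$habitat == "farmland"]
  bm <- beta_matrix(cm1, "taxonomic", sites = farm)
  expect_true(all(bm$b == 0))

  # occupancy 0 empties natural sites (flagged downstream, not an error)
  cfg0 <- sim_config(occupancy_natural = 1e-9, seed = 5)
  cm0 <- simulate_communities(cfg0, phy, seed = 8)
  # windows have width max(1, ...) = 1: minimal, not empty; farmland richer
  expect_gt(mean(rowSums(cm0$incidence[cm0$habitat == "farmland", ])),
            mean(rowSums(cm0$incidence[cm0$habitat == "forest", ])))

  # monotonicity: mean farmland taxonomic beta decreases in h
  meanbeta <- vapply(c(0, 0.5, 1), function(h) {
    v <- vapply(1:15, function(r) {
      cmh <- simulate_communities(sim_config(homogenization_h = h),
                                  phy, seed = 100 + r)
      fs <- cmh$site_ids[cmh$habitat == "farmland"]
      b <- beta_matrix(cmh, "taxonomic", sites = fs)$b
      mean(b[lower.tri(b)], na.rm = TRUE)
    }, 0)
    mean(v)
  }, 0)
  expect_true(all(diff(meanbeta) < 0))
})

test_that("farmland alpha exceeds natural alpha under the defaults", {
  wins <- vapply(1:30, function(r) {
    ds <- simulate_dataset(sim_config(seed = 700 + r))
    a <- rowSums(ds$cm$incidence)
    mean(a[ds$cm$habitat == "farmland"]) >
      mean(a[ds$cm$habitat != "farmland"])
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("grid generator places endemics in the hotspot", {
  cfg <- sim_config(seed = 6)
  phy <- simulate_phylogeny(60, seed = 6)
  g <- simulate_grid(cfg, phy, endemic_species = phy$tip.label[1:20],
                     widespread_species = phy$tip.label[21:30], seed = 10)
  expect_true(all(g$incidence %in% c(0, 1)))
  sizes <- colSums(g$incidence)
  expect_true(all(sizes[phy$tip.label[1:20]] <= 3))
  expect_true(all(sizes[phy$tip.label[21:30]] >= 0.4 * cfg$n_cells - 1))
  # hotspot cells out-complement the rest in nearly all seeds
  hits <- vapply(1:40, function(r) {
    gr <- simulate_grid(cfg, phy, endemic_species = phy$tip.label[1:20],
                        widespread_species = phy$tip.label[21:30],
                        seed = 200 + r)
    comp <- species_complementarity(gr)$comp_s
    hot <- cfg$hotspot_cells
    mean(comp[hot], na.rm = TRUE) > mean(comp[-hot], na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
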