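test_that("cell diversity: richness and PD per cell, oracle-checked", {
  phy <- tiny_tree()
  inc <- rbind(c1 = c(1, 1, 0), c2 = c(0, 1, 1), c3 = c(0, 0, 0))
  colnames(inc) <- c("A", "B", "C")
  g <- grid_assemblage(inc)
  cd <- cell_diversity(g, phy)
  expect_equal(cd$richness, c(2, 2, 0))
  expect_equal(cd$pd[1], 3)                 # {A,B}
  expect_equal(cd$pd[3], 0)                 # empty cell
  # random grids against the path-union oracle
  set.seed(161)
  rphy <- simulate_phylogeny(10, seed = 21)
  rinc <- matrix(rbinom(50, 1, 0.4), 5, 10,
                 dimnames = list(paste0("c", 1:5), rphy$tip.label))
  rg <- grid_assemblage(rinc)
  rcd <- cell_diversity(rg, rphy)
  for (i in 1:5) {
    sp <- rphy$tip.label[rinc[i, ] > 0]
    ref <- if (length(sp)) pd_oracle(rphy, sp) else 0
    expect_equal(rcd$pd[i], ref, tolerance = 1e-12)
  }
  expect_error(cell_diversity(grid_assemblage(
    matrix(1, 1, 1, dimnames = list("c1", "Zed"))), phy), "missing")
})

test_that("species complementarity reproduces the worked example", {
  # c1 = {A,B}, c2 = {B,C}, c3 = {B}
  inc <- rbind(c1 = c(1, 1, 0), c2 = c(0, 1, 1), c3 = c(0, 1, 0))
  colnames(inc) <- c("A", "B", "C")
  sc <- species_complementarity(grid_assemblage(inc))
  expect_equal(sc$we, c(4 / 3, 4 / 3, 1 / 3))
  expect_equal(sc$comp_s, c(2 / 3, 2 / 3, 1 / 3))
  expect_equal(sum(sc$we), 3)   # conservation: total species count

  # forced extremes
  d3 <- diag(3)
  dimnames(d3) <- list(paste0("c", 1:3), paste0("sp", 1:3))
  expect_equal(species_complementarity(grid_assemblage(d3))$comp_s,
               rep(1, 3))
  full <- matrix(1, 4, 5, dimnames = list(paste0("c", 1:4),
                                          paste0("sp", 1:5)))
  expect_equal(species_complementarity(grid_assemblage(full))$comp_s,
               rep(1 / 4, 4))
})

test_that("phylogenetic complementarity reproduces the worked example", {
  phy <- tiny_tree()
  inc <- rbind(c1 = c(1, 1, 0), c2 = c(0, 1, 1))
  colnames(inc) <- c("A", "B", "C")
  pc <- phylo_complementarity(grid_assemblage(inc), phy)
  expect_equal(pc$pe, c(2, 3))
  expect_equal(pc$comp_pd, c(2 / 3, 3 / 4))
  expect_equal(sum(pc$pe), sum(phy$edge.length))   # all edges occupied

  # single cell: pe = pd, comp = 1; identical cells: comp = 1/2
  m1 <- matrix(1, 1, 3, dimnames = list("c1", c("A", "B", "C")))
  pc1 <- phylo_complementarity(grid_assemblage(m1), phy)
  expect_equal(pc1$comp_pd, 1)
  two <- matrix(1, 2, 3, dimnames = list(c("c1", "c2"), c("A", "B", "C")))
  pc2 <- phylo_complementarity(grid_assemblage(two), phy)
  expect_equal(pc2$comp_pd, c(0.5, 0.5))
})

test_that("endemism conservation holds on random and edited grids", {
  set.seed(171)
  for (r in 1:10) {
    phy <- simulate_phylogeny(15, seed = 300 + r)
    inc <- matrix(rbinom(8 * 15, 1, runif(1, 0.2, 0.6)), 8, 15,
                  dimnames = list(paste0("c", 1:8), phy$tip.label))
    g <- grid_assemblage(inc)
    occupied <- sum(colSums(inc) > 0)
    sc <- species_complementarity(g)
    expect_equal(sum(sc$we), occupied, tolerance = 1e-12)
    pc <- phylo_complementarity(g, phy)
    tp <- divfacets:::.tree_paths(phy)
    occ_len <- sum(tp$lengths[unique(unlist(
      tp$paths[phy$tip.label[colSums(inc) > 0]]))])
    expect_equal(sum(pc$pe), occ_len, tolerance = 1e-9)
    ok <- sc$richness > 0
    expect_true(all(sc$comp_s[ok] > 0 & sc$comp_s[ok] <= 1))
    expect_true(all(pc$comp_pd[ok] > 0 & pc$comp_pd[ok] <= 1 + 1e-12))
  }
})

test_that("replace_cells edits exactly the named rows", {
  phy <- tiny_tree()
  inc <- matrix(rbinom(12, 1, 0.5), 4, 3,
                dimnames = list(paste0("c", 1:4), c("A", "B", "C")))
  g <- grid_assemblage(inc)
  g2 <- replace_cells(g, list(c2 = c("A", "C"), c3 = "B"))
  expect_identical(length(g2$cell_ids), length(g$cell_ids))
  expect_equal(unname(g2$incidence["c2", ]), c(1, 0, 1))
  expect_equal(unname(g2$incidence["c3", ]), c(0, 1, 0))
  expect_identical(g2$incidence["c1", ], g$incidence["c1", ])
  expect_identical(g2$incidence["c4", ], g$incidence["c4", ])
  # identity replacement leaves the grid unchanged
  cur <- colnames(inc)[inc["c1", ] > 0]
  g3 <- replace_cells(g, setNames(list(cur), "c1"))
  expect_identical(g3$incidence, g$incidence)
  expect_error(replace_cells(g, list(zz = "A")), "unknown cell")
  expect_error(replace_cells(g, list(c1 = "Qq")), "unknown species")
  # conservation survives the edit
  expect_equal(sum(species_complementarity(g2)$we),
               sum(colSums(g2$incidence) > 0), tolerance = 1e-12)
  # swapping a cell to widespread species weakly lowers its comp_s
  wide <- names(which.max(colSums(g$incidence)))
  before <- species_complementarity(g)$comp_s
  g4 <- replace_cells(g, setNames(list(wide), "c1"))
  after <- species_complementarity(g4)$comp_s
  expect_lte(after[1], max(before[1], 1))
})

test_that("scale_to_max rescales with NaN propagation", {
  expect_equal(scale_to_max(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(scale_to_max(5), 1)
  out <- scale_to_max(c(2, NaN, 4))
  expect_true(is.nan(out[2]))
  expect_equal(out[c(1, 3)], c(0.5, 1))
  expect_error(scale_to_max(c(0, -1)), "positive")
  # cell_table carries scaled columns with max exactly 1
  phy <- simulate_phylogeny(10, seed = 31)
  inc <- matrix(rbinom(40, 1, 0.5), 4, 10,
                dimnames = list(paste0("c", 1:4), phy$tip.label))
  ct <- cell_table(grid_assemblage(inc), phy)
  expect_equal(max(ct$comp_s_scaled, na.rm = TRUE), 1)
  expect_equal(max(ct$pd_scaled, na.rm = TRUE), 1)
})
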