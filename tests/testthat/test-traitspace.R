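test_that("gower distance reproduces the hand-worked mixed-trait case", {
  # svl at the dataset range ends (|20-60|/40 = 1), equal categorical (0),
  # webbing levels 0 vs 2 over observed levels {0,1,2} -> |1-3|/2 = 1
  tt <- trait_table(
    data.frame(svl = c(20, 60, 35), tadpole = c("pond", "pond", "stream"),
               webbing = c(0, 2, 1), row.names = c("A", "B", "C")),
    kinds = c(svl = "continuous", tadpole = "categorical",
              webbing = "ordinal"))
  d <- gower_distance(tt)
  expect_equal(d$d["A", "B"], 2 / 3)
  expect_equal(diag(d$d), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(d$d >= 0 & d$d <= 1))

  # identical rows -> 0; single continuous trait at range ends -> 1
  tt2 <- trait_table(data.frame(svl = c(10, 10, 50),
                                row.names = c("A", "B", "C")),
                     kinds = c(svl = "continuous"))
  d2 <- gower_distance(tt2)
  expect_equal(d2$d["A", "B"], 0)
  expect_equal(d2$d["A", "C"], 1)
})

test_that("gower is invariant to affine rescaling of continuous traits", {
  set.seed(7)
  base <- data.frame(x = rnorm(8), y = rnorm(8),
                     cat = sample(letters[1:3], 8, TRUE))
  rownames(base) <- paste0("s", 1:8)
  kinds <- c(x = "continuous", y = "continuous", cat = "categorical")
  d1 <- gower_distance(trait_table(base, kinds))$d
  resc <- base
  resc$x <- 100 * base$x - 7
  resc$y <- -2 * base$y + 3   # sign flip also preserves |differences|/range
  d2 <- gower_distance(trait_table(resc, kinds))$d
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("gower agrees with cluster::daisy on continuous+categorical data", {
  skip_if_not_installed("cluster")
  set.seed(11)
  df <- data.frame(a = rnorm(12), b = runif(12),
                   c = factor(sample(c("u", "v", "w"), 12, TRUE)))
  rownames(df) <- paste0("s", 1:12)
  tt <- trait_table(data.frame(a = df$a, b = df$b, c = as.character(df$c),
                               row.names = rownames(df)),
                    kinds = c(a = "continuous", b = "continuous",
                              c = "categorical"))
  ours <- gower_distance(tt)$d
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(ours, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("gower handles zero-range traits, missing values, no-overlap pairs", {
  tt <- trait_table(data.frame(svl = c(1, 1, 1), w = c(0, 1, 2),
                               row.names = c("A", "B", "C")),
                    kinds = c(svl = "continuous", w = "continuous"))
  expect_warning(d <- gower_distance(tt), "zero range")
  expect_equal(d$d["A", "C"], 1)

  suppressWarnings(ttm <- trait_table(
    data.frame(x = c(1, NA), y = c(NA, 2), row.names = c("A", "B")),
    kinds = c(x = "continuous", y = "continuous")))
  expect_error(gower_distance(ttm), "share no recorded traits")
})

test_that("nmds recovers embeddable configurations with ~0 stress", {
  set.seed(21)
  X <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(dist(X))
  rownames(d) <- colnames(d) <- paste0("p", 1:10)
  ts <- nmds_embed(d, k = 3, n_starts = 20, seed = 5)
  expect_lt(ts$stress, 0.01)
  # regular simplex: 4 points, all dissimilarities equal, exact in 3-D
  ds <- matrix(1, 4, 4); diag(ds) <- 0
  dimnames(ds) <- list(paste0("q", 1:4), paste0("q", 1:4))
  expect_warning(ts2 <- nmds_embed(ds, k = 3, n_starts = 5, seed = 5),
                 "dissimilarities equal")
  expect_lt(ts2$stress, 1e-3)
  expect_error(nmds_embed(ds[1:3, 1:3], k = 3), "n > k")
})

test_that("reported stress equals independent recomputation and the oracle", {
  set.seed(31)
  tt <- trait_table(as.data.frame(matrix(rnorm(36), 12, 3),
                                  row.names = paste0("s", 1:12)),
                    kinds = c(V1 = "continuous", V2 = "continuous",
                              V3 = "continuous"))
  g <- gower_distance(tt)
  ts <- nmds_embed(g, k = 3, n_starts = 6, seed = 9)
  expect_equal(ts$stress, stress1(ts$coords, g), tolerance = 1e-10)

  # exhaustive-partition PAVA oracle on a 5-point case
  set.seed(41)
  Y <- matrix(rnorm(15), 5, 3)
  dref <- as.matrix(dist(matrix(rnorm(15), 5, 3)))
  expect_equal(stress1(Y, dref), stress1_oracle(Y, dref), tolerance = 1e-10)

  # exact rank preservation -> 0; collapsed configuration -> 1
  Z <- matrix(rnorm(15), 5, 3)
  expect_equal(stress1(Z, as.matrix(dist(Z))), 0, tolerance = 1e-12)
  expect_equal(stress1(matrix(0, 5, 3), dref), 1)
})

test_that("stress never increases across starts' accepted iterations", {
  # final stress must not exceed the stress of the PCoA initial config
  set.seed(51)
  d <- as.matrix(dist(matrix(rnorm(48), 16, 3))) + matrix(runif(256, 0, .2),
                                                          16, 16)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("p", 1:16), paste0("p", 1:16))
  init <- cmdscale(d, k = 3)
  ts <- nmds_embed(d, k = 3, n_starts = 4, seed = 3)
  expect_lte(ts$stress, stress1(init, d) + 1e-9)
})

test_that("trait space CSV round-trips coordinates and stress", {
  set.seed(61)
  ts <- make_ts(matrix(rnorm(15), 5, 3))
  ts$stress <- 0.123456789
  f <- tempfile(fileext = ".csv")
  write_traitspace_csv(ts, f)
  ts2 <- read_traitspace_csv(f)
  expect_equal(ts2$coords, ts$coords, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(ts2$stress, ts$stress, tolerance = 1e-9)
})
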