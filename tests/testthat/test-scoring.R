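# Region scores and chromosome encoding.

# atlas whose region r occupies a known set of voxels: labels supplied directly
flat_atlas <- function(labels_vec, shape) {
  label_atlas(array(labels_vec, dim = shape))
}

test_that("the region score formula matches hand calculations", {
  # one region of four voxels with values 0.2, -0.1, 0.4, 0.0
  a <- flat_atlas(c(1, 1, 1, 1, 2, 2, 2, 2), c(8, 1, 1))
  h <- array(c(0.2, -0.1, 0.4, 0.0, 1, 1, 1, 1), dim = c(8, 1, 1))
  sc <- region_scores(h, a)
  expect_equal(sc[1], 0.6 / (4 * 0.4))            # 0.375
  expect_equal(sc[2], 1)                          # constant positive region
  h2 <- array(c(-1, -2, 0, -0.5, 0, 0, 0, 0), dim = c(8, 1, 1))
  expect_equal(region_scores(h2, a), c(0, 0))     # non-positive regions
})

test_that("scores stay in [0,1] on random heatmap/atlas pairs", {
  set.seed(20)
  atlases <- lapply(1:20, function(s) tiny_atlas(c(6L, 6L, 6L), R = 5L, seed = s))
  for (i in 1:1000) {
    a <- atlases[[(i - 1L) %% 20L + 1L]]
    h <- array(rnorm(6^3, mean = runif(1, -1, 1), sd = runif(1, 0.1, 3)),
               dim = c(6, 6, 6))
    sc <- region_scores(h, a)
    if (any(sc < 0) || any(sc > 1)) fail(sprintf("score out of range at i=%d", i))
  }
  succeed()
})

test_that("rank-percentile encoding fills the bands exactly", {
  set.seed(1)
  s10 <- runif(10)
  gA <- encode_chromosome(s10, scheme_A())
  expect_identical(as.integer(table(factor(gA, levels = 0:3))), c(3L, 2L, 2L, 3L))
  gB <- encode_chromosome(s10, scheme_B())
  expect_identical(as.integer(table(factor(gB, levels = 0:3))), c(4L, 2L, 2L, 2L))

  # ties: same occupancies, deterministic by index
  ties <- rep(0.5, 10)
  gt <- encode_chromosome(ties, scheme_A())
  expect_identical(as.integer(table(factor(gt, levels = 0:3))), c(3L, 2L, 2L, 3L))
  expect_identical(gt, c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
  expect_identical(gt, encode_chromosome(ties, scheme_A()))

  # band occupancies for R = 7 and R = 96 (hand-derived from the rank rule)
  g7 <- encode_chromosome(runif(7), scheme_A())
  expect_identical(as.integer(table(factor(g7, levels = 0:3))), c(2L, 1L, 1L, 3L))
  g96 <- encode_chromosome(runif(96), scheme_A())
  expect_identical(as.integer(table(factor(g96, levels = 0:3))),
                   c(28L, 20L, 19L, 29L))
  g96B <- encode_chromosome(runif(96), scheme_B())
  expect_identical(as.integer(table(factor(g96B, levels = 0:3))),
                   c(38L, 19L, 19L, 20L))
})

test_that("encoding is monotone in the score", {
  set.seed(33)
  for (rep in 1:25) {
    s <- rnorm(sample(5:40, 1))
    g <- encode_chromosome(s, if (rep %% 2) scheme_A() else scheme_B())
    o <- order(s)
    expect_true(all(diff(g[o]) >= 0))
  }
})

test_that("heatmap populations preserve order, cardinality and dominance", {
  a <- tiny_atlas(c(8L, 8L, 8L), R = 6L, seed = 2L)
  set.seed(9)
  hms <- lapply(1:7, function(i) array(rnorm(8^3), dim = c(8, 8, 8)))
  pop <- heatmaps_to_population(hms, a, scheme_A())
  expect_length(pop, 7L)
  expect_identical(pop[[3]],
                   encode_chromosome(region_scores(hms[[3]], a), scheme_A()))
  pop2 <- heatmaps_to_population(list(hms[[1]], hms[[1]]), a, scheme_A())
  expect_identical(pop2[[1]], pop2[[2]])
  expect_error(heatmaps_to_population(list(), a, scheme_A()), "heatmap")

  # a constant-positive region scores 1; regions with internal spread score
  # lower, so the uniform region encodes to the top gene
  h <- array(runif(8^3, 0.05, 0.95), dim = c(8, 8, 8))
  h[a$labels == 4L] <- 0.9
  sc <- region_scores(h, a)
  expect_identical(sc[4], 1)
  expect_true(all(sc[-4] < 1))
  g <- encode_chromosome(sc, scheme_A())
  expect_identical(g[4], 3L)
})

test_that("invalid binning schemes are rejected", {
  expect_error(binning_scheme(c(50, 30, 70)), "ascending")
  expect_error(binning_scheme(c(0, 50, 70)), "ascending|\\(0,100\\)")
  expect_error(binning_scheme(c(30, 50)), "3")
})
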