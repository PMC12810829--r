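# Genetic algorithm mechanics: fitness arithmetic, selection, variation
# operators, pruning, the generational loop and run intersection.

fixed_f1 <- function(f1) function(mask, ch) list(f1 = f1, counts = NULL)

test_that("fitness combines accuracy and compactness as specified", {
  a96 <- tiny_atlas(c(6L, 6L, 6L), R = 96L, seed = 2L)
  cfg <- ga_config()

  ch1 <- c(3L, rep(0L, 95))
  r1 <- ga_fitness(ch1, fixed_f1(1), a96, cfg = cfg)
  expect_equal(r1$fitness, 1.0, tolerance = 1e-9)

  ch11 <- c(rep(2L, 11), rep(0L, 85))
  r11 <- ga_fitness(ch11, fixed_f1(0.85), a96, cfg = cfg)
  expect_equal(r11$fitness, 0.975 * 0.85 + 0.025 / 11, tolerance = 1e-9)
  expect_equal(r11$fitness, 0.8310227, tolerance = 1e-6)

  ch96 <- rep(2L, 96)
  r96 <- ga_fitness(ch96, fixed_f1(0), a96, cfg = cfg)
  expect_equal(r96$fitness, 0.025 / 96, tolerance = 1e-9)
  expect_equal(r96$fitness, 2.604167e-4, tolerance = 1e-6)

  lit <- ga_config(literal_weights = TRUE)
  rl <- ga_fitness(ch11, fixed_f1(0.85), a96, cfg = lit)
  expect_equal(rl$fitness, 0.025 * 0.85 + 0.975 / 11, tolerance = 1e-9)

  expect_error(ga_fitness(rep(0L, 96), fixed_f1(1), a96, cfg = cfg), "all-zero")
  expect_error(ga_config(alpha = 0.1, beta = 0.5), "alpha")
})

test_that("fitness peaks at one perfect region and decreases with region count", {
  a <- tiny_atlas(c(6L, 6L, 6L), R = 8L, seed = 3L)
  cfg <- ga_config()
  fits <- sapply(1:8, function(n) {
    ga_fitness(c(rep(2L, n), rep(0L, 8L - n)), fixed_f1(1), a, cfg = cfg)$fitness
  })
  expect_equal(fits[1], 1)
  expect_true(all(diff(fits) < 0))
})

test_that("roulette frequencies follow fitness proportions", {
  expect_identical(unique(roulette_select(c(5), 50L)), 1L)
  set.seed(41)
  draws <- roulette_select(c(1, 3), 100000L)
  p2 <- mean(draws == 2L)
  expect_lt(abs(p2 - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
  draws4 <- roulette_select(rep(2, 4), 40000L)
  freq <- as.numeric(table(factor(draws4, levels = 1:4))) / 40000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 4e4)))
  expect_error(roulette_select(c(0.5, 0), 1L), "positive")
})

test_that("crossover offspring are exact prefix/suffix concatenations", {
  set.seed(7)
  a <- rep(3L, 96)
  b <- rep(1L, 96)
  seen <- integer(0)
  for (i in 1:3000) {
    off <- ga_crossover(a, b)
    n3 <- sum(off == 3L)
    # prefix of 3s then suffix of 1s, never interleaved
    expect_identical(off, c(rep(3L, n3), rep(1L, 96 - n3)))
    seen <- union(seen, n3)
  }
  expect_setequal(seen, 1:96)    # every cut point attainable, n = R included
  x <- sample(0:3, 12, replace = TRUE)
  expect_identical(ga_crossover(x, x), x)
  expect_error(ga_crossover(x, x[1:5]), "length")
})

test_that("mutation changes at most one gene, uniformly", {
  set.seed(8)
  ch <- sample(0:3, 30, replace = TRUE)
  expect_identical(ga_mutate(ch, pm = 0), ch)
  for (i in 1:200) {
    out <- ga_mutate(ch, pm = 1)
    expect_lte(sum(out != ch), 1L)
  }
  vals <- replicate(40000, ga_mutate(0L, pm = 1))
  freq <- as.numeric(table(factor(vals, levels = 0:3))) / 40000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 4e4)))
})

test_that("pruning freezes consensus-inactive regions", {
  pop <- list(c(1L, 0L, 2L, 0L), c(0L, 0L, 3L, 0L), c(2L, 0L, 0L, 0L))
  pr <- prune_initial_regions(pop, theta = 0.5)
  # region 2: zero everywhere -> frozen; region 4: zero everywhere -> frozen;
  # region 1: zero in 1/3 -> active; region 3: zero in 1/3 -> active
  expect_identical(pr$frozen, c(2L, 4L))
  expect_identical(pr$active, c(1L, 3L))
  expect_equal(pr$active_count, 2L)
  expect_true(all(vapply(pr$population, function(ch) all(ch[c(2, 4)] == 0L), logical(1))))

  # unanimity: theta = 1 keeps any region nonzero somewhere
  pr1 <- prune_initial_regions(pop, theta = 1)
  expect_identical(pr1$frozen, c(2L, 4L))
  expect_error(prune_initial_regions(list(c(0L, 0L)), 0.5), "every region")
})

test_that("the generational loop preserves invariants and terminates", {
  a <- tiny_atlas(c(8L, 8L, 8L), R = 6L, seed = 9L)
  set.seed(10)
  pop <- replicate(8, sample(0:3, 6, replace = TRUE), simplify = FALSE)
  pop <- lapply(pop, function(ch) { if (all(ch == 0L)) ch[1] <- 2L; ch })
  ev <- function(mask, ch) list(f1 = mean(ch[1:2] > 0L), counts = NULL)

  # huge stop_tol: exactly one generation beyond initialization
  res0 <- run_ga(pop, ev, a, ga_config(stop_tol = 10, seed = 1L))
  expect_equal(res0$generations, 1L)
  expect_equal(nrow(res0$trajectory), 2L)

  res <- run_ga(pop, ev, a, ga_config(max_generations = 30L, stop_tol = -Inf,
                                      seed = 5L))
  expect_equal(res$generations, 30L)
  expect_length(res$population, 8L)                       # constant size
  expect_true(all(vapply(res$population, function(ch)
    length(ch) == 6L && all(ch %in% 0:3) && any(ch > 0L), logical(1))))
  expect_true(all(diff(res$trajectory$best_fitness) >= -1e-12))  # elitism
  expect_identical(res$best_chromosome,
                   res$population[[which.max(vapply(res$population, function(ch)
                     ga_fitness(ch, ev, a, cfg = ga_config())$fitness, numeric(1)))]])

  # reproducibility
  res2 <- run_ga(pop, ev, a, ga_config(max_generations = 30L, stop_tol = -Inf,
                                       seed = 5L))
  expect_identical(res$best_chromosome, res2$best_chromosome)
  expect_identical(res$trajectory, res2$trajectory)

  # frozen regions never reactivate
  resf <- run_ga(pop, ev, a, ga_config(max_generations = 20L, stop_tol = -Inf,
                                       seed = 3L), frozen = c(5L, 6L))
  expect_true(all(vapply(resf$population, function(ch) all(ch[5:6] == 0L), logical(1))))
  expect_equal(resf$initial_active_regions, 4L)
})

test_that("population_cap subsamples or pads to a fixed size", {
  a <- tiny_atlas(c(8L, 8L, 8L), R = 5L, seed = 12L)
  set.seed(2)
  pop <- replicate(10, pmax(sample(0:3, 5, replace = TRUE), c(1L, 0L, 0L, 0L, 0L)),
                   simplify = FALSE)
  ev <- fixed_f1(0.9)
  down <- run_ga(pop, ev, a, ga_config(max_generations = 2L, stop_tol = -Inf,
                                       population_cap = 4L, seed = 1L))
  expect_length(down$population, 4L)
  up <- run_ga(pop[1:3], ev, a, ga_config(max_generations = 2L, stop_tol = -Inf,
                                          population_cap = 6L, seed = 1L))
  expect_length(up$population, 6L)
})

test_that("run intersection is exact set arithmetic", {
  mk <- function(sel, R = 24L) {
    ch <- rep(0L, R)
    ch[sel] <- 2L
    structure(list(best_chromosome = ch, atlas_R = R), class = "gashap_ga_result")
  }
  expect_identical(intersect_runs(mk(c(4, 9, 11)), mk(c(9, 11, 20))), c(9L, 11L))
  expect_identical(intersect_runs(mk(c(2, 5)), mk(c(2, 5))), c(2L, 5L))
  expect_identical(intersect_runs(mk(1:3), mk(10:12)), integer(0))
  expect_error(intersect_runs(mk(1:3), mk(1:3, R = 30L)), "atlas")
})
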