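# Genetic algorithm over region chromosomes: attribution-initialized
# population, fitness combining masked classification accuracy with an
# inverse-region-count compactness term, roulette or tournament selection,
# single-point crossover, single-gene mutation, elitism, mean-fitness
# termination, and per-generation trajectory logging.

#' Genetic algorithm configuration
#'
#' Defaults follow the reference configuration: compactness weight
#' `alpha = 0.025`, accuracy weight `beta = 0.975` (`alpha + beta = 1`),
#' crossover probability 0.4 per mating, mutation probability 0.6 per
#' offspring, at most 500 generations, termination when the improvement in
#' mean fitness between consecutive generations stays below `stop_tol = 0.001`
#' for `stop_window` consecutive generations (default 1, the literal
#' one-comparison rule; longer windows make the plateau test robust to the
#' small per-generation gains of the compactness term), roulette selection,
#' elitism 1.
#'
#' `literal_weights = TRUE` pairs `alpha` with accuracy and `beta` with the
#' compactness term instead (the printed form of the fitness equation); the
#' default pairing follows the stated semantics that the large weight
#' emphasizes accuracy.
#'
#' @param alpha Weight on the inverse-region-count term.
#' @param beta Weight on the masked-accuracy term.
#' @param pc Crossover probability per mating.
#' @param pm Mutation probability per offspring.
#' @param max_generations Generation cap.
#' @param population_cap Optional fixed population size (subsample or pad by
#'   mutation); `NULL` keeps one individual per initializing heatmap.
#' @param stop_tol Mean-fitness improvement threshold.
#' @param stop_window Consecutive below-threshold generations required to stop.
#' @param selection `"roulette"` or `"tournament"` (size 2).
#' @param elitism Number of best individuals copied unchanged each generation.
#' @param literal_weights Use the printed weight pairing (see above).
#' @param seed Integer RNG seed for the whole run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(alpha = 0.025, beta = 0.975, pc = 0.4, pm = 0.6,
                      max_generations = 500L, population_cap = NULL,
                      stop_tol = 0.001, stop_window = 1L,
                      selection = c("roulette", "tournament"), elitism = 1L,
                      literal_weights = FALSE, seed = 1L) {
  selection <- match.arg(selection)
  if (abs(alpha + beta - 1) > 1e-9) stop_format("alpha + beta must equal 1")
  if (pc < 0 || pc > 1 || pm < 0 || pm > 1) stop_format("pc and pm must be in [0,1]")
  structure(list(alpha = alpha, beta = beta, pc = pc, pm = pm,
                 max_generations = as.integer(max_generations),
                 population_cap = population_cap, stop_tol = stop_tol,
                 stop_window = as.integer(stop_window), selection = selection,
                 elitism = as.integer(elitism),
                 literal_weights = isTRUE(literal_weights),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Evaluators for the GA fitness accuracy term
#'
#' `classifier_evaluator()` scores a mask by masked classification accuracy of
#' `clf` on the given volumes (the train split during evolution).
#' `oracle_evaluator()` is a ground-truth surrogate for recovery experiments:
#' accuracy 1 exactly when every required region has a nonzero gene, else 0.
#'
#' @param clf A classifier accepted by [masked_accuracy()].
#' @param volumes,classes Evaluation volumes and labels.
#' @param fill Mask fill value.
#' @return A function `(mask, chromosome) -> list(f1, counts)`.
#' @export
classifier_evaluator <- function(clf, volumes, classes, fill = 0) {
  function(mask, chromosome) masked_accuracy(clf, volumes, classes, mask, fill)
}

#' @rdname classifier_evaluator
#' @param required_regions Region indices that must all be selected.
#' @export
oracle_evaluator <- function(required_regions) {
  required_regions <- as.integer(required_regions)
  function(mask, chromosome) {
    list(f1 = as.numeric(all(chromosome[required_regions] > 0L)), counts = NULL)
  }
}

#' Fitness of a chromosome
#'
#' Builds the mask, evaluates the masked accuracy `f1`, computes
#' `f2 = 1 / (number of nonzero genes)` and combines them as
#' `beta * f1 + alpha * f2` (or the literal pairing when configured). The
#' maximum value 1 is attained at `f1 = 1` with a single selected region.
#'
#' @param ch Chromosome (nonzero somewhere; all-zero individuals are invalid
#'   since the compactness term is undefined).
#' @param evaluator A function from [classifier_evaluator()] /
#'   [oracle_evaluator()].
#' @param atlas A [label_atlas()].
#' @param se A [structuring_element()].
#' @param cfg A [ga_config()].
#' @return List with `f1`, `f2`, `fitness`, `n_regions`, `counts`.
#' @export
ga_fitness <- function(ch, evaluator, atlas, se = structuring_element(),
                       cfg = ga_config()) {
  ch <- check_chromosome(ch, atlas$R)
  n_regions <- sum(ch > 0L)
  if (n_regions == 0L)
    stop_format("all-zero chromosome is invalid (compactness term undefined)")
  mask <- build_mask(ch, atlas, se)
  ev <- evaluator(mask, ch)
  f1 <- ev$f1
  f2 <- 1 / n_regions
  fit <- if (cfg$literal_weights) cfg$alpha * f1 + cfg$beta * f2
         else cfg$beta * f1 + cfg$alpha * f2
  list(f1 = f1, f2 = f2, fitness = fit, n_regions = n_regions,
       counts = ev$counts)
}

#' Roulette-wheel parent selection
#'
#' Draws an index with probability proportional to fitness.
#'
#' @param fitnesses Positive fitness values.
#' @param n Number of draws.
#' @return Integer indices (length `n`).
#' @export
roulette_select <- function(fitnesses, n = 1L) {
  if (any(fitnesses <= 0) || sum(fitnesses) <= 0)
    stop_format("roulette selection requires positive fitness values")
  sample.int(length(fitnesses), n, replace = TRUE, prob = fitnesses)
}

tournament_select <- function(fitnesses, n = 1L, k = 2L) {
  vapply(seq_len(n), function(i) {
    cand <- sample.int(length(fitnesses), k, replace = FALSE)
    cand[which.max(fitnesses[cand])]
  }, integer(1))
}

#' Single-point crossover
#'
#' Draws `n` uniformly from `1..R` and concatenates the first `n` genes of `a`
#' with the remaining genes of `b`.
#'
#' @param a,b Parent chromosomes of equal length.
#' @return Offspring chromosome.
#' @export
ga_crossover <- function(a, b) {
  if (length(a) != length(b)) stop_format("parents must have equal length")
  R <- length(a)
  n <- sample.int(R, 1L)
  if (n == R) a else c(a[seq_len(n)], b[(n + 1L):R])
}

#' Single-gene mutation
#'
#' With probability `pm` one uniformly chosen gene is replaced by a uniform
#' draw from `{0,1,2,3}`; otherwise the chromosome is returned unchanged. The
#' output differs from the input in at most one position.
#'
#' @param ch Chromosome.
#' @param pm Per-individual mutation probability.
#' @return Mutated chromosome.
#' @export
ga_mutate <- function(ch, pm = 0.6) {
  if (pm > 0 && stats::runif(1) < pm) {
    g <- sample.int(length(ch), 1L)
    ch[g] <- sample(0:3, 1L)
  }
  ch
}

#' Freeze consensus-inactive regions before the run
#'
#' A region whose gene is 0 in at least fraction `theta` of the initial
#' chromosomes is frozen at 0 for the whole run (its gene is zeroed in every
#' chromosome and mutation may not reactivate it).
#'
#' @param population List of chromosomes.
#' @param theta Consensus fraction in `(0, 1]`.
#' @return List with `population` (genes of frozen regions zeroed), `frozen`
#'   (region indices), `active` (region indices), `active_count`.
#' @export
prune_initial_regions <- function(population, theta = 0.5) {
  if (theta <= 0 || theta > 1) stop_format("theta must be in (0,1]")
  mat <- do.call(rbind, population)
  frac_zero <- colMeans(mat == 0L)
  frozen <- which(frac_zero >= theta)
  active <- setdiff(seq_len(ncol(mat)), frozen)
  if (length(active) == 0L) stop_format("pruning would freeze every region")
  population <- lapply(population, function(ch) {
    ch[frozen] <- 0L
    ch
  })
  list(population = population, frozen = frozen, active = active,
       active_count = length(active))
}

repair_chromosome <- function(ch, frozen) {
  ch[frozen] <- 0L
  if (all(ch == 0L)) {
    free <- setdiff(seq_along(ch), frozen)
    ch[free[sample.int(length(free), 1L)]] <- sample(1:3, 1L)
  }
  ch
}

#' Run the genetic algorithm
#'
#' Generational loop with constant population size: evaluate, select parents
#' (roulette by default), cross over with probability `pc` (otherwise copy the
#' selected parent), mutate with probability `pm`, carry the best `elitism`
#' individuals unchanged. Stops at `max_generations` or when the mean-fitness
#' improvement stays below `stop_tol` for `stop_window` consecutive
#' generations. Fitness evaluations are memoized per chromosome. Fully
#' reproducible for a fixed seed.
#'
#' @param population Nonempty list of valid chromosomes (e.g. from
#'   [heatmaps_to_population()], optionally pruned by
#'   [prune_initial_regions()]).
#' @param evaluator Accuracy evaluator (see [classifier_evaluator()]).
#' @param atlas A [label_atlas()].
#' @param cfg A [ga_config()].
#' @param se A [structuring_element()].
#' @param frozen Region indices kept at gene 0 for the whole run.
#' @param test_evaluator Optional second evaluator logged per generation for
#'   reporting (never used in selection).
#' @return An object of class `gashap_ga_result`.
#' @export
run_ga <- function(population, evaluator, atlas, cfg = ga_config(),
                   se = structuring_element(), frozen = integer(0),
                   test_evaluator = NULL) {
  if (length(population) == 0L) stop_format("population is empty")
  population <- lapply(population, check_chromosome, R = atlas$R)
  cache <- new.env(parent = emptyenv())
  eval_memo <- function(ch) {
    key <- paste(ch, collapse = "")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- ga_fitness(ch, evaluator, atlas, se, cfg)
      cache[[key]] <- got
    }
    got
  }
  traj <- list()
  with_seed(cfg$seed, {
    # optional resizing to a fixed population size
    if (!is.null(cfg$population_cap)) {
      cap <- as.integer(cfg$population_cap)
      if (length(population) > cap) {
        population <- population[sample.int(length(population), cap)]
      } else while (length(population) < cap) {
        donor <- population[[sample.int(length(population), 1L)]]
        population[[length(population) + 1L]] <-
          repair_chromosome(ga_mutate(donor, 1), frozen)
      }
    }
    population <- lapply(population, repair_chromosome, frozen = frozen)
    pop_size <- length(population)
    recs <- lapply(population, eval_memo)
    mean_prev <- mean(vapply(recs, `[[`, numeric(1), "fitness"))
    below <- 0L
    gen <- 0L
    log_gen <- function(gen, recs, population) {
      fit <- vapply(recs, `[[`, numeric(1), "fitness")
      b <- which.max(fit)
      f1_test <- if (is.null(test_evaluator)) NA_real_ else {
        mask <- build_mask(population[[b]], atlas, se)
        test_evaluator(mask, population[[b]])$f1
      }
      data.frame(generation = gen, best_fitness = fit[b], mean_fitness = mean(fit),
                 best_f1_train = recs[[b]]$f1, best_f1_test = f1_test,
                 n_regions_best = recs[[b]]$n_regions)
    }
    traj[[1L]] <- log_gen(0L, recs, population)
    while (gen < cfg$max_generations) {
      gen <- gen + 1L
      fit <- vapply(recs, `[[`, numeric(1), "fitness")
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(min(cfg$elitism, pop_size))]
      nextpop <- population[elite_idx]
      while (length(nextpop) < pop_size) {
        if (cfg$selection == "roulette") {
          pa <- roulette_select(fit, 1L)
        } else {
          pa <- tournament_select(fit, 1L)
        }
        if (stats::runif(1) < cfg$pc) {
          pb <- if (cfg$selection == "roulette") roulette_select(fit, 1L)
                else tournament_select(fit, 1L)
          child <- ga_crossover(population[[pa]], population[[pb]])
        } else {
          child <- population[[pa]]
        }
        child <- repair_chromosome(ga_mutate(child, cfg$pm), frozen)
        nextpop[[length(nextpop) + 1L]] <- child
      }
      population <- nextpop
      recs <- lapply(population, eval_memo)
      traj[[gen + 1L]] <- log_gen(gen, recs, population)
      mean_cur <- traj[[gen + 1L]]$mean_fitness
      if (mean_cur - mean_prev < cfg$stop_tol) below <- below + 1L else below <- 0L
      mean_prev <- mean_cur
      if (below >= cfg$stop_window) break
    }
  })
  trajectory <- do.call(rbind, traj)
  fit <- vapply(recs, `[[`, numeric(1), "fitness")
  b <- which.max(fit)
  best_ch <- population[[b]]
  structure(list(best_chromosome = best_ch,
                 best_record = recs[[b]],
                 best_mask = build_mask(best_ch, atlas, se),
                 trajectory = trajectory,
                 population = population,
                 initial_active_regions = atlas$R - length(frozen),
                 frozen = frozen,
                 generations = gen,
                 atlas_R = atlas$R,
                 atlas_names = atlas$names$name,
                 config = cfg),
            class = "gashap_ga_result")
}

#' @export
print.gashap_ga_result <- function(x, ...) {
  cat(sprintf("<gashap_ga_result> %d generations, best fitness %.5f (f1 = %.3f, %d regions of %d active)\n",
              x$generations, x$best_record$fitness, x$best_record$f1,
              x$best_record$n_regions, x$initial_active_regions))
  invisible(x)
}

#' @export
summary.gashap_ga_result <- function(object, ...) {
  print(object)
  sel <- which(object$best_chromosome > 0L)
  cat("selected regions:\n")
  print(data.frame(region = sel, gene = object$best_chromosome[sel],
                   importance = gene_labels(object$best_chromosome[sel]),
                   name = object$atlas_names[sel]))
  invisible(object)
}

#' Trajectory plots for a GA run
#'
#' Three panels: best/mean fitness, best train (and test, if logged) accuracy,
#' and the region count of the best individual, per generation.
#'
#' @param x A `gashap_ga_result`.
#' @param ... Unused.
#' @export
plot.gashap_ga_result <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$generation, tr$best_fitness, type = "l", col = "firebrick",
                 xlab = "generation", ylab = "fitness", main = "fitness",
                 ylim = range(c(tr$best_fitness, tr$mean_fitness)))
  graphics::lines(tr$generation, tr$mean_fitness, col = "grey40", lty = 2)
  graphics::legend("bottomright", c("best", "mean"), lty = c(1, 2),
                   col = c("firebrick", "grey40"), bty = "n")
  ylim <- range(c(tr$best_f1_train, tr$best_f1_test), na.rm = TRUE)
  graphics::plot(tr$generation, tr$best_f1_train, type = "l", col = "navy",
                 xlab = "generation", ylab = "accuracy", main = "masked accuracy",
                 ylim = ylim)
  if (any(is.finite(tr$best_f1_test)))
    graphics::lines(tr$generation, tr$best_f1_test, col = "darkorange")
  graphics::plot(tr$generation, tr$n_regions_best, type = "s", col = "forestgreen",
                 xlab = "generation", ylab = "regions", main = "selected regions")
  invisible(x)
}

#' Intersect the selected-region sets of two GA runs
#'
#' @param a,b `gashap_ga_result` objects from the same atlas.
#' @return Sorted integer vector of region indices nonzero in both best
#'   chromosomes.
#' @export
intersect_runs <- function(a, b) {
  if (a$atlas_R != b$atlas_R) stop_format("runs used different atlases")
  sort(intersect(which(a$best_chromosome > 0L), which(b$best_chromosome > 0L)))
}

#' Write a GA trajectory as delimited text
#'
#' @param res A `gashap_ga_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(res, path) {
  utils::write.table(res$trajectory, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
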