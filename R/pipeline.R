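# One-command orchestration: data -> classifier -> heatmaps -> per-scheme
# (encode -> prune -> GA) -> intersection -> summary. Every artifact lands in
# the run directory; re-running with one config and seed reproduces the run.

#' Pipeline configuration
#'
#' Desk-scale defaults throughout: the synthetic cohort of [synthetic_spec()],
#' the default [cnn_spec()] at 24^3, 40-epoch training, gradient-times-input
#' heatmaps, both binning schemes, and a GA capped at 12 generations with
#' population 24 and tournament selection (the compactness term moves mean
#' fitness by ~1e-4 per generation, so fitness-proportional selection is
#' nearly neutral at this scale).
#'
#' @param out_dir Run directory (created on demand).
#' @param synthetic A [synthetic_spec()], or `NULL` when `manifest` is given.
#' @param manifest,atlas_path Optional paths to a cohort manifest and atlas
#'   NIfTI for preprocessed real volumes.
#' @param names_path Optional atlas names table.
#' @param cnn A [cnn_spec()]; `NULL` derives one from the data shape.
#' @param train A [train_config()].
#' @param backend Heatmap backend for [compute_heatmap()].
#' @param backend_params Backend parameter list.
#' @param schemes Named list of [binning_scheme()]s (default A and B).
#' @param ga A [ga_config()].
#' @param prune_theta Consensus threshold for [prune_initial_regions()].
#' @param se A [structuring_element()].
#' @param seed Global seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = synthetic_spec(),
                            manifest = NULL, atlas_path = NULL,
                            names_path = NULL,
                            cnn = NULL,
                            train = train_config(),
                            backend = "grad_input",
                            backend_params = list(),
                            schemes = list(A = scheme_A(), B = scheme_B()),
                            ga = ga_config(selection = "tournament",
                                           max_generations = 12L,
                                           population_cap = 24L,
                                           stop_window = 25L),
                            prune_theta = 0.5,
                            se = structuring_element(),
                            seed = 1L) {
  if (length(schemes) == 0L) stop_format("at least one binning scheme is required")
  if (is.null(synthetic) && is.null(manifest))
    stop_format("either a synthetic spec or a data manifest is required")
  structure(list(out_dir = out_dir, synthetic = synthetic, manifest = manifest,
                 atlas_path = atlas_path, names_path = names_path, cnn = cnn,
                 train = train, backend = backend,
                 backend_params = backend_params, schemes = schemes, ga = ga,
                 prune_theta = prune_theta, se = se, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys override the defaults of [pipeline_config()]; nested sections
#' `synthetic`, `train`, `ga`, `cnn` are passed to the respective
#' constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("out_dir", "manifest", "atlas_path", "names_path", "backend",
               "prune_theta", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$synthetic)) args$synthetic <- do.call(synthetic_spec, y$synthetic)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$ga)) args$ga <- do.call(ga_config, y$ga)
  if (!is.null(y$cnn)) args$cnn <- do.call(cnn_spec, y$cnn)
  if (!is.null(y$schemes)) {
    args$schemes <- lapply(y$schemes, function(b) binning_scheme(unlist(b)))
  }
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Stages: load or generate the cohort and atlas; train the CNN; compute one
#' heatmap per training volume; per binning scheme encode the population,
#' freeze consensus-inactive regions and run the GA; intersect the
#' per-scheme selected-region sets; write all artifacts (cohort, atlas,
#' checkpoint, history, heatmaps, score tables, trajectories, masks,
#' intersection and a JSON summary) under `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisible list: `classifier`, `runs` (per scheme), `intersection`,
#'   `summary`, `dir`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_format("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("stage data")
  if (!is.null(cfg$manifest)) {
    ds <- stage("data", read_cohort(cfg$manifest))
    atlas <- stage("data", read_atlas(cfg$atlas_path, cfg$names_path))
    signal <- NULL
  } else {
    sp <- cfg$synthetic
    sp$seed <- cfg$seed
    atlas <- stage("data", generate_atlas(sp))
    ds <- stage("data", generate_cohort(atlas, sp))
    signal <- sp$signal_regions
    write_atlas(atlas, file.path(cfg$out_dir, "atlas.nii.gz"),
                file.path(cfg$out_dir, "atlas_names.tsv"))
    write_cohort(ds, file.path(cfg$out_dir, "cohort"))
    write_signal_regions(sp, file.path(cfg$out_dir, "signal_regions.tsv"))
  }
  check_same_shape(ds$volumes[[1]], atlas$labels, "volumes and atlas")

  say("stage train")
  # desk-scale default: 3^3 first kernel (the full-scale default is 5^3)
  spec <- if (is.null(cfg$cnn)) {
    cnn_spec(input_shape = ds$shape,
             conv_blocks = list(c(3L, 8L), c(3L, 16L), c(3L, 32L)))
  } else cfg$cnn
  tcfg <- cfg$train
  tcfg$seed <- cfg$seed + 1L
  clf <- stage("train", {
    model <- build_model(spec, seed = cfg$seed + 1L)
    train_cnn(model, ds, tcfg)
  })
  utils::write.table(clf$history, file.path(cfg$out_dir, "train_history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  saveRDS(clf, file.path(cfg$out_dir, "classifier.rds"))
  te <- dataset_split(ds, "test")
  va <- dataset_split(ds, "val")
  val_acc <- mean(predict(clf, va$volumes, type = "class") == va$classes)
  test_acc <- mean(predict(clf, te$volumes, type = "class") == te$classes)
  say("  val acc %.3f, test acc %.3f", val_acc, test_acc)

  say("stage explain")
  params <- cfg$backend_params
  if (cfg$backend == "region_shapley" && is.null(params$atlas)) params$atlas <- atlas
  heatmaps <- stage("explain", cohort_heatmaps(clf, ds, split = "train",
                                               backend = cfg$backend,
                                               params = params))
  hm_dir <- file.path(cfg$out_dir, "heatmaps")
  dir.create(hm_dir, showWarnings = FALSE)
  for (i in seq_along(heatmaps)) {
    write_heatmap(heatmaps[[i]], file.path(hm_dir, sprintf("heatmap_%03d.nii.gz", i)))
  }

  tr <- dataset_split(ds, "train")
  evaluator <- classifier_evaluator(clf, tr$volumes, tr$classes)
  test_eval <- classifier_evaluator(clf, te$volumes, te$classes)
  runs <- list()
  for (si in seq_along(cfg$schemes)) {
    nm <- names(cfg$schemes)[si]
    say("stage evolve (scheme %s)", nm)
    runs[[nm]] <- stage(paste0("evolve-", nm), {
      pop <- heatmaps_to_population(heatmaps, atlas, cfg$schemes[[si]])
      pr <- prune_initial_regions(pop, cfg$prune_theta)
      gcfg <- cfg$ga
      gcfg$seed <- cfg$seed + 10L + si
      run_ga(pr$population, evaluator, atlas, gcfg, cfg$se,
             frozen = pr$frozen, test_evaluator = test_eval)
    })
    scores1 <- region_scores(heatmaps[[1]], atlas)
    utils::write.table(score_table(scores1, runs[[nm]]$best_chromosome, atlas),
                       file.path(cfg$out_dir, sprintf("scores_%s.tsv", nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_trajectory(runs[[nm]], file.path(cfg$out_dir, sprintf("trajectory_%s.tsv", nm)))
    write_mask(runs[[nm]]$best_mask, file.path(cfg$out_dir, sprintf("mask_%s.nii.gz", nm)),
               atlas)
  }

  intersection <- if (length(runs) >= 2L) {
    Reduce(function(a, b) sort(intersect(a, b)),
           lapply(runs, function(r) which(r$best_chromosome > 0L)))
  } else which(runs[[1]]$best_chromosome > 0L)
  utils::write.table(
    data.frame(region = intersection, name = atlas$names$name[intersection]),
    file.path(cfg$out_dir, "intersection.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)

  summary <- list(
    seed = cfg$seed,
    n_volumes = length(ds$volumes),
    atlas_R = atlas$R,
    val_acc = val_acc,
    test_acc = test_acc,
    schemes = lapply(runs, function(r) list(
      best_fitness = r$best_record$fitness,
      best_f1_train = r$best_record$f1,
      n_regions = r$best_record$n_regions,
      initial_active_regions = r$initial_active_regions,
      generations = r$generations,
      selected_regions = which(r$best_chromosome > 0L))),
    intersection = intersection,
    signal_regions = signal)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(classifier = clf, dataset = ds, atlas = atlas,
                 heatmaps = heatmaps, runs = runs,
                 intersection = intersection, summary = summary,
                 dir = cfg$out_dir))
}

#' Generate report tables and plots from a completed run directory
#'
#' Emits, per scheme, the selected-region table (region, name, gene,
#' importance label, morphological operation; omitted regions excluded) and a
#' PDF of the fitness/accuracy/region-count trajectories.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return Invisible list of report file paths.
#' @export
make_report <- function(run_dir) {
  summary_path <- file.path(run_dir, "summary.json")
  if (!file.exists(summary_path))
    stop_format("incomplete run directory: missing %s", summary_path)
  schemes <- names(jsonlite::read_json(summary_path)$schemes)
  out <- list()
  for (nm in schemes) {
    prov <- file.path(run_dir, sprintf("mask_%s_provenance.tsv", nm))
    traj <- file.path(run_dir, sprintf("trajectory_%s.tsv", nm))
    missing <- c(prov, traj)[!file.exists(c(prov, traj))]
    if (length(missing))
      stop_format("incomplete run directory: missing %s",
                  paste(missing, collapse = ", "))
    tab <- utils::read.table(prov, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    tab <- tab[tab$gene > 0L, , drop = FALSE]
    rp <- file.path(run_dir, sprintf("report_regions_%s.tsv", nm))
    utils::write.table(tab, rp, sep = "\t", row.names = FALSE, quote = FALSE)
    out[[paste0("regions_", nm)]] <- rp

    tr <- utils::read.table(traj, sep = "\t", header = TRUE)
    pdf_path <- file.path(run_dir, sprintf("trajectory_%s.pdf", nm))
    grDevices::pdf(pdf_path, width = 9, height = 3)
    fake <- structure(list(trajectory = tr), class = "gashap_ga_result")
    plot(fake)
    grDevices::dev.off()
    out[[paste0("trajectory_", nm)]] <- pdf_path
  }
  invisible(out)
}
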