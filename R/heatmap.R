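# Voxel heatmap generation for a trained classifier. The default backend is
# gradient-times-input (exact for the in-package models); the Shapley backends
# attribute over cubic blocks or atlas regions and spread each group's value
# uniformly over its voxels; `external` is an adapter contract so a
# third-party deep explainer can supply the voxel map.

#' Construct an attribution heatmap object
#'
#' @param values Signed 3D array of per-voxel attributions.
#' @param target_class Explained class (0-based).
#' @param base_value Model output at the reference input (`phi0`), if known.
#' @param backend Name of the producing backend.
#' @return An object of class `gashap_heatmap`.
#' @export
attribution_heatmap <- function(values, target_class = 1L,
                                base_value = NA_real_, backend = "unknown") {
  if (!(is.array(values) && length(dim(values)) == 3L))
    stop_format("heatmap values must be a 3D array")
  if (!all(is.finite(values))) stop_format("heatmap contains non-finite values")
  structure(list(values = values, target_class = as.integer(target_class),
                 base_value = base_value, backend = backend),
            class = "gashap_heatmap")
}

heatmap_values <- function(h) {
  if (inherits(h, "gashap_heatmap")) h$values else h
}

#' @export
print.gashap_heatmap <- function(x, ...) {
  cat(sprintf("<gashap_heatmap> %s grid, backend %s, class %d, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"), x$backend, x$target_class,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Compute a voxel attribution heatmap
#'
#' Backends:
#' * `grad_input` (default): gradient of the target-class logit times the
#'   input, voxel-resolved.
#' * `block_shapley`: permutation-sampled Shapley values over cubic blocks
#'   (side `params$block`, default 4); each voxel receives its block's value
#'   divided by the block voxel count.
#' * `region_shapley`: Shapley over atlas regions (`params$atlas` required),
#'   exact when `R <= params$exact_max` (default 12), sampled otherwise,
#'   likewise spread over voxels.
#' * `external`: `params$fn(clf, v, target_class)` must return a 3D array.
#'
#' The explained class defaults to the classifier's prediction for `v`; the
#' Shapley reference input is the all-zeros volume (the mean of standardized
#' data) unless `params$reference` is given.
#'
#' @param clf A trained classifier (`cnn_classifier` or
#'   [template_classifier()]).
#' @param v Volume to explain.
#' @param backend One of `"grad_input"`, `"block_shapley"`,
#'   `"region_shapley"`, `"external"`.
#' @param target_class Explained class; `NULL` means the predicted class.
#' @param params Backend parameter list (see above; `n_permutations`, `seed`
#'   for the sampled backends).
#' @return A [attribution_heatmap()].
#' @export
compute_heatmap <- function(clf, v, backend = c("grad_input", "block_shapley",
                                                "region_shapley", "external"),
                            target_class = NULL, params = list()) {
  backend <- match.arg(backend)
  if (is.null(target_class)) {
    target_class <- predict(clf, list(v), type = "class")[1]
  }
  reference <- params$reference
  if (is.null(reference)) reference <- array(0, dim = dim(v))
  if (backend == "grad_input") {
    g <- input_gradient(clf, v, target_class)
    return(attribution_heatmap(g * v, target_class, base_value = NA_real_, backend = backend))
  }
  if (backend == "external") {
    if (!is.function(params$fn)) stop_format("external backend needs params$fn")
    vals <- params$fn(clf, v, target_class)
    if (!(is.array(vals) && identical(dim(vals), dim(v))))
      stop_format("external backend must return an array of the input shape")
    return(attribution_heatmap(vals, target_class, backend = backend))
  }
  model_fn <- classifier_margin_fn(clf, target_class)
  if (backend == "block_shapley") {
    block <- if (is.null(params$block)) 4L else as.integer(params$block)
    grouping <- grouping_blocks(dim(v), block)
  } else {
    if (is.null(params$atlas)) stop_format("region_shapley backend needs params$atlas")
    check_same_shape(v, params$atlas$labels, "volume and atlas")
    grouping <- grouping_from_atlas(params$atlas)
  }
  exact_max <- if (is.null(params$exact_max)) 12L else params$exact_max
  if (grouping$M <= exact_max) {
    sr <- exact_shapley(model_fn, v, reference, grouping)
  } else {
    n_perm <- if (is.null(params$n_permutations)) 100L else params$n_permutations
    seed <- if (is.null(params$seed)) 1L else params$seed
    sr <- sampled_shapley(model_fn, v, reference, grouping, n_perm, seed)
  }
  vals <- array(0, dim = dim(v))
  for (g in seq_len(grouping$M)) {
    idx <- grouping$index[[g]]
    vals[idx] <- sr$phi[g] / length(idx)
  }
  attribution_heatmap(vals, target_class, base_value = sr$phi0, backend = backend)
}

#' Heatmaps for a set of volumes
#'
#' One heatmap per volume (by default the training split of a dataset — each
#' image contributes one heatmap to the initial population). The
#' `correct_only` flag restricts to correctly classified volumes.
#'
#' @param clf Trained classifier.
#' @param dataset A [labeled_dataset()].
#' @param split Which split(s) to explain.
#' @param correct_only Keep only correctly classified volumes.
#' @inheritParams compute_heatmap
#' @return List of heatmaps.
#' @export
cohort_heatmaps <- function(clf, dataset, split = "train",
                            backend = "grad_input", correct_only = FALSE,
                            params = list()) {
  sub <- dataset_split(dataset, split)
  vols <- sub$volumes
  if (correct_only) {
    pred <- predict(clf, vols, type = "class")
    vols <- vols[pred == sub$classes]
    if (length(vols) == 0L) stop_format("no correctly classified volumes in split")
  }
  lapply(vols, function(v) compute_heatmap(clf, v, backend, params = params))
}

#' Write a heatmap as NIfTI
#'
#' @param h A [attribution_heatmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(h, path) {
  write_volume(h$values, path)
}
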