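# Synthetic phantom cohort: a Voronoi-parcellated cube and a two-class cohort
# in which class 1 carries an additive mean shift confined to a known subset of
# regions. Stands in for an access-controlled imaging cohort so every
# downstream stage (attribution, encoding, GA) is testable against planted
# ground truth.

#' Specification of a synthetic parcellated cohort
#'
#' Defaults are the package's desk-scale study conditions: a 24^3 grid with 20
#' Voronoi regions, 4 of which carry an additive class effect of 0.6 intensity
#' units against unit-variance Gaussian noise, 30 samples per class.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param R Number of atlas regions.
#' @param signal_regions Region indices (in `1..R`) carrying the class effect.
#' @param effect_size Additive mean shift inside signal regions (intensity
#'   units, pre-normalization).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_per_class Samples per class.
#' @param seed RNG seed; the full cohort is bit-reproducible given the seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(24L, 24L, 24L), R = 20L,
                           signal_regions = 1:4, effect_size = 0.6,
                           noise_sd = 1.0, n_per_class = 30L, seed = 1L) {
  shape <- as.integer(shape)
  R <- as.integer(R)
  if (length(shape) != 3L || any(shape < 1L)) stop_format("shape must be 3 positive integers")
  if (R < 1L || R > prod(shape)) stop_format("R must be in [1, number of voxels]")
  signal_regions <- sort(unique(as.integer(signal_regions)))
  if (length(signal_regions) == 0L || any(signal_regions < 1L | signal_regions > R))
    stop_format("signal_regions must be a nonempty subset of 1..R")
  if (effect_size <= 0) stop_format("effect_size must be > 0")
  if (noise_sd <= 0) stop_format("noise_sd must be > 0")
  structure(list(shape = shape, R = R, signal_regions = signal_regions,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_per_class = as.integer(n_per_class), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a Voronoi parcellation atlas
#'
#' Draws `R` distinct seed voxels uniformly and labels every voxel with its
#' nearest seed (Euclidean distance on voxel indices, ties to the lower region
#' index), yielding `R` nonempty irregular regions covering the grid.
#'
#' @param spec A [synthetic_spec()].
#' @return A [label_atlas()].
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  shape <- spec$shape
  nvox <- prod(shape)
  coords <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                  z = seq_len(shape[3])))
  with_seed(spec$seed, {
    seeds <- sample.int(nvox, spec$R)
  })
  sc <- coords[seeds, , drop = FALSE]
  # nearest seed per voxel; ties resolved toward the smaller region index
  best_d <- rep(Inf, nvox)
  lab <- integer(nvox)
  for (r in seq_len(spec$R)) {
    d <- (coords[, 1] - sc[r, 1])^2 + (coords[, 2] - sc[r, 2])^2 +
      (coords[, 3] - sc[r, 3])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    lab[upd] <- r
  }
  label_atlas(array(lab, dim = shape))
}

#' Generate a two-class synthetic cohort on an atlas
#'
#' Class-0 volumes are pure Gaussian noise; class-1 volumes additionally carry
#' `effect_size` inside the union of the planted signal regions. Each volume
#' is then standardized to zero mean / unit variance (signal injection happens
#' before normalization, as raw scans carry pathology before intensity
#' standardization), and the cohort is split 70/15/15 with class balance.
#'
#' @param atlas A [label_atlas()] whose grid matches `spec$shape`.
#' @param spec A [synthetic_spec()].
#' @param fractions Split fractions passed to [split_dataset()].
#' @return A [labeled_dataset()] with attribute `signal_regions`.
#' @export
generate_cohort <- function(atlas, spec, fractions = c(0.7, 0.15, 0.15)) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(spec, "synthetic_spec"))
  if (!identical(dim(atlas$labels), spec$shape))
    stop_format("atlas shape does not match spec shape")
  signal <- atlas$labels %in% spec$signal_regions
  dim(signal) <- spec$shape
  n <- 2L * spec$n_per_class
  classes <- rep(c(0L, 1L), each = spec$n_per_class)
  vols <- vector("list", n)
  with_seed(spec$seed + 1L, {
    for (i in seq_len(n)) {
      v <- array(stats::rnorm(prod(spec$shape), sd = spec$noise_sd),
                 dim = spec$shape)
      if (classes[i] == 1L) v[signal] <- v[signal] + spec$effect_size
      vols[[i]] <- normalize_volume(v)
    }
  })
  ds <- split_dataset(vols, classes, fractions, seed = spec$seed + 2L)
  attr(ds, "signal_regions") <- spec$signal_regions
  ds
}

#' Write the ground-truth signal region list
#'
#' @param spec A [synthetic_spec()].
#' @param path Output path (tab-delimited: region index per line).
#' @return `path`, invisibly.
#' @export
write_signal_regions <- function(spec, path) {
  utils::write.table(data.frame(region = spec$signal_regions), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
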