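# Shared in-code fixtures: tiny atlases, cohorts and toy attribution games.

# Deterministic small Voronoi atlas.
tiny_atlas <- function(shape = c(12L, 12L, 12L), R = 6L, seed = 1L) {
  generate_atlas(synthetic_spec(shape = shape, R = R,
                                signal_regions = seq_len(min(2L, R)),
                                n_per_class = 4L, seed = seed))
}

# Small synthetic cohort + its atlas.
tiny_cohort <- function(shape = c(12L, 12L, 12L), R = 6L, signal = 1:2,
                        effect = 3, n = 8L, seed = 1L) {
  sp <- synthetic_spec(shape = shape, R = R, signal_regions = signal,
                       effect_size = effect, noise_sd = 1, n_per_class = n,
                       seed = seed)
  atlas <- generate_atlas(sp)
  list(spec = sp, atlas = atlas, cohort = generate_cohort(atlas, sp))
}

# Single-voxel-per-group grouping on a 1D-ish grid: M groups, fast model evals.
line_grouping <- function(M) grouping_blocks(c(M, 1L, 1L), 1L)

# Random linear-plus-interactions game over group means; returns the model
# function together with everything needed for independent checks.
random_game <- function(M, seed, interactions = TRUE) {
  set.seed(seed)
  g <- line_grouping(M)
  w <- stats::rnorm(M)
  pairs <- if (interactions && M >= 2) {
    t(utils::combn(M, 2))[sample(choose(M, 2), min(3, choose(M, 2))), , drop = FALSE]
  } else NULL
  pw <- if (is.null(pairs)) NULL else stats::rnorm(nrow(pairs))
  fn <- function(v) {
    gm <- as.numeric(v)[seq_len(M)]
    out <- sum(w * gm)
    if (!is.null(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        out <- out + pw[k] * gm[pairs[k, 1]] * gm[pairs[k, 2]]
      }
    }
    out
  }
  x <- array(stats::rnorm(M), dim = c(M, 1, 1))
  list(fn = fn, x = x, ref = array(0, dim = c(M, 1, 1)), grouping = g, w = w)
}

# Manually constructed linear template classifier (no fitting).
manual_template <- function(w, b = 0) {
  structure(list(w = w, b = b, shape = dim(w)), class = "template_classifier")
}
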