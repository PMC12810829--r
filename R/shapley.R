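# Shapley-value attribution over voxel groupings.
#
# A grouping partitions the voxels of a volume into M groups (atlas regions or
# cubic blocks). The cooperative game evaluates the model on hybrid inputs in
# which in-coalition groups take their values from the explained volume x and
# all other groups from a reference volume. exact_shapley enumerates all 2^M
# coalitions with the factorial weights; sampled_shapley is the standard
# permutation estimator (unbiased, deterministic for a fixed seed).

#' Partition voxels into attribution groups
#'
#' `grouping_from_atlas()` uses the atlas regions (background voxels are
#' excluded from the explained support). `grouping_blocks()` tiles the grid
#' with cubic blocks of side `block`; partial blocks at the boundary are kept.
#'
#' @param atlas A [label_atlas()].
#' @return An object of class `feature_grouping`: list with `index` (list of
#'   voxel index vectors, one per group) and `M`.
#' @export
grouping_from_atlas <- function(atlas) {
  idx <- split(which(atlas$labels > 0L), atlas$labels[atlas$labels > 0L])
  structure(list(index = unname(idx), M = length(idx), shape = dim(atlas$labels)),
            class = "feature_grouping")
}

#' @rdname grouping_from_atlas
#' @param shape Grid dimensions.
#' @param block Cubic block side length (default 4).
#' @export
grouping_blocks <- function(shape, block = 4L) {
  shape <- as.integer(shape)
  block <- as.integer(block)
  if (block < 1L) stop_format("block side must be >= 1")
  bx <- (seq_len(shape[1]) - 1L) %/% block
  by <- (seq_len(shape[2]) - 1L) %/% block
  bz <- (seq_len(shape[3]) - 1L) %/% block
  nbx <- max(bx) + 1L
  nby <- max(by) + 1L
  g <- outer(outer(bx, by * nbx, "+"), bz * nbx * nby, "+") + 1L
  idx <- split(seq_len(prod(shape)), as.vector(g))
  structure(list(index = unname(idx), M = length(idx), shape = shape),
            class = "feature_grouping")
}

#' @export
print.feature_grouping <- function(x, ...) {
  cat(sprintf("<feature_grouping> M = %d groups over a %s grid\n", x$M,
              paste(x$shape, collapse = "x")))
  invisible(x)
}

# Value function: model output on the hybrid input where groups in `coal`
# (logical length M) come from x, the rest from reference.
coalition_value <- function(model_fn, x, reference, grouping, coal) {
  z <- reference
  for (g in which(coal)) z[grouping$index[[g]]] <- x[grouping$index[[g]]]
  model_fn(z)
}

#' Exact Shapley values by coalition enumeration
#'
#' Enumerates all `2^M` coalitions and combines marginal contributions with
#' the factorial weights `|S|! (M-|S|-1)! / M!`. Refuses `M > 20`.
#'
#' @param model_fn Function mapping a 3D array to a scalar model output.
#' @param x Explained volume.
#' @param reference Reference (background) volume; out-of-coalition groups take
#'   their voxel values from it.
#' @param grouping A [grouping_from_atlas()] / [grouping_blocks()] partition.
#' @return An object of class `shapley_result`: `phi` (length M), `phi0` (the
#'   model output at the reference), `grouping`, `full_value`.
#' @export
exact_shapley <- function(model_fn, x, reference, grouping) {
  M <- grouping$M
  if (M > 20L)
    stop_format("exact enumeration needs 2^M evaluations; M = %d > 20 — use sampled_shapley", M)
  nc <- bitwShiftL(1L, M)
  vals <- numeric(nc)
  members <- lapply(seq_len(nc) - 1L, function(s) {
    as.logical(bitwAnd(bitwShiftR(s, 0:(M - 1L)), 1L))
  })
  for (s in seq_len(nc)) {
    vals[s] <- coalition_value(model_fn, x, reference, grouping, members[[s]])
  }
  lf <- lfactorial(0:M)
  lM <- lfactorial(M)
  phi <- numeric(M)
  sizes <- vapply(members, sum, integer(1))
  for (i in seq_len(M)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(seq_len(nc) - 1L, bit) == 0L)
    s <- sizes[without]
    w <- exp(lf[s + 1L] + lf[M - s] - lM)
    phi[i] <- sum(w * (vals[without + bit] - vals[without]))
  }
  structure(list(phi = phi, phi0 = vals[1L], grouping = grouping,
                 full_value = vals[nc]),
            class = "shapley_result")
}

#' Permutation-sampling Shapley estimate
#'
#' Averages marginal contributions over `n_permutations` uniformly random
#' orderings, walking each permutation incrementally from the reference input.
#' Unbiased for the exact values; deterministic given `seed`.
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of sampled orderings (>= 1).
#' @param seed Integer RNG seed.
#' @return A `shapley_result` (with `phi0` the reference output).
#' @export
sampled_shapley <- function(model_fn, x, reference, grouping,
                            n_permutations = 200L, seed = 1L) {
  M <- grouping$M
  if (n_permutations < 1L) stop_format("n_permutations must be >= 1")
  phi <- numeric(M)
  base <- model_fn(reference)
  idx <- grouping$index
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(M)
      z <- reference
      prev <- base
      for (g in ord) {
        z[idx[[g]]] <- x[idx[[g]]]
        cur <- model_fn(z)
        phi[g] <- phi[g] + (cur - prev)
        prev <- cur
      }
    }
  })
  structure(list(phi = phi / n_permutations, phi0 = base, grouping = grouping,
                 full_value = NA_real_),
            class = "shapley_result")
}

#' @export
print.shapley_result <- function(x, ...) {
  cat(sprintf("<shapley_result> M = %d groups, phi0 = %.6g\n", x$grouping$M, x$phi0))
  print(round(x$phi, 6))
  invisible(x)
}

#' Check the consistency (monotonicity) axiom for one group
#'
#' Verifies by full enumeration that model `model_fprime` has marginal
#' contributions for group `i` dominating those of `model_f` on every
#' coalition (the premise), then checks that the Shapley value of `i` under
#' `model_fprime` is at least that under `model_f`. Errors if the premise
#' fails, since the axiom is then silent.
#'
#' @inheritParams exact_shapley
#' @param model_f,model_fprime Two models sharing the grouping.
#' @param i Group index to check.
#' @param tol Numeric slack for premise and conclusion comparisons.
#' @return `TRUE` if the conclusion holds (always, when the premise holds).
#' @export
check_consistency <- function(model_f, model_fprime, x, reference, grouping, i,
                              tol = 1e-9) {
  M <- grouping$M
  if (M > 20L) stop_format("premise verification requires M <= 20")
  nc <- bitwShiftL(1L, M)
  bit <- bitwShiftL(1L, i - 1L)
  for (s in seq_len(nc) - 1L) {
    if (bitwAnd(s, bit) == 0L) next
    coal <- as.logical(bitwAnd(bitwShiftR(s, 0:(M - 1L)), 1L))
    coal_noi <- coal
    coal_noi[i] <- FALSE
    d_f <- coalition_value(model_f, x, reference, grouping, coal) -
      coalition_value(model_f, x, reference, grouping, coal_noi)
    d_fp <- coalition_value(model_fprime, x, reference, grouping, coal) -
      coalition_value(model_fprime, x, reference, grouping, coal_noi)
    if (d_fp < d_f - tol)
      stop_format("consistency premise fails for group %d on a coalition", i)
  }
  phi_f <- exact_shapley(model_f, x, reference, grouping)$phi[i]
  phi_fp <- exact_shapley(model_fprime, x, reference, grouping)$phi[i]
  phi_fp >= phi_f - tol
}
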