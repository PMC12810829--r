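# Collapse a signed voxel heatmap into per-region scores in [0,1] and encode
# them as a length-R chromosome over {0,1,2,3} by rank-percentile binning.
#
# Region score = (sum of strictly positive attribution in the region) /
#                (region voxel count * maximum attribution in the region),
# with score 0 when the region's maximum is non-positive. The score is 1
# exactly when every voxel attains the same positive value, and negative or
# zero attributions never contribute.

check_chromosome <- function(ch, R = NULL) {
  ch <- as.integer(ch)
  if (!all(ch %in% 0:3)) stop_format("genes must be in {0,1,2,3}")
  if (!is.null(R) && length(ch) != R)
    stop_format("chromosome length %d does not match atlas R = %d", length(ch), R)
  ch
}

#' Per-region attribution scores
#'
#' @param h A heatmap ([compute_heatmap()] result) or a signed 3D array of the
#'   atlas shape.
#' @param atlas A [label_atlas()].
#' @return Numeric vector of length `atlas$R`, each score in `[0, 1]`, ordered
#'   by internal region index. Background voxels (label 0) are excluded.
#' @export
region_scores <- function(h, atlas) {
  vals <- heatmap_values(h)
  check_same_shape(vals, atlas$labels, "heatmap and atlas")
  lab <- atlas$labels
  nz <- lab > 0L
  labv <- lab[nz]
  hv <- vals[nz]
  n_r <- tabulate(labv, nbins = atlas$R)
  if (any(n_r == 0L)) stop_format("atlas contains an empty region")
  max_r <- vapply(split(hv, labv), max, numeric(1))
  ok <- max_r > 0
  # normalize by the region maximum before summing so a constant positive
  # region scores exactly 1 in floating point
  denom <- ifelse(ok[labv], max_r[labv], 1)
  scaled <- as.numeric(rowsum((hv / denom) * (hv > 0), labv, reorder = TRUE))
  score <- numeric(atlas$R)
  score[ok] <- scaled[ok] / n_r[ok]
  pmin(pmax(score, 0), 1)
}

#' Percentile binning scheme for score-to-gene encoding
#'
#' Scheme A uses cut points (30, 50, 70); scheme B uses (40, 60, 80). Genes
#' 0,1,2,3 are assigned to successive rank-percentile bands.
#'
#' @param breakpoints Strictly ascending percentiles in (0, 100), length 3.
#' @return An object of class `binning_scheme`.
#' @export
binning_scheme <- function(breakpoints = c(30, 50, 70)) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) != 3L || any(diff(breakpoints) <= 0) ||
      any(breakpoints <= 0 | breakpoints >= 100))
    stop_format("breakpoints must be 3 strictly ascending values in (0,100)")
  structure(list(breakpoints = breakpoints), class = "binning_scheme")
}

#' @rdname binning_scheme
#' @export
scheme_A <- function() binning_scheme(c(30, 50, 70))

#' @rdname binning_scheme
#' @export
scheme_B <- function() binning_scheme(c(40, 60, 80))

#' Encode region scores as a chromosome
#'
#' Regions are ranked ascending by score (ties broken by region index,
#' ascending); the region at 1-based ascending rank `k` of `R` has percentile
#' `p = 100 k / R` and receives gene 0 if `p <= b1`, 1 if `b1 < p <= b2`, 2 if
#' `b2 < p <= b3`, 3 if `p > b3`. The map is monotone: a higher score never
#' yields a lower gene.
#'
#' @param scores Numeric vector of region scores.
#' @param scheme A [binning_scheme()].
#' @return Integer chromosome over `{0,1,2,3}` of the same length.
#' @export
encode_chromosome <- function(scores, scheme = scheme_A()) {
  stopifnot(inherits(scheme, "binning_scheme"))
  R <- length(scores)
  rk <- rank(scores, ties.method = "first")  # ties broken by index order
  p <- 100 * rk / R
  b <- scheme$breakpoints
  genes <- ifelse(p <= b[1], 0L, ifelse(p <= b[2], 1L, ifelse(p <= b[3], 2L, 3L)))
  as.integer(genes)
}

#' Encode a set of heatmaps as an initial population
#'
#' One chromosome per heatmap, order preserved; percentiles are computed
#' per-heatmap over that heatmap's own R scores.
#'
#' @param heatmaps Nonempty list of heatmaps (or 3D arrays).
#' @param atlas A [label_atlas()].
#' @param scheme A [binning_scheme()].
#' @return List of integer chromosomes.
#' @export
heatmaps_to_population <- function(heatmaps, atlas, scheme = scheme_A()) {
  if (length(heatmaps) == 0L) stop_format("need at least one heatmap")
  lapply(heatmaps, function(h) encode_chromosome(region_scores(h, atlas), scheme))
}

#' Export region scores and genes as a table
#'
#' @param scores Region score vector.
#' @param ch Chromosome encoded from `scores`.
#' @param atlas A [label_atlas()].
#' @return Data frame (region, orig_id, name, score, gene, importance).
#' @export
score_table <- function(scores, ch, atlas) {
  data.frame(region = seq_len(atlas$R), orig_id = atlas$names$orig_id,
             name = atlas$names$name, score = scores, gene = ch,
             importance = gene_labels(ch), stringsAsFactors = FALSE)
}
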