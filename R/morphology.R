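# 3D binary morphology on region supports, and chromosome -> mask decoding.
# Erosion/dilation are implemented by vectorized array shifts over the
# structuring-element neighbourhood; voxels outside the grid count as
# background (zero-fill, no wraparound).

#' Structuring element for 3D binary morphology
#'
#' @param connectivity 6 (face neighbours, a 3x3x3 cross) or 26 (full 3x3x3
#'   cube). Default 6 — the smallest symmetric 3D element.
#' @param iterations Number of times the operator is applied (>= 1).
#' @return An object of class `structuring_element`.
#' @export
structuring_element <- function(connectivity = 6L, iterations = 1L) {
  connectivity <- as.integer(connectivity)
  iterations <- as.integer(iterations)
  if (!connectivity %in% c(6L, 26L)) stop_format("connectivity must be 6 or 26")
  if (iterations < 1L) stop_format("iterations must be >= 1")
  structure(list(connectivity = connectivity, iterations = iterations),
            class = "structuring_element")
}

se_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

# Shift a 3D logical array by (dx,dy,dz), filling exposed planes with FALSE.
shift3d <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

morph_once <- function(m, offsets, op) {
  acc <- m
  for (i in seq_len(nrow(offsets))) {
    s <- shift3d(m, offsets[i, 1], offsets[i, 2], offsets[i, 3])
    acc <- if (op == "erode") acc & s else acc | s
  }
  acc
}

#' Binary erosion / dilation of a 3D mask
#'
#' @param m 3D logical (or 0/1) array.
#' @param se A [structuring_element()].
#' @return 3D logical array.
#' @export
erode3d <- function(m, se = structuring_element()) {
  m <- as_binary3d(m)
  off <- se_offsets(se$connectivity)
  for (i in seq_len(se$iterations)) m <- morph_once(m, off, "erode")
  m
}

#' @rdname erode3d
#' @export
dilate3d <- function(m, se = structuring_element()) {
  m <- as_binary3d(m)
  off <- se_offsets(se$connectivity)
  for (i in seq_len(se$iterations)) m <- morph_once(m, off, "dilate")
  m
}

as_binary3d <- function(m) {
  if (!(is.array(m) && length(dim(m)) == 3L)) stop_format("mask must be a 3D array")
  array(as.logical(m != 0), dim = dim(m))
}

#' Decode a chromosome into a binary brain mask
#'
#' Each region contributes voxels according to its gene: 0 — omitted; 1 —
#' erosion of the region support; 2 — the support unchanged; 3 — dilation of
#' the support (clipped at the grid boundary, allowed to reach into
#' neighbouring regions; overlaps resolve by union).
#'
#' @param ch Integer vector of length `atlas$R` over `{0,1,2,3}`.
#' @param atlas A [label_atlas()].
#' @param se A [structuring_element()].
#' @return An object of class `brain_mask`: list with `mask` (3D 0/1 integer
#'   array) and `provenance` (chromosome + element settings).
#' @export
build_mask <- function(ch, atlas, se = structuring_element()) {
  ch <- check_chromosome(ch, atlas$R)
  acc <- array(FALSE, dim = dim(atlas$labels))
  for (r in which(ch > 0L)) {
    supp <- atlas$labels == r
    dim(supp) <- dim(atlas$labels)
    contrib <- switch(as.character(ch[r]),
                      "1" = erode3d(supp, se),
                      "2" = supp,
                      "3" = dilate3d(supp, se))
    acc <- acc | contrib
  }
  structure(list(mask = array(as.integer(acc), dim = dim(acc)),
                 provenance = list(chromosome = ch, se = se)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d/%d voxels on, %d regions selected\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              length(x$mask), sum(x$provenance$chromosome > 0L)))
  invisible(x)
}

#' Apply a binary mask to a volume
#'
#' Voxels where the mask is 1 keep their value; all others are set to `fill`
#' (default 0, the mean of a standardized volume).
#'
#' @param v 3D numeric array.
#' @param m A [build_mask()] result or a 3D 0/1 array of the same shape.
#' @param fill Replacement value outside the mask.
#' @return Masked volume (same shape).
#' @export
apply_mask <- function(v, m, fill = 0) {
  mk <- if (inherits(m, "brain_mask")) m$mask else m
  check_same_shape(v, mk, "volume and mask")
  out <- v
  out[mk == 0L] <- fill
  out
}

#' Write a mask and its provenance
#'
#' The mask goes out as an integer NIfTI; provenance (region, gene, operation)
#' as a tab-delimited sidecar.
#'
#' @param bm A [build_mask()] result.
#' @param path NIfTI output path; the sidecar replaces the extension with
#'   `_provenance.tsv`.
#' @param atlas Optional [label_atlas()] supplying region names.
#' @return `path`, invisibly.
#' @export
write_mask <- function(bm, path, atlas = NULL) {
  img <- RNifti::asNifti(array(as.numeric(bm$mask), dim = dim(bm$mask)))
  RNifti::writeNifti(img, path, datatype = "uint8")
  ch <- bm$provenance$chromosome
  tab <- data.frame(region = seq_along(ch), gene = ch,
                    importance = gene_labels(ch), operation = gene_operations(ch))
  if (!is.null(atlas)) tab$name <- atlas$names$name
  side <- sub("\\.nii(\\.gz)?$", "", path)
  utils::write.table(tab, paste0(side, "_provenance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

gene_labels <- function(g) c("UR", "IR", "VIR", "VVIR")[g + 1L]
gene_operations <- function(g) {
  c("omitted", "erosion", "none", "dilation")[g + 1L]
}
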