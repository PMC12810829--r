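#' @keywords internal
#' @useDynLib gashap, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a 3D scalar volume from a NIfTI file
#'
#' Reads a single-channel 3D image. A 4D payload whose fourth axis has length
#' one is squeezed to 3D. The NIfTI header (affine, voxel sizes) is retained in
#' the `"spatial_meta"` attribute and carried through [write_volume()]
#' unchanged.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3D numeric array with attribute `spatial_meta`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_format("volume file does not exist: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop_format("expected a 3D (or 4D singleton) payload, got %s dimensions in %s",
                length(dim(img)), path)
  }
  v <- array(as.numeric(img), dim = d)
  if (!is.numeric(v)) stop_format("non-scalar datatype in %s", path)
  attr(v, "spatial_meta") <- RNifti::niftiHeader(img)
  v
}

#' Write a 3D volume to a NIfTI file
#'
#' @param v 3D numeric array; a `spatial_meta` attribute, if present, supplies
#'   the header template.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  check_volume(v)
  meta <- attr(v, "spatial_meta")
  arr <- array(as.numeric(v), dim = dim(v))
  img <- if (is.null(meta)) RNifti::asNifti(arr) else RNifti::asNifti(arr, reference = meta)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

check_volume <- function(v) {
  if (!(is.array(v) && length(dim(v)) == 3L))
    stop_format("a volume must be a 3D array")
  if (any(dim(v) < 1L)) stop_format("all volume dimensions must be >= 1")
  if (!all(is.finite(v))) stop_format("volume contains non-finite values")
  invisible(v)
}

#' Normalize a volume to zero mean and unit variance
#'
#' Standardizes voxel intensities: `(v - mean(v)) / sd(v)`, using the
#' population standard deviation (divisor `n`). The output has mean 0 and
#' variance 1 to within 1e-6 and is idempotent under re-application.
#'
#' @param v 3D numeric array with nonzero variance.
#' @return The standardized volume (attributes preserved).
#' @export
normalize_volume <- function(v) {
  check_volume(v)
  n <- length(v)
  m <- mean(v)
  s2 <- sum((v - m)^2) / n
  if (s2 <= 0) stop_format("cannot normalize a constant volume (zero variance)")
  out <- (v - m) / sqrt(s2)
  attributes(out) <- attributes(v)
  out
}
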