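# Labelled cohort container and class-balanced splitting.

#' Construct a labelled dataset
#'
#' @param volumes List of 3D arrays, all of one shape.
#' @param classes Integer vector of class labels in `{0, 1}` (0 = control,
#'   1 = case), one per volume.
#' @param split Character vector over `{"train","val","test"}`, one per volume.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(volumes, classes, split) {
  if (length(volumes) != length(classes) || length(volumes) != length(split))
    stop_format("volumes, classes and split must have equal length")
  classes <- as.integer(classes)
  if (!all(classes %in% c(0L, 1L))) stop_format("classes must be 0 or 1")
  if (!all(split %in% c("train", "val", "test")))
    stop_format("split values must be 'train', 'val' or 'test'")
  shp <- dim(volumes[[1]])
  for (v in volumes) {
    if (!identical(dim(v), shp))
      stop_format("all volumes must share one shape")
  }
  structure(list(volumes = volumes, classes = classes, split = split,
                 shape = shp),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d volumes (%s), classes 0/1: %d/%d\n",
              length(x$volumes), paste(x$shape, collapse = "x"),
              sum(x$classes == 0L), sum(x$classes == 1L)))
  print(table(split = x$split, class = x$classes))
  invisible(x)
}

#' Subset a dataset by split
#'
#' @param ds A [labeled_dataset()].
#' @param which One or more of `"train"`, `"val"`, `"test"`.
#' @return A list with `volumes`, `classes` and `index` (positions in `ds`).
#' @export
dataset_split <- function(ds, which = "train") {
  idx <- which(ds$split %in% which)
  list(volumes = ds$volumes[idx], classes = ds$classes[idx], index = idx)
}

# Per-class largest-remainder allocation of n samples over split fractions.
# Remainder ties are broken by a split priority order rotated by the class
# index, so that across the two classes the totals track the exact fractions
# (e.g. 70/70 at 0.7/0.15/0.15 gives 98/21/21) while each class stays within
# one sample of its exact allocation.
allocate_counts <- function(n, fractions, rotate = 0L) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    prio <- order(-rem, (seq_along(fractions) - 1L + rotate) %% length(fractions))
    base[prio[seq_len(short)]] <- base[prio[seq_len(short)]] + 1L
  }
  as.integer(base)
}

#' Class-balanced train/validation/test split
#'
#' Assigns each volume to one split, preserving class balance: per class the
#' split counts differ from the exact fractional allocation by less than one
#' sample. Deterministic for a fixed seed.
#'
#' @param volumes List of 3D arrays.
#' @param classes Integer class labels (0/1), one per volume.
#' @param fractions Numeric length-3 vector (train, val, test) summing to 1.
#' @param seed Integer RNG seed.
#' @return A [labeled_dataset()].
#' @export
split_dataset <- function(volumes, classes, fractions = c(0.7, 0.15, 0.15),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop_format("split fractions must sum to 1")
  if (length(fractions) != 3L) stop_format("fractions must be (train, val, test)")
  classes <- as.integer(classes)
  split <- character(length(volumes))
  nm <- c("train", "val", "test")
  n_splits_used <- sum(fractions > 0)
  with_seed(seed, {
    for (k in sort(unique(classes))) {
      idx <- which(classes == k)
      if (length(idx) < n_splits_used)
        stop_format("class %d has fewer samples (%d) than nonempty splits (%d)",
                    k, length(idx), n_splits_used)
      counts <- allocate_counts(length(idx), fractions, rotate = k)
      perm <- idx[sample.int(length(idx))]
      split[perm] <- rep(nm, times = counts)
    }
  })
  labeled_dataset(volumes, classes, split)
}

# Run `code` under a fixed RNG seed, restoring the caller-visible RNG state
# afterwards. All seeded package entry points go through this so that callers'
# random streams are never perturbed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Write / read a dataset manifest with NIfTI volumes
#'
#' `write_cohort()` writes each volume as `vol_<i>.nii.gz` under `dir` plus a
#' tab-delimited `manifest.tsv` (path, class, split); `read_cohort()` loads one
#' back.
#'
#' @param ds A [labeled_dataset()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: the manifest path, invisibly; `read_cohort()`: a
#'   [labeled_dataset()].
#' @export
write_cohort <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(ds$volumes))
  for (i in seq_along(ds$volumes)) {
    paths[i] <- file.path(dir, sprintf("vol_%03d.nii.gz", i))
    write_volume(ds$volumes[[i]], paths[i])
  }
  man <- data.frame(path = basename(paths), class = ds$classes,
                    split = ds$split)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' @rdname write_cohort
#' @param manifest Path to a `manifest.tsv` written by `write_cohort()`.
#' @export
read_cohort <- function(manifest) {
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  base <- dirname(manifest)
  vols <- lapply(man$path, function(p) read_volume(file.path(base, p)))
  labeled_dataset(vols, man$class, man$split)
}
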