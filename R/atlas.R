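# Parcellation atlas: integer-labelled 3D grid, 0 = background, plus a region
# ID -> name lookup. Internally regions are re-indexed to 1..R; the original
# file IDs are kept in the names table.

#' Construct a label atlas
#'
#' @param labels 3D integer array; 0 is background, positive values are region
#'   IDs (need not be contiguous — they are re-indexed internally to `1..R`).
#' @param names Optional data frame with columns `id` and `name` covering every
#'   nonzero ID in `labels`. Auto-generated (`region_<id>`) when `NULL`.
#' @return An object of class `label_atlas` with elements `labels` (re-indexed
#'   1..R grid), `names` (data frame: `region`, `orig_id`, `name`), `R`.
#' @export
label_atlas <- function(labels, names = NULL) {
  if (!(is.array(labels) && length(dim(labels)) == 3L))
    stop_format("atlas labels must be a 3D array")
  lab <- as.integer(round(labels))
  if (any(lab < 0L)) stop_format("atlas labels must be >= 0 (0 = background)")
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) < 1L) stop_format("atlas contains no regions")
  if (is.null(names)) {
    names <- data.frame(id = ids, name = sprintf("region_%d", ids),
                        stringsAsFactors = FALSE)
  }
  if (!all(c("id", "name") %in% colnames(names)))
    stop_format("atlas names table needs columns 'id' and 'name'")
  missing_ids <- setdiff(ids, names$id)
  if (length(missing_ids))
    stop_format("atlas name table is missing IDs present in the image: {%s}",
                paste(missing_ids, collapse = ", "))
  # bijective re-index original IDs -> 1..R
  reindex <- integer(max(ids) + 1L)
  reindex[ids + 1L] <- seq_along(ids)
  new_lab <- array(0L, dim = dim(labels))
  nz <- lab > 0L
  new_lab[nz] <- reindex[lab[nz] + 1L]
  tab <- data.frame(region = seq_along(ids), orig_id = ids,
                    name = names$name[match(ids, names$id)],
                    stringsAsFactors = FALSE)
  structure(list(labels = new_lab, names = tab, R = length(ids)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %d regions on a %s grid\n",
              x$R, paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Read a parcellation atlas from a NIfTI label image and a names table
#'
#' The names file is a two-column delimited table (ID, name); the delimiter
#' (tab or comma) and an optional header row are auto-detected.
#'
#' @param label_path NIfTI file with integer labels.
#' @param names_path Delimited text file mapping region ID to region name, or
#'   `NULL` to auto-name regions.
#' @return A [label_atlas()].
#' @export
read_atlas <- function(label_path, names_path = NULL) {
  vol <- read_volume(label_path)
  if (max(abs(vol - round(vol))) > 1e-6)
    stop_format("atlas label image is not integer-valued: %s", label_path)
  nm <- if (is.null(names_path)) NULL else read_region_names(names_path)
  a <- label_atlas(array(as.integer(round(vol)), dim = dim(vol)), nm)
  a
}

read_region_names <- function(path) {
  if (!file.exists(path)) stop_format("names file does not exist: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- suppressWarnings(is.na(as.numeric(fields[1])))
  df <- if (header) {
    utils::read.table(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, quote = "\"")
  } else {
    utils::read.table(path, sep = sep, header = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      col.names = c("id", "name"))
  }
  colnames(df)[1:2] <- c("id", "name")
  df$id <- as.integer(df$id)
  df
}

#' Write an atlas as a NIfTI label image plus names table
#'
#' Labels are written with their original (pre-re-indexing) IDs.
#'
#' @param atlas A [label_atlas()].
#' @param label_path,names_path Output paths.
#' @return `label_path`, invisibly.
#' @export
write_atlas <- function(atlas, label_path, names_path = NULL) {
  orig <- array(0L, dim = dim(atlas$labels))
  nz <- atlas$labels > 0L
  orig[nz] <- atlas$names$orig_id[atlas$labels[nz]]
  img <- RNifti::asNifti(array(as.numeric(orig), dim = dim(orig)))
  RNifti::writeNifti(img, label_path, datatype = "int16")
  if (!is.null(names_path)) {
    utils::write.table(
      data.frame(id = atlas$names$orig_id, name = atlas$names$name),
      names_path, sep = "\t", row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  invisible(label_path)
}

region_voxel_counts <- function(atlas) {
  tabulate(atlas$labels[atlas$labels > 0L], nbins = atlas$R)
}

check_same_shape <- function(a, b, what = "objects") {
  da <- if (is.array(a)) dim(a) else dim(a$labels)
  db <- if (is.array(b)) dim(b) else dim(b$labels)
  if (!identical(da, db))
    stop_format("%s have mismatched shapes (%s vs %s)", what,
                paste(da, collapse = "x"), paste(db, collapse = "x"))
  invisible(TRUE)
}
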