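# Volume loading, the workspace container, ROI management and exports.
#
# The workspace is an environment (reference semantics): channels, levels and
# partitions accumulate in place as the pipeline advances, matching how an
# interactive session mutates state.

FORMATS <- c("hdf5", "mrc", "tiff")

format_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    h5 = , hdf5 = , hdf = "hdf5",
    mrc = , rec = , map = "mrc",
    tif = , tiff = "tiff",
    stop("unrecognised volume format: .", ext)
  )
}

read_hdf5_volume <- function(path, dataset = NULL) {
  ls <- rhdf5::h5ls(path)
  ds <- ls[ls$otype == "H5I_DATASET", , drop = FALSE]
  ndim <- vapply(strsplit(ds$dim, " x "), length, integer(1))
  ds3 <- ds[ndim == 3, , drop = FALSE]
  if (is.null(dataset)) {
    if (nrow(ds3) == 0) stop("no 3D dataset in ", path)
    if (nrow(ds3) > 1)
      stop("ambiguous HDF5 file (", nrow(ds3),
           " 3D datasets); pass `dataset` explicitly")
    dataset <- paste0(ds3$group[1], ifelse(ds3$group[1] == "/", "", "/"),
                      ds3$name[1])
  }
  a <- rhdf5::h5read(path, dataset)
  rhdf5::h5closeAll()
  if (length(dim(a)) != 3) stop("dataset ", dataset, " is not 3D")
  storage.mode(a) <- "double"
  a
}

write_hdf5_volume <- function(data, path, dataset = "data") {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(data, path, dataset)
  rhdf5::h5closeAll()
  invisible(path)
}

# TIFF stores float32 samples in [0,1]; the original intensity range is
# recorded in a small JSON sidecar (<path>.range.json) so round-trips of
# files we wrote restore intensities. Foreign TIFF stacks load as-is.
range_sidecar <- function(path) paste0(path, ".range.json")

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  sc <- range_sidecar(path)
  if (file.exists(sc)) {
    rng <- jsonlite::fromJSON(sc)$srvox_range
    a <- a * (rng[2] - rng[1]) + rng[1]
  }
  a
}

write_tiff_volume <- function(data, path) {
  lo <- min(data); hi <- max(data)
  scaled <- if (hi > lo) (data - lo) / (hi - lo) else data * 0
  pages <- lapply(seq_len(dim(data)[1]), function(z) scaled[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(srvox_range = c(lo, hi)), range_sidecar(path),
                       digits = NA)
  invisible(path)
}

#' Load a volume and open a workspace
#'
#' Reads a 3D scalar volume from HDF5 (a single 3D dataset, or a named one),
#' MRC (modes 0/1/2) or a multi-page TIFF stack, reorders axes to the internal
#' `(z, y, x)` convention, and returns a fresh workspace whose region of
#' interest spans the full volume.
#'
#' @param path path to the volume file.
#' @param orientation three-letter axis-order tag describing the order of the
#'   stored axes, e.g. `"zyx"` (default, no permutation) or `"xyz"` if the
#'   file's first axis is x. For TIFF stacks the page axis is always z.
#' @param dataset HDF5 dataset name, required when the file holds several 3D
#'   datasets.
#' @param impute_nonfinite non-finite voxels abort the load by default (they
#'   indicate acquisition faults); set `TRUE` to replace them with the volume
#'   median instead.
#' @param storage_dir optional directory associated with the workspace; used
#'   as the default export target.
#' @return a `srvox_workspace` environment.
#' @examples
#' ph <- make_multiregion(size = 16, seed = 1)
#' f <- tempfile(fileext = ".mrc")
#' write_mrc(ph$volume, f)
#' ws <- load_volume(f)
#' ws$shape
#' @export
load_volume <- function(path, orientation = "zyx", dataset = NULL,
                        impute_nonfinite = FALSE, storage_dir = NULL) {
  fmt <- format_of(path)
  a <- switch(fmt,
    hdf5 = read_hdf5_volume(path, dataset),
    mrc  = read_mrc(path),
    tiff = read_tiff_volume(path)
  )
  perm <- match(c("z", "y", "x"), strsplit(orientation, "")[[1]])
  if (anyNA(perm) || length(unique(perm)) != 3)
    stop("orientation must be a permutation of 'zyx', got: ", orientation)
  if (!identical(perm, 1:3)) a <- aperm(a, perm)
  if (any(!is.finite(a))) {
    if (!impute_nonfinite)
      stop("volume contains non-finite voxels; pass impute_nonfinite = TRUE ",
           "to replace them with the median")
    a[!is.finite(a)] <- median(a[is.finite(a)])
  }
  new_workspace(a, source_path = path, orientation = orientation,
                storage_dir = storage_dir)
}

#' Create a workspace from an in-memory array
#'
#' @param data numeric 3D array in `(z, y, x)` order.
#' @param source_path,orientation,storage_dir provenance metadata.
#' @return a `srvox_workspace` environment.
#' @export
new_workspace <- function(data, source_path = NA_character_,
                          orientation = "zyx", storage_dir = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(!is.finite(data))) stop("volume contains non-finite voxels")
  ws <- new.env(parent = emptyenv())
  ws$volume <- data
  ws$shape <- dim(data)
  ws$orientation <- orientation
  ws$source_path <- source_path
  ws$storage_dir <- storage_dir
  d <- dim(data)
  ws$roi <- list(z = c(1L, d[1]), y = c(1L, d[2]), x = c(1L, d[3]),
                 selected = TRUE)
  ws$channels <- list()
  ws$levels <- list()
  ws$supervoxels <- NULL
  ws$megavoxels <- NULL
  ws$next_level_id <- 1L
  class(ws) <- "srvox_workspace"
  ws
}

#' @export
print.srvox_workspace <- function(x, ...) {
  cat("srvox workspace\n")
  cat("  volume: ", paste(x$shape, collapse = " x "), " (z y x)\n", sep = "")
  r <- x$roi
  cat(sprintf("  ROI:    z %d..%d, y %d..%d, x %d..%d\n",
              r$z[1], r$z[2], r$y[1], r$y[2], r$x[1], r$x[2]))
  cat("  channels: ", if (length(x$channels))
      paste(names(x$channels), collapse = ", ") else "(none)", "\n", sep = "")
  cat("  levels: ", length(x$levels),
      "  supervoxels: ", if (is.null(x$supervoxels)) "no" else
        x$supervoxels$n_regions,
      "  megavoxels: ", if (is.null(x$megavoxels)) "no" else
        x$megavoxels$n_regions, "\n", sep = "")
  invisible(x)
}

#' Select the region of interest
#'
#' Bounds are 1-based closed intervals `(z0, z1, y0, y1, x0, x1)` on the
#' loaded volume. All downstream products (channels, super-regions,
#' annotation levels, training) are computed on the selected ROI only;
#' changing the ROI invalidates every product computed for the previous one.
#'
#' @param ws a workspace.
#' @param bounds integer vector `(z0, z1, y0, y1, x0, x1)`.
#' @return the ROI record, invisibly.
#' @export
set_roi <- function(ws, bounds) {
  stopifnot(inherits(ws, "srvox_workspace"), length(bounds) == 6)
  b <- as.integer(bounds)
  d <- ws$shape
  lo <- b[c(1, 3, 5)]; hi <- b[c(2, 4, 6)]
  if (any(lo < 1) || any(hi > d) || any(lo > hi))
    stop("ROI bounds out of range or inverted for volume ",
         paste(d, collapse = "x"))
  ws$roi <- list(z = b[1:2], y = b[3:4], x = b[5:6], selected = TRUE)
  # products tied to the previous ROI are no longer valid
  ws$channels <- list()
  ws$levels <- list()
  ws$supervoxels <- NULL
  ws$megavoxels <- NULL
  invisible(ws$roi)
}

roi_dim <- function(ws) {
  r <- ws$roi
  c(r$z[2] - r$z[1] + 1L, r$y[2] - r$y[1] + 1L, r$x[2] - r$x[1] + 1L)
}

#' Raw data restricted to the ROI
#' @param ws a workspace.
#' @return numeric 3D array over the ROI.
#' @export
roi_data <- function(ws) {
  r <- ws$roi
  ws$volume[r$z[1]:r$z[2], r$y[1]:r$y[2], r$x[1]:r$x[2], drop = FALSE]
}

# resolve a data source name: "raw" or a computed channel
source_data <- function(ws, source) {
  if (identical(source, "raw")) return(roi_data(ws))
  ch <- ws$channels[[source]]
  if (is.null(ch)) stop("unknown source: ", source)
  ch$data
}

write_volume_as <- function(data, path, format, integer_data = FALSE) {
  switch(format,
    hdf5 = write_hdf5_volume(data, path),
    mrc  = write_mrc(data, path, mode = if (integer_data) 1 else 2),
    tiff = write_tiff_volume(data, path)
  )
  path
}

#' Export workspace products
#'
#' Writes ROI data, annotations, per-label binary masks, or masked data to
#' HDF5, MRC or TIFF files (one file per output and level/label). Annotations
#' are written as integer grids (MRC mode 1); masks are binary. An optional
#' linear `scale` and an intensity `invert` (`v -> min + max - v`) are applied
#' to data-valued outputs before writing.
#'
#' @param ws a workspace.
#' @param output one of `"raw_data"`, `"raw_annotations"`,
#'   `"segmentation_masks"`, `"masked_data"`.
#' @param format one of `"hdf5"`, `"mrc"`, `"tiff"`.
#' @param dir output directory (defaults to the workspace `storage_dir`).
#' @param levels level ids to export (required for annotation-derived
#'   outputs; defaults to all levels).
#' @param scale optional multiplicative rescale applied before writing.
#' @param invert reflect intensities about the data range midpoint.
#' @param mask_source for `masked_data`: name of the channel (or `"raw"`)
#'   the masks are applied to.
#' @return character vector of files written.
#' @export
export_workspace <- function(ws, output, format = "hdf5", dir = NULL,
                             levels = NULL, scale = NULL, invert = FALSE,
                             mask_source = "raw") {
  stopifnot(inherits(ws, "srvox_workspace"))
  output <- match.arg(output, c("raw_data", "raw_annotations",
                                "segmentation_masks", "masked_data"))
  format <- match.arg(format, FORMATS)
  dir <- dir %||% ws$storage_dir %||% stop("no output directory given")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- switch(format, hdf5 = "h5", mrc = "mrc", tiff = "tif")

  prep <- function(x) {
    if (!is.null(scale)) x <- x * scale
    if (invert) x <- min(x) + max(x) - x
    x
  }
  need_levels <- function() {
    ids <- levels %||% names(ws$levels)
    if (length(ids) == 0) stop("no annotation level selected")
    ids <- as.character(ids)
    missing <- setdiff(ids, names(ws$levels))
    if (length(missing)) stop("unknown level(s): ",
                              paste(missing, collapse = ", "))
    ids
  }

  files <- character(0)
  if (output == "raw_data") {
    f <- file.path(dir, paste0("raw_data.", ext))
    write_volume_as(prep(roi_data(ws)), f, format)
    files <- f
  } else if (output == "raw_annotations") {
    for (id in need_levels()) {
      f <- file.path(dir, paste0("annotations_level", id, ".", ext))
      write_volume_as(ws$levels[[id]]$voxel_labels, f, format,
                      integer_data = TRUE)
      files <- c(files, f)
    }
  } else if (output == "segmentation_masks") {
    for (id in need_levels()) {
      lv <- ws$levels[[id]]
      for (lab in lv$labels) {
        m <- (lv$voxel_labels == lab$id) * 1
        dim(m) <- dim(lv$voxel_labels)
        f <- file.path(dir, paste0("mask_level", id, "_label", lab$id, ".",
                                   ext))
        write_volume_as(m, f, format, integer_data = TRUE)
        files <- c(files, f)
      }
    }
  } else { # masked_data
    target <- source_data(ws, mask_source)
    for (id in need_levels()) {
      lv <- ws$levels[[id]]
      masked <- prep(target) * (lv$voxel_labels >= 0)
      dim(masked) <- dim(target)
      f <- file.path(dir, paste0("masked_data_level", id, ".", ext))
      write_volume_as(masked, f, format)
      files <- c(files, f)
    }
  }
  files
}

`%||%` <- function(a, b) if (is.null(a)) b else a
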