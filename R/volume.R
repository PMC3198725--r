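#' @useDynLib emsynapse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D grayscale volume with voxel spacing
#'
#' Container for a serial electron microscopy stack (or any scalar map
#' derived from one). Data are held as a 3D array in `(z, y, x)` axis
#' order; all coordinates used throughout the package are 0-based
#' `(z, y, x)` triples, matching slice-major serial-section storage.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param spacing_nm Physical voxel size per axis in nanometres,
#'   `(z, y, x)`. Defaults to `c(9, 5, 5)` (typical FIB/SEM milling
#'   depth and pixel size).
#' @return An object of class `em_volume` with elements `data` and
#'   `spacing_nm`.
#' @export
em_volume <- function(data, spacing_nm = c(9, 5, 5)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(spacing_nm) || length(spacing_nm) != 3L ||
      any(!is.finite(spacing_nm)) || any(spacing_nm <= 0))
    stop("`spacing_nm` must be three positive values (z, y, x)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume intensities must be finite (no NA/NaN/Inf)")
  structure(list(data = data, spacing_nm = as.numeric(spacing_nm)),
            class = "em_volume")
}

#' @export
print.em_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("em_volume: %d x %d x %d voxels (z, y, x), spacing %g x %g x %g nm\n",
              d[1], d[2], d[3],
              x$spacing_nm[1], x$spacing_nm[2], x$spacing_nm[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.em_volume <- function(x) dim(x$data)

is_h5_path <- function(path) {
  grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)
}

is_tiff_path <- function(path) {
  grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)
}

sidecar_spacing <- function(path) {
  side <- paste0(tools::file_path_sans_ext(path), ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$spacing_nm)) return(as.numeric(meta$spacing_nm))
  }
  NULL
}

#' Read a 3D volume from disk
#'
#' Accepts a multipage TIFF stack, a directory of single-page 2D TIFFs
#' (slices taken in lexicographic filename order), or an HDF5 file.
#' Voxel spacing is taken from an HDF5 `spacing_nm` attribute or a YAML
#' sidecar (`<stem>.yaml` with a `spacing_nm` field) when present, and
#' defaults to `c(9, 5, 5)` nm otherwise.
#'
#' @param path File or directory to read.
#' @param dataset HDF5 dataset name; required when the file contains
#'   more than one dataset, defaults to `"data"`.
#' @param spacing_nm Optional spacing override.
#' @return An [em_volume].
#' @export
read_volume <- function(path, dataset = NULL, spacing_nm = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("directory contains no TIFF slices: ", path)
    slices <- lapply(files, function(f) tiff_page_matrix(tiff::readTIFF(f, as.is = TRUE)))
    data <- stack_slices(slices)
    sp <- spacing_nm %||% sidecar_spacing(file.path(path, "volume")) %||% c(9, 5, 5)
    return(em_volume(data, sp))
  }
  if (is_h5_path(path)) {
    dsets <- rhdf5::h5ls(path, recursive = TRUE)
    dsets <- dsets[dsets$otype == "H5I_DATASET", , drop = FALSE]
    if (is.null(dataset)) {
      if (nrow(dsets) == 1L) dataset <- file.path(dsets$group[1], dsets$name[1])
      else if ("data" %in% dsets$name) dataset <- "data"
      else stop("HDF5 file has ", nrow(dsets),
                " datasets; specify `dataset`")
    }
    data <- rhdf5::h5read(path, dataset)
    if (length(dim(data)) > 3L) stop("dataset has more than 3 dimensions")
    if (is.null(dim(data)) || length(dim(data)) == 2L)
      dim(data) <- c(dim(data), 1L)[1:3]
    attrs <- rhdf5::h5readAttributes(path, dataset)
    sp <- spacing_nm %||% attrs$spacing_nm %||% sidecar_spacing(path) %||% c(9, 5, 5)
    storage.mode(data) <- if (is.integer(data)) "integer" else "double"
    return(em_volume(data, as.numeric(sp)))
  }
  if (is_tiff_path(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, tiff_page_matrix)
    data <- stack_slices(slices)
    sp <- spacing_nm %||% sidecar_spacing(path) %||% c(9, 5, 5)
    return(em_volume(data, sp))
  }
  stop("unrecognized volume format: ", path,
       " (expected .tif/.tiff, .h5/.hdf5, or a directory of TIFFs)")
}

tiff_page_matrix <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
  if (length(dim(p)) != 2L) stop("TIFF page is not a 2D image")
  p
}

stack_slices <- function(slices) {
  shp <- dim(slices[[1]])
  ok <- vapply(slices, function(s) identical(dim(s), shp), logical(1))
  if (!all(ok)) stop("ragged slice shapes: all slices must share one size")
  data <- array(0, dim = c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  if (all(vapply(slices, is.integer, logical(1)))) storage.mode(data) <- "integer"
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 3D volume to disk
#'
#' HDF5 output (`.h5`/`.hdf5`) stores the array under one dataset
#' (default `"data"`) with the spacing as a `spacing_nm` attribute and
#' round-trips doubles exactly. TIFF output (`.tif`/`.tiff`) writes one
#' page per z-slice; non-integer data are stored as 32-bit float, so
#' doubles are rounded to float precision. If `path` is an existing
#' directory, one single-page TIFF per slice is written into it
#' (`s0000.tif`, `s0001.tif`, ...), with a `volume.yaml` spacing
#' sidecar.
#'
#' @param vol An [em_volume].
#' @param path Output file (extension selects the format) or existing
#'   directory.
#' @param dataset HDF5 dataset name (default `"data"`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, dataset = "data") {
  stopifnot(inherits(vol, "em_volume"))
  if (dir.exists(path)) {
    d <- dim(vol$data)
    for (i in seq_len(d[1])) {
      f <- file.path(path, sprintf("s%04d.tif", i - 1L))
      write_tiff_page(vol$data[i, , ], f)
    }
    yaml::write_yaml(list(spacing_nm = vol$spacing_nm),
                     file.path(path, "volume.yaml"))
    return(invisible(path))
  }
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (is_h5_path(path)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(vol$data, path, dataset)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, dataset)
    rhdf5::h5writeAttribute(vol$spacing_nm, did, "spacing_nm")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
    return(invisible(path))
  }
  if (is_tiff_path(path)) {
    d <- dim(vol$data)
    pages <- lapply(seq_len(d[1]), function(i) vol$data[i, , ])
    writeable <- prepare_tiff_pages(pages)
    tiff::writeTIFF(writeable$pages, path, bits.per.sample = writeable$bits,
                    reduce = FALSE)
    yaml::write_yaml(list(spacing_nm = vol$spacing_nm),
                     paste0(tools::file_path_sans_ext(path), ".yaml"))
    return(invisible(path))
  }
  stop("unrecognized output format: ", path)
}

write_tiff_page <- function(page, path) {
  w <- prepare_tiff_pages(list(page))
  tiff::writeTIFF(w$pages[[1]], path, bits.per.sample = w$bits, reduce = FALSE)
}

# r-tiff writes integers as scaled [0,1] samples and floats as 32-bit.
# Integer volumes in [0, 65535] are stored losslessly at 16 bit.
prepare_tiff_pages <- function(pages) {
  vals <- unlist(lapply(pages, range))
  allint <- all(vapply(pages, function(p) all(p == round(p)), logical(1)))
  if (allint && min(vals) >= 0 && max(vals) <= 65535) {
    list(pages = lapply(pages, function(p) p / 65535), bits = 16L)
  } else {
    list(pages = lapply(pages, function(p) {
      storage.mode(p) <- "double"; p
    }), bits = 32L)
  }
}

#' Sparse multi-class voxel labels
#'
#' Brush-stroke style training labels: a small set of voxels, each
#' assigned to one class. Default classes are synapse / membrane /
#' rest, the three-class labelling that separates synaptic densities
#' from other dark structures.
#'
#' @param coords Integer matrix `n x 3` of 0-based `(z, y, x)` voxel
#'   coordinates.
#' @param class_id Integer vector of class ids in `1..K`.
#' @param class_names Ordered class names, length `K >= 2`.
#' @return An object of class `sparse_labels`.
#' @export
sparse_labels <- function(coords, class_id,
                          class_names = c("synapse", "membrane", "rest")) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("`coords` must be an n x 3 (z,y,x) matrix")
  storage.mode(coords) <- "integer"
  class_id <- as.integer(class_id)
  if (nrow(coords) != length(class_id))
    stop("`coords` and `class_id` lengths differ")
  if (length(class_names) < 2L) stop("need at least 2 classes")
  if (length(class_id) && (any(class_id < 1L) || any(class_id > length(class_names))))
    stop("class ids must lie in 1..", length(class_names))
  colnames(coords) <- c("z", "y", "x")
  structure(list(coords = coords, class_id = class_id,
                 class_names = as.character(class_names)),
            class = "sparse_labels")
}

#' @export
print.sparse_labels <- function(x, ...) {
  cat(sprintf("sparse_labels: %d labeled voxels, %d classes\n",
              nrow(x$coords), length(x$class_names)))
  tab <- table(factor(x$class_id, levels = seq_along(x$class_names),
                      labels = x$class_names))
  for (nm in names(tab)) cat(sprintf("  %-10s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Validate 0-based voxel coordinates against a volume shape
#'
#' Shared bounds check used by every module that consumes coordinates.
#'
#' @param coords `n x 3` matrix of 0-based `(z, y, x)` coordinates.
#' @param shape Volume shape `(nz, ny, nx)`.
#' @return Invisibly `TRUE`; stops on any out-of-bounds coordinate.
#' @export
validate_coords <- function(coords, shape) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) return(invisible(TRUE))
  bad <- coords[, 1] < 0 | coords[, 1] >= shape[1] |
         coords[, 2] < 0 | coords[, 2] >= shape[2] |
         coords[, 3] < 0 | coords[, 3] >= shape[3]
  if (any(bad))
    stop(sum(bad), " coordinate(s) out of bounds for shape (",
         paste(shape, collapse = ", "), ")")
  invisible(TRUE)
}

#' Read sparse voxel labels
#'
#' Either a CSV with header `z,y,x,class_id` (0-based coordinates) or a
#' label volume (HDF5/TIFF) in which 0 means unlabeled and positive
#' integers are class ids. Class names come from a YAML sidecar
#' (`<stem>.yaml`, field `class_names`) when present.
#'
#' @param path CSV file or label volume.
#' @param volume Optional [em_volume] to bounds-check against.
#' @return A [sparse_labels] object.
#' @export
read_labels <- function(path, volume = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- sidecar_class_names(path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("z", "y", "x", "class_id")
    if (!all(need %in% names(df)))
      stop("label CSV must have header z,y,x,class_id")
    if (nrow(df) && any(!is.finite(df$class_id) | df$class_id <= 0))
      stop("class ids must be positive integers")
    k <- if (nrow(df)) max(df$class_id, 3L) else 3L
    nms <- side %||% default_class_names(k)
    lab <- sparse_labels(as.matrix(df[, c("z", "y", "x")]), df$class_id, nms)
  } else {
    vol <- read_volume(path)
    idx <- which(vol$data != 0)
    d <- dim(vol$data)
    coords <- cbind(z = (idx - 1L) %% d[1],
                    y = ((idx - 1L) %/% d[1]) %% d[2],
                    x = (idx - 1L) %/% (d[1] * d[2]))
    ids <- as.integer(round(vol$data[idx]))
    if (length(ids) && any(ids <= 0))
      stop("label volume must encode class ids as positive integers")
    k <- if (length(ids)) max(ids, 3L) else 3L
    nms <- side %||% default_class_names(k)
    lab <- sparse_labels(coords, ids, nms)
  }
  if (!is.null(volume)) validate_coords(lab$coords, dim(volume$data))
  lab
}

default_class_names <- function(k) {
  base <- c("synapse", "membrane", "rest")
  if (k <= 3L) base[seq_len(max(k, 3L))]
  else c(base, paste0("class", 4:k))
}

sidecar_class_names <- function(path) {
  side <- paste0(tools::file_path_sans_ext(path), ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$class_names)) return(as.character(meta$class_names))
  }
  NULL
}

#' Write sparse labels as CSV
#' @param labels A [sparse_labels] object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "sparse_labels"))
  df <- data.frame(labels$coords, class_id = labels$class_id)
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(class_names = labels$class_names),
                   paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' Ball annotations: gold-standard synapse markers
#'
#' Expert annotations mark each synapse with a sphere ("ball"): a
#' center voxel and an isotropic radius in voxel units. These are the
#' unit of the detection evaluation protocol.
#'
#' @param z,y,x 0-based center coordinates (may be fractional).
#' @param radius_vox Sphere radius in voxels, strictly positive.
#' @return A `data.frame` of class `ball_annotations` with columns
#'   `z, y, x, radius_vox`.
#' @export
ball_annotations <- function(z = numeric(), y = numeric(), x = numeric(),
                             radius_vox = numeric()) {
  if (length(radius_vox) && (any(!is.finite(radius_vox)) | any(radius_vox <= 0)))
    stop("ball radii must be positive and finite")
  structure(data.frame(z = as.numeric(z), y = as.numeric(y),
                       x = as.numeric(x), radius_vox = as.numeric(radius_vox)),
            class = c("ball_annotations", "data.frame"))
}

#' Read ball annotations from CSV
#'
#' CSV with mandatory header `z,y,x,radius_vox`; rows are kept in file
#' order. Radii must be strictly positive.
#'
#' @param path CSV file.
#' @return A [ball_annotations] data frame.
#' @export
read_balls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("z", "y", "x", "radius_vox")
  if (!all(need %in% names(df)))
    stop("ball CSV must have header z,y,x,radius_vox")
  if (nrow(df) && (any(!is.finite(as.numeric(df$radius_vox))) ||
                   any(as.numeric(df$radius_vox) <= 0)))
    stop("ball radii must be positive numbers")
  ball_annotations(df$z, df$y, df$x, df$radius_vox)
}

#' Write ball annotations to CSV
#' @param balls A [ball_annotations] data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_balls <- function(balls, path) {
  utils::write.csv(as.data.frame(balls)[, c("z", "y", "x", "radius_vox")],
                   path, row.names = FALSE)
  invisible(path)
}
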