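#' MRI volume container
#'
#' Bundles a 3D intensity grid with an optional voxel-label grid using the
#' fixed tissue coding of [tissue_classes()] (0 background, 1 CSF, 2 GM,
#' 3 WM). `axis_names` declares, for each array dimension, the anatomical
#' plane whose slices that dimension indexes; the mapping is declared rather
#' than inferred from file headers, so stored axis order is never reoriented
#' behind the user's back.
#'
#' @param intensities 3D numeric array.
#' @param labels Optional 3D integer array, same shape, values in
#'   `0:(n_classes - 1)`.
#' @param axis_names Character triple naming the plane indexed by each array
#'   dimension; must be a permutation of `c("coronal", "sagittal", "axial")`.
#' @param subject_id Identifier carried through to reports.
#' @param n_classes Number of tissue classes (default 4).
#'
#' @return An object of class `mri_volume`.
#' @export
#' @examples
#' v <- mri_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
#' dim(v$intensities)
mri_volume <- function(intensities, labels = NULL,
                       axis_names = c("coronal", "sagittal", "axial"),
                       subject_id = "subject", n_classes = 4L) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop_validation("`intensities` must be a 3D array, got %s dims",
                    length(dim(intensities)))
  if (!setequal(axis_names, c("coronal", "sagittal", "axial")))
    stop_validation("`axis_names` must be a permutation of coronal/sagittal/axial")
  if (!is.null(labels)) {
    if (!identical(dim(labels), dim(intensities)))
      stop_validation("label volume shape (%s) does not match intensities (%s)",
                      paste(dim(labels), collapse = "x"),
                      paste(dim(intensities), collapse = "x"))
    labels <- check_labels(labels, n_classes)
  }
  structure(list(intensities = intensities, labels = labels,
                 axis_names = axis_names, subject_id = subject_id,
                 n_classes = as.integer(n_classes)),
            class = "mri_volume")
}

check_labels <- function(labels, n_classes) {
  storage.mode(labels) <- "integer"
  bad <- labels < 0L | labels >= n_classes
  if (any(bad))
    stop_validation("label value %d outside 0..%d",
                    labels[which(bad)[1L]], n_classes - 1L)
  labels
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s: %s (%s), labels: %s\n", x$subject_id,
              paste(dim(x$intensities), collapse = "x"),
              paste(x$axis_names, collapse = ","),
              if (is.null(x$labels)) "none" else "present"))
  invisible(x)
}

#' 2D slice container
#'
#' A single anatomical slice: an intensity canvas plus an optional integer
#' label map of the same shape, the plane and index it came from, and the
#' zero-padding record needed to restore native geometry with [unpad()].
#'
#' @param pixels Numeric matrix (rows = image height, row 1 at the top).
#' @param labels Optional integer matrix, same shape.
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param index 1-based slice position within its volume.
#' @param pad_record Integer vector `c(top, bottom, left, right)` of zero
#'   rows/columns added by [pad_to_canvas()], or `NULL` if never padded.
#' @param n_classes Number of tissue classes.
#'
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, labels = NULL, plane = "axial", index = 1L,
                        pad_record = NULL, n_classes = 4L) {
  if (!is.matrix(pixels)) stop_validation("`pixels` must be a matrix")
  plane <- check_plane(plane)
  if (!is.null(labels)) {
    if (!identical(dim(labels), dim(pixels)))
      stop_validation("label slice shape does not match pixels")
    labels <- check_labels(labels, n_classes)
  }
  if (!is.null(pad_record)) {
    pad_record <- as.integer(pad_record)
    if (length(pad_record) != 4L || any(pad_record < 0L))
      stop_validation("`pad_record` must be four non-negative integers")
    names(pad_record) <- c("top", "bottom", "left", "right")
  }
  structure(list(pixels = pixels, labels = labels, plane = plane,
                 index = as.integer(index), pad_record = pad_record,
                 n_classes = as.integer(n_classes)),
            class = "slice_image")
}

check_plane <- function(plane) {
  if (!is.character(plane) || length(plane) != 1L ||
      !plane %in% c("axial", "coronal", "sagittal"))
    stop_validation("unknown plane '%s' (use axial, coronal or sagittal)",
                    paste(plane, collapse = ","))
  plane
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %s #%d: %dx%d, labels: %s, pad: %s\n",
              x$plane, x$index, nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$labels)) "none" else "present",
              if (is.null(x$pad_record)) "none"
              else paste(x$pad_record, collapse = "/")))
  invisible(x)
}

# file I/O ---------------------------------------------------------------

read_volume_array <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  ext <- tolower(path)
  arr <- tryCatch({
    if (grepl("\\.nii(\\.gz)?$", ext)) {
      as.array(RNifti::readNifti(path))
    } else if (grepl("\\.(img|hdr)$", ext)) {
      as.array(oro.nifti::readANALYZE(sub("\\.(img|hdr)$", "", path)))
    } else {
      stop_format("unrecognised volume format: %s", path)
    }
  }, error = function(e) {
    if (inherits(e, "patchunet_error")) stop(e)
    stop_format("could not read '%s': %s", path, conditionMessage(e))
  })
  arr <- drop(arr)
  if (length(dim(arr)) != 3L)
    stop_format("'%s' is not a 3D volume (dims: %s)", path,
                paste(dim(arr), collapse = "x"))
  arr
}

#' Read an MRI volume (NIfTI or Analyze)
#'
#' Reads `.nii`/`.nii.gz` via RNifti and `.img`/`.hdr` pairs via oro.nifti,
#' in stored axis order, optionally pairing the scan with a ground-truth
#' label volume of identical shape.
#'
#' @param path Path to the intensity volume.
#' @param label_path Optional path to a label volume of the same shape.
#' @inheritParams mri_volume
#' @return An [mri_volume()].
#' @export
load_volume <- function(path, label_path = NULL,
                        axis_names = c("coronal", "sagittal", "axial"),
                        subject_id = NULL, n_classes = 4L) {
  arr <- read_volume_array(path)
  labels <- if (!is.null(label_path)) round(read_volume_array(label_path))
  subject_id <- subject_id %||%
    sub("\\.nii(\\.gz)?$|\\.(img|hdr)$", "", basename(path))
  mri_volume(arr, labels = labels, axis_names = axis_names,
             subject_id = subject_id, n_classes = n_classes)
}

#' Write an MRI volume to NIfTI
#'
#' Intensities are written as float64 and labels as uint8, so a
#' write/reload round trip reproduces both arrays exactly.
#'
#' @param vol An [mri_volume()].
#' @param path Output `.nii`/`.nii.gz` path for intensities.
#' @param label_path Optional output path for the label volume.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, label_path = NULL) {
  stopifnot(inherits(vol, "mri_volume"))
  RNifti::writeNifti(RNifti::asNifti(vol$intensities), path,
                     datatype = "double")
  if (!is.null(label_path)) {
    if (is.null(vol$labels)) stop_validation("volume has no labels to write")
    RNifti::writeNifti(RNifti::asNifti(vol$labels), label_path,
                       datatype = "uint8")
  }
  invisible(path)
}

# plane extraction --------------------------------------------------------

plane_axis <- function(vol, plane) {
  plane <- check_plane(plane)
  which(vol$axis_names == plane)
}

take_slice <- function(arr, axis, k) {
  switch(axis, arr[k, , ], arr[, k, ], arr[, , k])
}

#' Extract all slices of a volume along an anatomical plane
#'
#' Returns one [slice_image()] per position along the array axis declared (in
#' `axis_names`) to index that plane, in stored order; labels are carried
#' through when present. The decomposition is lossless:
#' [restack_slices()] reproduces the volume bit-exactly.
#'
#' @param vol An [mri_volume()].
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return List of [slice_image()] objects.
#' @export
extract_slices <- function(vol, plane) {
  stopifnot(inherits(vol, "mri_volume"))
  axis <- plane_axis(vol, plane)
  n <- dim(vol$intensities)[axis]
  lapply(seq_len(n), function(k) {
    slice_image(take_slice(vol$intensities, axis, k),
                labels = if (!is.null(vol$labels))
                  take_slice(vol$labels, axis, k),
                plane = plane, index = k, n_classes = vol$n_classes)
  })
}

#' Restack slices into a volume
#'
#' Inverse of [extract_slices()]: places each slice back at its index along
#' the axis its plane occupies under `axis_names`.
#'
#' @param slices List of [slice_image()]s from one volume, one plane.
#' @inheritParams mri_volume
#' @return An [mri_volume()].
#' @export
restack_slices <- function(slices, axis_names = c("coronal", "sagittal", "axial"),
                           subject_id = "restacked", n_classes = 4L) {
  if (length(slices) == 0L) stop_validation("no slices to restack")
  plane <- slices[[1L]]$plane
  axis <- which(axis_names == plane)
  sdim <- dim(slices[[1L]]$pixels)
  d <- integer(3L)
  d[axis] <- length(slices)
  d[-axis] <- sdim
  intens <- array(0, d)
  has_lab <- !is.null(slices[[1L]]$labels)
  labels <- if (has_lab) array(0L, d)
  for (s in slices) {
    k <- s$index
    if (axis == 1L) {
      intens[k, , ] <- s$pixels
      if (has_lab) labels[k, , ] <- s$labels
    } else if (axis == 2L) {
      intens[, k, ] <- s$pixels
      if (has_lab) labels[, k, ] <- s$labels
    } else {
      intens[, , k] <- s$pixels
      if (has_lab) labels[, , k] <- s$labels
    }
  }
  mri_volume(intens, labels = labels, axis_names = axis_names,
             subject_id = subject_id, n_classes = n_classes)
}

# PNG export --------------------------------------------------------------

#' Export a slice as PNG
#'
#' Intensity slices are windowed to `[0, 1]`; label slices are stored as raw
#' grey levels (class value / 255) so they reload exactly with
#' [read_label_png()].
#'
#' @param s A [slice_image()].
#' @param path Output path.
#' @param what `"intensity"` or `"labels"`.
#' @param window Intensity window (two values); defaults to the slice range.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(s, path, what = c("intensity", "labels"),
                            window = NULL) {
  what <- match.arg(what)
  if (what == "intensity") {
    x <- s$pixels
    window <- window %||% range(x)
    span <- diff(window)
    x <- if (span > 0) pmin(pmax((x - window[1L]) / span, 0), 1) else x * 0
  } else {
    if (is.null(s$labels)) stop_validation("slice has no labels")
    x <- s$labels / 255
  }
  png::writePNG(x, path)
  invisible(path)
}

#' Read a PNG-coded label map
#'
#' @param path PNG written by [write_slice_png()] with `what = "labels"`.
#' @return Integer label matrix.
#' @export
read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}
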