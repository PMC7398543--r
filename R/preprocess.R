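#' Zero-pad a slice to a square canvas
#'
#' Centres the slice on a `canvas` x `canvas` grid of zeros (labels are padded
#' with background, class 0). For the 208x176 axial geometry this adds 24 rows
#' top and bottom and 40 columns left and right of zeros; a 128-row slice gets
#' 64 rows top and bottom. Odd remainders put the extra row/column at the
#' bottom/right. The amounts are recorded in `pad_record` so [unpad()] is an
#' exact inverse; padding an already-padded slice accumulates the record.
#'
#' @param s A [slice_image()].
#' @param canvas Target side length in pixels (default 256).
#' @return The padded [slice_image()].
#' @export
#' @examples
#' s <- slice_image(matrix(1, 208, 176))
#' pad_to_canvas(s)$pad_record
pad_to_canvas <- function(s, canvas = 256L) {
  stopifnot(inherits(s, "slice_image"))
  h <- nrow(s$pixels); w <- ncol(s$pixels)
  if (h > canvas || w > canvas)
    stop_validation("slice %dx%d exceeds canvas %d; cropping is never silent",
                    h, w, canvas)
  top <- (canvas - h) %/% 2L
  bottom <- canvas - h - top
  left <- (canvas - w) %/% 2L
  right <- canvas - w - left
  px <- matrix(0, canvas, canvas)
  px[top + seq_len(h), left + seq_len(w)] <- s$pixels
  lb <- NULL
  if (!is.null(s$labels)) {
    lb <- matrix(0L, canvas, canvas)
    lb[top + seq_len(h), left + seq_len(w)] <- s$labels
  }
  prev <- s$pad_record %||% c(top = 0L, bottom = 0L, left = 0L, right = 0L)
  slice_image(px, labels = lb, plane = s$plane, index = s$index,
              pad_record = prev + c(top, bottom, left, right),
              n_classes = s$n_classes)
}

#' Remove recorded zero padding
#'
#' Exact inverse of [pad_to_canvas()]: strips the rows/columns listed in
#' `pad_record`, restoring the slice's native geometry.
#'
#' @param s A [slice_image()] with a populated `pad_record`.
#' @return The unpadded [slice_image()] (with an all-zero `pad_record`).
#' @export
unpad <- function(s) {
  stopifnot(inherits(s, "slice_image"))
  if (is.null(s$pad_record))
    stop_validation("slice has no pad_record; nothing to undo")
  p <- s$pad_record
  h <- nrow(s$pixels); w <- ncol(s$pixels)
  rows <- (p[["top"]] + 1L):(h - p[["bottom"]])
  cols <- (p[["left"]] + 1L):(w - p[["right"]])
  slice_image(s$pixels[rows, cols, drop = FALSE],
              labels = if (!is.null(s$labels)) s$labels[rows, cols, drop = FALSE],
              plane = s$plane, index = s$index,
              pad_record = c(top = 0L, bottom = 0L, left = 0L, right = 0L),
              n_classes = s$n_classes)
}

#' Normalize volume intensities
#'
#' `minmax` maps the volume's intensity range onto `[0, 1]` (the package
#' default ahead of training); `zscore` standardises to zero mean and unit
#' variance; `none` is the identity. Labels are untouched. A constant volume
#' maps to all zeros under both non-trivial modes.
#'
#' @param vol An [mri_volume()].
#' @param mode `"minmax"`, `"zscore"` or `"none"`.
#' @return The normalized [mri_volume()].
#' @export
normalize_intensity <- function(vol, mode = c("minmax", "zscore", "none")) {
  stopifnot(inherits(vol, "mri_volume"))
  mode <- match.arg(mode)
  x <- vol$intensities
  if (mode == "minmax") {
    r <- range(x)
    x <- if (diff(r) > 0) (x - r[1L]) / diff(r) else x * 0
  } else if (mode == "zscore") {
    s <- sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x * 0
  }
  vol$intensities <- x
  vol
}

#' Select evenly spaced training slices
#'
#' Picks `count` slice indices with a constant step of `interval`, centred in
#' `0:(n_slices - 1)` (0-based, matching the package's offset convention):
#' `start = floor((n_slices - 1 - (count - 1) * interval) / 2)`. Peripheral
#' slices carry little anatomy and neighbouring slices are nearly redundant,
#' so a centred, strided subset keeps both central and non-central slices in
#' the training set at a fraction of the cost; the canonical setting is 48
#' slices at interval 3 from a 176-slice scan.
#'
#' @param n_slices Number of slices available.
#' @param count Number of slices to select (default 48).
#' @param interval Step between selected slices (default 3).
#' @return Integer vector of `count` 0-based slice indices.
#' @export
#' @examples
#' select_training_slices(176)[1:4]
select_training_slices <- function(n_slices, count = 48L, interval = 3L) {
  n_slices <- as.integer(n_slices)
  count <- as.integer(count)
  interval <- as.integer(interval)
  if (count < 1L || interval < 1L)
    stop_validation("count and interval must be >= 1")
  span <- (count - 1L) * interval
  if (span >= n_slices)
    stop_validation(paste0("selection span %d does not fit in %d slices; ",
                           "at this interval at most count = %d is feasible"),
                    span + 1L, n_slices, (n_slices - 1L) %/% interval + 1L)
  start <- (n_slices - 1L - span) %/% 2L
  start + interval * (seq_len(count) - 1L)
}
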