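#' Patch grid container
#'
#' The invertible record of a tiling: the ordered patches, their 0-based
#' `(row, col)` top-left offsets in row-major order (top-left, top-right,
#' bottom-left, bottom-right for the 2x2 case), the canvas shape, and the
#' stride. [stitch()] consumes this record to reassemble the canvas.
#'
#' @param patches List of `P x P` matrices (or `P x P x C` score arrays).
#' @param offsets Integer matrix, one `(row, col)` 0-based anchor per patch.
#' @param canvas_shape Integer `(H, W)`.
#' @param patch_size Patch side length `P`.
#' @param overlapping Logical; `FALSE` for the exhaustive disjoint tiling.
#' @param stride Offset step; equals `patch_size` when non-overlapping.
#' @param label_patches Optional list of label-map patches, same order.
#' @return An object of class `patch_grid`.
#' @export
patch_grid <- function(patches, offsets, canvas_shape, patch_size,
                       overlapping = FALSE, stride = patch_size,
                       label_patches = NULL) {
  offsets <- matrix(as.integer(offsets), ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  if (length(patches) != nrow(offsets))
    stop_validation("got %d patches but %d offsets",
                    length(patches), nrow(offsets))
  if (any(offsets < 0L) ||
      any(offsets[, 1L] + patch_size > canvas_shape[1L]) ||
      any(offsets[, 2L] + patch_size > canvas_shape[2L]))
    stop_validation("offsets place patches outside the %s canvas",
                    paste(canvas_shape, collapse = "x"))
  structure(list(patches = patches, offsets = offsets,
                 canvas_shape = as.integer(canvas_shape),
                 patch_size = as.integer(patch_size),
                 overlapping = isTRUE(overlapping),
                 stride = as.integer(stride),
                 label_patches = label_patches),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %d on %s (%s, stride %d)\n",
              length(x$patches), x$patch_size,
              paste(x$canvas_shape, collapse = "x"),
              if (x$overlapping) "overlapping" else "non-overlapping",
              x$stride))
  invisible(x)
}

slice_pixels <- function(s) if (inherits(s, "slice_image")) s$pixels else s
slice_labels <- function(s) if (inherits(s, "slice_image")) s$labels else NULL

crop_at <- function(m, off, P) m[off[1L] + seq_len(P), off[2L] + seq_len(P)]

grid_from_offsets <- function(s, offsets, P, overlapping, stride) {
  px <- slice_pixels(s)
  lb <- slice_labels(s)
  patches <- lapply(seq_len(nrow(offsets)),
                    function(i) crop_at(px, offsets[i, ], P))
  label_patches <- if (!is.null(lb))
    lapply(seq_len(nrow(offsets)), function(i) crop_at(lb, offsets[i, ], P))
  patch_grid(patches, offsets, dim(px), P, overlapping = overlapping,
             stride = stride, label_patches = label_patches)
}

row_major_offsets <- function(rows, cols) {
  cbind(rep(rows, each = length(cols)), rep(cols, times = length(rows)))
}

#' Split a slice into non-overlapping patches
#'
#' The exhaustive disjoint tiling at the heart of the patch-wise method: a
#' 256x256 canvas with `P = 128` yields the four quadrants, in row-major
#' order. No pixel is duplicated or dropped, so [stitch()] restores the slice
#' bit-exactly; labels are split identically when present.
#'
#' @param s A [slice_image()] or plain matrix.
#' @param patch_size Patch side length `P` (default 128); must divide both
#'   canvas dimensions.
#' @return A [patch_grid()].
#' @export
#' @examples
#' g <- split_nonoverlapping(matrix(rnorm(256^2), 256, 256))
#' g$offsets
split_nonoverlapping <- function(s, patch_size = 128L) {
  px <- slice_pixels(s)
  P <- as.integer(patch_size)
  h <- nrow(px); w <- ncol(px)
  if (h %% P != 0L || w %% P != 0L)
    stop_validation("canvas %dx%d is not divisible by patch size %d", h, w, P)
  offsets <- row_major_offsets(seq(0L, h - P, by = P), seq(0L, w - P, by = P))
  grid_from_offsets(s, offsets, P, overlapping = FALSE, stride = P)
}

#' Split a slice into overlapping strided patches
#'
#' Sliding-window tiling used by the overlapping baseline harness: anchors at
#' every multiple of `stride` with the patch inside the canvas, row-major.
#' Trailing anchors are not force-included unless `include_edges = TRUE`
#' (which appends the final row/column anchors when the stride does not
#' divide `H - P`).
#'
#' @inheritParams split_nonoverlapping
#' @param stride Anchor step in pixels (default 8).
#' @param include_edges Append flush-right/bottom anchors when the grid does
#'   not reach them (default `FALSE`).
#' @return A [patch_grid()] with `overlapping = TRUE`.
#' @export
split_overlapping <- function(s, patch_size = 128L, stride = 8L,
                              include_edges = FALSE) {
  px <- slice_pixels(s)
  P <- as.integer(patch_size)
  stride <- as.integer(stride)
  h <- nrow(px); w <- ncol(px)
  if (stride < 1L) stop_validation("stride must be >= 1")
  if (P > h || P > w)
    stop_validation("patch size %d exceeds canvas %dx%d", P, h, w)
  anchors <- function(n) {
    a <- seq(0L, n - P, by = stride)
    if (include_edges && a[length(a)] != n - P) a <- c(a, n - P)
    a
  }
  offsets <- row_major_offsets(anchors(h), anchors(w))
  grid_from_offsets(s, offsets, P, overlapping = TRUE, stride = stride)
}

#' Stitch patches back into a canvas
#'
#' Non-overlapping grids are reassembled exactly (each patch copied to its
#' offset); `stitch(split_nonoverlapping(x))` is the identity. Overlapping
#' grids are combined by the per-pixel mean over all covering patches —
#' applied per channel when the patches are `P x P x C` class-score stacks,
#' so averaging happens before any argmax.
#'
#' @param g A [patch_grid()].
#' @param what `"pixels"` or `"labels"` (labels only for non-overlapping
#'   grids carrying label patches).
#' @return A matrix (2D patches) or `H x W x C` array (score stacks).
#' @export
stitch <- function(g, what = c("pixels", "labels")) {
  stopifnot(inherits(g, "patch_grid"))
  what <- match.arg(what)
  patches <- if (what == "pixels") g$patches else g$label_patches
  if (is.null(patches)) stop_validation("grid carries no label patches")
  P <- g$patch_size
  h <- g$canvas_shape[1L]; w <- g$canvas_shape[2L]
  nc <- if (length(dim(patches[[1L]])) == 3L) dim(patches[[1L]])[3L] else 1L
  if (!g$overlapping) {
    covered <- matrix(0L, h, w)
    for (i in seq_len(nrow(g$offsets))) {
      o <- g$offsets[i, ]
      covered[o[1L] + seq_len(P), o[2L] + seq_len(P)] <-
        covered[o[1L] + seq_len(P), o[2L] + seq_len(P)] + 1L
    }
    if (any(covered != 1L))
      stop_validation("non-overlapping grid does not tile the canvas exactly")
  }
  acc <- array(0, c(h, w, nc))
  cnt <- matrix(0, h, w)
  for (i in seq_len(nrow(g$offsets))) {
    o <- g$offsets[i, ]
    ri <- o[1L] + seq_len(P); ci <- o[2L] + seq_len(P)
    p <- patches[[i]]
    if (nc == 1L) dim(p) <- c(P, P, 1L)
    acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  for (k in seq_len(nc)) acc[, , k] <- acc[, , k] / cnt
  if (nc == 1L) acc <- acc[, , 1L]
  if (what == "labels" && nc == 1L) storage.mode(acc) <- "integer"
  acc
}

# one-hot targets ---------------------------------------------------------

#' Encode a label map as a multi-channel binary stack
#'
#' Converts a `C`-class label map into its `C` binary indicator channels in
#' the fixed order background, CSF, GM, WM (classes 0..3): channel `c` is 1
#' exactly where the label equals `c`, so per-pixel channel sums are 1. This
#' is the network's training target.
#'
#' @param m Integer label matrix with values in `0:(n_classes - 1)`.
#' @param n_classes Number of classes `C` (default 4).
#' @return Numeric `H x W x C` array of 0/1 indicators.
#' @export
encode_onehot <- function(m, n_classes = 4L) {
  m <- check_labels(as.matrix(m), n_classes)
  h <- nrow(m); w <- ncol(m)
  out <- array(0, c(h, w, n_classes))
  for (c in seq_len(n_classes)) out[, , c] <- (m == c - 1L) + 0
  out
}

#' Decode a channel stack to a label map
#'
#' Per-pixel argmax over the `C` channels; works on exact one-hot stacks and
#' on real-valued class scores alike. Ties are broken toward the lowest class
#' index (so a uniform score field decodes to background), making the decode
#' deterministic.
#'
#' @param o `H x W x C` array of class scores.
#' @param n_classes Expected channel count; checked against `dim(o)[3]`.
#' @return Integer label matrix with values in `0:(C - 1)`.
#' @export
decode_onehot <- function(o, n_classes = dim(o)[3L]) {
  d <- dim(o)
  if (length(d) != 3L || d[3L] != n_classes)
    stop_validation("expected an H x W x %d score stack, got dims %s",
                    n_classes, paste(d, collapse = "x"))
  m <- matrix(o, d[1L] * d[2L], d[3L])
  lab <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1L], d[2L])
}

# serialization -----------------------------------------------------------

#' Serialize / restore a patch grid
#'
#' Writes the patches (one `.rds` of arrays) plus a JSON manifest recording
#' offsets, canvas shape, patch size, stride, mode and ordering, so grids can
#' be streamed from disk and regenerated reproducibly.
#'
#' @param g A [patch_grid()].
#' @param dir Output directory (created if needed).
#' @return `dir` (write) / the restored [patch_grid()] (read).
#' @export
write_patch_grid <- function(g, dir) {
  stopifnot(inherits(g, "patch_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(n_patches = length(g$patches),
                   offsets = unname(g$offsets),
                   canvas_shape = g$canvas_shape,
                   patch_size = g$patch_size,
                   overlapping = g$overlapping,
                   stride = g$stride,
                   ordering = "row-major",
                   has_labels = !is.null(g$label_patches))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(list(patches = g$patches, label_patches = g$label_patches),
          file.path(dir, "patches.rds"))
  invisible(dir)
}

#' @rdname write_patch_grid
#' @export
read_patch_grid <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  blobs <- readRDS(file.path(dir, "patches.rds"))
  patch_grid(blobs$patches,
             offsets = matrix(unlist(manifest$offsets), ncol = 2L),
             canvas_shape = manifest$canvas_shape,
             patch_size = manifest$patch_size,
             overlapping = manifest$overlapping,
             stride = manifest$stride,
             label_patches = blobs$label_patches)
}
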