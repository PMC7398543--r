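#' Training configuration
#'
#' Hyperparameters for plain stochastic gradient descent with momentum,
#' minimizing the categorical cross-entropy between the per-pixel softmax
#' output and the one-hot target stack. The optimizer defaults follow the
#' method's published setting — learning rate 0.001 with a high momentum of
#' 0.99 — and no data augmentation is ever applied.
#'
#' @param learning_rate SGD step size (default 0.001).
#' @param momentum Momentum coefficient in `[0, 1)` (default 0.99).
#' @param epochs Number of passes over the patch set (default 50).
#' @param batch_size Patches per gradient step (default 32).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param init Weight initialization scheme (`"he_normal"` or
#'   `"glorot_uniform"`).
#' @param shuffle Reshuffle patch order each epoch (default `TRUE`).
#' @param reinitialize Re-draw the model's weights from `init`/`seed` before
#'   training (default `TRUE`, so a run is fully determined by its config).
#' @param validation_split Held-out fraction used only when `early_stopping`
#'   is enabled.
#' @param early_stopping Stop when validation loss stops improving
#'   (default `FALSE`).
#' @param patience Epochs without improvement tolerated when early stopping.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.99,
                         epochs = 50L, batch_size = 32L, seed = 1L,
                         init = "he_normal", shuffle = TRUE,
                         reinitialize = TRUE, validation_split = 0.1,
                         early_stopping = FALSE, patience = 5L) {
  if (learning_rate < 0) stop_validation("learning_rate must be >= 0")
  if (momentum < 0 || momentum >= 1)
    stop_validation("momentum must be in [0, 1)")
  if (batch_size < 1L) stop_validation("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), init = init,
                 shuffle = isTRUE(shuffle),
                 reinitialize = isTRUE(reinitialize),
                 validation_split = validation_split,
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience),
                 loss = "categorical_crossentropy"),
            class = "train_config")
}

#' Assemble a patch training set from labeled volumes
#'
#' The full preprocessing pipeline, applied identically to intensities and
#' labels: extract slices along `plane`, keep a centred strided subset
#' ([select_training_slices()]), zero-pad to the canvas, normalize
#' intensities, split into non-overlapping patches and one-hot encode the
#' label patches. Pair order is deterministic given the config and the input
#' order (volumes, then slices, then row-major patches).
#'
#' @param volumes List of labeled [mri_volume()]s.
#' @param plane Anatomical plane to slice along.
#' @param slice_count,slice_interval Training-slice selection (see
#'   [select_training_slices()]).
#' @param canvas_size Padding target (default 256).
#' @param normalize Intensity normalization mode (default `"minmax"`).
#' @param patch_size Patch side `P` (default 128).
#' @return List with elements `x` (list of `P x P` intensity patches), `y`
#'   (list of `P x P x C` one-hot stacks) and `meta` (tibble: subject, slice
#'   index, patch offsets).
#' @export
make_training_set <- function(volumes, plane = "axial", slice_count = 48L,
                              slice_interval = 3L, canvas_size = 256L,
                              normalize = "minmax", patch_size = 128L) {
  if (length(volumes) == 0L) stop_validation("no volumes supplied")
  xs <- list(); ys <- list()
  meta <- list()
  for (vol in volumes) {
    stopifnot(inherits(vol, "mri_volume"))
    if (is.null(vol$labels))
      stop_validation("volume '%s' has no labels", vol$subject_id)
    vol <- normalize_intensity(vol, normalize)
    slices <- extract_slices(vol, plane)
    keep <- select_training_slices(length(slices), slice_count,
                                   slice_interval) + 1L
    for (k in keep) {
      s <- pad_to_canvas(slices[[k]], canvas_size)
      g <- split_nonoverlapping(s, patch_size)
      for (i in seq_along(g$patches)) {
        xs[[length(xs) + 1L]] <- g$patches[[i]]
        ys[[length(ys) + 1L]] <- encode_onehot(g$label_patches[[i]],
                                               vol$n_classes)
        meta[[length(meta) + 1L]] <-
          tibble::tibble(subject_id = vol$subject_id, slice = k,
                         offset_row = unname(g$offsets[i, 1L]),
                         offset_col = unname(g$offsets[i, 2L]))
      }
    }
  }
  list(x = xs, y = ys, meta = do.call(rbind, meta))
}

cross_entropy <- function(probs, target) {
  -sum(target * log(pmax(probs, 1e-12))) / (dim(probs)[1L] * dim(probs)[2L])
}

pixel_accuracy <- function(probs, target) {
  mean(decode_onehot(probs) == decode_onehot(target))
}

#' Train the patch-wise U-net
#'
#' Plain SGD with momentum on the categorical cross-entropy, exactly as
#' configured — no augmentation, no implicit validation split. Weights are
#' (re-)initialized from `cfg$init` with `cfg$seed`, so a fixed seed gives an
#' identical loss trace and identical trained weights across runs. Per-epoch
#' mean loss and mean patch pixel-accuracy are recorded in the returned
#' model's `history` (a tibble; see [tidy.unet_model()]).
#'
#' @param model A `unet_model` from [build_unet()].
#' @param data Patch pairs from [make_training_set()].
#' @param cfg A [train_config()].
#' @param verbose Print a line per epoch.
#' @return The trained `unet_model`.
#' @export
train_unet <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  n <- length(data$x)
  if (n == 0L) stop_validation("empty training set")
  d1 <- dim(data$y[[1L]])
  if (d1[3L] != model$spec$n_classes)
    stop_validation("target has %d channels but the model produces %d",
                    d1[3L], model$spec$n_classes)
  set.seed(cfg$seed)
  if (cfg$reinitialize)
    model$weights <- init_conv_weights(model$topology, cfg$init, cfg$seed)

  val_idx <- integer()
  if (cfg$early_stopping && cfg$validation_split > 0) {
    val_idx <- sample.int(n, max(1L, floor(cfg$validation_split * n)))
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  velocity <- lapply(model$weights, function(p)
    list(w = p$w * 0, b = p$b * 0))
  history <- vector("list", cfg$epochs)
  best_val <- Inf; stall <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    order <- if (cfg$shuffle) sample(train_idx) else train_idx
    ep_loss <- 0; ep_acc <- 0
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    for (batch in batches) {
      gsum <- NULL
      for (i in batch) {
        fw <- unet_forward(model, data$x[[i]], keep_cache = TRUE)
        target <- data$y[[i]]
        loss <- cross_entropy(fw$probs, target)
        if (!is.finite(loss))
          stop(sprintf(paste0("training diverged (non-finite loss) at epoch ",
                              "%d; lr = %g, momentum = %g"),
                       epoch, cfg$learning_rate, cfg$momentum))
        ep_loss <- ep_loss + loss
        ep_acc <- ep_acc + pixel_accuracy(fw$probs, target)
        dlogits <- (fw$probs - target) / (dim(target)[1L] * dim(target)[2L])
        pg <- unet_backward(model, fw, dlogits)
        gsum <- if (is.null(gsum)) pg else
          mapply(function(a, g) list(w = a$w + g$w, b = a$b + g$b),
                 gsum, pg, SIMPLIFY = FALSE)
      }
      nb <- length(batch)
      for (nm in names(gsum)) {
        velocity[[nm]]$w <- cfg$momentum * velocity[[nm]]$w -
          cfg$learning_rate * gsum[[nm]]$w / nb
        velocity[[nm]]$b <- cfg$momentum * velocity[[nm]]$b -
          cfg$learning_rate * gsum[[nm]]$b / nb
        model$weights[[nm]]$w <- model$weights[[nm]]$w + velocity[[nm]]$w
        model$weights[[nm]]$b <- model$weights[[nm]]$b + velocity[[nm]]$b
      }
    }
    val_loss <- NA_real_
    if (length(val_idx)) {
      val_loss <- mean(vapply(val_idx, function(i)
        cross_entropy(unet_forward(model, data$x[[i]])$probs, data$y[[i]]), 1))
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / length(order),
      accuracy = ep_acc / length(order), val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f", epoch,
                      ep_loss / length(order), ep_acc / length(order)))
    if (cfg$early_stopping && length(val_idx)) {
      if (val_loss < best_val - 1e-6) { best_val <- val_loss; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= cfg$patience) { history <- history[seq_len(epoch)]; break }
    }
  }
  model$history <- do.call(rbind, history)
  model$train_config <- cfg
  model
}

#' @rdname train_unet
#' @param x A trained `unet_model`.
#' @param ... Unused.
#' @export
tidy.unet_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble(epoch = integer(),
                                                loss = numeric(),
                                                accuracy = numeric()))
  tibble::as_tibble(x$history)
}

#' @rdname train_unet
#' @export
glance.unet_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = count_parameters(x),
    patch_size = x$spec$patch_size,
    base_filters = x$spec$base_filters,
    depth = x$spec$depth,
    n_classes = x$spec$n_classes,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_
                 else x$history$loss[nrow(x$history)],
    final_accuracy = if (is.null(x$history)) NA_real_
                     else x$history$accuracy[nrow(x$history)])
}

#' Segment a canvas slice patch-wise
#'
#' Splits the slice into patches, runs the network on each patch, stitches
#' the class-score stacks back onto the canvas (per-pixel mean over covering
#' patches in overlapping mode, before any argmax) and decodes the stitched
#' scores to a label map. With `mode = "overlap"` and `stride = patch_size`
#' the result is identical to non-overlapping prediction.
#'
#' @param model A trained `unet_model`.
#' @param s A [slice_image()] (or matrix), canvas-sized and normalized like
#'   the training data.
#' @param mode `"nonoverlap"` (the patch-wise method) or `"overlap"` (the
#'   strided baseline harness).
#' @param stride Anchor stride for overlapping mode (default 8).
#' @param include_edges Passed to [split_overlapping()].
#' @return Integer label matrix (classes `0:(C-1)`).
#' @export
predict_slice <- function(model, s, mode = c("nonoverlap", "overlap"),
                          stride = 8L, include_edges = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  mode <- match.arg(mode)
  P <- model$spec$patch_size
  g <- if (mode == "nonoverlap") split_nonoverlapping(s, P)
       else split_overlapping(s, P, stride, include_edges)
  g$patches <- lapply(g$patches, function(p) unet_forward(model, p)$probs)
  scores <- stitch(g)
  decode_onehot(scores, model$spec$n_classes)
}

#' Segment a whole volume
#'
#' Slice-wise prediction along `plane`: the volume is intensity-normalized,
#' each slice padded to the canvas, segmented with [predict_slice()],
#' unpadded back to native geometry and restacked, so the returned volume
#' carries predicted labels at the input's own shape.
#'
#' @param model A trained `unet_model`.
#' @param vol An [mri_volume()].
#' @param plane Anatomical plane to slice along.
#' @param canvas_size Padding target (default 256).
#' @param normalize Intensity normalization mode used in training.
#' @inheritParams predict_slice
#' @return The input [mri_volume()] with `labels` replaced by predictions.
#' @export
predict_volume <- function(model, vol, plane = "axial", canvas_size = 256L,
                           normalize = "minmax",
                           mode = c("nonoverlap", "overlap"), stride = 8L) {
  stopifnot(inherits(model, "unet_model"), inherits(vol, "mri_volume"))
  mode <- match.arg(mode)
  nvol <- normalize_intensity(vol, normalize)
  slices <- extract_slices(nvol, plane)
  pred <- lapply(slices, function(s) {
    ps <- pad_to_canvas(s, canvas_size)
    lab <- predict_slice(model, ps, mode = mode, stride = stride)
    unpad(slice_image(ps$pixels, labels = lab, plane = s$plane,
                      index = s$index, pad_record = ps$pad_record,
                      n_classes = vol$n_classes))
  })
  out <- restack_slices(pred, axis_names = vol$axis_names,
                        subject_id = vol$subject_id,
                        n_classes = vol$n_classes)
  vol$labels <- out$labels
  vol
}
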