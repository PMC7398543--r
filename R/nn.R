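# Forward and backward passes over the layer graph built by unet_topology().
# Feature maps are H x W x C arrays; convolution weights are
# (kh*kw*cin) x cout matrices matching the im2col layout of the C++ kernels.

as_feature_cube <- function(x, in_channels = 1L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3L] != in_channels)
    stop_validation("expected %d input channel(s), got %d",
                    in_channels, dim(x)[3L])
  x
}

# Runs the graph, returning post-activation maps for every layer plus the
# max-pooling argmax caches needed by the backward pass.
unet_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  x <- as_feature_cube(x, spec$in_channels)
  if (dim(x)[1L] != spec$patch_size || dim(x)[2L] != spec$patch_size)
    stop_validation("input is %dx%d but the model expects %dx%d patches",
                    dim(x)[1L], dim(x)[2L], spec$patch_size, spec$patch_size)
  acts <- list()
  pool_idx <- list()
  for (l in model$topology) {
    a <- switch(l$type,
      input = x,
      conv = {
        z <- .conv2d_forward(acts[[l$inputs]], model$weights[[l$name]]$w,
                             model$weights[[l$name]]$b,
                             l$kernel[1L], l$kernel[2L])
        if (l$activation == "relu") z[z < 0] <- 0
        z
      },
      maxpool = {
        r <- .maxpool_forward(acts[[l$inputs]])
        if (keep_cache) pool_idx[[l$name]] <- r$idx
        r$y
      },
      upsample = .upsample_forward(acts[[l$inputs]]),
      concat = {
        a1 <- acts[[l$inputs[1L]]]
        a2 <- acts[[l$inputs[2L]]]
        array(c(a1, a2), c(dim(a1)[1:2], dim(a1)[3L] + dim(a2)[3L]))
      })
    acts[[l$name]] <- a
  }
  out_name <- model$topology[[length(model$topology)]]$name
  list(logits = acts[[out_name]],
       probs = .softmax_channels(acts[[out_name]]),
       acts = if (keep_cache) acts,
       pool_idx = if (keep_cache) pool_idx,
       out_name = out_name)
}

# Backpropagates d(loss)/d(logits) through the cached graph; returns per-layer
# weight/bias gradients.
unet_backward <- function(model, cache, dlogits) {
  grads_out <- list()
  grads_out[[cache$out_name]] <- dlogits
  pgrads <- list()
  bump <- function(lst, nm, g) {
    lst[[nm]] <- if (is.null(lst[[nm]])) g else lst[[nm]] + g
    lst
  }
  for (l in rev(model$topology)) {
    g <- grads_out[[l$name]]
    if (is.null(g) || l$type == "input") next
    if (l$type == "conv") {
      if (l$activation == "relu") g <- g * (cache$acts[[l$name]] > 0)
      bw <- .conv2d_backward(cache$acts[[l$inputs]],
                             model$weights[[l$name]]$w, g,
                             l$kernel[1L], l$kernel[2L])
      pgrads[[l$name]] <- list(w = bw$gw, b = as.numeric(bw$gb))
      grads_out <- bump(grads_out, l$inputs, bw$gx)
    } else if (l$type == "maxpool") {
      din <- dim(cache$acts[[l$inputs]])
      gx <- .maxpool_backward(cache$pool_idx[[l$name]], g, din[1L], din[2L])
      grads_out <- bump(grads_out, l$inputs, gx)
    } else if (l$type == "upsample") {
      grads_out <- bump(grads_out, l$inputs, .upsample_backward(g))
    } else if (l$type == "concat") {
      c1 <- dim(cache$acts[[l$inputs[1L]]])[3L]
      grads_out <- bump(grads_out, l$inputs[1L], g[, , seq_len(c1), drop = FALSE])
      grads_out <- bump(grads_out, l$inputs[2L],
                        g[, , (c1 + 1L):dim(g)[3L], drop = FALSE])
    }
  }
  pgrads
}

#' Forward pass on a single patch
#'
#' Runs the network on one `P x P` intensity patch and returns the per-pixel
#' class probabilities (softmax across the `C` channels, so every pixel's
#' channel sum is 1).
#'
#' @param model A `unet_model` from [build_unet()].
#' @param x `P x P` matrix (or `P x P x 1` array), normalized like the
#'   training data.
#' @return `P x P x C` probability array.
#' @export
predict_patch <- function(model, x) {
  stopifnot(inherits(model, "unet_model"))
  unet_forward(model, x)$probs
}
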