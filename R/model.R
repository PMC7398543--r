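#' Declarative U-net architecture specification
#'
#' Describes the patch-wise multi-class U-net: `depth` encoder stages of two
#' same-padding 3x3 convolutions (ReLU) followed by 2x2 max pooling with the
#' filter count doubling at each stage, a two-convolution bottleneck at
#' `base_filters * 2^depth` channels, and a mirrored decoder where each stage
#' upsamples x2 (nearest neighbour), halves the channels with a 2x2
#' convolution, concatenates the matching encoder feature map, and applies two
#' 3x3 convolutions. A 1x1 convolution maps the final `base_filters` channels
#' to `n_classes` scores, normalized per pixel by a softmax. At the defaults
#' (patch 128, 64 base filters, depth 3, 4 classes) the bottleneck operates at
#' 16x16x512 and the network holds 7,696,388 trainable parameters.
#'
#' @param patch_size Input patch side `P`; must be divisible by `2^depth`.
#' @param in_channels Input channels (1 for T1-weighted intensity patches).
#' @param base_filters Filters `F` in the first encoder stage (default 64).
#' @param depth Number of pooling stages (default 3).
#' @param n_classes Output classes `C` (default 4).
#' @param kernel Encoder/decoder convolution kernel side (default 3).
#' @param upconv_kernel Kernel side of the post-upsampling convolution
#'   (default 2).
#' @return An object of class `unet_spec`.
#' @export
#' @examples
#' unet_spec()
#' unet_spec(patch_size = 64, base_filters = 8)
unet_spec <- function(patch_size = 128L, in_channels = 1L, base_filters = 64L,
                      depth = 3L, n_classes = 4L, kernel = 3L,
                      upconv_kernel = 2L) {
  patch_size <- as.integer(patch_size)
  depth <- as.integer(depth)
  if (patch_size %% 2L^depth != 0L)
    stop_validation("patch size %d is not divisible by 2^depth = %d",
                    patch_size, 2L^depth)
  if (base_filters < 1L || n_classes < 2L)
    stop_validation("base_filters must be >= 1 and n_classes >= 2")
  structure(list(patch_size = patch_size,
                 in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 depth = depth,
                 n_classes = as.integer(n_classes),
                 kernel = as.integer(kernel),
                 upconv_kernel = as.integer(upconv_kernel),
                 bottleneck_filters = as.integer(base_filters * 2L^depth)),
            class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  cat(sprintf(paste0("<unet_spec> patch %d, base filters %d, depth %d, ",
                     "%d classes (bottleneck %dx%dx%d)\n"),
              x$patch_size, x$base_filters, x$depth, x$n_classes,
              x$patch_size %/% 2L^x$depth, x$patch_size %/% 2L^x$depth,
              x$bottleneck_filters))
  invisible(x)
}

#' Read / write a `unet_spec` as YAML
#'
#' @param spec A [unet_spec()].
#' @param path YAML file path.
#' @return `path` (write) / a [unet_spec()] (read).
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "unet_spec"))
  yaml::write_yaml(unclass(spec)[setdiff(names(spec), "bottleneck_filters")],
                   path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  do.call(unet_spec, yaml::read_yaml(path))
}

conv_params <- function(kh, kw, cin, cout) (kh * kw * cin + 1L) * cout

# Ordered layer graph implied by a spec. Naming at the defaults follows the
# conventional auto-numbering: conv2d_1..conv2d_18, max_pooling2d_k,
# up_sampling2d_k, concatenated_k.
unet_topology <- function(spec) {
  P <- spec$patch_size; FF <- spec$base_filters
  d <- spec$depth; C <- spec$n_classes; k <- spec$kernel
  layers <- list()
  conv_i <- 0L
  add <- function(name, type, kernel, in_ch, out_ch, out_hw, activation,
                  inputs) {
    layers[[length(layers) + 1L]] <<- list(
      name = name, type = type, kernel = kernel,
      in_channels = as.integer(in_ch), out_channels = as.integer(out_ch),
      out_shape = c(out_hw, out_hw, as.integer(out_ch)),
      activation = activation, inputs = inputs,
      n_params = if (type == "conv")
        conv_params(kernel[1L], kernel[2L], in_ch, out_ch) else 0L)
    invisible(NULL)
  }
  conv <- function(kern, in_ch, out_ch, out_hw, inputs, activation = "relu") {
    conv_i <<- conv_i + 1L
    nm <- paste0("conv2d_", conv_i)
    add(nm, "conv", c(kern, kern), in_ch, out_ch, out_hw, activation, inputs)
    nm
  }
  add("input_1", "input", c(NA_integer_, NA_integer_), spec$in_channels,
      spec$in_channels, P, "linear", character())
  prev <- "input_1"; hw <- P; ch <- spec$in_channels
  skip <- character(d)
  for (s in seq_len(d)) {
    f <- FF * 2L^(s - 1L)
    prev <- conv(k, ch, f, hw, prev)
    prev <- conv(k, f, f, hw, prev)
    skip[s] <- prev
    hw <- hw %/% 2L
    nm <- paste0("max_pooling2d_", s)
    add(nm, "maxpool", c(2L, 2L), f, f, hw, "linear", prev)
    prev <- nm; ch <- f
  }
  f <- FF * 2L^d
  prev <- conv(k, ch, f, hw, prev)
  prev <- conv(k, f, f, hw, prev)
  for (u in seq_len(d)) {
    hw <- hw * 2L
    nm <- paste0("up_sampling2d_", u)
    add(nm, "upsample", c(2L, 2L), f, f, hw, "linear", prev)
    up <- conv(spec$upconv_kernel, f, f %/% 2L, hw, nm)
    f <- f %/% 2L
    enc <- skip[d + 1L - u]
    nm <- paste0("concatenated_", u)
    add(nm, "concat", c(NA_integer_, NA_integer_), 2L * f, 2L * f, hw,
        "linear", c(enc, up))
    prev <- conv(k, 2L * f, f, hw, nm)
    prev <- conv(k, f, f, hw, prev)
  }
  conv(1L, f, C, hw, prev, activation = "softmax")
  layers
}

topology_records <- function(topology) {
  tibble::tibble(
    name = vapply(topology, `[[`, "", "name"),
    type = vapply(topology, `[[`, "", "type"),
    kernel_h = vapply(topology, function(l) l$kernel[1L], 1L),
    kernel_w = vapply(topology, function(l) l$kernel[2L], 1L),
    in_channels = vapply(topology, `[[`, 1L, "in_channels"),
    out_channels = vapply(topology, `[[`, 1L, "out_channels"),
    out_h = vapply(topology, function(l) l$out_shape[1L], 1L),
    out_w = vapply(topology, function(l) l$out_shape[2L], 1L),
    out_c = vapply(topology, function(l) l$out_shape[3L], 1L),
    n_params = vapply(topology, function(l) as.integer(l$n_params), 1L),
    activation = vapply(topology, `[[`, "", "activation"),
    connected_to = lapply(topology, `[[`, "inputs")
  )
}

init_conv_weights <- function(topology, init = c("he_normal", "glorot_uniform"),
                              seed = 42L) {
  init <- match.arg(init)
  set.seed(as.integer(seed))
  weights <- list()
  for (l in topology) {
    if (l$type != "conv") next
    fan_in <- l$kernel[1L] * l$kernel[2L] * l$in_channels
    fan_out <- l$kernel[1L] * l$kernel[2L] * l$out_channels
    n <- fan_in * l$out_channels
    w <- if (init == "he_normal") {
      rnorm(n, sd = sqrt(2 / fan_in))
    } else {
      lim <- sqrt(6 / (fan_in + fan_out))
      runif(n, -lim, lim)
    }
    weights[[l$name]] <- list(w = matrix(w, fan_in, l$out_channels),
                              b = numeric(l$out_channels))
  }
  weights
}

#' Build the patch-wise U-net
#'
#' Instantiates the network described by a [unet_spec()]: allocates and
#' initializes every convolution's weights and produces the layer-record
#' table (name, type, output shape, parameter count, connectivity) that
#' mirrors the built network exactly — the closed form
#' `(kh*kw*c_in + 1)*c_out` per convolution, with zero-parameter pooling,
#' upsampling and concatenation rows.
#'
#' @param spec A [unet_spec()].
#' @param init Weight initialization: `"he_normal"` (default, suited to ReLU
#'   stacks) or `"glorot_uniform"`.
#' @param seed Integer seed for the initialization draw.
#' @return An object of class `unet_model` with elements `spec`, `records`
#'   (a tibble of layer records) and `weights`.
#' @export
#' @examples
#' m <- build_unet(unet_spec(patch_size = 32, base_filters = 4, depth = 2))
#' count_parameters(m)
build_unet <- function(spec, init = "he_normal", seed = 42L) {
  stopifnot(inherits(spec, "unet_spec"))
  topology <- unet_topology(spec)
  structure(list(spec = spec,
                 topology = topology,
                 records = topology_records(topology),
                 weights = init_conv_weights(topology, init, seed),
                 init = init, seed = as.integer(seed),
                 history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %d layers, %s trainable parameters%s\n",
              nrow(x$records),
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)"
              else sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

#' Count trainable parameters
#'
#' Closed-form accounting from the layer records: the total over all layers,
#' or a single named layer's count. The result is independently verifiable
#' against the instantiated weight arrays (see [model_weight_count()]).
#'
#' @param x A `unet_model` or its layer-record tibble.
#' @param layer Optional layer name (e.g. `"conv2d_8"`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(x, layer = NULL) {
  records <- if (inherits(x, "unet_model")) x$records else x
  if (is.null(layer)) return(sum(records$n_params))
  i <- match(layer, records$name)
  if (is.na(i)) stop_validation("no layer named '%s'", layer)
  records$n_params[i]
}

#' Parameter count reported by the instantiated network
#'
#' Sums the lengths of every allocated weight and bias array — the
#' "framework-reported" count that must equal the closed form of
#' [count_parameters()] exactly.
#'
#' @param model A `unet_model`.
#' @param layer Optional layer name.
#' @return Integer parameter count.
#' @export
model_weight_count <- function(model, layer = NULL) {
  stopifnot(inherits(model, "unet_model"))
  ws <- if (is.null(layer)) model$weights else {
    if (is.null(model$weights[[layer]]))
      stop_validation("no weighted layer named '%s'", layer)
    model$weights[layer]
  }
  sum(vapply(ws, function(p) length(p$w) + length(p$b), 1))
}

#' Architecture summary table
#'
#' Renders the layer-record table for any spec in the familiar
#' name / type / output shape / parameter count / connectivity layout, as a
#' tibble, aligned text, or JSON (which round-trips losslessly).
#'
#' @param x A `unet_model` or layer-record tibble.
#' @param format `"tibble"`, `"text"` or `"json"`.
#' @return A tibble, character vector of lines, or JSON string.
#' @export
summarize_architecture <- function(x, format = c("tibble", "text", "json")) {
  format <- match.arg(format)
  records <- if (inherits(x, "unet_model")) x$records else x
  if (format == "tibble") return(records)
  pretty <- data.frame(
    name = records$name,
    type = records$type,
    output_shape = sprintf("%dx%dx%d", records$out_h, records$out_w,
                           records$out_c),
    n_params = records$n_params,
    connected_to = vapply(records$connected_to, paste, "", collapse = ","))
  if (format == "json")
    return(as.character(jsonlite::toJSON(pretty, dataframe = "rows",
                                         auto_unbox = FALSE, digits = NA)))
  widths <- vapply(names(pretty), function(nm)
    max(nchar(c(nm, as.character(pretty[[nm]])))), 1)
  fmt_row <- function(vals)
    paste(mapply(formatC, as.character(vals), width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  c(fmt_row(names(pretty)),
    vapply(seq_len(nrow(pretty)),
           function(i) fmt_row(unlist(pretty[i, ], use.names = FALSE)), ""))
}

#' Save / load a trained model
#'
#' Checkpoints embed the [unet_spec()], the weights, the initialization
#' scheme/seed and the training history, so they are self-describing.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) / the restored `unet_model` (load).
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model"))
    stop_format("'%s' is not a unet_model checkpoint", path)
  model
}
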