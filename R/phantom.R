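#' Phantom generator configuration
#'
#' Parameters of the synthetic four-tissue head phantom used to exercise the
#' whole pipeline without patient data. Each slice is a nest of randomized
#' ellipses — an outer CSF rim, a grey-matter band with sinusoidal "sulcal"
#' boundary perturbations, a white-matter core carrying small CSF
#' "ventricles" — scaled by a head-size profile that peaks at the volume
#' centre, so peripheral slices carry little anatomy. Intensities mimic T1
#' contrast (CSF dark, WM bright) and are corrupted by a smooth multiplicative
#' bias field and additive Gaussian noise; labels are the noiseless geometry.
#'
#' @param canvas Slice side length in pixels (default 256; 64 for fast
#'   desk-scale work).
#' @param n_slices Slices per volume.
#' @param tissue_means Mean intensity per class in (background, CSF, GM, WM)
#'   order; must be strictly increasing to enforce T1-like contrast.
#' @param noise_sd Additive Gaussian noise sigma (default 0.05).
#' @param bias_amplitude Relative amplitude of the low-frequency
#'   multiplicative bias field (default 0.1; the data it emulates are
#'   bias-corrected, so the default is mild).
#' @param shape_jitter Scale of random boundary/centre perturbations
#'   (default 0.05, as a fraction of the canvas).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(canvas = 256L, n_slices = 32L,
                           tissue_means = c(0.0, 0.2, 0.5, 0.8),
                           noise_sd = 0.05, bias_amplitude = 0.1,
                           shape_jitter = 0.05, seed = 1L) {
  if (length(tissue_means) != 4L || any(diff(tissue_means) <= 0))
    stop_validation("tissue_means must be 4 strictly increasing values")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  structure(list(canvas = as.integer(canvas), n_slices = as.integer(n_slices),
                 tissue_means = as.numeric(tissue_means),
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 shape_jitter = shape_jitter, seed = as.integer(seed)),
            class = "phantom_config")
}

# ellipse interior test with a sinusoidal radial perturbation
inside_blob <- function(rr, cc, centre, radii, wobble_amp = 0, wobble_k = 0,
                        wobble_phase = 0) {
  dr <- rr - centre[1L]; dc <- cc - centre[2L]
  theta <- atan2(dc, dr)
  scale <- 1 + wobble_amp * sin(wobble_k * theta + wobble_phase)
  (dr / (radii[1L] * scale))^2 + (dc / (radii[2L] * scale))^2 <= 1
}

#' Generate one phantom slice
#'
#' `slice_frac` locates the slice within the head (0 and 1 are the poles,
#' 0.5 the centre); the in-plane anatomy is scaled by the spherical-cap
#' profile `sqrt(1 - (2 (slice_frac - 0.5))^2)`, so near-polar slices may
#' legitimately contain no anatomy at all — emulating non-central slices.
#' Deterministic given `cfg$seed` and `slice_frac`.
#'
#' @param cfg A [phantom_config()].
#' @param slice_frac Position in `[0, 1]` along the stack.
#' @param index Slice index stored on the result.
#' @return A labeled [slice_image()].
#' @export
generate_phantom_slice <- function(cfg, slice_frac, index = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (slice_frac < 0 || slice_frac > 1)
    stop_validation("slice_frac must lie in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.numeric(cfg$seed) * 10007 + round(slice_frac * 8191)) %%
             2147483629)

  n <- cfg$canvas
  head_scale <- sqrt(pmax(0, 1 - (2 * (slice_frac - 0.5))^2))
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  mid <- (n + 1) / 2
  jit <- function(k = 1) rnorm(k, sd = cfg$shape_jitter * n / 4)

  labels <- matrix(0L, n, n)
  if (head_scale > 0.05) {
    centre <- c(mid + jit(), mid + jit())
    r_head <- c(0.44, 0.38) * n * head_scale
    r_gm <- r_head * (0.90 + jit() / n)
    r_wm <- r_head * (0.62 + jit() / n)
    head <- inside_blob(rr, cc, centre, r_head)
    gm <- inside_blob(rr, cc, centre, r_gm,
                      wobble_amp = 0.06, wobble_k = 9,
                      wobble_phase = runif(1, 0, 2 * pi))
    wm <- inside_blob(rr, cc, centre, r_wm,
                      wobble_amp = 0.10, wobble_k = 7,
                      wobble_phase = runif(1, 0, 2 * pi))
    labels[head] <- 1L   # CSF rim
    labels[gm] <- 2L
    labels[wm] <- 3L
    # paired CSF ventricles inside the WM core, present while the core is wide
    if (head_scale > 0.35) {
      v_r <- c(0.10, 0.045) * n * head_scale
      for (side in c(-1, 1)) {
        vc <- centre + c(-0.02 * n * head_scale + jit() / 2,
                         side * 0.09 * n * head_scale + jit() / 2)
        vent <- inside_blob(rr, cc, vc, v_r) & wm
        labels[vent] <- 1L
      }
    }
  }

  intens <- cfg$tissue_means[labels + 1L]
  dim(intens) <- c(n, n)
  if (cfg$bias_amplitude > 0) {
    ph <- runif(2, 0, 2 * pi)
    bias <- cfg$bias_amplitude *
      cos(pi * rr / n + ph[1L]) * cos(pi * cc / n + ph[2L])
    intens <- intens * (1 + bias)
  }
  if (cfg$noise_sd > 0)
    intens <- intens + matrix(rnorm(n * n, sd = cfg$noise_sd), n, n)
  slice_image(intens, labels = labels, plane = "axial", index = index)
}

#' Generate a labeled phantom volume
#'
#' Stacks `cfg$n_slices` phantom slices with `slice_frac = (i-1)/(n-1)`,
#' giving a volume whose central slices carry the most anatomy. Labels are
#' attached; the volume writes/reloads exactly via [write_volume()].
#'
#' @param cfg A [phantom_config()].
#' @param subject_id Identifier for the volume.
#' @return A labeled [mri_volume()] (axial plane along the third axis).
#' @export
generate_phantom_volume <- function(cfg, subject_id = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$n_slices < 2L) stop_validation("n_slices must be >= 2")
  slices <- lapply(seq_len(cfg$n_slices), function(i) {
    generate_phantom_slice(cfg, (i - 1) / (cfg$n_slices - 1), index = i)
  })
  restack_slices(slices, subject_id = subject_id)
}

#' Generate a reproducible train/test phantom suite
#'
#' Draws disjoint per-volume seeds from a master seed and generates
#' `n_train` training and `n_test` test volumes (the canonical split is
#' 20/30). The manifest records every per-volume seed, so any volume — or
#' the whole suite — can be regenerated bit-exactly from it.
#'
#' @param n_train,n_test Number of training / test volumes.
#' @param cfg A [phantom_config()]; its `seed` field is superseded by the
#'   per-volume seeds drawn here.
#' @param seed Master seed for the suite.
#' @return List with `train` and `test` (lists of [mri_volume()]s) and
#'   `manifest` (tibble: role, subject_id, seed, plus the generator config).
#' @export
make_phantom_suite <- function(n_train = 20L, n_test = 30L, cfg = phantom_config(),
                               seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (n_train < 1L || n_test < 1L) stop_validation("counts must be >= 1")
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483629L, n_train + n_test)
  role <- rep(c("train", "test"), c(n_train, n_test))
  ids <- sprintf("%s_%02d", role, c(seq_len(n_train), seq_len(n_test)))
  vols <- lapply(seq_along(seeds), function(i) {
    ci <- cfg; ci$seed <- seeds[i]
    generate_phantom_volume(ci, subject_id = ids[i])
  })
  manifest <- tibble::tibble(role = role, subject_id = ids, seed = seeds,
                             canvas = cfg$canvas, n_slices = cfg$n_slices,
                             noise_sd = cfg$noise_sd,
                             bias_amplitude = cfg$bias_amplitude,
                             shape_jitter = cfg$shape_jitter,
                             master_seed = as.integer(seed))
  list(train = vols[role == "train"], test = vols[role == "test"],
       manifest = manifest)
}

#' Closed-form phantom segmenter
#'
#' Thresholds intensities at the midpoints between consecutive tissue means.
#' On a noiseless, bias-free phantom this recovers the label map exactly,
#' giving a perfect reference segmentation against which the metric suite
#' must report DSC = JI = 1, HD = 0 and MSE = 0.
#'
#' @param pixels Intensity matrix.
#' @param tissue_means Increasing per-class means (as in [phantom_config()]).
#' @return Integer label matrix.
#' @export
threshold_segment <- function(pixels, tissue_means = c(0.0, 0.2, 0.5, 0.8)) {
  cuts <- (tissue_means[-1L] + tissue_means[-length(tissue_means)]) / 2
  lab <- matrix(0L, nrow(pixels), ncol(pixels))
  for (k in seq_along(cuts)) lab[pixels > cuts[k]] <- k
  lab
}
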