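# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the library's own code paths.

# O(n*m) Hausdorff over explicit coordinate sets
hausdorff_oracle <- function(a, b) {
  pa <- which(a != 0, arr.ind = TRUE)
  pb <- which(b != 0, arr.ind = TRUE)
  directed <- function(p, q) {
    max(apply(p, 1L, function(r) {
      min(sqrt((q[, 1L] - r[1L])^2 + (q[, 2L] - r[2L])^2))
    }))
  }
  max(directed(pa, pb), directed(pb, pa))
}

# set-based Jaccard/Dice on pixel index sets
jaccard_oracle <- function(a, b) {
  sa <- which(a != 0); sb <- which(b != 0)
  if (length(union(sa, sb)) == 0L) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

dice_oracle <- function(a, b) {
  sa <- which(a != 0); sb <- which(b != 0)
  if (length(sa) + length(sb) == 0L) return(1)
  2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}

mse_oracle <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      tot <- tot + (a[i, j] - b[i, j])^2
  tot / (nrow(a) * ncol(a))
}

# per-pixel loop argmax with lowest-index tie break
argmax_oracle <- function(o) {
  d <- dim(o)
  out <- matrix(0L, d[1L], d[2L])
  for (i in seq_len(d[1L]))
    for (j in seq_len(d[2L]))
      out[i, j] <- which.max(o[i, j, ]) - 1L
  out
}

# accumulate/divide stitching oracle for overlapping grids
stitch_oracle <- function(g) {
  h <- g$canvas_shape[1L]; w <- g$canvas_shape[2L]; P <- g$patch_size
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (i in seq_len(nrow(g$offsets))) {
    o <- g$offsets[i, ]
    acc[o[1L] + seq_len(P), o[2L] + seq_len(P)] <-
      acc[o[1L] + seq_len(P), o[2L] + seq_len(P)] + g$patches[[i]]
    cnt[o[1L] + seq_len(P), o[2L] + seq_len(P)] <-
      cnt[o[1L] + seq_len(P), o[2L] + seq_len(P)] + 1
  }
  acc / cnt
}

random_mask <- function(n = 8L, p = 0.4) {
  matrix(runif(n * n) < p, n, n)
}

random_label_map <- function(h, w, n_classes = 4L) {
  matrix(sample(0:(n_classes - 1L), h * w, replace = TRUE), h, w)
}

toy_labeled_volume <- function(d = c(6L, 8L, 10L), seed = 1L) {
  set.seed(seed)
  mri_volume(array(rnorm(prod(d)), d),
             labels = array(sample(0:3, prod(d), replace = TRUE), d),
             subject_id = "toy")
}

tiny_phantom_cfg <- function(seed = 1L, ...) {
  phantom_config(canvas = 48L, n_slices = 8L, seed = seed, ...)
}
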