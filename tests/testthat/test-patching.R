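test_that("non-overlapping split produces the canonical quadrants", {
  s <- slice_image(matrix(rnorm(256^2), 256, 256),
                   labels = random_label_map(256, 256))
  g <- split_nonoverlapping(s, 128L)
  expect_length(g$patches, 4L)
  expect_identical(unname(g$offsets),
                   matrix(c(0L, 0L, 0L, 128L, 128L, 0L, 128L, 128L),
                          ncol = 2L, byrow = TRUE))
  expect_false(g$overlapping)
  # top-right patch content
  expect_identical(g$patches[[2L]], s$pixels[1:128, 129:256])
  expect_identical(g$label_patches[[3L]], s$labels[129:256, 1:128])
  expect_error(split_nonoverlapping(s, 100L), "not divisible",
               class = "patchunet_validation_error")
})

test_that("single-patch split is the identity and fine splits conserve pixels", {
  m <- matrix(rnorm(128^2), 128, 128)
  g1 <- split_nonoverlapping(m, 128L)
  expect_length(g1$patches, 1L)
  expect_identical(g1$patches[[1L]], m)

  m2 <- matrix(rnorm(256^2), 256, 256)
  g2 <- split_nonoverlapping(m2, 32L)
  expect_length(g2$patches, 64L)
  expect_identical(sort(unlist(g2$patches)), sort(as.vector(m2)))
})

test_that("overlapping split enumerates the strided sliding window", {
  m <- matrix(rnorm(256^2), 256, 256)
  g <- split_overlapping(m, 128L, 8L)
  expect_length(g$patches, 17L * 17L)
  expect_true(g$overlapping)
  # stride = P reproduces the non-overlapping offsets
  gP <- split_overlapping(m, 128L, 128L)
  expect_identical(gP$offsets, split_nonoverlapping(m, 128L)$offsets)
  # direct enumeration on a non-divisible canvas
  m3 <- matrix(rnorm(130^2), 130, 130)
  g3 <- split_overlapping(m3, 128L, 2L)
  expect_identical(unname(g3$offsets),
                   matrix(c(0L, 0L, 0L, 2L, 2L, 0L, 2L, 2L),
                          ncol = 2L, byrow = TRUE))
  # include_edges appends the flush anchors
  g4 <- split_overlapping(m3, 128L, 4L, include_edges = TRUE)
  expect_true(all(c(0L, 2L) %in% g4$offsets[, 1L]))
  expect_error(split_overlapping(matrix(0, 64, 64), 128L),
               class = "patchunet_validation_error")
})

test_that("split/stitch round trips are exact and ordering is reproducible", {
  set.seed(7)
  for (rep in seq_len(100L)) {
    P <- sample(c(4L, 8L, 16L), 1L)
    h <- P * sample(1:4, 1L); w <- P * sample(1:4, 1L)
    m <- matrix(rnorm(h * w), h, w)
    g <- split_nonoverlapping(m, P)
    expect_identical(stitch(g), m)
  }
  m <- matrix(rnorm(64^2), 64, 64)
  g1 <- split_nonoverlapping(m, 16L)
  g2 <- split_nonoverlapping(m, 16L)
  expect_identical(g1$offsets, g2$offsets)
  expect_identical(g1$patches, g2$patches)
})

test_that("overlapping stitch averages covering patches", {
  # identical constant patches stitch to a constant canvas
  m <- matrix(5, 16, 16)
  g <- split_overlapping(m, 8L, 4L)
  expect_equal(stitch(g), m)
  # random canvas agrees with the accumulate/divide oracle
  m2 <- matrix(rnorm(16 * 16), 16, 16)
  g2 <- split_overlapping(m2, 8L, 4L)
  expect_equal(stitch(g2), stitch_oracle(g2), tolerance = 1e-12)
  # stride = P equals the non-overlapping stitch exactly
  g3 <- split_overlapping(m2, 8L, 8L)
  expect_identical(stitch(g3), stitch(split_nonoverlapping(m2, 8L)))
})

test_that("stitch validates coverage for non-overlapping grids", {
  m <- matrix(rnorm(64), 8, 8)
  g <- split_nonoverlapping(m, 4L)
  g$offsets <- g$offsets[-1L, ]
  g$patches <- g$patches[-1L]
  expect_error(stitch(g), "tile", class = "patchunet_validation_error")
})

test_that("one-hot encoding builds indicator channels that sum to one", {
  m0 <- matrix(0L, 5, 5)
  o0 <- encode_onehot(m0)
  expect_true(all(o0[, , 1L] == 1))
  expect_true(all(o0[, , 2:4] == 0))
  set.seed(3)
  for (rep in seq_len(20L)) {
    m <- random_label_map(7, 9)
    o <- encode_onehot(m)
    expect_identical(decode_onehot(o), m)
    expect_true(all(apply(o, c(1, 2), sum) == 1))
    # channel sums equal the class histogram
    hist <- tabulate(m + 1L, nbins = 4L)
    expect_identical(as.integer(apply(o, 3L, sum)), hist)
  }
  expect_error(encode_onehot(matrix(4L, 2, 2)), "label value",
               class = "patchunet_validation_error")
})

test_that("score-stack decoding matches a per-pixel loop oracle", {
  # uniform scores decode to background via the lowest-index tie rule
  u <- array(0.25, c(4, 4, 4))
  expect_true(all(decode_onehot(u) == 0L))
  set.seed(11)
  for (rep in seq_len(20L)) {
    o <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
    expect_identical(decode_onehot(o), argmax_oracle(o))
  }
  expect_error(decode_onehot(array(0, c(3, 3, 2)), n_classes = 4L),
               class = "patchunet_validation_error")
})

test_that("patch grids serialize to a manifest directory and restore", {
  s <- slice_image(matrix(rnorm(32^2), 32, 32),
                   labels = random_label_map(32, 32))
  g <- split_nonoverlapping(s, 16L)
  dir <- withr::local_tempdir()
  write_patch_grid(g, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_patch_grid(dir)
  expect_identical(back$offsets, g$offsets)
  expect_identical(back$patches, g$patches)
  expect_identical(back$label_patches, g$label_patches)
  expect_identical(back$stride, g$stride)
})
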