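phantom_vols <- function(n, seed0 = 30L, canvas = 32L, n_slices = 8L) {
  lapply(seq_len(n), function(i)
    generate_phantom_volume(phantom_config(canvas = canvas,
                                           n_slices = n_slices,
                                           seed = seed0 + i),
                            subject_id = sprintf("ph%02d", i)))
}

test_that("training-set assembly follows the configured product of counts", {
  vols <- phantom_vols(3)
  ds <- make_training_set(vols, slice_count = 2L, slice_interval = 2L,
                          canvas_size = 32L, patch_size = 16L)
  expect_length(ds$x, 3L * 2L * 4L)
  expect_length(ds$y, length(ds$x))
  expect_identical(nrow(ds$meta), length(ds$x))
  # deterministic order: volumes, slices, then row-major patches
  expect_identical(ds$meta$subject_id[1:8], rep(c("ph01"), 8L))
  expect_identical(ds$meta$offset_row[1:4], c(0L, 0L, 16L, 16L))
  # every target is a valid one-hot stack
  for (k in sample(length(ds$y), 5L)) {
    expect_identical(dim(ds$y[[k]]), c(16L, 16L, 4L))
    expect_true(all(apply(ds$y[[k]], c(1, 2), sum) == 1))
  }
  expect_error(make_training_set(list(mri_volume(array(0, c(4, 4, 4)))),
                                 slice_count = 1L),
               "no labels", class = "patchunet_validation_error")
})

test_that("whole-slice mode yields a single unchanged pair", {
  vols <- phantom_vols(1)
  ds <- make_training_set(vols, slice_count = 1L, canvas_size = 32L,
                          normalize = "none", patch_size = 32L)
  expect_length(ds$x, 1L)
  mid <- select_training_slices(8L, 1L) + 1L
  expect_identical(ds$x[[1L]], vols[[1L]]$intensities[, , mid])
})

test_that("zero learning rate leaves weights bitwise unchanged", {
  vols <- phantom_vols(1)
  ds <- make_training_set(vols, slice_count = 2L, slice_interval = 2L,
                          canvas_size = 32L, patch_size = 32L)
  spec <- unet_spec(patch_size = 32, base_filters = 4, depth = 2)
  model <- build_unet(spec, seed = 40)
  cfg <- train_config(learning_rate = 0, epochs = 1L, batch_size = 2L,
                      seed = 41L, reinitialize = FALSE)
  fit <- train_unet(model, ds, cfg)
  expect_identical(fit$weights, model$weights)
})

test_that("a fixed seed reproduces the loss trace and the trained weights", {
  vols <- phantom_vols(1)
  ds <- make_training_set(vols, slice_count = 2L, slice_interval = 2L,
                          canvas_size = 32L, patch_size = 32L)
  spec <- unet_spec(patch_size = 32, base_filters = 4, depth = 2)
  cfg <- train_config(epochs = 2L, batch_size = 2L, seed = 42L)
  f1 <- train_unet(build_unet(spec), ds, cfg)
  f2 <- train_unet(build_unet(spec), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  f3 <- train_unet(build_unet(spec), ds,
                   train_config(epochs = 2L, batch_size = 2L, seed = 43L))
  expect_false(identical(f3$history$loss, f1$history$loss))
})

test_that("training on phantom patches drives the loss down", {
  vols <- phantom_vols(2)
  ds <- make_training_set(vols, slice_count = 3L, slice_interval = 2L,
                          canvas_size = 32L, patch_size = 32L)
  spec <- unet_spec(patch_size = 32, base_filters = 4, depth = 2)
  fit <- train_unet(build_unet(spec), ds,
                    train_config(epochs = 8L, batch_size = 3L, seed = 44L))
  h <- tidy(fit)
  expect_identical(nrow(h), 8L)
  expect_true(all(is.finite(h$loss)) && all(h$loss >= 0))
  expect_lt(h$loss[8L], h$loss[1L])
  expect_gt(h$accuracy[8L], h$accuracy[1L])
  g <- glance(fit)
  expect_identical(g$epochs_trained, 8L)
  expect_equal(g$final_loss, h$loss[8L])
})

test_that("target channel count must match the model head", {
  spec <- unet_spec(patch_size = 16, base_filters = 2, depth = 1,
                    n_classes = 3)
  model <- build_unet(spec)
  bad <- list(x = list(matrix(0, 16, 16)),
              y = list(array(0, c(16, 16, 4))))
  expect_error(train_unet(model, bad, train_config(epochs = 1L)),
               "channels", class = "patchunet_validation_error")
})

test_that("slice prediction equals a manual per-patch assembly", {
  spec <- unet_spec(patch_size = 16, base_filters = 4, depth = 2)
  model <- build_unet(spec, seed = 50)
  set.seed(51)
  s <- matrix(runif(32 * 32), 32, 32)
  pred <- predict_slice(model, s)
  # independent loop: forward each quadrant, paste scores, argmax
  scores <- array(0, c(32, 32, 4))
  for (o in list(c(0, 0), c(0, 16), c(16, 0), c(16, 16))) {
    patch <- s[o[1L] + 1:16, o[2L] + 1:16]
    scores[o[1L] + 1:16, o[2L] + 1:16, ] <- predict_patch(model, patch)
  }
  manual <- decode_onehot(scores)
  expect_identical(pred, manual)
  expect_true(all(pred %in% 0:3))
  expect_error(predict_slice(model, matrix(0, 30, 30)),
               class = "patchunet_validation_error")
})

test_that("overlapping prediction at stride P matches non-overlapping exactly", {
  spec <- unet_spec(patch_size = 16, base_filters = 4, depth = 2)
  model <- build_unet(spec, seed = 52)
  set.seed(53)
  s <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict_slice(model, s, mode = "overlap", stride = 16L),
                   predict_slice(model, s, mode = "nonoverlap"))
})

test_that("volume prediction is the slice-wise loop in native geometry", {
  cfg <- phantom_config(canvas = 28L, n_slices = 6L, seed = 60)
  vol <- generate_phantom_volume(cfg)
  spec <- unet_spec(patch_size = 16, base_filters = 2, depth = 2)
  model <- build_unet(spec, seed = 61)
  pred <- predict_volume(model, vol, canvas_size = 32L)
  expect_identical(dim(pred$labels), dim(vol$intensities))
  expect_true(all(pred$labels %in% 0:3))
  # manual loop oracle
  nv <- normalize_intensity(vol, "minmax")
  for (k in c(1L, 4L)) {
    ps <- pad_to_canvas(slice_image(nv$intensities[, , k]), 32L)
    lab <- predict_slice(model, ps)
    un <- lab[ps$pad_record[["top"]] + 1:28, ps$pad_record[["left"]] + 1:28]
    expect_identical(pred$labels[, , k], un)
  }
})

test_that("per-class binary maps are extractable from a prediction", {
  cfg <- phantom_config(canvas = 32L, n_slices = 6L, seed = 62)
  vol <- generate_phantom_volume(cfg)
  gt <- vol$labels[, , 3L]
  for (cl in c(CSF = 1L, GM = 2L, WM = 3L)) {
    bm <- gt == cl
    expect_identical(dim(bm), dim(gt))
    expect_type(bm, "logical")
  }
  # binary maps together with background partition the slice
  expect_identical(Reduce(`+`, lapply(0:3, function(cl) sum(gt == cl))),
                   length(gt))
})
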