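# Expected layer table for the default architecture (name, output channels,
# spatial side, parameter count). Used to pin every row of the builder's
# accounting.
default_conv_table <- data.frame(
  name = paste0("conv2d_", 1:18),
  out_c = c(64, 64, 128, 128, 256, 256, 512, 512,
            256, 256, 256, 128, 128, 128, 64, 64, 64, 4),
  side = c(128, 128, 64, 64, 32, 32, 16, 16,
           32, 32, 32, 64, 64, 64, 128, 128, 128, 128),
  n_params = c(640, 36928, 73856, 147584, 295168, 590080, 1180160, 2359808,
               524544, 1179904, 590080, 131200, 295040, 147584, 32832,
               73792, 36928, 260))

test_that("default architecture reproduces the full layer table", {
  m <- build_unet(unet_spec())
  r <- m$records
  expect_identical(nrow(r), 28L)
  conv <- r[r$type == "conv", ]
  expect_identical(conv$name, default_conv_table$name)
  expect_identical(conv$n_params, as.integer(default_conv_table$n_params))
  expect_identical(conv$out_c, as.integer(default_conv_table$out_c))
  expect_identical(conv$out_h, as.integer(default_conv_table$side))
  # zero-parameter plumbing layers
  expect_true(all(r$n_params[r$type %in%
                               c("maxpool", "upsample", "concat", "input")] == 0L))
  # skip wiring: first concatenation joins encoder stage 3 with the upsampled
  # bottleneck at 32x32x512
  cc <- r[r$name == "concatenated_1", ]
  expect_identical(sort(cc$connected_to[[1L]]), c("conv2d_6", "conv2d_9"))
  expect_identical(c(cc$out_h, cc$out_w, cc$out_c), c(32L, 32L, 512L))
  i8 <- r[r$name == "conv2d_8", ]
  expect_identical(c(i8$out_h, i8$out_w, i8$out_c), c(16L, 16L, 512L))
})

test_that("closed-form parameter counts equal the instantiated weights", {
  m <- build_unet(unet_spec())
  expect_identical(count_parameters(m), 7696388L)
  expect_identical(model_weight_count(m), 7696388)
  for (nm in c("conv2d_1", "conv2d_9", "conv2d_18")) {
    expect_identical(as.integer(model_weight_count(m, nm)),
                     count_parameters(m, nm))
  }
  expect_error(count_parameters(m, "conv2d_99"), "no layer",
               class = "patchunet_validation_error")
})

test_that("reduced specs follow the doubling/halving closed form", {
  m <- build_unet(unet_spec(patch_size = 32, base_filters = 4, depth = 2))
  r <- m$records
  # bottleneck at P/2^depth with F*2^depth channels
  expect_identical(r$out_h[r$name == "conv2d_6"], 8L)
  expect_identical(r$out_c[r$name == "conv2d_6"], 16L)
  expect_identical(count_parameters(m, "conv2d_1"), (9L + 1L) * 4L)
  # doubling the base width scales conv2d_1 per (9*cin + 1)*cout
  m8 <- build_unet(unet_spec(patch_size = 32, base_filters = 8, depth = 2))
  expect_identical(count_parameters(m8, "conv2d_1"), 80L)
  expect_identical(as.integer(model_weight_count(m8)),
                   sum(m8$records$n_params))
  expect_error(unet_spec(patch_size = 100, depth = 3),
               "divisible", class = "patchunet_validation_error")
})

test_that("forward pass emits per-pixel probability simplices", {
  m <- build_unet(unet_spec(patch_size = 32, base_filters = 4, depth = 2),
                  seed = 5)
  set.seed(1)
  p <- predict_patch(m, matrix(rnorm(32 * 32), 32, 32))
  expect_identical(dim(p), c(32L, 32L, 4L))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-12)
  expect_error(predict_patch(m, matrix(0, 16, 16)), "expects",
               class = "patchunet_validation_error")
})

test_that("default-architecture forward pass keeps the softmax contract", {
  m <- build_unet(unet_spec(), seed = 2)
  set.seed(2)
  p <- predict_patch(m, matrix(rnorm(128 * 128), 128, 128))
  expect_identical(dim(p), c(128L, 128L, 4L))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-10)
})

test_that("architecture summaries render and JSON round-trips", {
  m <- build_unet(unet_spec())
  txt <- summarize_architecture(m, "text")
  expect_length(txt, 29L)  # header + 28 rows
  expect_match(txt[grep("conv2d_1 ", txt)[1L]], "640")
  js <- summarize_architecture(m, "json")
  again <- as.character(jsonlite::toJSON(jsonlite::fromJSON(js),
                                         dataframe = "rows",
                                         auto_unbox = FALSE, digits = NA))
  expect_identical(again, js)
})

test_that("model specs and checkpoints round-trip through disk", {
  spec <- unet_spec(patch_size = 64, base_filters = 8)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, yml)
  expect_identical(read_model_spec(yml), spec)
  m <- build_unet(spec, seed = 9)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_unet(m, ck)
  back <- load_unet(ck)
  expect_identical(back$weights, m$weights)
  expect_identical(back$spec, m$spec)
})

test_that("weight initialization is seed-deterministic and scheme-sensitive", {
  spec <- unet_spec(patch_size = 16, base_filters = 4, depth = 2)
  a <- build_unet(spec, seed = 3)
  b <- build_unet(spec, seed = 3)
  expect_identical(a$weights, b$weights)
  c <- build_unet(spec, seed = 4)
  expect_false(identical(a$weights, c$weights))
  g <- build_unet(spec, init = "glorot_uniform", seed = 3)
  expect_false(identical(a$weights, g$weights))
  # He-normal scale: sd ~ sqrt(2 / fan_in) for the widest layer
  w <- a$weights$conv2d_2$w
  expect_equal(sd(w), sqrt(2 / (9 * 4)), tolerance = 0.2)
})
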