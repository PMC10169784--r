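test_that("train_config validates epochs and encodes the two-plateau
           learning-rate schedule", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(lr_initial = 0), "positive")
  cfg <- train_config(epochs = 10)
  expect_equal(learning_rate_at(1, cfg), 2e-4)
  expect_equal(learning_rate_at(5, cfg), 2e-4)
  # first epoch after 50% of the epochs runs at the reduced rate
  expect_equal(learning_rate_at(ceiling(10 / 2) + 1, cfg), 2e-5)
  expect_equal(learning_rate_at(10, cfg), 2e-5)
  cfg7 <- train_config(epochs = 7)
  expect_equal(learning_rate_at(4, cfg7), 2e-4)
  expect_equal(learning_rate_at(5, cfg7), 2e-5)
})

test_that("a tiny 2D blood-pool net trains deterministically and its loss
           decreases after the first epoch", {
  # small flat phantom: a handful of slices keeps the run cheap
  ph <- generate_phantom(canonical_anatomy("normal", seed = 9),
                         shape = c(48, 48, 33), spacing = c(2, 2, 3))
  slices <- list(spec = ph$spec,
                 image = intensity_volume(
                   ph$image$data[, , 15:17, drop = FALSE], ph$image$spacing),
                 truth = label_volume(
                   ph$truth$data[, , 15:17, drop = FALSE], ph$truth$spacing))
  class(slices) <- "phantom_case"
  cfg <- train_config(epochs = 3, seed = 5)
  bk <- train_unet(list(slices), cfg, "2D", levels = 2L, filters = 4L)
  expect_s3_class(bk, "trained_backend")
  expect_length(bk$loss_history, 3)
  expect_lt(bk$loss_history[2], bk$loss_history[1])
  bk2 <- train_unet(list(slices), cfg, "2D", levels = 2L, filters = 4L)
  expect_identical(bk$loss_history, bk2$loss_history)
  # the trained 2D net runs slice-wise on a volume
  seg <- segment_bloodpool_2d(slices$image, bk)
  expect_true(all(seg$data %in% c(0L, 1L, 2L)))
})

test_that("train configs and trained backends round-trip through files", {
  cfg <- train_config(epochs = 4, seed = 9)
  yp <- tempfile(fileext = ".yaml")
  write_train_config(cfg, yp)
  expect_equal(read_train_config(yp)$epochs, 4L)
  # minimal trained backend via a 1-epoch 2D run on a tiny slice stack
  ph <- generate_phantom(canonical_anatomy("normal", seed = 9),
                         shape = c(48, 48, 33), spacing = c(2, 2, 3))
  slices <- structure(list(
    spec = ph$spec,
    image = intensity_volume(ph$image$data[, , 16, drop = FALSE],
                             ph$image$spacing),
    truth = label_volume(ph$truth$data[, , 16, drop = FALSE],
                         ph$truth$spacing)), class = "phantom_case")
  bk <- train_unet(list(slices), train_config(epochs = 1, seed = 9), "2D",
                   levels = 2L, filters = 4L)
  rp <- tempfile(fileext = ".rds")
  save_backend(bk, rp)
  expect_true(file.exists(paste0(rp, ".json")))
  desc <- jsonlite::read_json(paste0(rp, ".json"), simplifyVector = TRUE)
  expect_equal(desc$dimensionality, "2D")
  expect_equal(desc$filters, 4L)
  b2 <- load_backend(rp)
  expect_identical(b2$model$layers, bk$model$layers)
})
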