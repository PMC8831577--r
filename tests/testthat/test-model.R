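test_that("soft Dice loss matches hand evaluations", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(soft_dice_loss(t, t), 1e-6)
  expect_gt(soft_dice_loss(1 - t, t), 1 - 1e-6)

  # uniform 0.5 on 4 pixels against two ones: 1 - (2*1)/(2+2) = 0.5
  p <- matrix(0.5, 2, 2)
  expect_equal(soft_dice_loss(p, t), 0.5, tolerance = 1e-6)

  expect_error(soft_dice_loss(matrix(2, 2, 2), t), "probabilities")
})

test_that("soft Dice on a binary prediction complements the Dice score", {
  set.seed(12)
  for (i in 1:20) {
    pr <- random_mask_pair()
    if (sum(pr$a) + sum(pr$b) == 0) next
    expect_equal(soft_dice_loss(pr$a, pr$b) + dice(pr$a, pr$b), 1,
                 tolerance = 1e-5)
  }
})

test_that("the stopping rule fires on the scripted Dice sequence", {
  tol <- 1e-5
  expect_false(should_stop(0.80, tol))
  expect_true(should_stop(c(0.80, 0.80000001), tol))  # stops after epoch 2
  expect_false(should_stop(c(0.5, 0.8), tol))
  expect_true(should_stop(c(0.5, 0.8, 0.8), tol))
})

test_that("oracle segmentation reproduces ground truth and zeros outside
           the extent", {
  ph <- generate_phantom(small_spec(), seed = 14)
  truth <- eatseg:::crop_mask_to_extent(ph$sac, ph$extent)
  pred <- segment_volume(ph$volume, ph$extent, oracle_segmenter(truth))
  expect_identical(pred$voxels, ph$sac$voxels)

  outside <- setdiff(seq_len(dim(pred$voxels)[3]),
                     ph$extent$bottom:ph$extent$top)
  expect_true(all(pred$voxels[, , outside] == 0L))
})

test_that("reassembly does not depend on the presentation order", {
  # the bisected and sequential plans visit slices in different orders;
  # with a per-slice oracle both must reassemble the identical volume
  ph <- generate_phantom(small_spec(), seed = 15)
  truth <- eatseg:::crop_mask_to_extent(ph$sac, ph$extent)
  m <- oracle_segmenter(truth)
  a <- segment_volume(ph$volume, ph$extent, m, bisect = TRUE)
  b <- segment_volume(ph$volume, ph$extent, m, bisect = FALSE)
  expect_identical(a$voxels, b$voxels)
})

test_that("training respects epoch caps, logs and determinism", {
  set.seed(100)
  cohort <- lapply(1:3, function(i) generate_phantom(small_spec(), seed = i))
  items <- lapply(cohort, function(ph) {
    build_slab_dataset(ph$volume, ph$extent, ph$sac)
  })
  train <- c(items[[1]], items[[2]])
  val <- items[[3]]
  cfg <- training_config(batch_size = 8, max_epochs = 3, seed = 5)

  fit1 <- train_segmenter(unet_segmenter(), train, val, cfg)
  expect_lte(fit1$log$epochs, 3)
  expect_equal(length(fit1$log$loss), length(fit1$log$val_dice))
  expect_true(fit1$log$stop_reason %in% c("max_epochs", "tolerance"))
  if (fit1$log$stop_reason == "max_epochs") {
    expect_equal(fit1$log$epochs, 3)
  }

  fit2 <- train_segmenter(unet_segmenter(), train, val, cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$model$state$weights, fit2$model$state$weights)

  expect_error(train_segmenter(unet_segmenter(), list(), val, cfg),
               "empty")
})

test_that("predictions are binary, shaped like the slab, and stable", {
  ph <- generate_phantom(small_spec(), seed = 16)
  items <- build_slab_dataset(ph$volume, ph$extent, ph$sac)
  fit <- train_segmenter(unet_segmenter(), items, items,
                         training_config(batch_size = 8, max_epochs = 1,
                                         seed = 2))
  slab <- items[[1]]$image
  p1 <- predict_slice(fit$model, slab)
  expect_equal(dim(p1), dim(slab)[1:2])
  expect_true(all(p1 %in% c(0L, 1L)))
  expect_identical(p1, predict_slice(fit$model, slab))

  expect_error(predict_slice(unet_segmenter(), slab), "not been trained")
})

test_that("checkpoints round-trip through disk with a JSON sidecar", {
  ph <- generate_phantom(small_spec(), seed = 17)
  items <- build_slab_dataset(ph$volume, ph$extent, ph$sac)
  cfg <- training_config(batch_size = 8, max_epochs = 1, seed = 3)
  fit <- train_segmenter(unet_segmenter(), items, items, cfg)

  f <- withr::local_tempfile(fileext = ".rds")
  save_segmenter(fit$model, f, config = cfg, log = fit$log)
  m2 <- load_segmenter(f)
  expect_identical(m2$state$weights, fit$model$state$weights)

  sidecar <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(sidecar$class, "unet_segmenter")
  expect_equal(sidecar$training$batch_size, cfg$batch_size)
  expect_lt(sidecar$n_parameters, 1e5)
})
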