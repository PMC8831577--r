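#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` for a probability
#' map `p` and binary truth `t`. Dice-based loss is insensitive to class
#' prevalence, which matters here because the pericardial interior is a
#' small fraction of each slice.
#'
#' @param pred numeric grid of probabilities in `[0, 1]`.
#' @param truth binary grid of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(pred, truth, eps = 1e-6) {
  if (!identical(dim(pred), dim(truth)) &&
      length(pred) != length(truth)) stop("shape mismatch")
  if (any(pred < 0 | pred > 1)) stop("pred must be probabilities in [0, 1]")
  1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}

#' Training configuration for the per-slice segmenter
#'
#' Mirrors the pipeline's training protocol: Adam optimisation of a soft
#' Dice loss, mini-batches of 20 slabs, at most 30 epochs at a constant
#' learning rate of 1e-3, with validation at the end of every epoch and
#' early stopping once the epoch-to-epoch change in validation Dice falls
#' below `stop_tolerance` (1e-5).
#'
#' @param batch_size mini-batch size (>= 1).
#' @param max_epochs epoch cap (>= 1).
#' @param learning_rate Adam learning rate (constant).
#' @param stop_tolerance threshold on `|valDice(e) - valDice(e-1)|`.
#' @param seed integer seed controlling batch order and augmentation draws.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 20, max_epochs = 30,
                            learning_rate = 1e-3, stop_tolerance = 1e-5,
                            seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, stop_tolerance > 0,
            learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 stop_tolerance = stop_tolerance,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Early-stopping rule on validation Dice
#'
#' Given the validation Dice value of each completed epoch, returns TRUE
#' once the absolute change between the last two epochs is below the
#' tolerance.
#'
#' @param val_dice numeric vector of per-epoch validation Dice values.
#' @param tolerance stopping tolerance.
#' @return Logical.
#' @export
should_stop <- function(val_dice, tolerance) {
  n <- length(val_dice)
  n >= 2L && abs(val_dice[n] - val_dice[n - 1L]) < tolerance
}

#' Per-slice segmenter contract
#'
#' A segmenter maps a three-channel [assemble_slab()] to a binary mask of
#' its target slice via [predict_slice()]. Two implementations ship with
#' the package: [unet_segmenter()], a small trainable encoder-decoder,
#' and [oracle_segmenter()], a test double that returns stored ground
#' truth and lets every downstream stage be verified independently of
#' model quality.
#'
#' @param model a segmenter object.
#' @param slab a `slab` from [assemble_slab()].
#' @param ... passed to methods.
#' @return Binary matrix with the slab's in-plane shape.
#' @export
predict_slice <- function(model, slab, ...) UseMethod("predict_slice")

#' Oracle segmenter (ground-truth test double)
#'
#' Wraps a known mask volume; prediction for a slab simply returns the
#' stored mask of the slab's target slice. Used to exercise slab
#' assembly, reassembly and quantification with a perfect segmenter.
#'
#' @param truth a [mask_volume()] already cropped to the heart extent
#'   (slice i corresponds to target index i).
#' @return An object of classes `oracle_segmenter`, `slice_segmenter`.
#' @export
oracle_segmenter <- function(truth) {
  stopifnot(inherits(truth, "mask_volume"))
  structure(list(truth = truth),
            class = c("oracle_segmenter", "slice_segmenter"))
}

#' @export
predict_slice.oracle_segmenter <- function(model, slab, ...) {
  k <- attr(slab, "target")
  model$truth$voxels[, , k]
}

#' Small trainable encoder-decoder segmenter
#'
#' A deliberately small U-Net-style fully-convolutional network (about
#' 15k parameters at the default widths): two 3x3-conv + 2x2-max-pool
#' encoder levels, a bottleneck convolution, and two nearest-neighbour
#' upsample + skip-concatenation + 3x3-conv decoder levels, closed by a
#' 1x1 sigmoid head. The head bias is initialised to -2 so the network
#' starts from the background-dominated prior, which stabilises early
#' Dice-loss optimisation. It is the reference backend for the segmenter
#' contract - trainable in CPU-minutes on small phantoms - while heavier
#' pretrained networks can be plugged in through the same
#' [predict_slice()] generic.
#'
#' @param channels integer length-5: feature widths `(enc1, enc2,
#'   bottleneck, dec2, dec1)`.
#' @param threshold binarisation threshold on the sigmoid output.
#' @return An untrained object of classes `unet_segmenter`,
#'   `slice_segmenter`. Weight initialisation happens at the start of
#'   [train_segmenter()] under the training seed.
#' @export
unet_segmenter <- function(channels = c(8L, 16L, 32L, 16L, 8L),
                           threshold = 0.5) {
  stopifnot(length(channels) == 5L, all(channels >= 1L))
  structure(list(channels = as.integer(channels), threshold = threshold,
                 state = NULL, trained = FALSE),
            class = c("unet_segmenter", "slice_segmenter"))
}

unet_init_state <- function(channels) {
  he <- function(nout, nin) {
    matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  }
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  d2 <- channels[4]; d1 <- channels[5]
  weights <- list(
    W1 = he(c1, 3L * 9L), b1 = rep(0, c1),
    W2 = he(c2, c1 * 9L), b2 = rep(0, c2),
    W3 = he(c3, c2 * 9L), b3 = rep(0, c3),
    W4 = he(d2, (c2 + c3) * 9L), b4 = rep(0, d2),
    W5 = he(d1, (c1 + d2) * 9L), b5 = rep(0, d1),
    W6 = he(1L, d1), b6 = -2  # start at the background prior
  )
  zeros <- lapply(weights, function(w) w * 0)
  list(weights = weights, adam_m = zeros, adam_v = zeros, step = 0)
}

n_parameters <- function(model) {
  sum(vapply(model$state$weights, length, 0L))
}

items_to_matrices <- function(items) {
  d <- dim(items[[1]]$image)
  X <- vapply(items, function(it) as.numeric(it$image) / 255,
              numeric(prod(d)))
  Y <- vapply(items, function(it) as.numeric(it$mask),
              numeric(d[1] * d[2]))
  list(X = X, Y = Y, H = d[1], W = d[2])
}

#' Train a per-slice segmenter
#'
#' Mini-batch Adam on soft Dice loss. Each epoch the training items are
#' re-augmented with fresh random rotation/scale draws ([random_geometric()])
#' and presented in a fresh random order; validation (slice-mean Dice of
#' binarised predictions, un-augmented) runs at the end of every epoch and
#' the run stops early when the change in validation Dice drops below the
#' configured tolerance.
#'
#' Blur duplication ([blur_duplicate()]) is a dataset-preparation step and
#' should be applied to `train` before calling this function.
#'
#' @param model an untrained [unet_segmenter()].
#' @param train,val non-empty lists of `list(image, mask)` items sharing
#'   one in-plane shape.
#' @param config a [training_config()].
#' @param augment an [augment_config()], or `NULL` to disable geometric
#'   augmentation.
#' @return `list(model, log)` where `log` has per-epoch `loss` and
#'   `val_dice` vectors plus `stop_reason` (`"tolerance"` or
#'   `"max_epochs"`).
#' @export
train_segmenter <- function(model, train, val, config = training_config(),
                            augment = augment_config()) {
  stopifnot(inherits(model, "unet_segmenter"))
  if (length(train) == 0L || length(val) == 0L) stop("empty dataset")
  d <- dim(train[[1]]$image)
  ok <- vapply(c(train, val), function(it) identical(dim(it$image), d),
               TRUE)
  if (!all(ok)) stop("all slabs must share one shape")
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L) {
    stop("in-plane dimensions must be divisible by 4")
  }

  set.seed(config$seed)
  model$state <- unet_init_state(model$channels)
  vm <- items_to_matrices(val)

  losses <- numeric(0)
  val_dice <- numeric(0)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    epoch_items <- if (is.null(augment)) train else {
      lapply(train, function(it) {
        aug <- random_geometric(it$image, it$mask, augment)
        list(image = aug$image, mask = aug$mask)
      })
    }
    tm <- items_to_matrices(epoch_items)
    ord <- sample.int(ncol(tm$X))
    res <- cpp_unet_train_epoch(tm$X, tm$Y, tm$H, tm$W, model$state,
                                config$learning_rate, config$batch_size,
                                ord)
    model$state <- res$state
    losses <- c(losses, res$loss)

    probs <- cpp_unet_predict(vm$X, vm$H, vm$W, model$state$weights)
    pred <- probs >= model$threshold
    dice_slices <- vapply(seq_len(ncol(probs)), function(i) {
      dice(matrix(pred[, i], vm$H, vm$W), matrix(vm$Y[, i], vm$H, vm$W))
    }, 0)
    val_dice <- c(val_dice, mean(dice_slices))

    if (should_stop(val_dice, config$stop_tolerance)) {
      stop_reason <- "tolerance"
      break
    }
  }

  model$trained <- TRUE
  list(model = model,
       log = list(loss = losses, val_dice = val_dice,
                  stop_reason = stop_reason, epochs = length(losses)))
}

#' @export
predict_slice.unet_segmenter <- function(model, slab, ...) {
  if (is.null(model$state)) stop("segmenter has not been trained")
  d <- dim(slab)
  X <- matrix(as.numeric(slab) / 255, ncol = 1)
  prob <- cpp_unet_predict(X, d[1], d[2], model$state$weights)
  out <- matrix(as.integer(prob[, 1] >= model$threshold), d[1], d[2])
  out
}

#' Serialize / restore a trained segmenter
#'
#' Checkpoints are a plain RDS of the weights plus a JSON sidecar holding
#' the architecture and, optionally, the training configuration and log.
#'
#' @param model a trained [unet_segmenter()].
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @param config,log optional [training_config()] and training log to
#'   record in the sidecar.
#' @return `save_segmenter` invisibly returns `path`.
#' @export
save_segmenter <- function(model, path, config = NULL, log = NULL) {
  stopifnot(inherits(model, "unet_segmenter"))
  saveRDS(model, path)
  sidecar <- list(class = "unet_segmenter", channels = model$channels,
                  threshold = model$threshold,
                  n_parameters = n_parameters(model))
  if (!is.null(config)) sidecar$training <- unclass(config)
  if (!is.null(log)) {
    sidecar$log <- log[c("stop_reason", "epochs")]
    sidecar$final_val_dice <- log$val_dice[length(log$val_dice)]
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_segmenter"))
  model
}

#' Segment the pericardial interior of a full volume
#'
#' The complete inference pipeline: window the volume to 8-bit, crop to
#' the heart extent, build the (bisected) slab plan, assemble a slab per
#' plan entry, predict each target slice with the segmenter, and place
#' each predicted mask back at its anatomical slice index. Slices outside
#' the extent are zero; every in-extent slice is predicted exactly once,
#' so the result does not depend on the order the plan is processed in.
#'
#' @param volume a [ct_volume()].
#' @param extent a [heart_extent()] valid for `volume`.
#' @param model a segmenter honouring [predict_slice()].
#' @param window a [window_spec()].
#' @param bisect use [bisect_plan()] (default) or [sequential_plan()].
#' @return A [mask_volume()] with label `"sac_interior"`, aligned to
#'   `volume`.
#' @export
segment_volume <- function(volume, extent, model, window = window_spec(),
                           bisect = TRUE) {
  validate_extent(extent, volume)
  heart <- crop_to_extent(volume, extent)
  vol8 <- hu_window_to_8bit(heart, window)
  plan <- if (bisect) bisect_plan(extent) else sequential_plan(extent)

  out <- array(0L, dim = dim(volume$voxels))
  for (i in seq_len(nrow(plan))) {
    slab <- assemble_slab(vol8, plan$k[i], plan$s[i])
    pred <- predict_slice(model, slab)
    if (!all(pred %in% c(0, 1))) stop("segmenter returned non-binary mask")
    out[, , extent$bottom + plan$k[i] - 1L] <- as.integer(pred)
  }
  mask_volume(out, spacing = volume$spacing, label = "sac_interior")
}
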