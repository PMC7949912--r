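#' Training configuration for a slice regressor
#'
#' Defaults are the reference recipe: Adam with learning rate 6e-4 and
#' weight decay 6e-4, batch size 64, a sigmoid learning-rate rampup over the
#' first 20 epochs followed by a cosine rampdown to zero at epoch 100, and
#' an absolute-error loss (the reporting metric is MAE in years).
#'
#' @param learning_rate Peak Adam learning rate.
#' @param weight_decay L2 weight decay folded into the Adam gradient.
#' @param batch_size Mini-batch size.
#' @param total_epochs Total number of epochs.
#' @param rampup_epochs Epochs of sigmoid rampup; must be in
#'   `(0, total_epochs)`.
#' @param seed Integer seed controlling initialization, shuffling, and
#'   augmentation.
#' @param orientation Optional orientation label stored with the model.
#' @param tissue Tissue configuration label (`"both"`, `"gm"` or `"wm"`).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 6e-4, weight_decay = 6e-4,
                         batch_size = 64L, total_epochs = 100L,
                         rampup_epochs = 20L, seed = 1L,
                         orientation = NULL, tissue = "both") {
  if (rampup_epochs <= 0 || rampup_epochs >= total_epochs) {
    abort("`rampup_epochs` must satisfy 0 < rampup < total_epochs.")
  }
  structure(
    list(
      learning_rate = learning_rate, weight_decay = weight_decay,
      batch_size = as.integer(batch_size),
      total_epochs = as.numeric(total_epochs),
      rampup_epochs = as.numeric(rampup_epochs),
      seed = as.integer(seed), loss = "mae",
      orientation = orientation, tissue = tissue
    ),
    class = "train_config"
  )
}

#' Learning rate at a (possibly fractional) epoch
#'
#' Sigmoid rampup `lr_max * exp(-5 (1 - t/rampup)^2)` for `t < rampup`, then
#' cosine rampdown `lr_max * (1 + cos(pi (t - rampup)/(total - rampup))) / 2`.
#' The schedule is continuous and attains `lr_max` exactly at `t = rampup`
#' and 0 at `t = total_epochs`.
#'
#' @param epoch Numeric epoch(s) in `[0, total_epochs]`.
#' @param config A [train_config()].
#' @return Learning rate(s), same length as `epoch`.
#' @export
lr_at <- function(epoch, config = train_config()) {
  if (any(epoch < 0 | epoch > config$total_epochs)) {
    abort("`epoch` out of [0, total_epochs].")
  }
  up <- config$rampup_epochs
  tot <- config$total_epochs
  ifelse(
    epoch < up,
    config$learning_rate * exp(-5 * (1 - epoch / up)^2),
    config$learning_rate * 0.5 * (1 + cos(pi * (epoch - up) / (tot - up)))
  )
}

#' Build an untrained slice regressor backbone
#'
#' Two presets are available. `"small_cnn"` — three stride-2 3x3
#' convolution/batch-norm/ReLU blocks (16, 32, 64 filters), global average
#' pooling and a linear head — is the desk-scale default used throughout the
#' tests. `"resnet18"` is an 18-layer residual network whose stem
#' accepts 1 or 2 channels, whose final pooling is global (the feature map at
#' this input size is smaller than a fixed 4-wide pooling window), and whose
#' penultimate fully connected stage is widened to 1,024 units before the
#' single regression output.
#'
#' @param preset `"small_cnn"` or `"resnet18"`.
#' @param in_channels 1 (single tissue) or 2 (GM + WM).
#' @param seed Optional seed for weight initialization.
#' @return An object of class `orientation_regressor` (untrained).
#' @export
build_backbone <- function(preset = c("small_cnn", "resnet18"),
                           in_channels = 2L, seed = NULL) {
  preset <- match.arg(preset)
  if (!in_channels %in% c(1L, 2L)) abort("`in_channels` must be 1 or 2.")
  build <- function() {
    if (preset == "small_cnn") {
      list(
        nn_conv(in_channels, 16L, 3L, 2L, 1L), nn_bn(16L), nn_relu(),
        nn_conv(16L, 32L, 3L, 2L, 1L), nn_bn(32L), nn_relu(),
        nn_conv(32L, 64L, 3L, 2L, 1L), nn_bn(64L), nn_relu(),
        nn_gap(), nn_linear(64L, 1L)
      )
    } else {
      list(
        nn_conv(in_channels, 64L, 7L, 2L, 3L), nn_bn(64L), nn_relu(),
        nn_maxpool(3L, 2L, 1L),
        nn_resblock(64L, 64L), nn_resblock(64L, 64L),
        nn_resblock(64L, 128L, 2L), nn_resblock(128L, 128L),
        nn_resblock(128L, 256L, 2L), nn_resblock(256L, 256L),
        nn_resblock(256L, 512L, 2L), nn_resblock(512L, 512L),
        nn_gap(), nn_linear(512L, 1024L), nn_relu(), nn_linear(1024L, 1L)
      )
    }
  }
  layers <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(
    list(
      preset = preset, in_channels = as.integer(in_channels),
      layers = layers, orientation = NA_character_,
      age_center = 0, age_scale = 1, trained = FALSE,
      input_shape = NULL, history = NULL, config = NULL
    ),
    class = "orientation_regressor"
  )
}

#' @export
print.orientation_regressor <- function(x, ...) {
  cat("<orientation_regressor> ", x$preset, " (", x$in_channels,
    " channel", if (x$in_channels > 1) "s", ", ",
    format(n_parameters(x), big.mark = ","), " parameters), ",
    if (x$trained) paste0("trained [", x$orientation, "]") else "untrained",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of trainable parameters of a regressor
#'
#' @param model An `orientation_regressor`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  count_params(model$layers)
}

forward_model <- function(model, x, training = FALSE) {
  seq_forward(model$layers, x, training)
}

predict_raw <- function(model, data, batch = 64L) {
  N <- dim(data)[4]
  out <- numeric(N)
  i <- 1L
  while (i <= N) {
    j <- min(i + batch - 1L, N)
    xb <- aperm(data[, , , i:j, drop = FALSE], c(3, 1, 2, 4))
    f <- forward_model(model, xb, training = FALSE)
    out[i:j] <- as.vector(f$out)
    i <- j + 1L
  }
  model$age_center + model$age_scale * out
}

#' Train a slice regressor
#'
#' Minimizes the mean absolute error of slice-level age predictions with
#' Adam, the sigmoid-rampup/cosine-rampdown schedule of [lr_at()], and
#' training-time augmentation applied to training slices only. Ages are
#' standardized internally from the training set (the model stores the
#' center/scale and predictions are returned in years). The run is
#' reproducible bit-for-bit from `config$seed` in single-threaded BLAS.
#'
#' @param model An untrained `orientation_regressor` from [build_backbone()].
#' @param train List with `data` (H x W x C x N array) and `age`
#'   (length-N years), e.g. from [bind_stacks()] of [extract_slices()]
#'   output.
#' @param val Validation list in the same format (may be `NULL`).
#' @param config A [train_config()].
#' @param augment An [augment_config()], or `NULL` to disable augmentation.
#' @return The trained model, with `$history` a tibble of per-epoch
#'   learning rate and train/validation MAE (years).
#' @export
train_regressor <- function(model, train, val = NULL,
                            config = train_config(),
                            augment = augment_config()) {
  if (is.null(train$data) || dim(train$data)[4] == 0) {
    abort("empty training set.")
  }
  d <- dim(train$data)
  if (d[3] != model$in_channels) {
    abort(sprintf(
      "training data has %d channels but model expects %d", d[3], model$in_channels
    ))
  }
  model$input_shape <- d[1:3]
  model$age_center <- mean(train$age)
  model$age_scale <- sd(train$age)
  if (model$age_scale == 0) model$age_scale <- 1
  z <- (train$age - model$age_center) / model$age_scale

  N <- d[4]
  bs <- config$batch_size
  nb <- max(1L, ceiling(N / bs))
  state <- adam_init(model$layers)
  step <- 0L
  hist <- vector("list", config$total_epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$total_epochs)) {
      perm <- sample.int(N)
      ep_abs <- 0
      ep_n <- 0L
      for (b in seq_len(nb)) {
        idx <- perm[((b - 1) * bs + 1):min(b * bs, N)]
        if (length(idx) < 2) next # batch norm needs >= 2 samples
        xb <- train$data[, , , idx, drop = FALSE]
        if (!is.null(augment)) {
          for (n in seq_along(idx)) {
            xb[, , , n] <- augment_pipeline(xb[, , , n, drop = TRUE], augment)
          }
        }
        zb <- z[idx]
        lr <- lr_at(min(epoch - 1 + (b - 1) / nb, config$total_epochs), config)
        xb <- aperm(xb, c(3, 1, 2, 4)) # channel-first for the layer library
        f <- forward_model(model, xb, training = TRUE)
        model$layers <- apply_states(model$layers, f$states)
        pred <- as.vector(f$out)
        loss <- mean(abs(pred - zb))
        if (!is.finite(loss)) {
          abort(sprintf("NaN loss at epoch %d batch %d; aborting.", epoch, b))
        }
        dout <- matrix(sign(pred - zb) / length(zb), 1)
        bk <- seq_backward(model$layers, dout, f$caches)
        up <- adam_update(
          model$layers, bk$grads, state, lr, config$weight_decay,
          t = (step <- step + 1L)
        )
        model$layers <- up$layers
        state <- up$state
        ep_abs <- ep_abs + sum(abs(pred - zb))
        ep_n <- ep_n + length(zb)
      }
      # recalibrate BN running stats on clean (unaugmented) slices before
      # evaluating: augmented-batch statistics are intensity-shifted
      refresh_idx <- perm[seq_len(min(N, 2048L))]
      model$layers <- refresh_bn(
        model$layers, train$data[, , , refresh_idx, drop = FALSE], bs
      )
      train_mae <- ep_abs / ep_n * model$age_scale
      val_mae <- NA_real_
      if (!is.null(val) && length(val$age)) {
        val_mae <- mean(abs(predict_raw(model, val$data) - val$age))
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr_at(epoch - 1, config),
        train_mae = train_mae, val_mae = val_mae
      )
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model$orientation <- config$orientation %||% NA_character_
  model$config <- config
  model
}

#' Predict age from a single slice
#'
#' @param model A trained `orientation_regressor`.
#' @param slice A (H, W) matrix or (H, W, C) array matching the training
#'   slice shape.
#' @return Predicted age in years (finite scalar).
#' @export
predict_slice <- function(model, slice) {
  x <- as_hwc(slice)
  d <- dim(x)
  if (!is.null(model$input_shape) && !identical(as.integer(d), as.integer(model$input_shape))) {
    abort(sprintf(
      "slice shape (%s) does not match training shape (%s)",
      paste(d, collapse = ", "), paste(model$input_shape, collapse = ", ")
    ))
  }
  dim(x) <- c(d, 1)
  predict_raw(model, x)
}

#' Predict ages for a stack or array of slices
#'
#' @param model A trained `orientation_regressor`.
#' @param slices A `slice_stack` or an (H, W, C, N) array.
#' @return Numeric vector of predicted ages (years).
#' @export
predict_slices <- function(model, slices) {
  data <- if (inherits(slices, "slice_stack")) slices$data else slices
  predict_raw(model, data)
}

#' @export
glance.orientation_regressor <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    preset = x$preset, orientation = x$orientation,
    n_parameters = n_parameters(x),
    epochs = if (is.null(h)) 0L else nrow(h),
    train_mae = if (is.null(h)) NA_real_ else tail(h$train_mae, 1),
    val_mae = if (is.null(h)) NA_real_ else tail(h$val_mae, 1)
  )
}
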