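#' U-Net architecture configuration
#'
#' The segmenter is an encoder-decoder with skip connections: each
#' encoder level applies two 3x3 same-padded convolutions with rectified
#' linear activations followed by 2x2 max-pooling; the decoder mirrors it
#' with nearest-neighbour up-sampling, a 3x3 convolution, concatenation
#' with the matching encoder features, and two further convolutions; a
#' final 1x1 convolution and logistic activation yield per-pixel fascicle
#' probabilities in `[0, 1]`. Same-padding keeps the output exactly the
#' input size.
#'
#' @param input_size Expected square input side in pixels (default 400);
#'   must be divisible by `2^depth`.
#' @param depth Number of down-sampling levels (default 4; use 2 with
#'   `base_channels = 16` for desk-scale experiments).
#' @param base_channels Channels at the first level (default 64); doubled
#'   (`channel_multiplier`) at each deeper level.
#' @param channel_multiplier Per-level channel factor (default 2).
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(input_size = 400L, depth = 4L, base_channels = 64L,
                        channel_multiplier = 2L) {
  check_that(is_count(depth), "depth", "must be a positive integer")
  check_that(is_count(base_channels), "base_channels",
             "must be a positive integer")
  check_that(is_count(channel_multiplier), "channel_multiplier",
             "must be a positive integer")
  check_that(is_count(input_size) && input_size %% 2^depth == 0, "input_size",
             sprintf("must be a positive integer divisible by 2^depth = %d",
                     2^depth))
  structure(
    list(input_size = as.integer(input_size), depth = as.integer(depth),
         base_channels = as.integer(base_channels),
         channel_multiplier = as.integer(channel_multiplier)),
    class = "unet_config"
  )
}

#' Training schedule configuration
#'
#' Defaults follow the full-scale training recipe: 60 epochs, Adam with
#' an initial learning rate of 5e-4 multiplied by 0.75 every 8 epochs,
#' mini-batches of 20 images, and a soft Dice loss.
#'
#' @param epochs Number of epochs (default 60).
#' @param initial_lr Initial learning rate (default 5e-4).
#' @param lr_decay_factor Multiplicative decay (default 0.75).
#' @param lr_decay_every Epoch period of the decay (default 8).
#' @param batch_size Mini-batch size (default 20).
#' @param seed Seed governing batch shuffling and augmentation draws.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 60L, initial_lr = 5e-4,
                         lr_decay_factor = 0.75, lr_decay_every = 8L,
                         batch_size = 20L, seed = 1L) {
  check_that(is_count(epochs), "epochs", "must be a positive integer")
  check_that(is_number(initial_lr) && initial_lr > 0, "initial_lr",
             "must be positive")
  check_that(is_number(lr_decay_factor) && lr_decay_factor > 0 &&
               lr_decay_factor < 1, "lr_decay_factor", "must lie in (0, 1)")
  check_that(is_count(lr_decay_every), "lr_decay_every",
             "must be a positive integer")
  check_that(is_count(batch_size), "batch_size", "must be a positive integer")
  structure(
    list(epochs = as.integer(epochs), initial_lr = initial_lr,
         lr_decay_factor = lr_decay_factor,
         lr_decay_every = as.integer(lr_decay_every),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Stepped learning-rate schedule
#'
#' `initial_lr * decay^floor((epoch - 1) / decay_every)`: piecewise
#' constant, non-increasing, stepping down every `lr_decay_every` epochs.
#'
#' @param epoch 1-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  check_that(is_count(epoch), "epoch", "must be a 1-based positive integer")
  config$initial_lr *
    config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_every)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`, with a smoothing
#' constant `eps` (in pixel-count units) stabilizing empty masks. The
#' loss lies in `[0, 1]` and is differentiable in the prediction, which
#' is what makes it usable against the severe class imbalance of
#' fascicle segmentation (foreground near 5% of pixels).
#'
#' @param prediction Numeric matrix of probabilities in `[0, 1]`.
#' @param truth Logical (or 0/1) matrix of the same size.
#' @param eps Smoothing constant (default 1).
#' @return The scalar loss.
#' @export
dice_loss <- function(prediction, truth, eps = 1) {
  stopifnot_same_dim(prediction, truth, "prediction and truth")
  1 - (2 * sum(prediction * truth) + eps) /
    (sum(prediction) + sum(truth) + eps)
}

# gradient of dice_loss wrt the prediction
dice_loss_grad <- function(prediction, truth, eps = 1) {
  denom <- sum(prediction) + sum(truth) + eps
  numer <- 2 * sum(prediction * truth) + eps
  -(2 * (truth * 1) * denom - numer) / denom^2
}

relu <- function(a) {
  a[a < 0] <- 0
  a
}

bind_channels <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

conv_layer <- function(k, cin, cout) {
  fan_in <- k * k * cin
  list(
    w = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
    b = rep(0, cout),
    k = as.integer(k)
  )
}

layer_names <- function(depth) {
  nms <- character(0)
  for (l in seq_len(depth)) nms <- c(nms, sprintf("enc%d_c%d", l, 1:2))
  nms <- c(nms, "bott_c1", "bott_c2")
  for (l in seq_len(depth)) {
    nms <- c(nms, sprintf("dec%d_up", l), sprintf("dec%d_c%d", l, 1:2))
  }
  c(nms, "out")
}

#' Build a U-Net model
#'
#' Initializes all convolution weights (He initialization, seeded) for
#' the architecture described in [unet_config()].
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet` holding the configuration and a flat
#'   named list of convolution layers.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth
  ch <- config$base_channels * config$channel_multiplier^(0:d)
  layers <- withr::with_seed(seed, {
    L <- list()
    cin <- 1L
    for (l in seq_len(d)) {
      L[[sprintf("enc%d_c1", l)]] <- conv_layer(3, cin, ch[l])
      L[[sprintf("enc%d_c2", l)]] <- conv_layer(3, ch[l], ch[l])
      cin <- ch[l]
    }
    L[["bott_c1"]] <- conv_layer(3, ch[d], ch[d + 1])
    L[["bott_c2"]] <- conv_layer(3, ch[d + 1], ch[d + 1])
    for (l in seq_len(d)) {
      L[[sprintf("dec%d_up", l)]] <- conv_layer(3, ch[l + 1], ch[l])
      L[[sprintf("dec%d_c1", l)]] <- conv_layer(3, 2L * ch[l], ch[l])
      L[[sprintf("dec%d_c2", l)]] <- conv_layer(3, ch[l], ch[l])
    }
    L[["out"]] <- conv_layer(1, ch[1], 1L)
    L
  })
  structure(
    list(config = config, layers = layers, history = NULL),
    class = "unet"
  )
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf(
    "<unet>: depth %d, base %d channels, %s parameters%s\n",
    x$config$depth, x$config$base_channels,
    format(n_parameters(x), big.mark = ","),
    if (!is.null(x$history)) sprintf(", trained %d epoch(s)", nrow(x$history))
    else " (untrained)"
  ))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `unet`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$w) + length(l$b), numeric(1)))
}

check_input_dims <- function(model, x) {
  div <- 2^model$config$depth
  if (nrow(x) %% div != 0 || ncol(x) %% div != 0) {
    stop(sprintf(
      "input %dx%d is not divisible by 2^depth = %d required by this model",
      nrow(x), ncol(x), div
    ), call. = FALSE)
  }
}

unet_forward <- function(model, x, keep = FALSE) {
  L <- model$layers
  d <- model$config$depth
  a <- array(as.numeric(x), c(nrow(x), ncol(x), 1))
  skips <- vector("list", d)
  ce <- vector("list", d)
  for (l in seq_len(d)) {
    in0 <- a
    c1 <- L[[sprintf("enc%d_c1", l)]]
    c2 <- L[[sprintf("enc%d_c2", l)]]
    a1 <- relu(.conv2d_fwd(in0, c1$w, c1$b, 3L))
    a2 <- relu(.conv2d_fwd(a1, c2$w, c2$b, 3L))
    mp <- .maxpool2_fwd(a2)
    skips[[l]] <- a2
    if (keep) ce[[l]] <- list(in0 = in0, a1 = a1, a2 = a2, idx = mp$idx)
    a <- mp$y
  }
  b_in <- a
  b1 <- relu(.conv2d_fwd(b_in, L$bott_c1$w, L$bott_c1$b, 3L))
  b2 <- relu(.conv2d_fwd(b1, L$bott_c2$w, L$bott_c2$b, 3L))
  a <- b2
  cd <- vector("list", d)
  for (l in rev(seq_len(d))) {
    up <- L[[sprintf("dec%d_up", l)]]
    c1 <- L[[sprintf("dec%d_c1", l)]]
    c2 <- L[[sprintf("dec%d_c2", l)]]
    u <- .upsample2_fwd(a)
    au <- relu(.conv2d_fwd(u, up$w, up$b, 3L))
    cat_in <- bind_channels(au, skips[[l]])
    a1 <- relu(.conv2d_fwd(cat_in, c1$w, c1$b, 3L))
    a2 <- relu(.conv2d_fwd(a1, c2$w, c2$b, 3L))
    if (keep) cd[[l]] <- list(u = u, au = au, cat = cat_in, a1 = a1, a2 = a2)
    a <- a2
  }
  z <- .conv2d_fwd(a, L$out$w, L$out$b, 1L)[, , 1]
  p <- 1 / (1 + exp(-z))
  list(
    prob = p, z = z,
    cache = if (keep) {
      list(enc = ce, bott = list(in0 = b_in, b1 = b1, b2 = b2),
           dec = cd, final_in = a)
    }
  )
}

# backward pass; dz is the gradient w.r.t. the logits (H x W matrix)
unet_backward <- function(model, fw, dz) {
  L <- model$layers
  d <- model$config$depth
  ca <- fw$cache
  g <- list()
  bw <- .conv2d_bwd(ca$final_in, L$out$w, array(dz, c(dim(dz), 1)), 1L)
  g$out <- list(dw = bw$dw, db = bw$db)
  da <- bw$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {
    cdl <- ca$dec[[l]]
    up <- sprintf("dec%d_up", l)
    c1 <- sprintf("dec%d_c1", l)
    c2 <- sprintf("dec%d_c2", l)
    dz2 <- da * (cdl$a2 > 0)
    b2 <- .conv2d_bwd(cdl$a1, L[[c2]]$w, dz2, 3L)
    dz1 <- b2$dx * (cdl$a1 > 0)
    b1 <- .conv2d_bwd(cdl$cat, L[[c1]]$w, dz1, 3L)
    nau <- dim(cdl$au)[3]
    dau <- b1$dx[, , seq_len(nau), drop = FALSE]
    dskips[[l]] <- b1$dx[, , -seq_len(nau), drop = FALSE]
    dzu <- dau * (cdl$au > 0)
    bu <- .conv2d_bwd(cdl$u, L[[up]]$w, dzu, 3L)
    da <- .upsample2_bwd(bu$dx)
    g[[c2]] <- list(dw = b2$dw, db = b2$db)
    g[[c1]] <- list(dw = b1$dw, db = b1$db)
    g[[up]] <- list(dw = bu$dw, db = bu$db)
  }
  db2 <- da * (ca$bott$b2 > 0)
  b2 <- .conv2d_bwd(ca$bott$b1, L$bott_c2$w, db2, 3L)
  db1 <- b2$dx * (ca$bott$b1 > 0)
  b1 <- .conv2d_bwd(ca$bott$in0, L$bott_c1$w, db1, 3L)
  g$bott_c2 <- list(dw = b2$dw, db = b2$db)
  g$bott_c1 <- list(dw = b1$dw, db = b1$db)
  da <- b1$dx
  for (l in rev(seq_len(d))) {
    cel <- ca$enc[[l]]
    c1 <- sprintf("enc%d_c1", l)
    c2 <- sprintf("enc%d_c2", l)
    dpool <- .maxpool2_bwd(cel$idx, da, dim(cel$a2)[1], dim(cel$a2)[2])
    da2 <- dpool + dskips[[l]]
    dz2 <- da2 * (cel$a2 > 0)
    b2 <- .conv2d_bwd(cel$a1, L[[c2]]$w, dz2, 3L)
    dz1 <- b2$dx * (cel$a1 > 0)
    b1 <- .conv2d_bwd(cel$in0, L[[c1]]$w, dz1, 3L)
    g[[c2]] <- list(dw = b2$dw, db = b2$db)
    g[[c1]] <- list(dw = b1$dw, db = b1$db)
    da <- b1$dx
  }
  g
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    list(mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(layers, state, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(layers)) {
    s <- state[[nm]]; gr <- grads[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * gr$dw
    s$vw <- beta2 * s$vw + (1 - beta2) * gr$dw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gr$db
    s$vb <- beta2 * s$vb + (1 - beta2) * gr$db^2
    mw_hat <- s$mw / (1 - beta1^t)
    vw_hat <- s$vw / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t)
    vb_hat <- s$vb / (1 - beta2^t)
    layers[[nm]]$w <- layers[[nm]]$w - lr * mw_hat / (sqrt(vw_hat) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * as.numeric(mb_hat) /
      (sqrt(as.numeric(vb_hat)) + eps)
    state[[nm]] <- s
  }
  list(layers = layers, state = state)
}

#' Train a U-Net with the Dice loss
#'
#' Mini-batch Adam training under the stepped learning-rate schedule of
#' [lr_schedule()]. When an [augmentation_config()] is supplied,
#' augmentation is applied on-the-fly to each training image every epoch
#' (never to validation images). The model state with the best validation
#' Dice (prediction binarized at 0.5) is retained; without validation
#' data the final state is kept.
#'
#' @param model A `unet` from [build_unet()].
#' @param train_images List of numeric matrices (preprocessed,
#'   normalized slices).
#' @param train_masks List of logical matrices paired with
#'   `train_images`.
#' @param val_images,val_masks Optional validation pairs.
#' @param config A [train_config()].
#' @param augment Optional [augmentation_config()] for on-the-fly
#'   training augmentation.
#' @param verbose Print one line per epoch.
#' @return The trained `unet`, with a `history` tibble (`epoch`, `lr`,
#'   `train_loss`, `val_dice`) and the best-validation weights.
#' @export
train_unet <- function(model, train_images, train_masks,
                       val_images = NULL, val_masks = NULL,
                       config = train_config(), augment = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "unet"), inherits(config, "train_config"))
  n <- length(train_images)
  if (n == 0) stop("empty training set", call. = FALSE)
  stopifnot(length(train_masks) == n)
  for (x in train_images) check_input_dims(model, x)
  has_val <- !is.null(val_images) && length(val_images) > 0

  withr::with_seed(config$seed, {
    state <- adam_init(model$layers)
    t_step <- 0L
    best <- list(dice = -Inf, layers = model$layers)
    hist <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_schedule(epoch, config)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      losses <- numeric(0)
      for (batch in batches) {
        grads <- NULL
        for (i in batch) {
          img <- train_images[[i]]
          msk <- train_masks[[i]]
          if (!is.null(augment)) {
            aug <- augment_pair(img, msk, augment)
            img <- aug$image
            msk <- aug$mask
          }
          fw <- unet_forward(model, img, keep = TRUE)
          losses <- c(losses, dice_loss(fw$prob, msk))
          dp <- dice_loss_grad(fw$prob, msk)
          dz <- dp * fw$prob * (1 - fw$prob)
          g <- unet_backward(model, fw, dz)
          grads <- if (is.null(grads)) g else {
            mapply(function(acc, new) {
              list(dw = acc$dw + new$dw, db = acc$db + new$db)
            }, grads, g, SIMPLIFY = FALSE)
          }
        }
        grads <- lapply(grads, function(gr) {
          list(dw = gr$dw / length(batch), db = gr$db / length(batch))
        })
        t_step <- t_step + 1L
        upd <- adam_step(model$layers, state, grads, lr, t_step)
        model$layers <- upd$layers
        state <- upd$state
      }
      val_dice <- NA_real_
      if (has_val) {
        val_dice <- mean(vapply(seq_along(val_images), function(i) {
          p <- unet_forward(model, val_images[[i]])$prob
          dice_coefficient(val_masks[[i]], binarize(p, 0.5))
        }, numeric(1)))
        if (val_dice > best$dice) {
          best <- list(dice = val_dice, layers = model$layers)
        }
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr,
        train_loss = mean(losses), val_dice = val_dice
      )
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  val dice %s",
                        epoch, lr, mean(losses),
                        ifelse(is.na(val_dice), "-", sprintf("%.4f", val_dice))))
      }
    }
    if (has_val) model$layers <- best$layers
    model$history <- dplyr::bind_rows(hist)
    model$best_val_dice <- if (has_val) best$dice else NA_real_
  })
  model
}

#' Predict per-pixel fascicle probabilities
#'
#' @param model A `unet`.
#' @param image A preprocessed slice (numeric matrix) whose sides are
#'   divisible by `2^depth`.
#' @return A probability matrix of the same size with values in `[0, 1]`.
#' @export
predict_unet <- function(model, image) {
  stopifnot(inherits(model, "unet"))
  check_input_dims(model, image)
  unet_forward(model, image)$prob
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability strictly exceeds the
#' threshold.
#'
#' @param map Numeric matrix of probabilities.
#' @param threshold Threshold in `[0, 1]` (default 0.5).
#' @return Logical matrix.
#' @export
binarize <- function(map, threshold = 0.5) {
  check_that(is_number(threshold) && threshold >= 0 && threshold <= 1,
             "threshold", "must lie in [0, 1]")
  map > threshold
}

#' @describeIn train_unet Tidy the training history of a fitted model.
#' @param x A `unet`.
#' @param ... Unused.
#' @export
tidy.unet <- function(x, ...) {
  x$history %||% tibble::tibble(
    epoch = integer(0), lr = numeric(0),
    train_loss = numeric(0), val_dice = numeric(0)
  )
}

#' @describeIn train_unet One-row model summary.
#' @export
glance.unet <- function(x, ...) {
  tibble::tibble(
    depth = x$config$depth,
    base_channels = x$config$base_channels,
    n_parameters = n_parameters(x),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$train_loss, 1),
    best_val_dice = x$best_val_dice %||% NA_real_
  )
}
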