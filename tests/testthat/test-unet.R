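test_that("the soft Dice loss matches its closed form", {
  t <- matrix(FALSE, 20, 20); t[1:4, 1:5] <- TRUE     # 20 of 400 px = 5%
  perfect <- t * 1.0
  expect_lt(dice_loss(perfect, t), 0.05)              # ~0 up to smoothing
  expect_gt(dice_loss(1 - perfect, t), 0.95)          # disjoint -> ~1

  # uniform 0.5 prediction against 5% foreground: soft Dice = 0.05/0.55
  u <- matrix(0.5, 20, 20)
  expect_equal(dice_loss(u, t, eps = 0), 1 - 0.05 / 0.55, tolerance = 1e-12)
  expect_equal(dice_loss(u, t), 1 - (2 * 0.5 * 20 + 1) / (200 + 20 + 1),
               tolerance = 1e-12)
  expect_error(dice_loss(matrix(0.5, 2, 2), t), "dimensions")
})

test_that("loss and soft Dice are exact complements", {
  set.seed(6)
  for (i in 1:5) {
    p <- matrix(runif(64), 8, 8)
    t <- matrix(runif(64) > 0.7, 8, 8)
    soft <- (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1)
    expect_equal(dice_loss(p, t) + soft, 1)
  }
})

test_that("the analytic Dice-loss gradient matches numerical differentiation", {
  withr::with_seed(12, {
    p <- matrix(runif(16, 0.2, 0.8), 4, 4)
    t <- matrix(runif(16) > 0.5, 4, 4)
  })
  g <- fascseg:::dice_loss_grad(p, t)
  num <- p * 0
  for (j in seq_along(p)) {
    e <- 1e-6
    p1 <- p; p1[j] <- p[j] + e
    p2 <- p; p2[j] <- p[j] - e
    num[j] <- (dice_loss(p1, t) - dice_loss(p2, t)) / (2 * e)
  }
  expect_equal(g, num, tolerance = 1e-4)
})

test_that("the learning-rate schedule steps down by 0.75 every 8 epochs", {
  cfg <- train_config()
  expect_equal(lr_schedule(1, cfg), 5e-4)
  expect_equal(lr_schedule(8, cfg), 5e-4)
  expect_equal(lr_schedule(9, cfg), 3.75e-4)
  expect_equal(lr_schedule(17, cfg), 2.8125e-4)
  lrs <- vapply(1:40, lr_schedule, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))                       # non-increasing
  expect_identical(length(unique(lrs)), 5L)              # piecewise constant
  expect_true(all(rle(lrs)$lengths == 8))                # period 8
})

test_that("the network builds with the right shapes and output range", {
  cfg <- unet_config(input_size = 32, depth = 2, base_channels = 4)
  net <- build_unet(cfg, seed = 1)
  x <- matrix(runif(32 * 32), 32, 32)
  p <- predict_unet(net, x)
  expect_identical(dim(p), c(32L, 32L))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(predict_unet(net, matrix(0, 32, 32)) >= 0))
  # determinism at inference
  expect_identical(predict_unet(net, x), predict_unet(net, x))
  # indivisible input sizes are rejected
  expect_error(predict_unet(net, matrix(0, 30, 30)), "divisible")
  expect_error(unet_config(input_size = 100, depth = 3), "input_size")
  # parameter count grows with width
  wide <- build_unet(unet_config(input_size = 32, depth = 2,
                                 base_channels = 8), seed = 1)
  expect_gt(n_parameters(wide), n_parameters(net))
})

test_that("backpropagation matches numerical gradients on a tiny network", {
  cfg <- unet_config(input_size = 8, depth = 1, base_channels = 2)
  net <- build_unet(cfg, seed = 2)
  withr::with_seed(1, {
    x <- matrix(runif(64), 8, 8)
    t <- matrix(runif(64) > 0.7, 8, 8)
  })
  fw <- fascseg:::unet_forward(net, x, keep = TRUE)
  dz <- fascseg:::dice_loss_grad(fw$prob, t) * fw$prob * (1 - fw$prob)
  g <- fascseg:::unet_backward(net, fw, dz)
  lossfn <- function(n) dice_loss(fascseg:::unet_forward(n, x)$prob, t)
  for (nm in names(net$layers)) {
    w <- net$layers[[nm]]$w
    for (j in withr::with_seed(3, sample(length(w), min(3, length(w))))) {
      e <- 1e-6
      n2 <- net; n2$layers[[nm]]$w[j] <- w[j] + e
      n3 <- net; n3$layers[[nm]]$w[j] <- w[j] - e
      expect_equal(g[[nm]]$dw[j], (lossfn(n2) - lossfn(n3)) / (2 * e),
                   tolerance = 1e-4)
    }
    b <- net$layers[[nm]]$b
    n2 <- net; n2$layers[[nm]]$b[1] <- b[1] + 1e-6
    n3 <- net; n3$layers[[nm]]$b[1] <- b[1] - 1e-6
    expect_equal(g[[nm]]$db[1], (lossfn(n2) - lossfn(n3)) / 2e-6,
                 tolerance = 1e-4)
  }
})

test_that("training runs, logs the schedule, and reduces the loss", {
  proc <- desk_phantom(41, 8, image_size = 96, crop = 64)
  net <- build_unet(unet_config(input_size = 64, depth = 2,
                                base_channels = 8), seed = 1)
  cfg <- train_config(epochs = 10, batch_size = 4, seed = 2)
  net <- train_unet(net, proc$slices, proc$fascicle_masks, config = cfg)
  h <- tidy(net)
  expect_identical(nrow(h), 10L)
  expect_true(all(is.finite(h$train_loss)))
  expect_equal(h$lr, vapply(1:10, lr_schedule, numeric(1), config = cfg))
  expect_lt(h$train_loss[10], h$train_loss[1])
  expect_error(train_unet(net, list(), list(), config = cfg), "empty")
})

test_that("a one-epoch run produces a single finite history entry", {
  proc <- desk_phantom(42, 5, image_size = 96, crop = 64)
  net <- build_unet(unet_config(input_size = 64, depth = 1,
                                base_channels = 4), seed = 3)
  net <- train_unet(net, proc$slices, proc$fascicle_masks,
                    config = train_config(epochs = 1, batch_size = 5, seed = 1))
  expect_identical(nrow(tidy(net)), 1L)
  expect_true(is.finite(tidy(net)$train_loss))
  expect_identical(glance(net)$epochs_trained, 1L)
})

test_that("binarize thresholds strictly above", {
  m <- matrix(c(0.4, 0.6, 0, 1), 2, 2)
  expect_identical(binarize(m, 0.5), m > 0.5)
  expect_identical(binarize(m, 0), matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  expect_false(any(binarize(m, 1)))
  expect_error(binarize(m, 1.5), "threshold")
})
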