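make_pair <- function(S = 32, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(runif(S * S, 0.5, 1.5), S, S)
    msk <- matrix(FALSE, S, S)
    msk[(S / 2 - 4):(S / 2 + 4), (S / 2 - 2):(S / 2 + 6)] <- TRUE
    list(img = img, msk = msk)
  })
}

test_that("right-angle rotations are lossless permutations", {
  p <- make_pair()
  r0 <- apply_rotation(p$img, p$msk, 0)
  expect_identical(r0$image, p$img)
  r90 <- apply_rotation(p$img, p$msk, 90)
  expect_identical(sort(c(r90$image)), sort(c(p$img)))  # permutation
  r360 <- r90
  for (i in 1:3) r360 <- apply_rotation(r360$image, r360$mask, 90)
  expect_identical(r360$image, p$img)
  expect_identical(r360$mask, p$msk)
  # 180 twice is the identity too
  r180 <- apply_rotation(p$img, p$msk, 180)
  back <- apply_rotation(r180$image, r180$mask, 180)
  expect_equal(back$image, p$img, tolerance = 1e-6)
})

test_that("arbitrary-angle rotation agrees with the exact path at 90 degrees", {
  p <- make_pair()
  exact <- apply_rotation(p$img, p$msk, 90)
  warped <- fascseg:::warp_similarity(p$img, angle = 90, method = "bilinear")
  expect_equal(warped, exact$image, tolerance = 1e-12)
})

test_that("rotation keeps dimensions and fills out-of-frame regions with zero", {
  p <- make_pair()
  r <- apply_rotation(p$img, p$msk, 45)
  expect_identical(dim(r$image), dim(p$img))
  expect_identical(r$image[1, 1], 0)  # corner leaves the frame under 45 deg
  expect_type(r$mask[1, 1], "logical")
})

test_that("flips are involutions with the documented index mapping", {
  p <- make_pair()
  f <- apply_flip(p$img, p$msk, "vertical")
  expect_identical(apply_flip(f$image, f$mask, "vertical")$image, p$img)
  H <- nrow(p$img)
  expect_identical(f$image[H - 3, 5], p$img[4, 5])  # (r,c) -> (H-1-r, c)
  sym <- p$img + p$img[, ncol(p$img):1]
  expect_identical(apply_flip(sym, p$msk, "horizontal")$image, sym)
})

test_that("scaling changes mask area by the squared factor", {
  disk <- matrix(FALSE, 101, 101)
  ctr <- 51
  for (r in 1:101) {
    for (c in 1:101) if ((r - ctr)^2 + (c - ctr)^2 <= 400) disk[r, c] <- TRUE
  }
  up <- apply_scale(disk * 1.0, disk, 1.2)
  expect_equal(sum(up$mask) / sum(disk), 1.44, tolerance = 0.05)
  r_eq <- sqrt(sum(up$mask) / pi)
  expect_equal(r_eq, 1.2 * 20, tolerance = 1)
  down <- apply_scale(disk * 1.0, disk, 0.9)
  expect_equal(sum(down$mask) / sum(disk), 0.81, tolerance = 0.81 * 0.05)
  idn <- apply_scale(disk * 1.0, disk, 1)
  expect_identical(idn$mask, disk)
})

test_that("additive noise has the requested spread and zero mean", {
  img <- matrix(1, 400, 400)
  withr::with_seed(10, {
    noisy <- apply_noise(img, 0.003)
    d <- noisy - img
    expect_gte(stats::sd(d), 0.0028)
    expect_lte(stats::sd(d), 0.0032)
    expect_lt(abs(mean(d)), 3 * 0.003 / sqrt(length(d)))
  })
  expect_identical(apply_noise(img, 0), img)
})

test_that("the intensity field is multiplicative with unit value at the origin", {
  p <- make_pair()
  expect_identical(apply_intensity_field(p$img, 0, 0, 0.1, 0.2), p$img)
  mod <- apply_intensity_field(p$img, 0.3, 0, 0.05, 0.1)
  ratio <- mod / p$img
  expect_true(all(abs(ratio - ratio[rep(1, nrow(ratio)), ]) < 1e-12))  # constant along columns
  expect_true(all(ratio >= 0.7 - 1e-9 & ratio <= 1.3 + 1e-9))
  expect_equal(ratio[1, 1], 1)  # sin(0) = 0 at x = y = 0
})

test_that("compound augmentation is deterministic and records its draws", {
  p <- make_pair()
  cfg <- augmentation_config()
  a1 <- augment_pair(p$img, p$msk, cfg, seed = 99)
  a2 <- augment_pair(p$img, p$msk, cfg, seed = 99)
  expect_identical(a1, a2)
  expect_true(all(a1$applied$transform %in%
                    c("rotation", "flip_vertical", "flip_horizontal",
                      "scale", "noise", "intensity_field")))
  # masks stay strictly binary through every transform
  expect_type(a1$mask[1, 1], "logical")
})

test_that("an all-off configuration is the identity with an empty record", {
  p <- make_pair()
  cfg <- augmentation_config(p_rotation = 0, p_flip_vertical = 0,
                             p_flip_horizontal = 0, p_scale = 0,
                             noise_std_range = c(0, 0),
                             p_intensity_field = 0)
  a <- augment_pair(p$img, p$msk, cfg, seed = 1)
  expect_identical(a$image, p$img)
  expect_identical(a$mask, p$msk)
  expect_identical(nrow(a$applied), 0L)
})

test_that("geometric draws are shared so the mask never moves off its image", {
  # mark the image with the mask itself: after any augmentation the bright
  # region must coincide with the transformed mask wherever it is interior
  S <- 48
  msk <- matrix(FALSE, S, S); msk[20:28, 14:30] <- TRUE
  img <- msk * 1.0
  cfg <- augmentation_config(noise_std_range = c(0, 0))
  for (seed in 1:10) {
    a <- augment_pair(img, msk, cfg, seed = seed)
    inside <- a$image > 0.5
    agree <- mean(inside == a$mask)
    expect_gte(agree, 0.98)  # only interpolated blob edges may disagree
  }
})

test_that("application frequencies follow the configured probabilities", {
  n <- 4000
  cfg <- augmentation_config()
  img <- matrix(1, 8, 8); msk <- matrix(FALSE, 8, 8)
  counts <- withr::with_seed(123, {
    tab <- c(rotation = 0, flip_vertical = 0, flip_horizontal = 0,
             scale = 0, intensity_field = 0)
    for (i in seq_len(n)) {
      a <- augment_pair(img, msk, cfg)
      for (tr in a$applied$transform) {
        if (tr %in% names(tab)) tab[tr] <- tab[tr] + 1
      }
    }
    tab
  })
  probs <- c(0.5, 1 / 3, 1 / 3, 2 / 3, 0.5)
  for (i in seq_along(counts)) {
    expect_gt(stats::binom.test(counts[i], n, probs[i])$p.value, 0.01)
  }
})
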