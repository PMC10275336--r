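#' Augmentation configuration
#'
#' Application probabilities and parameter ranges for the compound
#' on-the-fly augmentation applied to training image/mask pairs:
#' (1) random rotation of 0-270 degrees on 50% of images, (2) a vertical
#' or horizontal flip each on 1/3 of images, (3) random scaling between
#' 0.9x and 1.2x on 2/3 of images, (4) additive zero-mean Gaussian noise
#' with a standard deviation drawn uniformly from 0.001-0.003 on every
#' image (on the normalized, mean-1 intensity scale), and (5) a random
#' multiplicative intensity field `f(x, y) = A sin(a x) + B sin(b y) + 1`
#' with `A, B, a, b` drawn from 0.001-0.3, on 50% of images.
#'
#' @param p_rotation,p_flip_vertical,p_flip_horizontal,p_scale,p_intensity_field
#'   Application probabilities.
#' @param rotation_range Degrees, drawn uniformly.
#' @param scale_range Scale factors, drawn uniformly.
#' @param noise_std_range Noise standard deviation range (drawn uniformly;
#'   noise itself is applied to every image).
#' @param field_param_range Range for each of the intensity-field
#'   parameters `A`, `B`, `a`, `b`.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(p_rotation = 0.5,
                                rotation_range = c(0, 270),
                                p_flip_vertical = 1 / 3,
                                p_flip_horizontal = 1 / 3,
                                p_scale = 2 / 3,
                                scale_range = c(0.9, 1.2),
                                noise_std_range = c(0.001, 0.003),
                                p_intensity_field = 0.5,
                                field_param_range = c(0.001, 0.3)) {
  for (nm in c("p_rotation", "p_flip_vertical", "p_flip_horizontal",
               "p_scale", "p_intensity_field")) {
    check_that(is_prob(get(nm)), nm, "must be a probability in [0, 1]")
  }
  for (nm in c("rotation_range", "scale_range", "noise_std_range",
               "field_param_range")) {
    check_that(is_range(get(nm)), nm, "must be an ordered numeric pair")
  }
  check_that(all(noise_std_range >= 0), "noise_std_range",
             "must be nonnegative")
  structure(
    list(p_rotation = p_rotation, rotation_range = rotation_range,
         p_flip_vertical = p_flip_vertical,
         p_flip_horizontal = p_flip_horizontal,
         p_scale = p_scale, scale_range = scale_range,
         noise_std_range = noise_std_range,
         p_intensity_field = p_intensity_field,
         field_param_range = field_param_range),
    class = "augmentation_config"
  )
}

# Inverse-mapping similarity warp (rotation about the image center by
# `angle` degrees counter-clockwise, then scaling about the center).
# Bilinear or nearest-neighbour sampling; out-of-frame regions -> fill.
warp_similarity <- function(m, angle = 0, scale = 1,
                            method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  th <- angle * pi / 180
  dr <- matrix(0:(H - 1) - cr, H, W)
  dc <- matrix(0:(W - 1) - cc, H, W, byrow = TRUE)
  # inverse transform: un-scale, then rotate by -angle
  # (forward CCW rotation in display coordinates maps (r,c) -> (W-1-c, r)
  #  at 90 degrees; the inverse therefore uses the transpose rotation)
  sr <- (cos(th) * dr + sin(th) * dc) / scale + cr
  sc <- (-sin(th) * dr + cos(th) * dc) / scale + cc
  if (method == "nearest") {
    ri <- round_half_away(sr) + 1
    ci <- round_half_away(sc) + 1
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(fill, H, W)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(fill, H, W)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  out <- gather(r0 + 1, c0 + 1) * (1 - fr) * (1 - fc) +
    gather(r0 + 2, c0 + 1) * fr * (1 - fc) +
    gather(r0 + 1, c0 + 2) * (1 - fr) * fc +
    gather(r0 + 2, c0 + 2) * fr * fc
  out
}

#' Rotate an image/mask pair about the image center
#'
#' The image is interpolated bilinearly and the mask by nearest neighbour;
#' output dimensions are unchanged and out-of-frame regions are filled
#' with 0 / `FALSE`. Multiples of 90 degrees on square inputs take an
#' exact permutation path with no interpolation loss.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same size.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @return A list with rotated `image` and `mask`.
#' @export
apply_rotation <- function(image, mask, angle) {
  stopifnot_same_dim(image, mask, "image and mask")
  if (angle %% 90 == 0 && nrow(image) == ncol(image)) {
    k <- as.integer((angle %/% 90) %% 4)
    return(list(image = rot90_mat(image, k), mask = rot90_mat(mask, k)))
  }
  list(
    image = warp_similarity(image, angle = angle, method = "bilinear", fill = 0),
    mask = warp_similarity(mask * 1, angle = angle, method = "nearest",
                           fill = 0) > 0
  )
}

#' Flip an image/mask pair
#'
#' A vertical flip mirrors rows (pixel `(r, c)` moves to `(H-1-r, c)` in
#' 0-based coordinates); a horizontal flip mirrors columns. Flips are
#' exact permutations and involutions.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same size.
#' @param axis `"vertical"` or `"horizontal"`.
#' @return A list with flipped `image` and `mask`.
#' @export
apply_flip <- function(image, mask, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  stopifnot_same_dim(image, mask, "image and mask")
  flip <- function(m) {
    if (axis == "vertical") m[nrow(m):1, , drop = FALSE]
    else m[, ncol(m):1, drop = FALSE]
  }
  list(image = flip(image), mask = flip(mask))
}

#' Scale an image/mask pair about the image center
#'
#' Content is rescaled by `factor` about the center on a fixed canvas, so
#' factors above 1 crop the enlarged content back to the original frame
#' and factors below 1 leave a zero-filled border. The mask is resampled
#' by nearest neighbour.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same size.
#' @param factor Scale factor.
#' @return A list with scaled `image` and `mask`.
#' @export
apply_scale <- function(image, mask, factor) {
  stopifnot_same_dim(image, mask, "image and mask")
  check_that(is_number(factor) && factor > 0, "factor", "must be positive")
  if (factor == 1) return(list(image = image, mask = mask))
  list(
    image = warp_similarity(image, scale = factor, method = "bilinear", fill = 0),
    mask = warp_similarity(mask * 1, scale = factor, method = "nearest",
                           fill = 0) > 0
  )
}

#' Additive zero-mean Gaussian noise
#'
#' @param image Numeric matrix (normalized, mean-1 intensity scale).
#' @param std Noise standard deviation.
#' @return The noisy image; masks are never touched by noise.
#' @export
apply_noise <- function(image, std) {
  check_that(is_number(std) && std >= 0, "std", "must be nonnegative")
  if (std == 0) return(image)
  image + matrix(rnorm(length(image), 0, std), nrow(image), ncol(image))
}

#' Multiplicative sinusoidal intensity field
#'
#' Multiplies the image pointwise by
#' `f(x, y) = A sin(a x) + B sin(b y) + 1`, where `x` is the 0-based
#' column index and `y` the 0-based row index in pixels. With parameters
#' in the configured 0.001-0.3 range the field stays within about
#' `[0.4, 1.6]`, emulating smooth illumination/staining variation.
#'
#' @param image Numeric matrix.
#' @param A,B Sine amplitudes.
#' @param a,b Spatial frequencies (radians per pixel).
#' @return The modulated image.
#' @export
apply_intensity_field <- function(image, A, B, a, b) {
  y <- matrix(0:(nrow(image) - 1), nrow(image), ncol(image))
  x <- matrix(0:(ncol(image) - 1), nrow(image), ncol(image), byrow = TRUE)
  image * (A * sin(a * x) + B * sin(b * y) + 1)
}

#' Compound random augmentation of an image/mask pair
#'
#' Applies each sub-transform independently with its configured
#' probability, in the fixed order rotation, vertical flip, horizontal
#' flip, scale, noise, intensity field. Geometric transforms use a single
#' parameter draw shared by image and mask, so the mask never moves
#' relative to its image. Noise is applied to every image with a standard
#' deviation drawn from the configured range.
#'
#' @param image Numeric matrix (preprocessed, mean-1 scale).
#' @param mask Logical matrix paired with `image`.
#' @param config An [augmentation_config()].
#' @param seed Optional integer; when given, draws come from a private
#'   RNG stream seeded with it (the caller's RNG state is untouched).
#'   When `NULL`, the current RNG stream is used, which is how the
#'   training loop obtains one reproducible stream for a whole run.
#' @return A list with `image`, `mask`, and `applied`, a tibble recording
#'   each applied transform and its sampled parameters.
#' @export
augment_pair <- function(image, mask, config = augmentation_config(),
                         seed = NULL) {
  stopifnot(inherits(config, "augmentation_config"))
  stopifnot_same_dim(image, mask, "image and mask")
  if (!is.null(seed)) {
    return(withr::with_seed(seed, augment_pair(image, mask, config)))
  }
  applied <- list()
  note <- function(transform, ...) {
    applied[[length(applied) + 1L]] <<-
      tibble::tibble(transform = transform, params = list(list(...)))
  }
  if (runif(1) < config$p_rotation) {
    angle <- runif(1, config$rotation_range[1], config$rotation_range[2])
    rot <- apply_rotation(image, mask, angle)
    image <- rot$image; mask <- rot$mask
    note("rotation", angle = angle)
  }
  if (runif(1) < config$p_flip_vertical) {
    fl <- apply_flip(image, mask, "vertical")
    image <- fl$image; mask <- fl$mask
    note("flip_vertical")
  }
  if (runif(1) < config$p_flip_horizontal) {
    fl <- apply_flip(image, mask, "horizontal")
    image <- fl$image; mask <- fl$mask
    note("flip_horizontal")
  }
  if (runif(1) < config$p_scale) {
    factor <- runif(1, config$scale_range[1], config$scale_range[2])
    sc <- apply_scale(image, mask, factor)
    image <- sc$image; mask <- sc$mask
    note("scale", factor = factor)
  }
  std <- runif(1, config$noise_std_range[1], config$noise_std_range[2])
  if (std > 0) {
    image <- apply_noise(image, std)
    note("noise", std = std)
  }
  if (runif(1) < config$p_intensity_field) {
    pr <- runif(4, config$field_param_range[1], config$field_param_range[2])
    image <- apply_intensity_field(image, pr[1], pr[2], pr[3], pr[4])
    note("intensity_field", A = pr[1], B = pr[2], a = pr[3], b = pr[4])
  }
  list(
    image = image, mask = mask,
    applied = if (length(applied)) dplyr::bind_rows(applied) else
      tibble::tibble(transform = character(0), params = list())
  )
}
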