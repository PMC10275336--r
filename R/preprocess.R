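#' Contrast-enhancement parameters
#'
#' Settings for the 16-to-8-bit contrast step of [enhance_contrast()]:
#' pixels above `saturation_threshold` (bright staining-artifact specks)
#' are zeroed, then the lowest `low_tail` fraction of the remaining pixels
#' maps to 1, the highest `high_tail` fraction to 255, and everything in
#' between is rescaled linearly.
#'
#' @param saturation_threshold 16-bit intensity above which a pixel is
#'   treated as a staining artifact (default 18,000).
#' @param low_tail,high_tail Tail fractions in (0, 0.5) (default 0.001,
#'   i.e. 0.1%).
#' @return A list of class `contrast_params`.
#' @export
contrast_params <- function(saturation_threshold = 18000,
                            low_tail = 0.001, high_tail = 0.001) {
  check_that(is_number(saturation_threshold) && saturation_threshold > 0 &&
               saturation_threshold <= 65535,
             "saturation_threshold", "must lie in (0, 65535]")
  check_that(is_number(low_tail) && low_tail > 0 && low_tail < 0.5,
             "low_tail", "must lie in (0, 0.5)")
  check_that(is_number(high_tail) && high_tail > 0 && high_tail < 0.5,
             "high_tail", "must lie in (0, 0.5)")
  structure(
    list(saturation_threshold = saturation_threshold,
         low_tail = low_tail, high_tail = high_tail),
    class = "contrast_params"
  )
}

#' Drop slices whose epineurium is not fully in the field of view
#'
#' Removes every slice whose epineurium mask has a true pixel on any image
#' border (the sheath is cut off by the frame) or is entirely empty. The
#' 1-based indices of removed slices are attached as attribute `removed`.
#'
#' @param stack A [nerve_stack()] with epineurium masks.
#' @return The filtered [nerve_stack()] (possibly empty, with a warning).
#' @export
exclude_border_slices <- function(stack) {
  stopifnot(inherits(stack, "nerve_stack"))
  bad <- vapply(stack$epineurium_masks, function(m) {
    !any(m) || any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])
  }, logical(1))
  keep <- which(!bad)
  if (length(keep) == 0 && length(bad) > 0) {
    warning("all slices removed: no slice contains a whole interior epineurium",
            call. = FALSE)
  }
  out <- nerve_stack(
    stack$nerve_id,
    stack$slices[keep],
    stack$fascicle_masks[keep],
    stack$epineurium_masks[keep],
    stack$pixel_spacing,
    stack$slice_spacing
  )
  attr(out, "removed") <- which(bad)
  out
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the true-pixel coordinates, in 0-based `(row, col)`
#' convention (so a lone pixel in the top-left corner is at `(0, 0)`).
#'
#' @param mask Logical matrix with at least one true pixel.
#' @return Numeric `c(row, col)`, 0-based.
#' @export
compute_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("cannot compute the centroid of an empty mask (unusable slice)",
         call. = FALSE)
  }
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
}

# crop any matrix to a size x size window starting at 0-based (r0, c0),
# zero/FALSE-padding where the window leaves the image
crop_window <- function(m, r0, c0, size, fill = 0) {
  out <- matrix(fill, size, size)
  storage.mode(out) <- storage.mode(m)
  src_r <- (r0 + 1):(r0 + size)
  src_c <- (c0 + 1):(c0 + size)
  ok_r <- which(src_r >= 1 & src_r <= nrow(m))
  ok_c <- which(src_c >= 1 & src_c <= ncol(m))
  if (length(ok_r) && length(ok_c)) {
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  }
  out
}

#' Crop a slice (and its masks) around a centroid
#'
#' Extracts a `size` x `size` window centered at the centroid (rounded
#' half-away-from-zero to the nearest pixel); image and all masks are cut
#' with the same window, and any window extent beyond the image is padded
#' with zeros (background) / `FALSE`.
#'
#' @param image Numeric matrix.
#' @param centroid Numeric `c(row, col)`, 0-based, e.g. from
#'   [compute_centroid()].
#' @param size Output side length in pixels (default 400).
#' @param masks Optional named list of logical matrices cropped with the
#'   same window.
#' @return A list with `image`, `masks`, and the 0-based inclusive
#'   `window` (`row0`, `row1`, `col0`, `col1`).
#' @export
center_crop <- function(image, centroid, size = 400L, masks = list()) {
  check_that(is_count(size), "size", "must be a positive integer")
  size <- as.integer(size)
  cr <- round_half_away(centroid[[1]])
  cc <- round_half_away(centroid[[2]])
  r0 <- cr - size %/% 2L
  c0 <- cc - size %/% 2L
  list(
    image = crop_window(image, r0, c0, size, fill = 0),
    masks = lapply(masks, function(m) crop_window(m, r0, c0, size, fill = FALSE) > 0),
    window = c(row0 = r0, row1 = r0 + size - 1, col0 = c0, col1 = c0 + size - 1)
  )
}

#' Saturation-aware 16-to-8-bit contrast enhancement
#'
#' Pixels above the saturation threshold (staining artifacts) are set to
#' 0. Over the remaining pixels, the `low_tail` / `high_tail` percentile
#' bounds are computed (artifact pixels are excluded so their zeroed mass
#' cannot corrupt the low tail); pixels at or below the low bound map to
#' 1, at or above the high bound to 255, and the rest are rescaled
#' linearly onto `[1, 255]` and rounded to the nearest integer (ties to
#' even). Output values therefore lie in `{0} U [1, 255]`.
#'
#' If the two percentile bounds coincide (a constant non-saturated image),
#' all non-saturated pixels are set to 255 and a warning is emitted.
#'
#' @param image Numeric matrix of 16-bit intensities.
#' @param params A [contrast_params()] object.
#' @return Integer matrix with values in `{0} U [1, 255]`.
#' @export
enhance_contrast <- function(image, params = contrast_params()) {
  stopifnot(inherits(params, "contrast_params"), length(image) > 0)
  sat <- image > params$saturation_threshold
  out <- matrix(0L, nrow(image), ncol(image))
  v <- image[!sat]
  if (length(v) == 0) {
    warning("every pixel is saturated; output is all zero", call. = FALSE)
    return(out)
  }
  lo <- unname(quantile(v, params$low_tail))
  hi <- unname(quantile(v, 1 - params$high_tail))
  if (hi <= lo) {
    warning("degenerate contrast: percentile bounds coincide; mapping to 255",
            call. = FALSE)
    out[!sat] <- 255L
    return(out)
  }
  scaled <- (v - lo) / (hi - lo) * 254 + 1
  scaled[v <= lo] <- 1
  scaled[v >= hi] <- 255
  out[!sat] <- as.integer(round(scaled))
  out
}

#' Normalize a slice by its mean intensity
#'
#' Divides every pixel by the slice mean (and records nothing else), so
#' the output mean is 1 to floating tolerance. Conversion to floating
#' point happens implicitly.
#'
#' @param image Numeric matrix with positive mean.
#' @return Numeric matrix with mean 1.
#' @export
normalize_slice <- function(image) {
  m <- mean(image)
  if (!is.finite(m) || m <= 0) {
    stop("cannot normalize: slice mean is not positive", call. = FALSE)
  }
  image / m
}

# reflect-pad a matrix by r pixels on every side
pad_reflect <- function(m, r) {
  n <- nrow(m); k <- ncol(m)
  ri <- c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1, 1))
  ci <- c(pmin(r:1, k), 1:k, pmax(k - seq_len(r) + 1, 1))
  m[ri, ci, drop = FALSE]
}

#' Gaussian smoothing with reflective boundaries
#'
#' Separable 2-D Gaussian convolution. The discrete kernel is the sampled
#' Gaussian normalized to unit sum, truncated at `max(1, ceiling(4 sigma))`
#' pixels; boundaries are handled by reflection, so a constant image is
#' exactly preserved and total intensity is conserved to well within 0.1%
#' on interior-dominated images.
#'
#' @param image Numeric matrix.
#' @param sigma Kernel standard deviation in pixels (default 1).
#' @return Smoothed numeric matrix of the same size.
#' @export
gaussian_smooth <- function(image, sigma = 1) {
  check_that(is_number(sigma) && sigma > 0, "sigma", "must be positive")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  xp <- pad_reflect(image, r)
  n <- nrow(image); m <- ncol(image)
  # convolve along rows
  tmp <- matrix(0, n, ncol(xp))
  for (j in seq_along(k)) {
    tmp <- tmp + k[j] * xp[(j - 1) + seq_len(n), , drop = FALSE]
  }
  out <- matrix(0, n, m)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j - 1) + seq_len(m), drop = FALSE]
  }
  out
}

#' Run the full preprocessing chain on a stack
#'
#' Applies, in order: border-slice exclusion, epineurium-centroid
#' centering and cropping, contrast enhancement, mean normalization, and
#' Gaussian smoothing (smoothing is placed after normalization and
#' recorded as such in the provenance). Masks are cropped with the same
#' windows as their slices.
#'
#' @param stack A [nerve_stack()] with epineurium masks.
#' @param crop_size Crop window side in pixels (default 400).
#' @param contrast A [contrast_params()] object.
#' @param sigma Gaussian smoothing standard deviation in pixels; `NULL`
#'   skips smoothing.
#' @param exclude_border Whether to drop border-touching slices first.
#' @return A list of class `processed_stack` with elements `nerve_id`,
#'   `slices` (normalized float matrices), `fascicle_masks`,
#'   `epineurium_masks`, `pixel_spacing`, and `provenance` (a tibble with
#'   one row per surviving slice: original index, centroid, crop window,
#'   applied steps).
#' @export
preprocess_stack <- function(stack, crop_size = 400L,
                             contrast = contrast_params(), sigma = 1,
                             exclude_border = TRUE) {
  stopifnot(inherits(stack, "nerve_stack"))
  removed <- integer(0)
  orig_index <- seq_along(stack$slices)
  if (exclude_border) {
    stack <- exclude_border_slices(stack)
    removed <- attr(stack, "removed")
    orig_index <- setdiff(orig_index, removed)
  }
  n <- length(stack$slices)
  slices <- vector("list", n)
  fmasks <- vector("list", n)
  emasks <- vector("list", n)
  prov <- vector("list", n)
  steps <- paste(
    c("center_crop", "enhance_contrast", "normalize",
      if (!is.null(sigma)) "gaussian_smooth"),
    collapse = "+"
  )
  for (i in seq_len(n)) {
    ctr <- compute_centroid(stack$epineurium_masks[[i]])
    cr <- center_crop(
      stack$slices[[i]], ctr, crop_size,
      masks = list(fascicle = stack$fascicle_masks[[i]],
                   epineurium = stack$epineurium_masks[[i]])
    )
    img <- enhance_contrast(cr$image, contrast)
    img <- normalize_slice(img)
    if (!is.null(sigma)) img <- gaussian_smooth(img, sigma)
    slices[[i]] <- img
    fmasks[[i]] <- cr$masks$fascicle
    emasks[[i]] <- cr$masks$epineurium
    prov[[i]] <- tibble::tibble(
      slice = i, original_slice = orig_index[i],
      centroid_row = unname(ctr[1]), centroid_col = unname(ctr[2]),
      window_row0 = unname(cr$window["row0"]),
      window_col0 = unname(cr$window["col0"]),
      steps = steps
    )
  }
  structure(
    list(
      nerve_id = stack$nerve_id,
      slices = slices,
      fascicle_masks = fmasks,
      epineurium_masks = emasks,
      pixel_spacing = stack$pixel_spacing,
      removed_slices = removed,
      provenance = dplyr::bind_rows(prov)
    ),
    class = "processed_stack"
  )
}

#' @export
print.processed_stack <- function(x, ...) {
  cat(sprintf(
    "<processed_stack '%s'>: %d slice(s)%s\n",
    x$nerve_id, length(x$slices),
    if (length(x$removed_slices)) {
      sprintf(" (%d border slice(s) removed)", length(x$removed_slices))
    } else ""
  ))
  invisible(x)
}
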