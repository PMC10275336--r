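#' Nerve image stack
#'
#' A `nerve_stack` bundles an ordered set of 2-D 16-bit microCT slices with
#' their paired ground-truth binary masks: one fascicle layer and one
#' epineurium layer per slice. Every ground-truth fascicle pixel lies inside
#' the epineurium mask, mirroring the anatomy (fascicles are enclosed by the
#' epineurial sheath).
#'
#' @param nerve_id Character scalar identifying the specimen.
#' @param slices List of integer/numeric matrices with values in
#'   `[0, 65535]`, all with identical dimensions.
#' @param fascicle_masks,epineurium_masks Lists of logical matrices paired
#'   one-to-one with `slices`.
#' @param pixel_spacing In-plane pixel size in micrometres (default 10).
#' @param slice_spacing Distance between consecutive slices in micrometres
#'   (default 100).
#'
#' @return An object of class `nerve_stack`.
#' @export
nerve_stack <- function(nerve_id, slices, fascicle_masks, epineurium_masks,
                        pixel_spacing = 10, slice_spacing = 100) {
  stopifnot(is.character(nerve_id), length(nerve_id) == 1L)
  n <- length(slices)
  if (length(fascicle_masks) != n || length(epineurium_masks) != n) {
    stop("slices, fascicle_masks and epineurium_masks must have equal length",
         call. = FALSE)
  }
  if (n > 0) {
    d <- dim(slices[[1]])
    for (i in seq_len(n)) {
      if (!identical(dim(slices[[i]]), d)) {
        stop(sprintf(
          "slice %d has dimensions %s but slice 1 has %s",
          i, paste(dim(slices[[i]]), collapse = "x"), paste(d, collapse = "x")
        ), call. = FALSE)
      }
      stopifnot_same_dim(fascicle_masks[[i]], slices[[i]],
                         sprintf("fascicle mask %d and its slice", i))
      stopifnot_same_dim(epineurium_masks[[i]], slices[[i]],
                         sprintf("epineurium mask %d and its slice", i))
      if (any(fascicle_masks[[i]] & !epineurium_masks[[i]])) {
        stop(sprintf("fascicle mask %d has pixels outside the epineurium", i),
             call. = FALSE)
      }
    }
  }
  structure(
    list(
      nerve_id = nerve_id,
      slices = slices,
      fascicle_masks = lapply(fascicle_masks, function(m) m > 0),
      epineurium_masks = lapply(epineurium_masks, function(m) m > 0),
      pixel_spacing = pixel_spacing,
      slice_spacing = slice_spacing
    ),
    class = "nerve_stack"
  )
}

#' @export
print.nerve_stack <- function(x, ...) {
  n <- length(x$slices)
  d <- if (n > 0) paste(dim(x$slices[[1]]), collapse = " x ") else "empty"
  cat(sprintf(
    "<nerve_stack '%s'>: %d slice(s) of %s px, %g um/px in-plane, %g um between slices\n",
    x$nerve_id, n, d, x$pixel_spacing, x$slice_spacing
  ))
  if (n > 0) {
    frac <- mean(vapply(x$fascicle_masks, mean, numeric(1)))
    cat(sprintf("  mean fascicle pixel fraction: %.3f\n", frac))
  }
  invisible(x)
}

#' Number of slices in a stack
#' @param x A `nerve_stack`.
#' @return Integer slice count.
#' @export
n_slices <- function(x) {
  stopifnot(inherits(x, "nerve_stack"))
  length(x$slices)
}

#' Per-slice summary of a nerve stack
#'
#' @param x A `nerve_stack`.
#' @param ... Unused.
#' @return A tibble with one row per slice: slice index, mean intensity,
#'   fascicle pixel fraction, and the number of 8-connected fascicle
#'   components.
#' @export
tidy.nerve_stack <- function(x, ...) {
  tibble::tibble(
    slice = seq_along(x$slices),
    mean_intensity = vapply(x$slices, mean, numeric(1)),
    fascicle_fraction = vapply(x$fascicle_masks, mean, numeric(1)),
    n_fascicles = vapply(
      x$fascicle_masks,
      function(m) max(0L, max(label_fascicles(m)$labels)),
      integer(1)
    )
  )
}
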