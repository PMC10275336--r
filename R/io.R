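#' Write a nerve stack to a directory of TIFF files
#'
#' Slices are written as 16-bit grayscale TIFFs named
#' `<nerve_id>_slice_<index:04d>.tif` (slice indices 1-based in filenames);
#' the paired masks as 8-bit 0/255 TIFFs with `_fascicle` / `_epineurium`
#' suffixes. A JSON sidecar `<nerve_id>_meta.json` records the identifier
#' and voxel spacing so a stack round-trips exactly.
#'
#' @param stack A [nerve_stack()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "nerve_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- stack$nerve_id
  for (i in seq_along(stack$slices)) {
    base <- file.path(dir, sprintf("%s_slice_%04d", id, i))
    tiff::writeTIFF(stack$slices[[i]] / 65535, paste0(base, ".tif"),
                    bits.per.sample = 16L)
    tiff::writeTIFF((stack$fascicle_masks[[i]] * 255) / 255,
                    paste0(base, "_fascicle.tif"), bits.per.sample = 8L)
    tiff::writeTIFF((stack$epineurium_masks[[i]] * 255) / 255,
                    paste0(base, "_epineurium.tif"), bits.per.sample = 8L)
  }
  meta <- list(
    nerve_id = id,
    n_slices = length(stack$slices),
    pixel_spacing = stack$pixel_spacing,
    slice_spacing = stack$slice_spacing
  )
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_meta.json", id)),
                       auto_unbox = TRUE)
  invisible(dir)
}

read_one_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  structure(matrix(as.integer(img), nrow(img), ncol(img)), bits = bits)
}

#' Read a nerve stack from disk
#'
#' Reads either a directory written by [write_stack()] (per-slice 16-bit
#' image TIFFs plus optional `_fascicle` / `_epineurium` 8-bit mask TIFFs,
#' ordered by the slice index parsed from the filenames) or a single
#' multi-page 16-bit TIFF (with sibling `<stem>_fascicle.tif` /
#' `<stem>_epineurium.tif` multi-page mask files, ordered by page). Mask
#' pixels are binarized at `> 0`. Missing mask layers default to all-false
#' fascicles and all-true epineurium.
#'
#' @param path Directory or multi-page TIFF file.
#' @param pixel_spacing,slice_spacing Voxel spacing in um, used when no
#'   JSON sidecar provides them.
#' @return A [nerve_stack()].
#' @export
read_stack <- function(path, pixel_spacing = 10, slice_spacing = 100) {
  if (dir.exists(path)) {
    return(read_stack_dir(path, pixel_spacing, slice_spacing))
  }
  if (!file.exists(path)) {
    stop(sprintf("no such file or directory: %s", path), call. = FALSE)
  }
  read_stack_multipage(path, pixel_spacing, slice_spacing)
}

read_stack_dir <- function(dir, pixel_spacing, slice_spacing) {
  files <- list.files(dir, pattern = "_slice_[0-9]+\\.tif$", full.names = TRUE)
  files <- files[!grepl("_(fascicle|epineurium)\\.tif$", files)]
  if (length(files) == 0) {
    stop(sprintf("no '<id>_slice_<index>.tif' images found in %s", dir),
         call. = FALSE)
  }
  idx <- as.integer(sub("^.*_slice_([0-9]+)\\.tif$", "\\1", files))
  files <- files[order(idx)]
  id <- sub("_slice_[0-9]+\\.tif$", "", basename(files[1]))

  meta_path <- file.path(dir, sprintf("%s_meta.json", id))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pixel_spacing <- as.numeric(meta$pixel_spacing %||% pixel_spacing)
    slice_spacing <- as.numeric(meta$slice_spacing %||% slice_spacing)
  }

  slices <- vector("list", length(files))
  fmasks <- vector("list", length(files))
  emasks <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- read_one_tiff(files[i])
    if (!identical(attr(img, "bits"), 16L)) {
      stop(sprintf("%s: expected a 16-bit image, found %s bits per sample",
                   files[i], attr(img, "bits")), call. = FALSE)
    }
    if (i > 1 && !identical(dim(img), dim(slices[[1]]))) {
      stop(sprintf(
        "mixed slice dimensions in %s: %s is %s but %s is %s",
        dir, basename(files[1]), paste(dim(slices[[1]]), collapse = "x"),
        basename(files[i]), paste(dim(img), collapse = "x")
      ), call. = FALSE)
    }
    attr(img, "bits") <- NULL
    slices[[i]] <- img
    base <- sub("\\.tif$", "", files[i])
    fp <- paste0(base, "_fascicle.tif")
    ep <- paste0(base, "_epineurium.tif")
    fmasks[[i]] <- if (file.exists(fp)) read_one_tiff(fp) > 0 else
      matrix(FALSE, nrow(img), ncol(img))
    emasks[[i]] <- if (file.exists(ep)) read_one_tiff(ep) > 0 else
      matrix(TRUE, nrow(img), ncol(img))
  }
  nerve_stack(id, slices, fmasks, emasks, pixel_spacing, slice_spacing)
}

read_stack_multipage <- function(path, pixel_spacing, slice_spacing) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!identical(bits, 16L)) {
    stop(sprintf("%s: expected a 16-bit image, found %s bits per sample",
                 path, bits), call. = FALSE)
  }
  to_int <- function(m) matrix(as.integer(m), nrow(m), ncol(m))
  slices <- lapply(pages, to_int)
  stem <- sub("\\.tif{1,2}$", "", path)
  read_masks <- function(suffix, default) {
    f <- paste0(stem, suffix, ".tif")
    if (file.exists(f)) {
      lapply(tiff::readTIFF(f, all = TRUE, as.is = TRUE), function(m) m > 0)
    } else {
      lapply(slices, function(s) matrix(default, nrow(s), ncol(s)))
    }
  }
  nerve_stack(
    basename(stem), slices,
    read_masks("_fascicle", FALSE), read_masks("_epineurium", TRUE),
    pixel_spacing, slice_spacing
  )
}

#' Down-sample a stack along the nerve axis
#'
#' Keeps every `factor`-th slice, i.e. the slices at 1-based indices
#' `factor, 2*factor, ...`, so a 512-slice volume down-sampled 10x yields
#' exactly 51 slices (`floor(512/10)`). Masks are down-sampled with the
#' same rule, and the slice spacing is multiplied by `factor`.
#'
#' @param stack A [nerve_stack()].
#' @param factor Positive integer down-sampling factor (default 10).
#' @return A [nerve_stack()] with `floor(n_slices / factor)` slices.
#' @export
downsample_stack <- function(stack, factor = 10L) {
  stopifnot(inherits(stack, "nerve_stack"))
  check_that(is_count(factor), "factor", "must be a positive integer")
  factor <- as.integer(factor)
  keep <- seq_len(length(stack$slices) %/% factor) * factor
  if (length(keep) == 0) {
    warning(sprintf(
      "down-sampling %d slice(s) by %d leaves no slices",
      length(stack$slices), factor
    ), call. = FALSE)
  }
  nerve_stack(
    stack$nerve_id,
    stack$slices[keep],
    stack$fascicle_masks[keep],
    stack$epineurium_masks[keep],
    stack$pixel_spacing,
    stack$slice_spacing * factor
  )
}
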