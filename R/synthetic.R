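#' Parameters for the synthetic nerve-phantom generator
#'
#' Bundles and validates every knob of [generate_stack()]. The defaults are
#' chosen to emulate the statistical structure of osmium-stained microCT
#' cross-sections of a large peripheral nerve: bright fascicle blobs inside
#' a dimmer epineurium ellipse on a dark background, roughly 5% of the
#' frame covered by fascicle pixels, fascicle areas spanning the tiny
#' (<20,000 um^2) through large (>300,000 um^2) size classes, per-slice
#' brightness drift, rare very bright staining-artifact specks above the
#' 16-bit value 18,000, and occasional fascicle merge/split along the
#' stack axis.
#'
#' @param image_size Pixels per side of the square frame (default 512).
#' @param n_slices Number of slices in the stack.
#' @param n_fascicles Number of fascicles.
#' @param fascicle_area_range Min/max fascicle cross-section area in um^2.
#' @param target_fascicle_fraction Target mean fraction of frame pixels
#'   covered by fascicles, in (0, 0.5) (default 0.05).
#' @param artifact_density Expected artifact specks per slice (Poisson
#'   mean); when positive, at least one speck above 18,000 is guaranteed
#'   per stack.
#' @param artifact_value_range 16-bit intensity range for artifact specks;
#'   the upper bound must exceed 18,000 and may not exceed 65,535.
#' @param brightness_drift Range of the multiplicative per-slice
#'   brightness factor.
#' @param merge_split_rate Expected merge/split events per millimetre of
#'   nerve; when positive at least one event is placed. Real human vagus
#'   nerves show roughly one event per 0.56 mm; the default is gentler so
#'   that default phantoms keep mostly distinct fascicles.
#' @param pixel_spacing In-plane pixel size, um (default 10).
#' @param slice_spacing Slice-to-slice distance, um (default 100).
#' @param seed Integer seed; the whole stack is a deterministic function
#'   of the parameter set including this seed.
#'
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(image_size = 512,
                         n_slices = 51,
                         n_fascicles = 8,
                         fascicle_area_range = c(5e3, 4e5),
                         target_fascicle_fraction = 0.05,
                         artifact_density = 0.5,
                         artifact_value_range = c(19000, 32000),
                         brightness_drift = c(0.85, 1.15),
                         merge_split_rate = 0.5,
                         pixel_spacing = 10,
                         slice_spacing = 100,
                         seed = 1L) {
  check_that(is_count(image_size) && image_size >= 16, "image_size",
             "must be a single integer >= 16")
  check_that(is_count(n_slices), "n_slices", "must be a positive integer")
  check_that(is_count(n_fascicles), "n_fascicles", "must be a positive integer")
  check_that(is_range(fascicle_area_range) && fascicle_area_range[1] > 0,
             "fascicle_area_range", "must be an increasing positive pair (um^2)")
  check_that(is_number(target_fascicle_fraction) &&
               target_fascicle_fraction > 0 && target_fascicle_fraction < 0.5,
             "target_fascicle_fraction", "must lie in (0, 0.5)")
  check_that(is_number(artifact_density) && artifact_density >= 0,
             "artifact_density", "must be a nonnegative number")
  check_that(is_range(artifact_value_range) &&
               artifact_value_range[2] > 18000 &&
               artifact_value_range[2] <= 65535 &&
               artifact_value_range[1] > 0,
             "artifact_value_range",
             "must be a positive pair including values > 18,000 and <= 65,535")
  check_that(is_range(brightness_drift) && brightness_drift[1] > 0,
             "brightness_drift", "must be an increasing positive pair")
  check_that(is_number(merge_split_rate) && merge_split_rate >= 0,
             "merge_split_rate", "must be a nonnegative rate per mm")
  check_that(is_number(pixel_spacing) && pixel_spacing > 0, "pixel_spacing",
             "must be a positive length in um")
  check_that(is_number(slice_spacing) && slice_spacing > 0, "slice_spacing",
             "must be a positive length in um")
  check_that(is_count(abs(seed) + 1), "seed", "must be a single integer")
  structure(
    list(
      image_size = as.integer(image_size),
      n_slices = as.integer(n_slices),
      n_fascicles = as.integer(n_fascicles),
      fascicle_area_range = as.numeric(fascicle_area_range),
      target_fascicle_fraction = target_fascicle_fraction,
      artifact_density = artifact_density,
      artifact_value_range = as.numeric(artifact_value_range),
      brightness_drift = as.numeric(brightness_drift),
      merge_split_rate = merge_split_rate,
      pixel_spacing = pixel_spacing,
      slice_spacing = slice_spacing,
      seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

# smooth mean-zero-start random walk used for slice-to-slice drift
smooth_walk <- function(n, sd, span = 7L) {
  if (n <= 1L) return(rep(0, n))
  span <- min(span, n)
  steps <- rnorm(n, 0, sd)
  sm <- stats::filter(steps, rep(1 / span, span), sides = 2)
  sm[is.na(sm)] <- 0
  p <- cumsum(as.numeric(sm))
  p - p[1]
}

# paint an ellipse into a logical matrix, restricted to its bounding box
paint_ellipse <- function(mask, cx, cy, a, b, theta) {
  S_r <- nrow(mask); S_c <- ncol(mask)
  rmax <- max(a, b)
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(S_r, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(S_c, ceiling(cx + rmax))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[rows, cols] <- mask[rows, cols] | inside
  mask
}

# keep point (x, y) inside the ellipse (cx, cy, a, b, theta) shrunk by margin
clamp_into_ellipse <- function(x, y, cx, cy, a, b, theta, margin) {
  ae <- max(a - margin, 1); be <- max(b - margin, 1)
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  s <- sqrt((u / ae)^2 + (v / be)^2)
  if (s > 1) {
    u <- u / s; v <- v / s
    dx <- u * cos(theta) - v * sin(theta)
    dy <- u * sin(theta) + v * cos(theta)
  }
  c(cx + dx, cy + dy)
}

# choose per-fascicle target areas (px^2): anchor one fascicle per size
# class when possible, fill the remainder log-uniformly, then rescale so
# the total matches the target coverage fraction
draw_fascicle_areas <- function(p) {
  ps2 <- p$pixel_spacing^2
  target_px <- p$target_fascicle_fraction * p$image_size^2
  lo <- p$fascicle_area_range[1] / ps2
  hi <- p$fascicle_area_range[2] / ps2
  anchors_um2 <- c(315000, 150000, 45000, 10000)
  n_anchor <- min(4L, p$n_fascicles)
  anchors <- pmin(pmax(anchors_um2[seq_len(n_anchor)] / ps2, lo), hi)
  n_fill <- p$n_fascicles - n_anchor
  fill <- if (n_fill > 0) 10^runif(n_fill, log10(lo), log10(hi)) else numeric(0)
  areas <- c(anchors, fill)
  if (n_fill > 0 && sum(anchors) < target_px) {
    fill <- fill * (target_px - sum(anchors)) / sum(fill)
    areas <- c(anchors, fill)
  } else {
    areas <- areas * target_px / sum(areas)
  }
  areas
}

#' Generate a synthetic nerve-phantom stack
#'
#' Produces a [nerve_stack()] whose images and ground-truth masks have the
#' statistical structure of microCT nerve cross-sections: an epineurium
#' ellipse (intensity around 8,000) on a dark background (around 3,000)
#' containing bright elliptical fascicle blobs (around 14,000), with
#' additive Gaussian noise, a multiplicative per-slice brightness factor,
#' and rare saturating artifact specks. Fascicle centers drift smoothly
#' from slice to slice; when `merge_split_rate > 0`, selected fascicle
#' pairs are drawn together over a window of slices so that their blobs
#' merge into one connected component and separate again, emulating the
#' merge/split behaviour of real fascicles along the nerve.
#'
#' The generator is fully deterministic given the parameter set (one RNG
#' stream seeded from `params$seed`).
#'
#' @param params A [synth_params()] object.
#' @param nerve_id Identifier stored on the resulting stack.
#' @return A [nerve_stack()].
#' @export
generate_stack <- function(params, nerve_id = "phantom") {
  if (!inherits(params, "synth_params")) {
    params <- do.call(synth_params, as.list(params))
  }
  p <- params
  withr::with_seed(p$seed, generate_stack_impl(p, nerve_id))
}

generate_stack_impl <- function(p, nerve_id) {
  S <- p$image_size; n <- p$n_slices; nf <- p$n_fascicles
  ctr <- (S + 1) / 2

  # epineurium geometry and its drift along z
  ea <- 0.40 * S * runif(1, 0.95, 1.05)
  eb <- 0.33 * S * runif(1, 0.95, 1.05)
  eth <- runif(1, 0, pi)
  ecx0 <- ctr + runif(1, -S / 64, S / 64)
  ecy0 <- ctr + runif(1, -S / 64, S / 64)
  ecx <- ecx0 + smooth_walk(n, S / 600)
  ecy <- ecy0 + smooth_walk(n, S / 600)
  re <- max(ea, eb)
  ecx <- pmin(pmax(ecx, re + 2), S - re - 1)
  ecy <- pmin(pmax(ecy, re + 2), S - re - 1)

  # fascicle geometry at the reference slice
  areas <- draw_fascicle_areas(p)
  aspect <- runif(nf, 0.75, 1.3)
  fa <- sqrt(areas * aspect / pi)
  fb <- sqrt(areas / (aspect * pi))
  fth <- runif(nf, 0, pi)
  rmax <- pmax(fa, fb)
  gap <- 3

  # rejection-sample non-overlapping centers inside the epineurium
  fx <- numeric(nf); fy <- numeric(nf)
  for (i in seq_len(nf)) {
    placed <- FALSE
    for (attempt in seq_len(600)) {
      t <- sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
      u <- t * cos(phi) * max(ea - rmax[i] - 4, 1)
      v <- t * sin(phi) * max(eb - rmax[i] - 4, 1)
      x <- ecx0 + u * cos(eth) - v * sin(eth)
      y <- ecy0 + u * sin(eth) + v * cos(eth)
      ok <- TRUE
      if (i > 1) {
        d <- sqrt((x - fx[seq_len(i - 1)])^2 + (y - fy[seq_len(i - 1)])^2)
        ok <- all(d >= rmax[i] + rmax[seq_len(i - 1)] + gap)
      }
      if (ok) { fx[i] <- x; fy[i] <- y; placed <- TRUE; break }
      if (attempt %% 150 == 0) {
        # crowded frame: shrink this fascicle and keep trying
        areas[i] <- areas[i] * 0.8
        fa[i] <- sqrt(areas[i] * aspect[i] / pi)
        fb[i] <- sqrt(areas[i] / (aspect[i] * pi))
        rmax[i] <- max(fa[i], fb[i])
      }
    }
    if (!placed) { fx[i] <- ecx0; fy[i] <- ecy0 }
  }

  # per-fascicle drift and size modulation along z
  dx <- lapply(seq_len(nf), function(i) smooth_walk(n, 0.8))
  dy <- lapply(seq_len(nf), function(i) smooth_walk(n, 0.8))
  rphase <- runif(nf, 0, 2 * pi)
  rfreq <- runif(nf, 0.5, 2)

  # merge/split events: pairs attracted over ~1 mm windows
  events <- list()
  if (p$merge_split_rate > 0 && nf >= 2 && n >= 3) {
    length_mm <- n * p$slice_spacing / 1000
    n_ev <- rpois(1, p$merge_split_rate * length_mm)
    if (n_ev == 0) n_ev <- 1L
    halfw <- max(2L, round(500 / p$slice_spacing))
    for (e in seq_len(n_ev)) {
      pair <- sample.int(nf, 2)
      z0 <- sample(seq(max(2L, ceiling(0.15 * n)), max(2L, floor(0.85 * n))), 1)
      events[[e]] <- list(i = pair[1], j = pair[2], z0 = z0, halfw = halfw)
    }
  }
  event_weight <- function(ev, z) {
    d <- abs(z - ev$z0)
    if (d > ev$halfw) 0 else 0.5 * (1 + cos(pi * d / ev$halfw))
  }

  drift <- runif(n, p$brightness_drift[1], p$brightness_drift[2])
  n_art <- if (p$artifact_density > 0) rpois(n, p$artifact_density) else rep(0L, n)
  if (p$artifact_density > 0 && sum(n_art) == 0) {
    n_art[sample.int(n, 1)] <- 1L
  }
  art_forced <- FALSE

  slices <- vector("list", n)
  fmasks <- vector("list", n)
  emasks <- vector("list", n)

  for (z in seq_len(n)) {
    cx <- fx + vapply(dx, `[`, numeric(1), z)
    cy <- fy + vapply(dy, `[`, numeric(1), z)
    rmod <- 1 + 0.06 * sin(2 * pi * rfreq * z / n + rphase)
    az <- fa * rmod; bz <- fb * rmod
    rz <- pmax(az, bz)

    # active merge/split attraction
    active <- matrix(FALSE, nf, nf)
    for (ev in events) {
      w <- event_weight(ev, z)
      if (w > 0.05) {
        active[ev$i, ev$j] <- active[ev$j, ev$i] <- TRUE
        d <- sqrt((cx[ev$i] - cx[ev$j])^2 + (cy[ev$i] - cy[ev$j])^2)
        dt <- (1 - w) * d + w * 0.5 * (rz[ev$i] + rz[ev$j])
        if (d > 1e-9 && dt < d) {
          mx <- (cx[ev$i] + cx[ev$j]) / 2; my <- (cy[ev$i] + cy[ev$j]) / 2
          ux <- (cx[ev$i] - mx) / d * dt; uy <- (cy[ev$i] - my) / d * dt
          cx[ev$i] <- mx + ux; cy[ev$i] <- my + uy
          cx[ev$j] <- mx - ux; cy[ev$j] <- my - uy
        }
      }
    }

    # separation enforcement for non-event pairs, then containment
    if (nf >= 1) {
      for (iter in seq_len(15)) {
        moved <- FALSE
        if (nf >= 2) {
          for (i in seq_len(nf - 1)) {
            for (j in seq(i + 1, nf)) {
              if (active[i, j]) next
              d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
              need <- rz[i] + rz[j] + gap
              if (d < need) {
                moved <- TRUE
                if (d < 1e-9) { cx[i] <- cx[i] + 0.5; d <- 0.5 }
                push <- (need - d) / 2 + 1e-6
                ux <- (cx[i] - cx[j]) / d; uy <- (cy[i] - cy[j]) / d
                cx[i] <- cx[i] + ux * push; cy[i] <- cy[i] + uy * push
                cx[j] <- cx[j] - ux * push; cy[j] <- cy[j] - uy * push
              }
            }
          }
        }
        for (i in seq_len(nf)) {
          xy <- clamp_into_ellipse(cx[i], cy[i], ecx[z], ecy[z], ea, eb, eth,
                                   rz[i] + 2)
          cx[i] <- xy[1]; cy[i] <- xy[2]
        }
        if (!moved && iter > 2) break
      }
    }

    emask <- paint_ellipse(matrix(FALSE, S, S), ecx[z], ecy[z], ea, eb, eth)
    fmask <- matrix(FALSE, S, S)
    for (i in seq_len(nf)) {
      fmask <- paint_ellipse(fmask, cx[i], cy[i], az[i], bz[i], fth[i])
    }
    fmask <- fmask & emask

    img <- matrix(3000, S, S)
    img[emask] <- 8000
    img[fmask] <- 14000
    img <- img * drift[z] + rnorm(S * S, 0, 250)

    if (n_art[z] > 0) {
      for (k in seq_len(n_art[z])) {
        if (!art_forced) {
          val <- runif(1, max(18001, p$artifact_value_range[1]),
                       p$artifact_value_range[2])
          art_forced <- TRUE
        } else {
          val <- runif(1, p$artifact_value_range[1], p$artifact_value_range[2])
        }
        ar <- sample.int(S, 1); ac <- sample.int(S, 1)
        sz <- sample.int(3, 1)
        rr <- pmin(pmax(ar + seq_len(sz) - 1L, 1L), S)
        img[cbind(rr, rep(ac, sz))] <- val
      }
    }

    storage.mode(img) <- "double"
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)), S, S)
    slices[[z]] <- img
    fmasks[[z]] <- fmask
    emasks[[z]] <- emask
  }

  nerve_stack(nerve_id, slices, fmasks, emasks,
              pixel_spacing = p$pixel_spacing, slice_spacing = p$slice_spacing)
}

#' Generate a degenerate single-slice fixture
#'
#' Returns a slice/mask triple exhibiting exactly one named degeneracy,
#' for exercising edge-case handling in the preprocessing and metric
#' stages.
#'
#' @param kind One of `"empty"` (no fascicle pixels),
#'   `"single_pixel_fascicle"`, `"fascicle_touching_border"`,
#'   `"epineurium_touching_border"`, or `"all_saturated"` (every image
#'   pixel above the 18,000 saturation threshold).
#' @param image_size Pixels per side (default 64).
#' @return A list with elements `image` (integer matrix), `fascicle` and
#'   `epineurium` (logical matrices).
#' @export
generate_edge_case_slice <- function(kind = c("empty", "single_pixel_fascicle",
                                              "fascicle_touching_border",
                                              "epineurium_touching_border",
                                              "all_saturated"),
                                     image_size = 64L) {
  kind <- match.arg(kind)
  S <- as.integer(image_size)
  ctr <- (S + 1) / 2
  emask <- paint_ellipse(matrix(FALSE, S, S), ctr, ctr, 0.4 * S, 0.33 * S, 0)
  fmask <- matrix(FALSE, S, S)
  if (kind == "single_pixel_fascicle") {
    fmask[round(ctr), round(ctr)] <- TRUE
  } else if (kind == "fascicle_touching_border") {
    emask <- paint_ellipse(matrix(FALSE, S, S), 2, ctr, 0.45 * S, 0.33 * S, 0)
    fmask <- paint_ellipse(fmask, 1, ctr, 0.18 * S, 0.14 * S, 0)
    fmask <- fmask & emask
    if (!any(fmask[, 1])) {
      fmask[round(ctr), 1] <- TRUE
      emask[round(ctr), 1] <- TRUE
    }
  } else if (kind == "epineurium_touching_border") {
    emask <- paint_ellipse(matrix(FALSE, S, S), 2, ctr, 0.45 * S, 0.33 * S, 0)
    if (!any(emask[, 1])) emask[round(ctr), 1] <- TRUE
    fmask <- paint_ellipse(fmask, 0.35 * S, ctr, 0.12 * S, 0.1 * S, 0) & emask
  }
  img <- matrix(3000L, S, S)
  img[emask] <- 8000L
  img[fmask] <- 14000L
  if (kind == "all_saturated") {
    img[] <- 30000L
  }
  list(image = img, fascicle = fmask, epineurium = emask)
}
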