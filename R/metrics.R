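#' Dice similarity coefficient between two binary masks
#'
#' `2 |T intersect P| / (|T| + |P|)`. When both masks are empty the
#' coefficient is 1 by convention (nothing to find, nothing found).
#'
#' @param truth,prediction Logical matrices of identical dimensions.
#' @return The Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(truth, prediction) {
  stopifnot_same_dim(truth, prediction, "truth and prediction")
  nt <- sum(truth); np <- sum(prediction)
  if (nt + np == 0) return(1)
  2 * sum(truth & prediction) / (nt + np)
}

#' Pixel-wise precision and recall
#'
#' `precision = |T intersect P| / |P|`, `recall = |T intersect P| / |T|`.
#' An empty denominator yields 1 when the other set is also empty and 0
#' otherwise.
#'
#' @param truth,prediction Logical matrices of identical dimensions.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
pixel_precision_recall <- function(truth, prediction) {
  stopifnot_same_dim(truth, prediction, "truth and prediction")
  nt <- sum(truth); np <- sum(prediction); ni <- sum(truth & prediction)
  precision <- if (np == 0) as.numeric(nt == 0) else ni / np
  recall <- if (nt == 0) as.numeric(np == 0) else ni / nt
  c(precision = precision, recall = recall)
}

#' Precision-recall sweep over probability thresholds
#'
#' Binarizes the probability maps at every threshold in
#' `{0, 0.02, ..., 1}` (51 points) and computes aggregate precision,
#' recall and Dice over all pixels of the stack. The area under the
#' precision-recall curve is obtained by trapezoidal integration over
#' recall; for the curve (and the AUC only), an empty prediction set at
#' the highest thresholds contributes precision 1, the usual boundary
#' convention that makes a perfect predictor integrate to exactly 1. The
#' optimal threshold is the grid point maximizing the Dice coefficient
#' (ties broken towards the lowest threshold).
#'
#' @param truth_stack List of logical matrices (or one matrix).
#' @param probability_stack List of probability matrices paired with
#'   `truth_stack`.
#' @param step Threshold step (default 0.02).
#' @return An object of class `pr_curve`: a list with `curve` (a tibble
#'   with `threshold`, `precision`, `recall`, `dice`), `auc`, and
#'   `optimal_threshold`.
#' @export
pr_curve <- function(truth_stack, probability_stack, step = 0.02) {
  if (is.matrix(truth_stack)) truth_stack <- list(truth_stack)
  if (is.matrix(probability_stack)) probability_stack <- list(probability_stack)
  if (length(truth_stack) == 0) stop("empty stack", call. = FALSE)
  stopifnot(length(truth_stack) == length(probability_stack))
  for (i in seq_along(truth_stack)) {
    stopifnot_same_dim(truth_stack[[i]], probability_stack[[i]],
                       sprintf("truth and probability (slice %d)", i))
  }
  tr <- unlist(lapply(truth_stack, as.logical), use.names = FALSE)
  pr <- unlist(lapply(probability_stack, as.numeric), use.names = FALSE)
  nt <- sum(tr)
  thresholds <- seq(0, 1, by = step)
  rows <- lapply(thresholds, function(t) {
    pos <- pr > t
    np <- sum(pos)
    ni <- sum(pos & tr)
    tibble::tibble(
      threshold = t,
      precision = if (np == 0) 1 else ni / np,
      recall = if (nt == 0) 1 else ni / nt,
      dice = if (nt + np == 0) 1 else 2 * ni / (nt + np)
    )
  })
  curve <- dplyr::bind_rows(rows)
  ord <- order(curve$recall)
  x <- curve$recall[ord]; y <- curve$precision[ord]
  auc <- if (max(x) - min(x) < .Machine$double.eps) {
    x[1] * max(y)
  } else {
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
  structure(
    list(
      curve = curve,
      auc = auc,
      optimal_threshold = curve$threshold[which.max(curve$dice)]
    ),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf(
    "<pr_curve>: %d threshold points, AUC %.4f, optimal threshold %.2f (Dice %.4f)\n",
    nrow(x$curve), x$auc, x$optimal_threshold, max(x$curve$dice)
  ))
  invisible(x)
}

#' @export
tidy.pr_curve <- function(x, ...) x$curve

#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(
    n_thresholds = nrow(x$curve),
    auc = x$auc,
    optimal_threshold = x$optimal_threshold,
    max_dice = max(x$curve$dice)
  )
}

#' Label fascicle instances in a binary mask
#'
#' Connected components (8-connected by default, so diagonally touching
#' pixels join) labeled `1..K` in raster order (row-major scan) of each
#' component's first pixel; 0 is background.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return An object of class `label_map`: list with `labels` (integer
#'   matrix) and `connectivity`.
#' @export
label_fascicles <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  check_that(connectivity %in% c(4L, 8L), "connectivity", "must be 4 or 8")
  labels <- .label_components(mask > 0, as.integer(connectivity))
  structure(
    list(labels = labels, connectivity = as.integer(connectivity)),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map>: %d component(s), %d-connected, %dx%d px\n",
              max(0L, max(x$labels)), x$connectivity,
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

as_label_map <- function(x, connectivity = 8L) {
  if (inherits(x, "label_map")) return(x)
  label_fascicles(x, connectivity)
}

#' Pairwise fascicle intersection-over-union matrix
#'
#' Entry `(i, j)` is `|True_i intersect Pred_j| / |True_i union Pred_j|`
#' for ground-truth fascicle `i` and predicted fascicle `j`. A property
#' of IoU is that at most one entry per row and per column can exceed
#' 0.5.
#'
#' @param truth,prediction `label_map` objects (or logical masks, which
#'   are labeled with 8-connectivity first) of identical dimensions.
#' @return An `n_true x n_pred` numeric matrix of class `iou_matrix`.
#' @export
iou_matrix <- function(truth, prediction) {
  truth <- as_label_map(truth)
  prediction <- as_label_map(prediction)
  tl <- truth$labels; pl <- prediction$labels
  stopifnot_same_dim(tl, pl, "truth and prediction label maps")
  kt <- max(0L, max(tl)); kp <- max(0L, max(pl))
  m <- matrix(0, kt, kp)
  if (kt > 0 && kp > 0) {
    both <- tl > 0 & pl > 0
    if (any(both)) {
      inter <- table(factor(tl[both], levels = seq_len(kt)),
                     factor(pl[both], levels = seq_len(kp)))
      inter <- matrix(as.numeric(inter), kt, kp)
      at <- tabulate(tl[tl > 0], nbins = kt)
      ap <- tabulate(pl[pl > 0], nbins = kp)
      uni <- outer(at, ap, `+`) - inter
      m <- ifelse(uni > 0, inter / uni, 0)
    }
  }
  structure(m, class = c("iou_matrix", "matrix", "array"))
}

#' Classify fascicles from an IoU matrix
#'
#' At matching threshold `t`: a ground-truth fascicle whose row maximum
#' reaches `t` is a true positive, otherwise a miss (false negative); a
#' predicted fascicle whose column maximum stays below `t` is an added
#' fascicle (false positive). Independently of `t`, a row with more than
#' one entry above the effective IoU threshold (0.1) flags a split
#' ground-truth fascicle, and such a column flags a merging prediction.
#' A split's supporting prediction can back two rows at low `t`; that is
#' deliberate — splits are tallied separately rather than double-
#' penalized in the detection counts.
#'
#' @param matrix An [iou_matrix()] (a plain matrix is accepted).
#' @param t Matching threshold in (0, 1).
#' @param merge_threshold Effective IoU threshold for merge/split
#'   detection (default 0.1).
#' @return An object of class `fascicle_match`: list with `threshold`,
#'   `tp`, `fp`, `fn`, `split_true_ids`, `merged_pred_ids`, `row_max`,
#'   `col_max`.
#' @export
classify_fascicles <- function(matrix, t, merge_threshold = 0.1) {
  check_that(is_number(t) && t > 0 && t < 1, "t", "must lie in (0, 1)")
  m <- unclass(matrix)
  n_true <- nrow(m); n_pred <- ncol(m)
  row_max <- if (n_pred == 0) rep(0, n_true) else apply(m, 1, max)
  col_max <- if (n_true == 0) rep(0, n_pred) else apply(m, 2, max)
  tp <- sum(row_max >= t)
  structure(
    list(
      threshold = t,
      tp = tp,
      fn = n_true - tp,
      fp = sum(col_max < t),
      split_true_ids = if (n_pred == 0) integer(0) else
        which(rowSums(m > merge_threshold) > 1),
      merged_pred_ids = if (n_true == 0) integer(0) else
        which(colSums(m > merge_threshold) > 1),
      row_max = row_max,
      col_max = col_max
    ),
    class = "fascicle_match"
  )
}

#' @export
print.fascicle_match <- function(x, ...) {
  cat(sprintf(
    "<fascicle_match> at t = %.2f: TP %d, FP %d, FN %d; %d split, %d merged; F1 %.4f\n",
    x$threshold, x$tp, x$fp, x$fn,
    length(x$split_true_ids), length(x$merged_pred_ids),
    f1_fascicle(x$tp, x$fp, x$fn)
  ))
  invisible(x)
}

#' Fascicle detection F1 score
#'
#' `TP / (TP + (FP + FN) / 2)`: the instance-level detection score over
#' fascicle cross-sections. With no fascicles anywhere (all counts zero)
#' the score is defined as 1, with a warning.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return The F1 score in `[0, 1]`.
#' @export
f1_fascicle <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) {
    warning("no fascicles in truth or prediction; F1 defined as 1",
            call. = FALSE)
    return(1)
  }
  tp / (tp + (fp + fn) / 2)
}

#' Physical area of a labeled fascicle
#'
#' Pixel count times the squared in-plane pixel spacing.
#'
#' @param label Integer label present in `map`.
#' @param map A `label_map`.
#' @param pixel_spacing Pixel size in um (default 10).
#' @return Area in um^2.
#' @export
fascicle_area_um2 <- function(label, map, pixel_spacing = 10) {
  stopifnot(inherits(map, "label_map"))
  n <- sum(map$labels == label)
  if (length(label) != 1 || label < 1 || n == 0) {
    stop(sprintf("label %s is not present in the label map", label),
         call. = FALSE)
  }
  n * pixel_spacing^2
}

size_class_levels <- c("large", "medium", "small", "tiny")

#' Size class of a fascicle area
#'
#' Half-open binning of cross-section areas: large `>= 300,000 um^2`,
#' medium `[90,000, 300,000)`, small `[20,000, 90,000)`, tiny
#' `(0, 20,000)`. (The shared endpoints are assigned to the larger bin.)
#'
#' @param area Positive area(s) in um^2.
#' @return Factor with levels `large`, `medium`, `small`, `tiny`.
#' @export
size_class_of <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("fascicle areas must be positive and finite", call. = FALSE)
  }
  cls <- ifelse(area >= 3e5, "large",
                ifelse(area >= 9e4, "medium",
                       ifelse(area >= 2e4, "small", "tiny")))
  factor(cls, levels = size_class_levels)
}

# per-fascicle bookkeeping for one slice: sizes, miss/split flags on the
# truth side, added/merge flags on the prediction side
slice_fascicle_records <- function(truth_map, pred_map, t, merge_threshold,
                                   pixel_spacing, slice = 1L) {
  m <- iou_matrix(truth_map, pred_map)
  match <- classify_fascicles(m, t, merge_threshold)
  kt <- nrow(m); kp <- ncol(m)
  at <- tabulate(truth_map$labels[truth_map$labels > 0], nbins = kt)
  ap <- tabulate(pred_map$labels[pred_map$labels > 0], nbins = kp)
  truth_rec <- if (kt > 0) {
    tibble::tibble(
      slice = slice, side = "truth", id = seq_len(kt),
      area_um2 = at * pixel_spacing^2,
      size_class = size_class_of(at * pixel_spacing^2),
      missed = match$row_max < t,
      split = seq_len(kt) %in% match$split_true_ids,
      added = FALSE, merged = FALSE
    )
  }
  pred_rec <- if (kp > 0) {
    tibble::tibble(
      slice = slice, side = "prediction", id = seq_len(kp),
      area_um2 = ap * pixel_spacing^2,
      size_class = size_class_of(ap * pixel_spacing^2),
      missed = FALSE, split = FALSE,
      added = match$col_max < t,
      merged = seq_len(kp) %in% match$merged_pred_ids
    )
  }
  list(records = dplyr::bind_rows(truth_rec, pred_rec), match = match)
}

#' Size-stratified fascicle error breakdown
#'
#' Tallies, per size class and overall, the percentage of ground-truth
#' fascicles that were missed or split and of predicted fascicles that
#' were added or merged. Missed/split errors are sized by the true
#' fascicle, added/merged errors by the predicted fascicle (the side on
#' which each error is observable); percentages are computed against the
#' class's fascicle count on the corresponding side.
#'
#' @param truth_maps,pred_maps Lists of `label_map` objects (or logical
#'   masks), paired per slice.
#' @param t Detection threshold (default 0.4).
#' @param merge_threshold Effective IoU threshold for merge/split flags
#'   (default 0.1).
#' @param pixel_spacing Pixel size in um (default 10).
#' @return A tibble of class `fascicle_error_report` with one row per
#'   size class plus a `total` row: fascicle counts on each side and
#'   counts/percentages for missed, split, added, and merged errors.
#' @export
error_breakdown <- function(truth_maps, pred_maps, t = 0.4,
                            merge_threshold = 0.1, pixel_spacing = 10) {
  if (inherits(truth_maps, "label_map") || is.matrix(truth_maps)) {
    truth_maps <- list(truth_maps)
  }
  if (inherits(pred_maps, "label_map") || is.matrix(pred_maps)) {
    pred_maps <- list(pred_maps)
  }
  stopifnot(length(truth_maps) == length(pred_maps))
  recs <- dplyr::bind_rows(lapply(seq_along(truth_maps), function(i) {
    slice_fascicle_records(
      as_label_map(truth_maps[[i]]), as_label_map(pred_maps[[i]]),
      t, merge_threshold, pixel_spacing, slice = i
    )$records
  }))
  summarize_error_records(recs, t)
}

summarize_error_records <- function(recs, t) {
  per_class <- function(sub) {
    n_true <- sum(sub$side == "truth")
    n_pred <- sum(sub$side == "prediction")
    pct <- function(k, n) if (n > 0) 100 * k / n else 0
    tibble::tibble(
      n_true = n_true, n_pred = n_pred,
      missed = sum(sub$missed), missed_pct = pct(sum(sub$missed), n_true),
      split = sum(sub$split), split_pct = pct(sum(sub$split), n_true),
      added = sum(sub$added), added_pct = pct(sum(sub$added), n_pred),
      merged = sum(sub$merged), merged_pct = pct(sum(sub$merged), n_pred)
    )
  }
  by_class <- lapply(size_class_levels, function(cl) {
    dplyr::bind_cols(tibble::tibble(size_class = cl),
                     per_class(recs[recs$size_class == cl, , drop = FALSE]))
  })
  out <- dplyr::bind_rows(
    dplyr::bind_rows(by_class),
    dplyr::bind_cols(tibble::tibble(size_class = "total"), per_class(recs))
  )
  attr(out, "t") <- t
  class(out) <- c("fascicle_error_report", class(out))
  out
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Runs the full evaluation framework on a paired stack of binary masks:
#' per-slice pixel Dice/precision/recall, fascicle detection F1 at each
#' requested IoU threshold (both averaged per slice and pooled over the
#' stack's summed TP/FP/FN), and the size-stratified error breakdown at
#' `t_report`.
#'
#' @param truth_masks,pred_masks Lists of logical matrices (or single
#'   matrices), paired per slice.
#' @param t_values IoU matching thresholds for the F1-vs-t curve
#'   (default `seq(0.1, 0.9, by = 0.1)`).
#' @param t_report Threshold used for the error breakdown (default 0.4).
#' @param merge_threshold Effective IoU threshold for merge/split flags.
#' @param pixel_spacing Pixel size in um.
#' @param connectivity Connected-component connectivity (default 8).
#' @return An object of class `stack_evaluation`: list with `per_slice`
#'   (tibble), `f1_curve` (tibble with per-slice-mean and pooled F1 per
#'   threshold), `error_report`, and `summary` (one-row tibble with mean
#'   and 5th/95th-percentile Dice).
#' @export
evaluate_stack <- function(truth_masks, pred_masks,
                           t_values = seq(0.1, 0.9, by = 0.1),
                           t_report = 0.4, merge_threshold = 0.1,
                           pixel_spacing = 10, connectivity = 8L) {
  if (is.matrix(truth_masks)) truth_masks <- list(truth_masks)
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (length(truth_masks) != length(pred_masks)) {
    stop("truth and prediction stacks differ in length", call. = FALSE)
  }
  if (length(truth_masks) == 0) stop("empty stack", call. = FALSE)

  n <- length(truth_masks)
  per_slice <- vector("list", n)
  f1_rows <- vector("list", n)
  err_recs <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- truth_masks[[i]] > 0
    pm <- pred_masks[[i]] > 0
    stopifnot_same_dim(tm, pm, sprintf("truth and prediction (slice %d)", i))
    tmap <- label_fascicles(tm, connectivity)
    pmap <- label_fascicles(pm, connectivity)
    m <- iou_matrix(tmap, pmap)
    pr <- pixel_precision_recall(tm, pm)
    per_slice[[i]] <- tibble::tibble(
      slice = i,
      dice = dice_coefficient(tm, pm),
      precision = unname(pr["precision"]),
      recall = unname(pr["recall"]),
      n_true = nrow(m),
      n_pred = ncol(m)
    )
    f1_rows[[i]] <- dplyr::bind_rows(lapply(t_values, function(t) {
      cm <- classify_fascicles(m, t, merge_threshold)
      tibble::tibble(slice = i, t = t, tp = cm$tp, fp = cm$fp, fn = cm$fn,
                     f1 = f1_fascicle(cm$tp, cm$fp, cm$fn))
    }))
    err_recs[[i]] <- slice_fascicle_records(
      tmap, pmap, t_report, merge_threshold, pixel_spacing, slice = i
    )$records
  }
  per_slice <- dplyr::bind_rows(per_slice)
  f1_long <- dplyr::bind_rows(f1_rows)
  f1_curve <- f1_long |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(
      f1_mean = mean(.data$f1),
      tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      f1_pooled = ifelse(.data$tp + .data$fp + .data$fn == 0, 1,
                         .data$tp / (.data$tp + (.data$fp + .data$fn) / 2))
    )
  structure(
    list(
      per_slice = per_slice,
      per_slice_f1 = f1_long,
      f1_curve = f1_curve,
      error_report = summarize_error_records(dplyr::bind_rows(err_recs),
                                             t_report),
      summary = tibble::tibble(
        n_slices = n,
        mean_dice = mean(per_slice$dice),
        dice_q05 = unname(quantile(per_slice$dice, 0.05)),
        dice_q95 = unname(quantile(per_slice$dice, 0.95)),
        t_report = t_report
      )
    ),
    class = "stack_evaluation"
  )
}

#' @export
print.stack_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<stack_evaluation>: %d slice(s); mean Dice %.4f [5th-95th pct: %.4f, %.4f]\n",
    s$n_slices, s$mean_dice, s$dice_q05, s$dice_q95
  ))
  f4 <- x$f1_curve[abs(x$f1_curve$t - 0.4) < 1e-9, ]
  if (nrow(f4)) {
    cat(sprintf("  fascicle F1 at t = 0.4: %.4f (per-slice mean), %.4f (pooled)\n",
                f4$f1_mean, f4$f1_pooled))
  }
  invisible(x)
}

#' @export
tidy.stack_evaluation <- function(x, ...) x$per_slice

#' @export
glance.stack_evaluation <- function(x, ...) {
  f4 <- x$f1_curve[abs(x$f1_curve$t - 0.4) < 1e-9, ]
  dplyr::bind_cols(
    x$summary,
    tibble::tibble(
      f1_mean_t04 = if (nrow(f4)) f4$f1_mean else NA_real_,
      f1_pooled_t04 = if (nrow(f4)) f4$f1_pooled else NA_real_
    )
  )
}

#' Write an evaluation to CSV and JSON files
#'
#' @param x A `stack_evaluation`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_evaluation <- function(x, dir) {
  stopifnot(inherits(x, "stack_evaluation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(x$per_slice, file.path(dir, "per_slice.csv"),
                   row.names = FALSE)
  utils::write.csv(x$f1_curve, file.path(dir, "f1_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(x$error_report),
                   file.path(dir, "error_report.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(x$summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
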