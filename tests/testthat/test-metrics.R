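test_that("the Dice coefficient follows pixel-count arithmetic", {
  a <- matrix(FALSE, 4, 4); a[1, 1:4] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3, 1:4] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  ov <- matrix(FALSE, 4, 4); ov[1, 3:4] <- TRUE; ov[2, 1:2] <- TRUE
  expect_equal(dice_coefficient(a, ov), 0.5)   # |T|=4, |P|=4, overlap 2
  expect_equal(dice_coefficient(a == -1, b == -1), 1)  # both empty
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_error(dice_coefficient(a, matrix(FALSE, 2, 2)), "dimensions")
})

test_that("pixel precision/recall follow set arithmetic with empty conventions", {
  t <- matrix(FALSE, 4, 4); t[1:2, 1:2] <- TRUE
  p <- matrix(FALSE, 4, 4); p[1:2, 1] <- TRUE          # subset, half size
  expect_equal(unname(pixel_precision_recall(t, p)), c(1, 0.5))
  expect_equal(unname(pixel_precision_recall(t, t)), c(1, 1))
  d <- matrix(FALSE, 4, 4); d[4, 4] <- TRUE
  expect_equal(unname(pixel_precision_recall(t, d)), c(0, 0))
  none <- matrix(FALSE, 4, 4)
  expect_equal(unname(pixel_precision_recall(none, none)), c(1, 1))
  expect_equal(unname(pixel_precision_recall(t, none)), c(0, 0))
})

test_that("connected components use 8-connectivity in raster label order", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE      # diagonal touch: one 8-component
  expect_identical(max(label_fascicles(m)$labels), 1L)
  expect_identical(max(label_fascicles(m, 4)$labels), 2L)
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  lm <- label_fascicles(two)
  expect_identical(max(lm$labels), 2L)
  expect_identical(lm$labels[1, 1], 1L)  # raster-first pixel gets label 1
  expect_identical(lm$labels[5, 5], 2L)
  expect_identical(max(label_fascicles(matrix(FALSE, 3, 3))$labels), 0L)
})

test_that("the IoU matrix holds pairwise intersection-over-union values", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  expect_equal(unclass(iou_matrix(a, a))[1, 1], 1)
  # one 8 px true fascicle covered exactly by two 4 px predicted instances
  # (instance maps built directly: a split prediction cutting one blob)
  tl <- matrix(0L, 6, 6); tl[2:3, 2:5] <- 1L
  pl <- matrix(0L, 6, 6); pl[2:3, 2:3] <- 1L; pl[2:3, 4:5] <- 2L
  as_map <- function(lab) {
    structure(list(labels = lab, connectivity = 8L), class = "label_map")
  }
  m <- iou_matrix(as_map(tl), as_map(pl))
  expect_identical(dim(m), c(1L, 2L))
  expect_equal(unclass(m)[1, ], c(4 / 8, 4 / 8))
  disj <- matrix(FALSE, 6, 6); disj[6, 6] <- TRUE
  expect_true(all(unclass(iou_matrix(a, disj)) == 0))
})

test_that("fascicle classification applies the row/column threshold rules", {
  ident <- diag(3)
  cm <- classify_fascicles(ident, t = 0.4)
  expect_identical(c(cm$tp, cm$fp, cm$fn), c(3L, 0L, 0L))
  expect_length(cm$split_true_ids, 0)
  expect_length(cm$merged_pred_ids, 0)

  split <- matrix(c(0.5, 0.5), 1, 2)
  cs <- classify_fascicles(split, t = 0.4)
  expect_identical(c(cs$tp, cs$fp, cs$fn), c(1L, 0L, 0L))
  expect_identical(cs$split_true_ids, 1L)

  miss <- matrix(0, 2, 1)
  cz <- classify_fascicles(miss, t = 0.4)
  expect_identical(c(cz$tp, cz$fp, cz$fn), c(0L, 1L, 2L))

  merged <- matrix(c(0.3, 0.3), 2, 1)
  expect_identical(classify_fascicles(merged, t = 0.4)$merged_pred_ids, 1L)
})

test_that("the detection F1 follows its closed form", {
  expect_equal(f1_fascicle(5, 0, 0), 1)
  expect_equal(f1_fascicle(0, 3, 0), 0)
  expect_equal(f1_fascicle(3, 1, 2), 3 / 4.5)
  expect_warning(v <- f1_fascicle(0, 0, 0), "F1")
  expect_equal(v, 1)
})

test_that("fascicle areas and size classes use physical units", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE  # 100 px blob
  lm <- label_fascicles(m)
  expect_equal(fascicle_area_um2(1, lm, 10), 100 * 100)
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(fascicle_area_um2(1, label_fascicles(one), 10), 100)
  expect_error(fascicle_area_um2(2, label_fascicles(one)), "not present")

  expect_identical(as.character(size_class_of(500000)), "large")
  expect_identical(as.character(size_class_of(300100)), "large")
  expect_identical(as.character(size_class_of(19999)), "tiny")
  expect_identical(as.character(size_class_of(25000)), "small")
  expect_identical(as.character(size_class_of(90000)), "medium")
  expect_error(size_class_of(0), "positive")
})

test_that("perfect predictions yield an all-zero error breakdown", {
  t <- matrix(FALSE, 20, 20); t[2:5, 2:5] <- TRUE; t[10:15, 10:15] <- TRUE
  rep <- error_breakdown(list(t), list(t), t = 0.4)
  pct <- unlist(rep[, grepl("_pct$", names(rep))])
  expect_true(all(pct == 0))
  expect_identical(rep$n_true[rep$size_class == "total"], 2L)
})

test_that("two missing tiny fascicles out of twenty give 10% tiny-missed", {
  S <- 60
  truth <- matrix(FALSE, S, S)
  centers <- expand.grid(r = seq(3, 58, by = 11), c = seq(3, 58, by = 11))
  centers <- centers[seq_len(20), ]
  for (i in seq_len(20)) {
    truth[centers$r[i] + 0:1, centers$c[i] + 0:1] <- TRUE  # 4 px = 400 um^2
  }
  pred <- truth
  # erase fascicles 3 and 7 from the prediction
  for (i in c(3, 7)) pred[centers$r[i] + 0:1, centers$c[i] + 0:1] <- FALSE
  rep <- error_breakdown(list(truth), list(pred), t = 0.4)
  tiny <- rep[rep$size_class == "tiny", ]
  expect_identical(tiny$n_true, 20L)
  expect_identical(tiny$missed, 2L)
  expect_equal(tiny$missed_pct, 10)
  # detected + missed partition the class
  expect_equal(tiny$missed_pct + 100 * (tiny$n_true - tiny$missed) / tiny$n_true,
               100)
})

test_that("evaluate_stack is exact on identical stacks and monotone in t", {
  p <- synth_params(image_size = 96, n_slices = 4, n_fascicles = 4,
                    merge_split_rate = 0, seed = 13)
  st <- generate_stack(p)
  ev <- evaluate_stack(st$fascicle_masks, st$fascicle_masks)
  expect_equal(ev$summary$mean_dice, 1)
  expect_true(all(ev$f1_curve$f1_mean == 1))
  expect_true(all(ev$f1_curve$f1_pooled == 1))

  # against a degraded prediction, F1 never increases with t
  pred <- lapply(st$fascicle_masks, function(m) {
    m[, seq(1, ncol(m), by = 3)] <- FALSE
    m
  })
  ev2 <- evaluate_stack(st$fascicle_masks, pred,
                        t_values = seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(ev2$f1_curve$f1_pooled) <= 1e-12))
  expect_true(all(diff(ev2$f1_curve$f1_mean) <= 1e-12))
  expect_error(evaluate_stack(st$fascicle_masks, pred[-1]), "length")
})

test_that("Dice and IoU obey their identity on single matched pairs", {
  withr::with_seed(31, {
    for (i in 1:20) {
      t <- matrix(FALSE, 16, 16)
      p <- matrix(FALSE, 16, 16)
      r0 <- sample(4:10, 1); c0 <- sample(4:10, 1)
      t[r0 + 0:4, c0 + 0:4] <- TRUE
      p[r0 + sample(-2:2, 1) + 0:4, c0 + sample(-2:2, 1) + 0:4] <- TRUE
      iou <- unclass(iou_matrix(t, p))[1, 1]
      expect_equal(dice_coefficient(t, p), 2 * iou / (1 + iou))
    }
  })
})

test_that("detection counts are conserved and unique above IoU 0.5", {
  withr::with_seed(17, {
    for (i in 1:25) {
      pair <- random_mask_pair(32)
      m <- iou_matrix(pair$truth, pair$pred)
      # at most one entry per row and column can exceed 0.5
      if (nrow(m) > 0 && ncol(m) > 0) {
        expect_true(all(rowSums(unclass(m) > 0.5) <= 1))
        expect_true(all(colSums(unclass(m) > 0.5) <= 1))
      }
      for (t in c(0.2, 0.4, 0.6, 0.8)) {
        cm <- classify_fascicles(m, t)
        expect_identical(cm$tp + cm$fn, nrow(m))
        if (t > 0.5 && ncol(m) > 0 && nrow(m) > 0) {
          expect_identical(cm$tp, sum(apply(unclass(m), 2, max) >= t))
        }
      }
    }
  })
})

test_that("metrics are invariant under relabeling of components", {
  withr::with_seed(23, {
    pair <- random_mask_pair(32)
    m <- iou_matrix(pair$truth, pair$pred)
    cm <- classify_fascicles(m, 0.4)
    if (nrow(m) > 1) {
      perm <- rev(seq_len(nrow(m)))
      cm2 <- classify_fascicles(unclass(m)[perm, , drop = FALSE], 0.4)
      expect_identical(c(cm$tp, cm$fp, cm$fn), c(cm2$tp, cm2$fp, cm2$fn))
      expect_equal(f1_fascicle(cm$tp, cm$fp, cm$fn),
                   f1_fascicle(cm2$tp, cm2$fp, cm2$fn))
    }
  })
})

test_that("package metrics agree exactly with the pixel-set oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(77, {
    for (i in 1:40) {
      pair <- random_mask_pair(32)
      t <- runif(1, 0.15, 0.85)
      o <- oracle_eval(pair$truth, pair$pred, t)
      expect_identical(label_fascicles(pair$truth)$labels, o$labels_true)
      expect_identical(label_fascicles(pair$pred)$labels, o$labels_pred)
      m <- iou_matrix(pair$truth, pair$pred)
      expect_equal(unclass(m), o$iou, tolerance = 1e-14)
      expect_equal(dice_coefficient(pair$truth, pair$pred), o$dice)
      cm <- classify_fascicles(m, t)
      expect_identical(c(cm$tp, cm$fp, cm$fn), c(o$tp, o$fp, o$fn))
      expect_identical(as.integer(cm$split_true_ids), as.integer(o$split))
      expect_identical(as.integer(cm$merged_pred_ids), as.integer(o$merged))
    }
  })
})

test_that("the PR sweep has 51 points with correct boundary behaviour", {
  t <- matrix(FALSE, 10, 10); t[3:6, 3:6] <- TRUE
  pc <- pr_curve(t, t * 1.0)
  expect_identical(nrow(pc$curve), 51L)
  expect_equal(pc$auc, 1)
  interior <- pc$curve[pc$curve$threshold > 0 & pc$curve$threshold < 1, ]
  expect_true(all(interior$precision == 1))
  expect_true(all(interior$recall == 1))
  # the reported optimum maximizes Dice on the grid
  expect_equal(max(pc$curve$dice), pc$curve$dice[pc$curve$threshold ==
                                                   pc$optimal_threshold])

  # constant 0.5 map: recall steps from 1 to 0 at threshold 0.5
  const <- matrix(0.5, 10, 10)
  pc2 <- pr_curve(t, const)
  expect_equal(pc2$curve$recall[pc2$curve$threshold < 0.5],
               rep(1, sum(pc2$curve$threshold < 0.5)))
  expect_equal(pc2$curve$recall[pc2$curve$threshold >= 0.5],
               rep(0, sum(pc2$curve$threshold >= 0.5)))
  expect_equal(pc2$curve$precision[pc2$curve$threshold < 0.5],
               rep(0.16, sum(pc2$curve$threshold < 0.5)))
  expect_error(pr_curve(list(), list()), "empty")
})

test_that("a graded probability map yields the optimum at the best Dice", {
  withr::with_seed(5, {
    t <- matrix(FALSE, 20, 20); t[5:12, 5:12] <- TRUE
    p <- ifelse(t, 0.9, 0.2) + matrix(rnorm(400, 0, 0.05), 20, 20)
    p <- pmin(pmax(p, 0), 1)
  })
  pc <- pr_curve(t, p)
  expect_equal(pc$curve$dice[pc$curve$threshold == pc$optimal_threshold],
               max(pc$curve$dice))
  expect_true(pc$auc > 0.9)
})
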