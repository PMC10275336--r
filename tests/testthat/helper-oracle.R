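# Brute-force pixel-set oracle for the fascicle metrics, written against
# plain set operations (and igraph for component membership) so it shares
# no code path with the package implementation.

oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0) return(lab)
  pos <- rep(NA_integer_, H * W)
  pos[idx] <- seq_along(idx)
  r <- (idx - 1) %% H + 1
  cc <- (idx - 1) %/% H + 1
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  if (connectivity == 4) offs <- list(c(-1, 0), c(0, -1))
  ev <- integer(0)
  for (o in offs) {
    rr <- r + o[1]; c2 <- cc + o[2]
    ok <- rr >= 1 & rr <= H & c2 >= 1 & c2 <= W
    lin <- (c2[ok] - 1) * H + rr[ok]
    v1 <- which(ok)
    v2 <- pos[lin]
    keep <- !is.na(v2)
    ev <- c(ev, rbind(v1[keep], v2[keep]))
  }
  g <- igraph::make_graph(edges = ev, n = length(idx), directed = FALSE)
  mem <- igraph::components(g)$membership
  # relabel components 1..K in raster (row-major) order of first pixel
  rord <- order(r, cc)
  seen <- mem[rord][!duplicated(mem[rord])]
  relab <- integer(max(mem))
  relab[seen] <- seq_along(seen)
  lab[idx] <- relab[mem]
  lab
}

# direct set-arithmetic evaluation of Dice, the IoU matrix, detection
# counts, merge/split flags and size classes
oracle_eval <- function(truth, pred, t, merge_t = 0.1, pixel_spacing = 10) {
  tl <- oracle_label(truth)
  pl <- oracle_label(pred)
  kt <- max(tl); kp <- max(pl)
  tsets <- lapply(seq_len(kt), function(k) which(tl == k))
  psets <- lapply(seq_len(kp), function(k) which(pl == k))
  ts <- which(truth); ps <- which(pred)
  dice <- if (length(ts) + length(ps) == 0) 1 else
    2 * length(intersect(ts, ps)) / (length(ts) + length(ps))
  iou <- matrix(0, kt, kp)
  for (i in seq_len(kt)) {
    for (j in seq_len(kp)) {
      iou[i, j] <- length(intersect(tsets[[i]], psets[[j]])) /
        length(union(tsets[[i]], psets[[j]]))
    }
  }
  row_max <- if (kp == 0) rep(0, kt) else apply(iou, 1, max)
  col_max <- if (kt == 0) rep(0, kp) else apply(iou, 2, max)
  tp <- sum(row_max >= t)
  list(
    dice = dice,
    labels_true = tl, labels_pred = pl,
    iou = iou,
    tp = tp, fn = kt - tp, fp = sum(col_max < t),
    split = if (kp == 0) integer(0) else
      which(vapply(seq_len(kt), function(i) sum(iou[i, ] > merge_t) > 1,
                   logical(1))),
    merged = if (kt == 0) integer(0) else
      which(vapply(seq_len(kp), function(j) sum(iou[, j] > merge_t) > 1,
                   logical(1))),
    f1 = if (tp + sum(col_max < t) + (kt - tp) == 0) 1 else
      tp / (tp + 0.5 * (sum(col_max < t) + kt - tp)),
    true_sizes = vapply(tsets, function(s) {
      a <- length(s) * pixel_spacing^2
      if (a >= 3e5) "large" else if (a >= 9e4) "medium"
      else if (a >= 2e4) "small" else "tiny"
    }, character(1))
  )
}

# random blobby mask pairs used for the oracle-equivalence trials: the
# prediction is a jittered copy of the truth with occasional dropped or
# spurious components
random_mask_pair <- function(S = 32) {
  disc <- function(m, r0, c0, rad) {
    for (r in max(1, r0 - rad):min(S, r0 + rad)) {
      for (c in max(1, c0 - rad):min(S, c0 + rad)) {
        if ((r - r0)^2 + (c - c0)^2 <= rad^2) m[r, c] <- TRUE
      }
    }
    m
  }
  truth <- matrix(FALSE, S, S)
  pred <- matrix(FALSE, S, S)
  n_blobs <- sample(0:4, 1)
  for (b in seq_len(n_blobs)) {
    r0 <- sample(S, 1); c0 <- sample(S, 1); rad <- sample(1:6, 1)
    truth <- disc(truth, r0, c0, rad)
    if (runif(1) < 0.85) {  # detected, with jitter
      pred <- disc(pred, r0 + sample(-2:2, 1), c0 + sample(-2:2, 1),
                   max(1, rad + sample(-1:1, 1)))
    }
  }
  for (b in seq_len(sample(0:2, 1))) {  # spurious components
    pred <- disc(pred, sample(S, 1), sample(S, 1), sample(1:3, 1))
  }
  list(truth = truth, pred = pred)
}
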