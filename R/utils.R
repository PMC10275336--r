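# Shared internal helpers.

# Round half away from zero (used when snapping centroids to pixel grids,
# where determinism across platforms matters more than unbiasedness).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# abort with the offending field named, for parameter validators
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

is_range <- function(x) {
  length(x) == 2L && is.numeric(x) && all(is.finite(x)) && x[1] <= x[2]
}

is_prob <- function(x) {
  is_number(x) && x >= 0 && x <= 1
}

stopifnot_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf(
      "%s must have identical dimensions (got %s vs %s)",
      what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# Rotate a matrix by a multiple of 90 degrees counter-clockwise as an exact
# index permutation (no interpolation).
rot90_mat <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1L, , drop = FALSE]
  m
}
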