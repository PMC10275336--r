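#' Grouped leave-one-out cross-validation splits
#'
#' Builds a split plan in which whole nerves — never individual slices —
#' are assigned to training, validation, or testing, because consecutive
#' slices of one nerve are highly correlated and would leak across sets.
#' One fold is produced per non-test nerve; fold *k* trains on all other
#' non-test nerves and validates on nerve *k*. An optional test nerve is
#' excluded from every fold.
#'
#' @param nerve_ids Character vector of at least two unique nerve
#'   identifiers (excluding the test nerve).
#' @param test_id Optional identifier of a held-out test nerve; must not
#'   appear in `nerve_ids`.
#' @return A `split_plan`: a tibble with columns `fold` (integer),
#'   `validation` (character), and `train` (list of character vectors),
#'   plus a `test_nerve_id` attribute (`NA` if absent).
#' @export
make_loocv_splits <- function(nerve_ids, test_id = NULL) {
  stopifnot(is.character(nerve_ids))
  if (anyDuplicated(nerve_ids)) {
    stop("nerve_ids contains duplicates", call. = FALSE)
  }
  if (!is.null(test_id)) {
    stopifnot(is.character(test_id), length(test_id) == 1L)
    if (test_id %in% nerve_ids) {
      stop(sprintf("test_id '%s' must not appear in nerve_ids", test_id),
           call. = FALSE)
    }
  }
  if (length(nerve_ids) < 2) {
    stop("need at least 2 non-test nerve ids to build leave-one-out folds",
         call. = FALSE)
  }
  plan <- tibble::tibble(
    fold = seq_along(nerve_ids),
    validation = nerve_ids,
    train = lapply(seq_along(nerve_ids), function(k) nerve_ids[-k])
  )
  attr(plan, "test_nerve_id") <- test_id %||% NA_character_
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  test <- attr(x, "test_nerve_id")
  cat(sprintf("<split_plan>: %d leave-one-out fold(s); test nerve: %s\n",
              nrow(x), if (is.na(test)) "none" else test))
  NextMethod()
}

#' Serialize a split plan to JSON
#'
#' @param plan A `split_plan` from [make_loocv_splits()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  obj <- list(
    folds = lapply(seq_len(nrow(plan)), function(k) {
      list(train = as.list(plan$train[[k]]), validation = plan$validation[k])
    }),
    test_nerve_id = attr(plan, "test_nerve_id")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a split plan from JSON
#'
#' @param path JSON file written by [write_split_plan()].
#' @return A `split_plan` tibble.
#' @export
read_split_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  validation <- vapply(obj$folds, function(f) f$validation, character(1))
  train <- lapply(obj$folds, function(f) unlist(f$train, use.names = FALSE))
  plan <- tibble::tibble(
    fold = seq_along(validation),
    validation = validation,
    train = train
  )
  test <- obj$test_nerve_id
  attr(plan, "test_nerve_id") <-
    if (is.null(test)) NA_character_ else as.character(test)
  class(plan) <- c("split_plan", class(plan))
  plan
}
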