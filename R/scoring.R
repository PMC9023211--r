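#' Numerically stable softmax
#'
#' Maps a vector of real logits to a probability vector:
#' `exp(x_i - max(x)) / sum_j exp(x_j - max(x))`. Subtracting the maximum
#' leaves the result unchanged mathematically (shift invariance) and avoids
#' overflow. This is the scoring front-end through which raw network outputs
#' become the score vectors the quantum classifier consumes.
#'
#' @param logits Finite numeric vector of length >= 2.
#' @return Numeric probability vector of the same length, summing to 1.
#' @examples
#' softmax(c(1, 2, 3, 4))
#' @export
softmax <- function(logits) {
  if (!is.numeric(logits) || length(logits) < 2L || !all(is.finite(logits))) {
    stop("`logits` must be a finite numeric vector of length >= 2", call. = FALSE)
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

score_cols <- function(n_classes) paste0("s", seq_len(n_classes) - 1L)

#' Validate a tibble of labelled score vectors
#'
#' Checks that score columns `s0..s{K-1}` are in `[0, 1]` and each row sums
#' to 1 within `1e-8`, and that `label` is an integer in `[0, K)`. Errors
#' name the first offending row.
#'
#' @param data A data frame with columns `s0..s{K-1}` and `label`.
#' @param n_classes Number of classes `K` (default: inferred from the score
#'   columns present).
#' @return `data` as a tibble, invisibly validated.
#' @export
validate_scores <- function(data, n_classes = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(n_classes)) {
    n_classes <- sum(grepl("^s[0-9]+$", names(data)))
  }
  cols <- score_cols(n_classes)
  missing <- setdiff(c(cols, "label"), names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- as.matrix(data[cols])
  if (!is.numeric(s) || anyNA(s)) {
    stop("score columns must be numeric with no missing values", call. = FALSE)
  }
  bad <- which(s < -1e-12 | s > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("row ", bad[1, 1], ": score out of [0, 1]", call. = FALSE)
  }
  sums <- rowSums(s)
  off <- which(abs(sums - 1) > 1e-8)
  if (length(off)) {
    stop("row ", off[1], ": scores sum to ", format(sums[off[1]], digits = 6),
         ", not 1 (tolerance 1e-8)", call. = FALSE)
  }
  lab <- data$label
  badlab <- which(is.na(lab) | lab != as.integer(lab) |
                    lab < 0 | lab >= n_classes)
  if (length(badlab)) {
    stop("row ", badlab[1], ": label must be an integer in [0, ",
         n_classes, ")", call. = FALSE)
  }
  data$label <- as.integer(lab)
  data
}

#' Read and write labelled score-vector CSV files
#'
#' The on-disk dialect is comma-separated UTF-8 with a header
#' `s0,s1,...,label`, '.' decimal marks and no index column. Reading
#' validates every row (scores in `[0,1]` summing to 1 within 1e-8, labels
#' in range) and reports the first offending row by number. Writing uses
#' full double precision so a write/read round trip reproduces scores to
#' better than 1e-12.
#'
#' @param path File path.
#' @param n_classes Number of classes (default 4).
#' @param data A data frame with columns `s0..s{K-1}` and `label`.
#' @return `read_scores()` returns a validated tibble; `write_scores()`
#'   returns `data` invisibly.
#' @export
read_scores <- function(path, n_classes = 4L) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  cols <- score_cols(n_classes)
  spec <- readr::cols(label = readr::col_double(), .default = readr::col_double())
  data <- readr::read_csv(path, col_types = spec, progress = FALSE)
  missing <- setdiff(c(cols, "label"), names(data))
  if (length(missing)) {
    stop("malformed CSV (missing columns ", paste(missing, collapse = ", "),
         "): ", path, call. = FALSE)
  }
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop("row ", probs$row[1], ": cannot parse field", call. = FALSE)
  }
  validate_scores(data, n_classes)
}

#' @rdname read_scores
#' @export
write_scores <- function(data, path) {
  n_classes <- sum(grepl("^s[0-9]+$", names(data)))
  data <- validate_scores(data, n_classes)
  out <- data[c(score_cols(n_classes), "label")]
  # format() at 17 significant digits keeps the round trip exact
  num <- lapply(out[score_cols(n_classes)], function(x) {
    sub("^\\s+", "", format(x, digits = 17, scientific = FALSE))
  })
  lines <- do.call(paste, c(num, list(out$label), sep = ","))
  writeLines(c(paste(names(out), collapse = ","), lines), path, useBytes = TRUE)
  invisible(data)
}

#' Class names of the four-class tumor task
#'
#' Label coding 0, 1, 2, 3 for no tumor, meningioma, pituitary tumor and
#' glioma respectively.
#'
#' @param n_classes 4 (the tumor-type task) or 2 (tumor vs. no tumor).
#' @return Character vector of class names.
#' @export
class_names <- function(n_classes = 4L) {
  if (n_classes == 4L) {
    c("no tumor", "meningioma", "pituitary tumor", "glioma")
  } else if (n_classes == 2L) {
    c("no tumor", "tumor")
  } else {
    paste0("class ", seq_len(n_classes) - 1L)
  }
}
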