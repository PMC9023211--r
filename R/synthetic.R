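#' Generate labelled synthetic score vectors
#'
#' Emulates the softmax score vectors a trained CNN produces: for each class
#' `c` it draws `n_per_class` vectors from a Dirichlet distribution whose
#' parameter is `concentration_true` at position `c` and
#' `concentration_other` elsewhere. Softmax outputs live on the probability
#' simplex, and the ratio of the two concentrations is a single knob for
#' class separability: equal concentrations give unseparable (symmetric)
#' data, `concentration_true = 50, concentration_other = 1` gives nearly
#' one-hot vectors whose argmax almost always equals the label.
#'
#' Classes are exactly balanced and the draw is deterministic given `seed`
#' (the global RNG state is left untouched).
#'
#' @param n_per_class Samples per class (default 200).
#' @param n_classes Number of classes, 4 or 2 (default 4).
#' @param concentration_true Dirichlet weight on the true class (default 50).
#' @param concentration_other Dirichlet weight on each other class (default 1).
#' @param seed Integer RNG seed (default 7).
#' @return A tibble with columns `s0..s{K-1}` (scores) and `label`
#'   (integer `0..K-1`), `n_per_class * n_classes` rows.
#' @examples
#' d <- generate_scores(n_per_class = 5, seed = 1)
#' table(d$label)
#' @export
generate_scores <- function(n_per_class = 200L, n_classes = 4L,
                            concentration_true = 50, concentration_other = 1,
                            seed = 7L) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L ||
      is.na(n_per_class) || n_per_class < 1) {
    stop("`n_per_class` must be a positive integer", call. = FALSE)
  }
  if (!n_classes %in% c(2L, 4L)) {
    stop("`n_classes` must be 2 or 4", call. = FALSE)
  }
  if (!is.numeric(concentration_true) || concentration_true <= 0 ||
      !is.numeric(concentration_other) || concentration_other <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  with_preserved_seed(seed, {
    rows <- lapply(seq_len(n_classes) - 1L, function(cls) {
      alpha <- rep(concentration_other, n_classes)
      alpha[cls + 1L] <- concentration_true
      s <- rdirichlet(n_per_class, alpha)
      out <- tibble::as_tibble(as.data.frame(s),
                               .name_repair = ~score_cols(n_classes))
      out$label <- cls
      out
    })
    dplyr::bind_rows(rows)
  })
}

# Dirichlet via normalized gamma draws; rows sum to 1 exactly after division
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Monte-Carlo Bayes accuracy of the synthetic generator
#'
#' Estimates the accuracy of the argmax rule (predict the class with the
#' largest score) under the generator's Dirichlet mixture. For this
#' generator the argmax rule is the Bayes rule, so the estimate is the
#' ceiling no classifier trained on these scores can beat; end-to-end tests
#' calibrate their expectations against it.
#'
#' @inheritParams generate_scores
#' @param n_mc Total Monte-Carlo draws (>= 1000; default 10000).
#' @return A single accuracy in `[0, 1]`.
#' @examples
#' bayes_accuracy(concentration_true = 50, n_mc = 1000)
#' @export
bayes_accuracy <- function(concentration_true = 50, concentration_other = 1,
                           n_classes = 4L, n_mc = 10000L, seed = 7L) {
  if (n_mc < 1000) {
    stop("`n_mc` must be at least 1000", call. = FALSE)
  }
  per <- ceiling(n_mc / n_classes)
  d <- generate_scores(n_per_class = per, n_classes = n_classes,
                       concentration_true = concentration_true,
                       concentration_other = concentration_other, seed = seed)
  s <- as.matrix(d[score_cols(n_classes)])
  pred <- max.col(s, ties.method = "first") - 1L
  mean(pred == d$label)
}
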