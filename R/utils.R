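# shared internal helpers

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

#' @noRd
assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# sample skewness (moment estimator, b1); NA-free input expected
#' @noRd
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# numeric measurement columns of a cohort table (everything but id/DX)
#' @noRd
measurement_cols <- function(data, catalog) {
  vars <- catalog$variable[catalog$category != "DX"]
  intersect(names(data), vars)
}

# Manhattan distances from each row of `x` to each row of `medoids`
#' @noRd
manhattan_to_rows <- function(x, medoids) {
  x <- as.matrix(x)
  medoids <- as.matrix(medoids)
  out <- matrix(0, nrow(x), nrow(medoids))
  for (j in seq_len(nrow(medoids))) {
    out[, j] <- rowSums(abs(sweep(x, 2, medoids[j, ], "-")))
  }
  out
}

# all unordered cluster pairs (a < b in level order)
#' @noRd
cluster_pairs <- function(levels) {
  if (length(levels) < 2) {
    return(tibble(cluster_a = character(), cluster_b = character()))
  }
  idx <- utils::combn(seq_along(levels), 2)
  tibble(cluster_a = levels[idx[1, ]], cluster_b = levels[idx[2, ]])
}
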