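# Gap statistic for guiding the number of clusters, in the Manhattan /
# k-medoids setting. The within-cluster dispersion is
#
#   W_k = sum_r D_r / (2 n_r),  D_r = sum over ordered within-cluster pairs
#                                     of the Manhattan distance,
#
# and gap_k = E*[log W*_k] - log W_k with the expectation estimated from B
# reference data sets drawn uniformly over the per-feature range box of the
# observed data and clustered with the same k-medoids procedure. The
# standard-error term carries the usual sqrt(1 + 1/B) factor.

# log W_k for a given partition, on a Manhattan dist object
#' @noRd
log_within_dispersion <- function(dmat, labels) {
  W <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_r <- length(idx)
    if (n_r > 1) {
      # D_r counts both orders: twice the sum over unordered pairs
      D_r <- 2 * sum(dmat[idx, idx][upper.tri(diag(n_r))])
      W <- W + D_r / (2 * n_r)
    }
  }
  log(W)
}

#' Gap statistic over a range of cluster counts
#'
#' @param data Numeric tibble/matrix (screened CMs); an optional
#'   `subject_id` column is ignored.
#' @param k_range Contiguous integer range of candidate cluster counts.
#' @param B Number of uniform reference draws (>= 10). Default 50.
#' @param seed Seed for the reference draws.
#' @param nstart PAM starts per clustering run (see
#'   [kmedoids_manhattan()]). Default 10.
#'
#' @return Object of class `threec_gap`: a `curve` tibble with columns `k`,
#'   `logW`, `E_logW`, `gap`, `SE_sim`, plus `B` and `seed`. The curve is
#'   invariant to subject order.
#' @seealso [choose_k_candidates()]
#' @export
gap_statistic <- function(data, k_range = 1:8, B = 50, seed = 1,
                          nstart = 10) {
  data <- as_tibble(data)
  x <- as.matrix(data[, setdiff(names(data), "subject_id"), drop = FALSE])
  if (!is.numeric(x)) abort("All columns must be numeric.")
  if (all(apply(x, 2, var) == 0)) {
    abort("Degenerate (constant) data: gap statistic undefined.")
  }
  B <- assert_count(B, "B", min = 10)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(diff(k_range) != 1)) abort("`k_range` must be contiguous.")
  n_distinct_rows <- nrow(unique(x))
  if (max(k_range) > n_distinct_rows) {
    abort("`k_range` exceeds the number of distinct rows.")
  }

  cluster_logW <- function(xx) {
    dmat <- as.matrix(dist(xx, method = "manhattan"))
    map_dbl(k_range, function(k) {
      fit <- kmedoids_manhattan(as_tibble(as.data.frame(xx)), k, seed = seed,
                                nstart = nstart)
      log_within_dispersion(dmat, fit$assignment)
    })
  }

  logW <- cluster_logW(x)

  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  set.seed(seed)
  ref_logW <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    ref <- sapply(seq_along(lo), function(j) runif(nrow(x), lo[j], hi[j]))
    ref_logW[b, ] <- cluster_logW(ref)
  }

  E_logW <- colMeans(ref_logW)
  sd_k <- sqrt(colMeans(sweep(ref_logW, 2, E_logW)^2))
  s_k <- sd_k * sqrt(1 + 1 / B)

  structure(
    list(
      curve = tibble(k = k_range, logW = logW, E_logW = E_logW,
                     gap = E_logW - logW, SE_sim = s_k),
      B = B, seed = assert_count(seed, "seed")
    ),
    class = "threec_gap"
  )
}

#' @export
print.threec_gap <- function(x, ...) {
  cat(sprintf("<threec_gap> k in [%d, %d], B = %d reference draws\n",
              min(x$curve$k), max(x$curve$k), x$B))
  print(x$curve)
  invisible(x)
}

#' Tidy a gap curve
#'
#' @param x A `threec_gap` object.
#' @param ... Unused.
#' @return The per-k curve tibble (`k`, `logW`, `E_logW`, `gap`, `SE_sim`).
#' @method tidy threec_gap
#' @export
tidy.threec_gap <- function(x, ...) x$curve

#' Candidate cluster counts from a gap curve
#'
#' A "drop" at k means gap(k+1) < gap(k). With two or more drops, the
#' inclusive range from the first-drop k through the second-drop k is
#' returned (e.g. drops after 3 and after 8 suggest 3-8 candidate
#' clusters). With exactly one drop the Tibshirani rule is applied
#' (smallest k with gap(k) >= gap(k+1) - SE(k+1)), returned as a singleton.
#' A curve with no drop returns the largest k with a warning. The choice of
#' the final k is advisory: combining the candidates with subject-matter
#' review is deliberate.
#'
#' @param gap A `threec_gap` object (or its `curve` tibble with columns
#'   `k`, `gap`, `SE_sim`).
#' @return Integer vector of candidate values of k.
#' @export
choose_k_candidates <- function(gap) {
  curve <- if (inherits(gap, "threec_gap")) gap$curve else as_tibble(gap)
  stopifnot(all(c("k", "gap", "SE_sim") %in% names(curve)))
  curve <- arrange(curve, k)
  g <- curve$gap
  k <- curve$k
  drops <- k[which(diff(g) < 0)]
  if (length(drops) >= 2) {
    return(seq(drops[1], drops[2]))
  }
  if (length(drops) == 1) {
    m <- length(g)
    ok <- which(g[-m] >= g[-1] - curve$SE_sim[-1])
    return(k[ok[1]])
  }
  warn("Gap curve has no drop; returning the largest k.")
  k[length(k)]
}

#' Plot a gap curve
#'
#' @param object A `threec_gap` object.
#' @param ... Unused.
#' @return A ggplot of gap against k with simulation standard-error bars.
#' @method autoplot threec_gap
#' @export
autoplot.threec_gap <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$SE_sim,
                                          ymax = .data$gap + .data$SE_sim)) +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic",
                  title = "Gap statistic",
                  subtitle = sprintf("B = %d uniform reference draws", object$B)) +
    ggplot2::theme_minimal()
}
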