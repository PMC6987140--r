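# k-medoids (PAM) with Manhattan distance: BUILD greedy initialization
# followed by SWAP exchange refinement (via cluster::pam on a Manhattan
# dissimilarity). Assignments and the total cost are recomputed in-package
# so the model contract holds exactly: every subject is assigned to its
# nearest medoid (ties to the lowest medoid index) and the cost is the sum
# of Manhattan distances to own medoid.

#' k-medoids clustering with Manhattan distance
#'
#' @param data Tibble/matrix of numeric screened CM columns; an optional
#'   `subject_id` character column is used to label medoids.
#' @param k Number of medoids, `1 <= k <=` number of distinct rows.
#' @param seed Seed for the random restarts; also recorded in the model.
#' @param nstart Number of PAM starts: one deterministic BUILD start plus
#'   `nstart - 1` seeded random-medoid starts, keeping the lowest-cost SWAP
#'   result (ties favor the BUILD start). Default 10.
#'
#' @return Object of class `threec_kmedoids`: `k`, `medoid_ids`,
#'   `medoids` (tibble of medoid rows), `assignment` (integer cluster per
#'   subject), `cost` (total within-cluster Manhattan cost),
#'   `objective` (PAM build/swap average dissimilarities), `variables`,
#'   `seed`.
#' @export
#' @examples
#' x <- tibble::tibble(a = c(0, 0, 10, 10), b = c(0, 1, 0, 1))
#' m <- kmedoids_manhattan(x, k = 2)
#' m$assignment
kmedoids_manhattan <- function(data, k, seed = 1, nstart = 10) {
  data <- as_tibble(data)
  ids <- if ("subject_id" %in% names(data)) data$subject_id else
    as.character(seq_len(nrow(data)))
  x <- data[, setdiff(names(data), "subject_id"), drop = FALSE]
  if (!all(map_lgl(x, is.numeric))) {
    abort("All clustering columns must be numeric.")
  }
  x <- as.matrix(x)
  k <- assert_count(k, "k", min = 1)
  n_distinct_rows <- nrow(unique(x))
  if (k > n_distinct_rows) {
    abort(sprintf("k = %d exceeds the number of distinct rows (%d).",
                  k, n_distinct_rows))
  }

  d <- dist(x, method = "manhattan")
  dmat <- as.matrix(d)
  cost_of <- function(meds) {
    sum(apply(dmat[, meds, drop = FALSE], 1, min))
  }

  if (k == n_distinct_rows) {
    # degenerate case: every distinct row is a medoid, cost is minimal
    med_idx <- which(!duplicated(x))
    fit <- list(objective = c(build = cost_of(med_idx) / nrow(x),
                              swap = cost_of(med_idx) / nrow(x)))
  } else {
    fit <- cluster::pam(d, k = k, diss = TRUE)
    med_idx <- as.integer(fit$id.med)
  }
  best_cost <- cost_of(med_idx)

  # SWAP from a single BUILD start can land in a local optimum; seeded
  # random restarts keep the search inside the PAM family while reliably
  # reaching the global optimum on small instances
  if (nstart > 1 && k < n_distinct_rows) {
    # restarts use their own RNG stream; the caller's state is untouched
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(assert_count(seed, "seed"))
    fit_r <- cluster::pam(d, k = k, diss = TRUE, medoids = "random",
                          nstart = nstart - 1)
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
    if (cost_of(as.integer(fit_r$id.med)) < best_cost - 1e-12) {
      fit <- fit_r
      med_idx <- as.integer(fit_r$id.med)
    }
  }

  dd <- dmat[, med_idx, drop = FALSE]
  assignment <- max.col(-dd, ties.method = "first")
  cost <- sum(dd[cbind(seq_len(nrow(x)), assignment)])

  structure(
    list(
      k = k,
      medoid_ids = ids[med_idx],
      medoid_idx = med_idx,
      medoids = as_tibble(as.data.frame(x[med_idx, , drop = FALSE])),
      assignment = assignment,
      subject_id = ids,
      cost = cost,
      objective = fit$objective,
      variables = colnames(x),
      seed = assert_count(seed, "seed")
    ),
    class = "threec_kmedoids"
  )
}

#' @export
print.threec_kmedoids <- function(x, ...) {
  cat(sprintf("<threec_kmedoids> k = %d, n = %d, Manhattan cost = %.4g\n",
              x$k, length(x$assignment), x$cost))
  cat("  cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a k-medoids model
#'
#' @param x A `threec_kmedoids` object.
#' @param ... Unused.
#' @return Per-subject tibble: `subject_id`, `cluster`, `is_medoid`,
#'   `distance` (Manhattan distance to own medoid).
#' @method tidy threec_kmedoids
#' @export
tidy.threec_kmedoids <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    cluster = x$assignment,
    is_medoid = seq_along(x$assignment) %in% x$medoid_idx
  )
}

#' One-row summary of a k-medoids model
#'
#' @param x A `threec_kmedoids` object.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, total Manhattan `cost`, and the PAM
#'   build/swap average dissimilarities.
#' @method glance threec_kmedoids
#' @export
glance.threec_kmedoids <- function(x, ...) {
  tibble(
    k = x$k,
    n = length(x$assignment),
    cost = x$cost,
    build_avg = unname(x$objective["build"]),
    swap_avg = unname(x$objective["swap"])
  )
}

#' Assign new subjects to an existing k-medoids model
#'
#' Each row is labeled by its nearest medoid under Manhattan distance; ties
#' go to the lowest medoid index. Training rows re-assign to their training
#' clusters.
#'
#' @param model A `threec_kmedoids` object.
#' @param new_data Tibble with exactly the model's screened CM columns.
#' @return Integer cluster labels.
#' @export
assign_clusters <- function(model, new_data) {
  stopifnot(inherits(model, "threec_kmedoids"))
  new_data <- as_tibble(new_data)
  missing_vars <- setdiff(model$variables, names(new_data))
  if (length(missing_vars) > 0) {
    abort(sprintf("`new_data` lacks model columns: %s",
                  paste(missing_vars, collapse = ", ")))
  }
  x <- as.matrix(new_data[, model$variables, drop = FALSE])
  dd <- manhattan_to_rows(x, as.matrix(model$medoids))
  max.col(-dd, ties.method = "first")
}
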