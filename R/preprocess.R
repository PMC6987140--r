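# Data-reduction pipeline: complete-case filtering, redundancy removal,
# domain composites, monotone symmetrizing transforms.
#
# The order of the complete-case steps matters: high-missingness variables
# are dropped first (threshold `max_var_missing_frac`), then any subject
# still carrying a missing cell. In cohorts where missingness is informative
# of diagnosis this variable-light / subject-heavy reduction retains the
# complete-case core without imputation.

#' Retrieve the report attached by a preprocessing step
#'
#' [filter_complete_cases()], [remove_redundant()] and [transform_cohort()]
#' attach a report describing what they changed; this accessor returns it.
#'
#' @param x A tibble returned by a preprocessing step.
#' @return The report (a list or tibble), or `NULL` if none is attached.
#' @export
preprocess_report <- function(x) attr(x, "threec_report")

#' Retrieve the updated catalog attached by a preprocessing step
#'
#' [add_domain_scores()] appends composite variables and attaches a catalog
#' extended with matching rows; this accessor returns it.
#'
#' @param x A tibble returned by [add_domain_scores()].
#' @return The updated catalog tibble, or `NULL` if none is attached.
#' @export
cohort_catalog <- function(x) attr(x, "threec_catalog")

#' Complete-case filtering
#'
#' Two-step rule: (1) drop every variable whose missing fraction exceeds
#' `max_var_missing_frac`; (2) drop every subject with any remaining missing
#' cell. The returned table has zero missing cells.
#'
#' @param data Cohort tibble; column `id_col` identifies subjects and is
#'   exempt from filtering.
#' @param max_var_missing_frac Variables with a larger missing fraction are
#'   dropped before subjects are filtered. Default 0.3.
#' @param id_col Name of the subject id column. Default `"subject_id"`.
#'
#' @return A complete tibble, with a report (`preprocess_report()`) listing
#'   the variables and subjects dropped.
#' @export
#' @examples
#' x <- tibble::tibble(subject_id = letters[1:4],
#'                     a = c(NA, NA, 1, 2), b = c(1, 2, NA, 4), c = 1:4)
#' y <- filter_complete_cases(x, max_var_missing_frac = 0.3)
#' preprocess_report(y)
filter_complete_cases <- function(data, max_var_missing_frac = 0.3,
                                  id_col = "subject_id") {
  assert_prob(max_var_missing_frac, "max_var_missing_frac")
  data <- as_tibble(data)
  vars <- setdiff(names(data), id_col)

  miss_frac <- map_dbl(data[vars], ~ mean(is.na(.x)))
  drop_vars <- vars[miss_frac > max_var_missing_frac]
  kept <- data[, setdiff(names(data), drop_vars), drop = FALSE]

  keep_rows <- complete.cases(kept)
  dropped_subjects <- if (id_col %in% names(data)) {
    data[[id_col]][!keep_rows]
  } else {
    which(!keep_rows)
  }
  out <- kept[keep_rows, , drop = FALSE]

  report <- list(
    variables_dropped = tibble(variable = drop_vars,
                               missing_frac = unname(miss_frac[drop_vars])),
    subjects_dropped = dropped_subjects
  )
  if (length(setdiff(names(out), id_col)) == 0 || nrow(out) == 0) {
    abort(
      sprintf(
        "Complete-case filtering removed everything (%d variables, %d subjects dropped).",
        length(drop_vars), length(dropped_subjects)
      )
    )
  }
  attr(out, "threec_report") <- report
  out
}

# Gini impurity 1 - sum(p^2) of the observed class frequencies
#' @noRd
gini_impurity <- function(x) {
  p <- table(x) / length(x)
  1 - sum(p^2)
}

#' Remove redundant variables
#'
#' Continuous variable pairs with `|Pearson r| >` `corr_threshold` lose the
#' later variable in catalog order; discrete variables with Gini impurity
#' `1 - sum(p_c^2) <` `gini_threshold` are dropped (a nearly-constant
#' discrete variable carries almost no information). Constant continuous
#' variables are treated as Gini-degenerate and dropped with reason
#' `"constant"`. The DX variable is never dropped.
#'
#' @param data Complete cohort tibble.
#' @param catalog Variable catalog (columns `variable`, `category`,
#'   `vartype`); catalog order defines which of a correlated pair is kept.
#' @param corr_threshold Absolute Pearson correlation above which the later
#'   continuous variable is dropped. Default 0.99.
#' @param gini_threshold Gini impurity below which a discrete variable is
#'   dropped. Default 0.05.
#' @param id_col Subject id column name.
#'
#' @return Tibble without the redundant columns; `preprocess_report()` lists
#'   each drop with its reason. Idempotent: a second application changes
#'   nothing.
#' @export
remove_redundant <- function(data, catalog, corr_threshold = 0.99,
                             gini_threshold = 0.05, id_col = "subject_id") {
  assert_prob(corr_threshold, "corr_threshold")
  assert_prob(gini_threshold, "gini_threshold")
  data <- as_tibble(data)

  cat_order <- catalog$variable[catalog$variable %in% names(data)]
  info <- catalog[match(cat_order, catalog$variable), ]
  non_dx <- info$variable[info$category != "DX"]

  drops <- tibble(variable = character(), reason = character())

  cont <- info$variable[info$category != "DX" & info$vartype == "continuous"]
  disc <- setdiff(non_dx, cont)

  # constant continuous variables: degenerate, dropped first
  const <- cont[map_lgl(cont, ~ var(data[[.x]]) == 0)]
  if (length(const) > 0) {
    drops <- bind_rows(drops, tibble(variable = const, reason = "constant"))
    cont <- setdiff(cont, const)
  }

  if (length(cont) > 1) {
    cm <- abs(cor(as.matrix(data[cont])))
    alive <- rep(TRUE, length(cont))
    for (i in seq_along(cont)[-length(cont)]) {
      if (!alive[i]) next
      for (j in seq((i + 1), length(cont))) {
        if (alive[j] && cm[i, j] > corr_threshold) {
          alive[j] <- FALSE
          drops <- bind_rows(
            drops,
            tibble(variable = cont[j],
                   reason = sprintf("correlated_with:%s", cont[i]))
          )
        }
      }
    }
  }

  low_gini <- disc[map_lgl(disc, ~ gini_impurity(data[[.x]]) < gini_threshold)]
  if (length(low_gini) > 0) {
    drops <- bind_rows(drops,
                       tibble(variable = low_gini, reason = "low_gini"))
  }

  out <- data[, setdiff(names(data), drops$variable), drop = FALSE]
  attr(out, "threec_report") <- drops
  out
}

#' Append per-domain composite scores
#'
#' Adds one new variable per domain, the row-wise sum of its item variables
#' (e.g. summing item scores per cognitive domain). Items of a domain must
#' share a severity direction, which the composite inherits. Original item
#' columns are retained.
#'
#' @param data Cohort tibble with all item variables present and numeric.
#' @param catalog Variable catalog (used for the direction check).
#' @param domain_map Named list: domain name -> character vector of item
#'   variables.
#'
#' @return Tibble with composite columns appended; `cohort_catalog()`
#'   returns the catalog extended with one CM row per composite.
#' @export
add_domain_scores <- function(data, catalog, domain_map) {
  data <- as_tibble(data)
  new_catalog <- catalog
  if (length(domain_map) == 0) {
    attr(data, "threec_catalog") <- new_catalog
    return(data)
  }
  if (is.null(names(domain_map)) || any(names(domain_map) == "")) {
    abort("`domain_map` must be a named list of item vectors.")
  }
  for (dom in names(domain_map)) {
    items <- domain_map[[dom]]
    missing_items <- setdiff(items, names(data))
    if (length(missing_items) > 0) {
      abort(sprintf("Domain '%s': items not in data: %s", dom,
                    paste(missing_items, collapse = ", ")))
    }
    if (!all(map_lgl(data[items], is.numeric))) {
      abort(sprintf("Domain '%s': all items must be numeric.", dom))
    }
    dirs <- unique(catalog$direction[catalog$variable %in% items])
    if (length(dirs) != 1) {
      abort(sprintf("Domain '%s': items have mixed severity directions.", dom))
    }
    data[[dom]] <- rowSums(as.matrix(data[items]))
    new_catalog <- bind_rows(
      new_catalog,
      tibble(variable = dom, category = "CM", vartype = "continuous",
             direction = dirs, domain = dom)
    )
  }
  attr(data, "threec_catalog") <- new_catalog
  data
}

# transform candidates; all strictly monotone increasing on the sample.
# log/sqrt shift only when needed for domain validity, so an all-positive
# variable gets the plain transform
#' @noRd
transform_candidates <- function() {
  list(
    identity = function(x) x,
    log = function(x) {
      if (min(x) > 0) log(x) else log(x - min(x) + 1)
    },
    sqrt = function(x) {
      if (min(x) >= 0) sqrt(x) else sqrt(x - min(x))
    },
    rank_normal = function(x) {
      n <- length(x)
      qnorm((rank(x, ties.method = "average") - 0.375) / (n + 0.25))
    }
  )
}

#' Choose a monotone symmetrizing transform
#'
#' Evaluates a family of strictly monotone increasing candidate transforms
#' (identity, log, square root -- shifted only when the domain requires
#' it -- and rank-normal scores) and returns the transformed values of the
#' candidate minimizing absolute sample skewness. Because rank-normal
#' scores have essentially zero skewness by construction, the earliest
#' (simplest) candidate within `tol` of the minimum is preferred, keeping
#' interpretable transforms when their gain is negligible. Output is
#' always order-isomorphic to the input.
#'
#' @param x Complete numeric vector, length >= 3.
#' @param family Character subset of
#'   `c("identity", "log", "sqrt", "rank_normal")`, in preference order.
#' @param tol Near-tie tolerance on |skewness| for preferring an earlier
#'   candidate. The default `NULL` uses `max(0.1, 2 * sqrt(6 / n))`, twice
#'   the large-sample standard error of the skewness estimator under
#'   symmetry: differences smaller than the estimator's own noise do not
#'   justify a less interpretable transform.
#'
#' @return The transformed numeric vector, with attributes `transform`
#'   (chosen label), `skewness_before`, `skewness_after` and `degenerate`
#'   (`TRUE` for a constant input, returned untouched).
#' @export
#' @examples
#' x <- exp(rnorm(200))
#' y <- monotone_transform(x)
#' attr(y, "transform")
monotone_transform <- function(x,
                               family = c("identity", "log", "sqrt",
                                          "rank_normal"),
                               tol = NULL) {
  if (!is.numeric(x) || anyNA(x)) abort("`x` must be complete and numeric.")
  if (length(x) < 3) abort("`x` must have length >= 3.")
  tol <- tol %||% max(0.1, 2 * sqrt(6 / length(x)))
  candidates <- transform_candidates()[match.arg(family, names(transform_candidates()),
                                                 several.ok = TRUE)]
  skew_before <- sample_skewness(x)
  if (var(x) == 0) {
    return(structure(x, transform = "identity",
                     skewness_before = 0, skewness_after = 0,
                     degenerate = TRUE))
  }
  transformed <- map(candidates, ~ .x(x))
  skews <- map_dbl(transformed, ~ abs(sample_skewness(.x)))
  best <- which(skews <= min(skews) + tol)[1]
  structure(
    transformed[[best]],
    transform = names(candidates)[best],
    skewness_before = skew_before,
    skewness_after = sample_skewness(transformed[[best]]),
    degenerate = FALSE
  )
}

#' Apply monotone transforms across a cohort
#'
#' Runs [monotone_transform()] on every continuous non-DX variable and
#' replaces the column with its transformed values.
#'
#' @inheritParams remove_redundant
#' @param ... Passed to [monotone_transform()].
#' @return Tibble with transformed columns; `preprocess_report()` returns a
#'   tibble of chosen transforms and before/after skewness per variable.
#' @export
transform_cohort <- function(data, catalog, id_col = "subject_id", ...) {
  data <- as_tibble(data)
  vars <- intersect(
    catalog$variable[catalog$category != "DX" &
                       catalog$vartype == "continuous"],
    names(data)
  )
  rows <- map(vars, function(v) {
    y <- monotone_transform(data[[v]], ...)
    tibble(variable = v, transform = attr(y, "transform"),
           skewness_before = attr(y, "skewness_before"),
           skewness_after = attr(y, "skewness_after"))
  })
  for (i in seq_along(vars)) {
    data[[vars[i]]] <- as.numeric(monotone_transform(data[[vars[i]]], ...))
  }
  attr(data, "threec_report") <- bind_rows(rows)
  data
}
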