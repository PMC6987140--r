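# Descriptive surfaces: pooled empirical-quantile cluster profiles with
# order-statistic (binomial) median confidence intervals, similarity
# ordering of variables, the three-state pairwise signature heatmap, and
# per-cluster characterization tables.

#' Pooled empirical-quantile transform
#'
#' Maps values to severity quantiles in \[0, 1\] computed across all
#' subjects pooled: quantile = (midrank - 1) / (n - 1), so the observed
#' minimum maps to 0 (healthiest state) and the maximum to 1 (most
#' severe); ties share midrank-based quantiles. Variables oriented
#' "higher is better" are flipped (quantile := 1 - quantile) so 0 is
#' always the healthy end.
#'
#' @param x Complete numeric vector, length >= 2.
#' @param direction `"higher_worse"` or `"higher_better"`.
#' @return Numeric vector of quantiles in \[0, 1\]. A constant vector
#'   returns all 0.5 with a warning.
#' @export
#' @examples
#' empirical_quantile_transform(c(1, 3, 5), "higher_worse")   # 0 0.5 1
#' empirical_quantile_transform(c(1, 3, 5), "higher_better")  # 1 0.5 0
empirical_quantile_transform <- function(x,
                                         direction = c("higher_worse",
                                                       "higher_better")) {
  direction <- match.arg(direction)
  if (!is.numeric(x) || anyNA(x)) abort("`x` must be complete and numeric.")
  if (length(x) < 2) abort("`x` must have length >= 2.")
  if (var(x) == 0) {
    warn("Constant variable: all quantiles set to 0.5.")
    return(rep(0.5, length(x)))
  }
  q <- (rank(x, ties.method = "average") - 1) / (length(x) - 1)
  if (direction == "higher_better") q <- 1 - q
  q
}

#' Median with order-statistic (binomial) confidence interval
#'
#' The CI endpoints are observed order statistics chosen from the
#' Binomial(n, 1/2) distribution: the lower endpoint is x(l) with l the
#' largest integer such that P(Binom < l) <= (1 - level)/2, and the upper
#' endpoint x(u) with u the smallest integer such that
#' P(Binom < u) >= 1 - (1 - level)/2. Guaranteed coverage >= `level` for
#' continuous data.
#'
#' @param x Nonempty numeric vector.
#' @param level Nominal coverage. Default 0.95.
#' @return One-row tibble: `median`, `lower`, `upper`, `n`, `degenerate`
#'   (`TRUE` when n is too small for a proper interval and the full range
#'   is returned).
#' @export
median_with_binomial_ci <- function(x, level = 0.95) {
  if (length(x) == 0) abort("`x` must be nonempty.")
  assert_prob(level, "level")
  n <- length(x)
  xs <- sort(x)
  med <- median(x)
  alpha <- 1 - level
  if (n == 1) {
    return(tibble(median = med, lower = xs[1], upper = xs[1],
                  n = n, degenerate = TRUE))
  }
  lows <- which(pbinom(seq_len(n) - 1, n, 0.5) <= alpha / 2)
  ups <- which(pbinom(seq_len(n) - 1, n, 0.5) >= 1 - alpha / 2)
  degenerate <- length(lows) == 0 || length(ups) == 0
  l <- if (length(lows) > 0) max(lows) else 1L
  u <- if (length(ups) > 0) min(ups) else n
  tibble(median = med, lower = xs[l], upper = xs[u], n = n,
         degenerate = degenerate)
}

#' Order variables by profile similarity
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' the variables' median-profile vectors (clusters x variables); the
#' dendrogram's leaves, reordered by mean profile value for a canonical
#' orientation, give the display order. Variables with similar cluster
#' patterns end up adjacent.
#'
#' @param profile_matrix Numeric matrix, rows = clusters, columns =
#'   variables (column names required).
#' @return Character vector: variable names in display order.
#' @export
order_variables_by_similarity <- function(profile_matrix) {
  m <- as.matrix(profile_matrix)
  if (ncol(m) < 2) return(colnames(m))
  hc <- hclust(dist(t(m), method = "euclidean"), method = "average")
  dend <- reorder(as.dendrogram(hc), colMeans(m), agglo.FUN = mean)
  colnames(m)[order.dendrogram(dend)]
}

#' Empirical-quantile cluster profiles
#'
#' For every profiled variable, all subjects' values are transformed to
#' pooled empirical quantiles (oriented by the catalog's severity
#' direction) and each cluster is summarized by the median quantile with
#' its order-statistic binomial CI. Pooling across clusters makes the
#' cluster medians comparable on one severity axis. Variables are ordered
#' by profile similarity for display.
#'
#' @param data Complete cohort tibble.
#' @param catalog Variable catalog (supplies severity directions; variables
#'   with direction `"none"` are excluded with a warning).
#' @param labels Cluster labels aligned with `data` rows.
#' @param variables Variables to profile; default every cataloged CM and
#'   pBM present in `data`.
#' @param level CI coverage. Default 0.95.
#'
#' @return Object of class `threec_profile`: `profile` tibble (`variable`,
#'   `cluster`, `n`, `median`, `lower`, `upper`), `variable_order`,
#'   `level`.
#' @export
quantile_profile <- function(data, catalog, labels, variables = NULL,
                             level = 0.95) {
  data <- as_tibble(data)
  labels <- droplevels(factor(labels))
  if (length(labels) != nrow(data)) abort("`labels` must match `data` rows.")

  vars <- variables %||% intersect(
    catalog$variable[catalog$category %in% c("CM", "PBM")], names(data)
  )
  dirs <- catalog$direction[match(vars, catalog$variable)]
  no_dir <- vars[is.na(dirs) | dirs == "none"]
  if (length(no_dir) > 0) {
    warn(sprintf("Excluding variables without a severity direction: %s",
                 paste(no_dir, collapse = ", ")))
    keep <- !(vars %in% no_dir)
    vars <- vars[keep]
    dirs <- dirs[keep]
  }
  if (length(vars) == 0) abort("No variables with a direction to profile.")

  prof <- purrr::map2_dfr(vars, dirs, function(v, d) {
    q <- empirical_quantile_transform(data[[v]], d)
    purrr::map_dfr(levels(labels), function(cl) {
      ci <- median_with_binomial_ci(q[labels == cl], level = level)
      tibble(variable = v, cluster = cl, n = ci$n, median = ci$median,
             lower = ci$lower, upper = ci$upper)
    })
  })

  med_mat <- tidyr::pivot_wider(prof[, c("variable", "cluster", "median")],
                                names_from = "variable",
                                values_from = "median")
  m <- as.matrix(med_mat[, -1, drop = FALSE])
  ord <- order_variables_by_similarity(m)

  structure(
    list(profile = prof, variable_order = ord, level = level,
         cluster_levels = levels(labels)),
    class = "threec_profile"
  )
}

#' @export
print.threec_profile <- function(x, ...) {
  cat(sprintf("<threec_profile> %d variables x %d clusters (%.0f%% CIs)\n",
              length(x$variable_order), length(x$cluster_levels),
              100 * x$level))
  invisible(x)
}

#' Tidy a quantile profile
#'
#' @param x A `threec_profile` object.
#' @param ... Unused.
#' @return The per-(variable, cluster) tibble with medians and CI bounds;
#'   `variable` is a factor in display order.
#' @method tidy threec_profile
#' @export
tidy.threec_profile <- function(x, ...) {
  mutate(x$profile,
         variable = factor(.data$variable, levels = x$variable_order))
}

#' Parallel-coordinates plot of cluster quantile profiles
#'
#' Variables on the vertical axis (similarity order), median severity
#' quantile on the horizontal axis, one line per cluster with its binomial
#' median CI as a ribbon: 0 is the healthy end, 1 the most severe.
#'
#' @param object A `threec_profile` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threec_profile
#' @export
autoplot.threec_profile <- function(object, ...) {
  df <- arrange(tidy(object), .data$cluster, .data$variable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$variable,
                                   color = .data$cluster,
                                   group = .data$cluster)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                      fill = .data$cluster),
                         alpha = 0.15, color = NA, orientation = "y") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "median severity quantile (0 = healthy, 1 = severe)",
                  y = NULL, color = "cluster", fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Three-state pairwise signature heatmap matrix
#'
#' Rows are the pBMs with at least one significant pair, columns the
#' k(k-1)/2 cluster pairs; each cell is +1 (first cluster of the pair has
#' the significantly larger mean rank), -1 (second larger) or 0 (not
#' significant). Row and column orders come from average-linkage
#' hierarchical clustering on Manhattan (Hamming-like) distances over the
#' three-state codes.
#'
#' @param table A `threec_signatures` object.
#' @return Object of class `threec_heatmap`: `matrix` (rows x pairs),
#'   `row_order`, `col_order`, `pair_labels`. With no significant pBMs the
#'   matrix is empty but valid.
#' @export
build_heatmap_matrix <- function(table) {
  stopifnot(inherits(table, "threec_signatures"))
  lev <- table$cluster_levels
  pair_grid <- cluster_pairs(lev)
  pair_labels <- paste(pair_grid$cluster_a, pair_grid$cluster_b, sep = ":")

  pairs <- table$pairs
  active <- unique(pairs$pbm[pairs$sign != 0])
  m <- matrix(0, length(active), length(pair_labels),
              dimnames = list(active, pair_labels))
  if (length(active) > 0 && nrow(pairs) > 0) {
    key <- paste(pairs$cluster_a, pairs$cluster_b, sep = ":")
    for (i in seq_len(nrow(pairs))) {
      if (pairs$pbm[i] %in% active) {
        m[pairs$pbm[i], key[i]] <- pairs$sign[i]
      }
    }
  }

  row_order <- rownames(m)
  col_order <- colnames(m)
  if (nrow(m) > 2) {
    hc <- hclust(dist(m, method = "manhattan"), method = "average")
    row_order <- rownames(m)[hc$order]
  }
  if (nrow(m) > 0 && ncol(m) > 2) {
    hc <- hclust(dist(t(m), method = "manhattan"), method = "average")
    col_order <- colnames(m)[hc$order]
  }

  structure(
    list(matrix = m, row_order = row_order, col_order = col_order,
         pair_labels = pair_labels, k = table$k),
    class = "threec_heatmap"
  )
}

#' @export
print.threec_heatmap <- function(x, ...) {
  cat(sprintf("<threec_heatmap> %d pBMs x %d cluster pairs\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Tidy a signature heatmap
#'
#' @param x A `threec_heatmap` object.
#' @param ... Unused.
#' @return Long tibble (`pbm`, `pair`, `sign`) with factor levels in
#'   dendrogram order.
#' @method tidy threec_heatmap
#' @export
tidy.threec_heatmap <- function(x, ...) {
  if (nrow(x$matrix) == 0) {
    return(tibble(pbm = character(), pair = character(), sign = numeric()))
  }
  df <- as_tibble(as.data.frame(x$matrix), rownames = "pbm")
  df <- tidyr::pivot_longer(df, -"pbm", names_to = "pair",
                            values_to = "sign")
  mutate(df,
         pbm = factor(.data$pbm, levels = x$row_order),
         pair = factor(.data$pair, levels = x$col_order))
}

#' Plot a three-state signature heatmap
#'
#' Turquoise: no significant difference; yellow: the pair's first cluster
#' has the larger mean rank; purple: the second cluster is larger.
#'
#' @param object A `threec_heatmap` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threec_heatmap
#' @export
autoplot.threec_heatmap <- function(object, ...) {
  df <- tidy(object)
  df$state <- factor(df$sign, levels = c(-1, 0, 1),
                     labels = c("second larger", "n.s.", "first larger"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$pbm,
                                   fill = .data$state)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c("second larger" = "#9467bd", "n.s." = "#40E0D0",
                 "first larger" = "#FFD700"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "cluster pair", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-cluster characterization table
#'
#' Summarizes each cluster (n; mean and sd for continuous variables;
#' counts and percentages per level for categorical ones) and tests
#' across-cluster differences: Kruskal-Wallis for continuous variables,
#' chi-square for categorical ones. With a single cluster no test
#' p-values are emitted; empty clusters are dropped with a warning.
#'
#' @param data Cohort tibble.
#' @param labels Cluster labels aligned with `data` rows.
#' @param variables Variables to characterize; default all non-id columns.
#' @param id_col Subject id column name.
#' @return Long tibble: `variable`, `vartype`, `cluster`, `n`, `mean`,
#'   `sd` (continuous rows), `level`, `count`, `pct` (categorical rows),
#'   `p_value` (repeated per variable), `test`.
#' @export
characterize_clusters <- function(data, labels, variables = NULL,
                                  id_col = "subject_id") {
  data <- as_tibble(data)
  labels <- factor(labels)
  if (length(labels) != nrow(data)) abort("`labels` must match `data` rows.")
  empty <- levels(labels)[tabulate(labels, nlevels(labels)) == 0]
  if (length(empty) > 0) {
    warn(sprintf("Omitting empty clusters: %s", paste(empty, collapse = ", ")))
    labels <- droplevels(labels)
  }
  vars <- variables %||% setdiff(names(data), id_col)
  single <- nlevels(labels) < 2

  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      p <- if (single) NA_real_ else kruskal_wallis(x, labels)$p_value
      purrr::map_dfr(levels(labels), function(cl) {
        xi <- x[labels == cl]
        tibble(variable = v, vartype = "continuous", cluster = cl,
               n = length(xi), mean = mean(xi), sd = sd(xi),
               level = NA_character_, count = NA_integer_, pct = NA_real_,
               p_value = p, test = if (single) NA_character_ else "kruskal_wallis")
      })
    } else {
      xf <- factor(x)
      p <- if (single) NA_real_ else
        suppressWarnings(chisq.test(table(labels, xf))$p.value)
      purrr::map_dfr(levels(labels), function(cl) {
        xi <- xf[labels == cl]
        tb <- table(xi)
        tibble(variable = v, vartype = "categorical", cluster = cl,
               n = length(xi), mean = NA_real_, sd = NA_real_,
               level = names(tb), count = as.integer(tb),
               pct = 100 * as.integer(tb) / max(length(xi), 1),
               p_value = p, test = if (single) NA_character_ else "chi_square")
      })
    }
  })
}
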