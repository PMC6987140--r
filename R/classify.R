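# Step 3 of 3C: biomarker signature testing.
#
# Stage 1 screens the pBMs with Kruskal-Wallis tests across the clusters
# and Benjamini-Hochberg FDR control at budget q. Stage 2 tests all
# k(k-1)/2 cluster pairs per selected pBM with two-sided Wilcoxon rank-sum
# tests; to account for the stage-1 selection, pairwise BH runs at the
# Benjamini-Bogomolov adjusted level q * S / M (S selected of M candidate
# pBMs). Both stages are rank-based throughout, so decisions are invariant
# to strictly monotone transforms of the biomarkers.

#' Kruskal-Wallis test across groups
#'
#' Midrank-based H statistic with the standard tie correction and a
#' chi-square upper-tail p-value (df = groups - 1). A constant input
#' returns H = 0, p = 1.
#'
#' @param x Numeric values.
#' @param g Group labels (>= 2 groups with >= 1 observation each).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
kruskal_wallis <- function(x, g) {
  g <- droplevels(factor(g))
  if (nlevels(g) < 2) abort("Kruskal-Wallis needs >= 2 groups.")
  if (length(x) != length(g)) abort("`x` and `g` lengths differ.")
  if (var(x) == 0) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  ht <- kruskal.test(x, g)
  tibble(statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact enumeration null when the pooled sample size is at most
#' 20 and there are no ties; otherwise the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y Nonempty numeric samples.
#' @return One-row tibble: `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `exact`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # exact p = 1/3
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("Both samples must be nonempty.")
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= 20 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic),
         p_value = min(ht$p.value, 1),
         exact = exact)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Rejects all ordered p-values up to the largest i with
#' p(i) <= i * level / m, and reports the monotone step-up adjusted
#' p-values (ties handled jointly).
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param level FDR budget. Default 0.05.
#' @return Tibble: `p_value`, `p_adjusted`, `rejected`.
#' @export
benjamini_hochberg <- function(p, level = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  assert_prob(level, "level")
  adj <- p.adjust(p, method = "BH")
  tibble(p_value = p, p_adjusted = adj, rejected = adj <= level)
}

#' Benjamini-Bogomolov adjusted testing level
#'
#' When S of M candidate families were selected by a first-stage screen at
#' FDR budget q, testing within the selected families at level q * S / M
#' preserves the average FDR over the selected families.
#'
#' @param q FDR budget, 0 < q < 1.
#' @param S Number of selected families (0 <= S <= M).
#' @param M Number of candidate families (M >= 1).
#' @return The adjusted level q * S / M.
#' @export
#' @examples
#' bb_adjusted_level(0.05, 51, 170)  # 0.015
bb_adjusted_level <- function(q, S, M) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("`q` must be a single number in (0, 1).")
  }
  M <- assert_count(M, "M", min = 1)
  S <- assert_count(S, "S", min = 0)
  if (S > M) abort("`S` cannot exceed `M`.")
  q * S / M
}

#' Build the biomarker signature table
#'
#' Runs the full classify stage: Kruskal-Wallis screening of all M pBMs
#' across the clusters with BH at budget `q`; then, for each selected pBM,
#' two-sided Wilcoxon rank-sum tests for all k(k-1)/2 cluster pairs, with
#' BH within each selected pBM's pair family at the Benjamini-Bogomolov
#' adjusted level q * S / M. The sign of a rejected pair is +1 when the
#' first cluster of the (lower, higher)-ordered pair has the larger mean
#' rank, -1 otherwise, and 0 for non-rejected pairs. Pairs involving a
#' cluster with fewer than 2 subjects are untestable (sign 0, p absent).
#'
#' @param pbm Tibble of numeric pBM columns.
#' @param labels Cluster labels (>= 2 clusters), e.g. from
#'   [kmedoids_manhattan()].
#' @param q FDR budget. Default 0.05.
#' @param pool_pairs If `TRUE`, the pairwise BH pools all selected pBMs'
#'   pair p-values into a single family at the adjusted level instead of
#'   running per-pBM families. Default `FALSE`.
#'
#' @return Object of class `threec_signatures`: `screening` tibble (per
#'   pBM: `statistic`, `p_value`, `p_adjusted`, `selected`), `pairs` tibble
#'   (per selected pBM and cluster pair: `p_value`, `p_adjusted`, `sign`,
#'   `testable`), and metadata `q`, `M`, `S`, `adjusted_level`, `k`,
#'   `cluster_levels`.
#' @seealso [signature_for_cluster()], [build_heatmap_matrix()]
#' @export
build_signature_table <- function(pbm, labels, q = 0.05, pool_pairs = FALSE) {
  pbm <- as_tibble(pbm)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) abort("Need >= 2 clusters.")
  if (nrow(pbm) != length(labels)) abort("`pbm` rows and `labels` differ.")
  if (ncol(pbm) < 1) abort("Need >= 1 pBM.")

  M <- ncol(pbm)
  lev <- levels(labels)
  k <- length(lev)

  screening <- purrr::map_dfr(names(pbm), function(v) {
    kw <- kruskal_wallis(pbm[[v]], labels)
    tibble(pbm = v, statistic = kw$statistic, p_value = kw$p_value)
  })
  bh <- benjamini_hochberg(screening$p_value, level = q)
  screening$p_adjusted <- bh$p_adjusted
  screening$selected <- bh$rejected
  S <- sum(screening$selected)
  adjusted_level <- bb_adjusted_level(q, S, M)

  sizes <- table(labels)
  pair_grid <- cluster_pairs(lev)

  pairs <- purrr::map_dfr(screening$pbm[screening$selected], function(v) {
    vals <- pbm[[v]]
    res <- purrr::pmap_dfr(pair_grid, function(cluster_a, cluster_b) {
      xa <- vals[labels == cluster_a]
      xb <- vals[labels == cluster_b]
      if (length(xa) < 2 || length(xb) < 2) {
        return(tibble(cluster_a = cluster_a, cluster_b = cluster_b,
                      p_value = NA_real_, mean_rank_diff = NA_real_,
                      testable = FALSE))
      }
      w <- wilcoxon_rank_sum(xa, xb)
      r <- rank(c(xa, xb))
      diff <- mean(r[seq_along(xa)]) - mean(r[-seq_along(xa)])
      tibble(cluster_a = cluster_a, cluster_b = cluster_b,
             p_value = w$p_value, mean_rank_diff = diff, testable = TRUE)
    })
    res$pbm <- v
    res
  })

  if (nrow(pairs) > 0) {
    pairs$p_adjusted <- NA_real_
    pairs$rejected <- FALSE
    if (adjusted_level > 0) {
      if (pool_pairs) {
        idx <- which(pairs$testable)
        if (length(idx) > 0) {
          bh2 <- benjamini_hochberg(pairs$p_value[idx], adjusted_level)
          pairs$p_adjusted[idx] <- bh2$p_adjusted
          pairs$rejected[idx] <- bh2$rejected
        }
      } else {
        for (v in unique(pairs$pbm)) {
          idx <- which(pairs$pbm == v & pairs$testable)
          if (length(idx) > 0) {
            bh2 <- benjamini_hochberg(pairs$p_value[idx], adjusted_level)
            pairs$p_adjusted[idx] <- bh2$p_adjusted
            pairs$rejected[idx] <- bh2$rejected
          }
        }
      }
    }
    pairs$sign <- ifelse(pairs$rejected & pairs$mean_rank_diff != 0,
                         sign(pairs$mean_rank_diff), 0)
    pairs <- pairs[, c("pbm", "cluster_a", "cluster_b", "p_value",
                       "p_adjusted", "sign", "testable")]
  } else {
    pairs <- tibble(pbm = character(), cluster_a = character(),
                    cluster_b = character(), p_value = numeric(),
                    p_adjusted = numeric(), sign = numeric(),
                    testable = logical())
  }

  structure(
    list(screening = screening, pairs = pairs, q = q, M = M, S = S,
         adjusted_level = adjusted_level, k = k, cluster_levels = lev,
         pool_pairs = pool_pairs),
    class = "threec_signatures"
  )
}

#' @export
print.threec_signatures <- function(x, ...) {
  cat(sprintf(
    "<threec_signatures> %d/%d pBMs selected at q = %g; pairwise level %.4g\n",
    x$S, x$M, x$q, x$adjusted_level
  ))
  cat(sprintf("  %d clusters -> %d pairs per selected pBM; %d signed calls\n",
              x$k, x$k * (x$k - 1) / 2, sum(x$pairs$sign != 0)))
  invisible(x)
}

#' Tidy a signature table
#'
#' @param x A `threec_signatures` object.
#' @param ... Unused.
#' @return Long tibble joining the screening columns onto the per-pair
#'   rows (one row per selected pBM and cluster pair).
#' @method tidy threec_signatures
#' @export
tidy.threec_signatures <- function(x, ...) {
  left_join(
    x$pairs,
    rename(x$screening, kw_statistic = "statistic",
           kw_p_value = "p_value", kw_p_adjusted = "p_adjusted"),
    by = "pbm"
  )
}

#' One-row summary of a signature table
#'
#' @param x A `threec_signatures` object.
#' @param ... Unused.
#' @return Tibble with `M`, `S`, `q`, `adjusted_level`, `k`, `n_pairs` and
#'   `n_signed`.
#' @method glance threec_signatures
#' @export
glance.threec_signatures <- function(x, ...) {
  tibble(M = x$M, S = x$S, q = x$q, adjusted_level = x$adjusted_level,
         k = x$k, n_pairs = x$k * (x$k - 1) / 2,
         n_signed = sum(x$pairs$sign != 0))
}

#' Biomarker signature of one cluster
#'
#' The signature of a cluster is the set of pBMs with at least one
#' nonzero-signed pair involving that cluster, with per-pair directions
#' re-expressed relative to the cluster (+1: the cluster's values are
#' larger than the comparison cluster's).
#'
#' @param table A `threec_signatures` object.
#' @param cluster A cluster label present in the table.
#' @return Tibble: `pbm`, `other_cluster`, `direction`.
#' @export
signature_for_cluster <- function(table, cluster) {
  stopifnot(inherits(table, "threec_signatures"))
  cluster <- as.character(cluster)
  if (!cluster %in% table$cluster_levels) {
    abort(sprintf("Unknown cluster '%s' (known: %s).", cluster,
                  paste(table$cluster_levels, collapse = ", ")))
  }
  hits <- filter(table$pairs, .data$sign != 0,
                 .data$cluster_a == cluster | .data$cluster_b == cluster)
  tibble(
    pbm = hits$pbm,
    other_cluster = ifelse(hits$cluster_a == cluster,
                           hits$cluster_b, hits$cluster_a),
    direction = ifelse(hits$cluster_a == cluster, hits$sign, -hits$sign)
  )
}
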