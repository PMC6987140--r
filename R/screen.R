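# Supervised relevance screening of clinical measurements by random-forest
# permutation importance against the assigned diagnosis, in two stages:
#
#   thresholding    - fit n_forests_threshold forests; per CM take the mean
#                     and sd of permutation importance across forests; drop
#                     CMs whose mean importance falls below the minimum of a
#                     regression-tree fit of sd-of-importance against
#                     importance rank (a data-driven noise floor);
#   interpretation  - order survivors by mean importance, fit nested forests
#                     on the top-1, top-2, ... prefixes
#                     (n_forests_interpretation forests each) and keep the
#                     smallest prefix whose mean out-of-bag error is within
#                     one sd of the best prefix's error.
#
# The screen leverages the diagnosis as a supervisory hint without treating
# it as ground truth: the selected CMs feed the *unsupervised* clustering.

#' Two-stage random-forest importance screening of CMs
#'
#' @param cm Tibble/data frame of numeric clinical measurements (>= 2
#'   columns).
#' @param dx Diagnosis labels (factor with >= 2 observed levels).
#' @param n_forests_threshold Forests fitted in the thresholding stage.
#'   Default 50.
#' @param n_forests_interpretation Forests fitted per nested prefix in the
#'   interpretation stage. Default 25.
#' @param num_trees Trees per forest. Default 100.
#' @param mtry Variables sampled per split; `NULL` uses the forest default
#'   (square root of the number of CMs).
#' @param seed Integer seed controlling all forest randomness.
#'
#' @return An object of class `threec_screen` with elements `importance`
#'   (per-CM tibble: mean/sd of importance, rank, elimination stage),
#'   `selected` (character vector of selected CMs, ordered by importance),
#'   `prefix` (per-prefix OOB error tibble), `threshold`, and the
#'   hyperparameters used. Constant (zero-variance) CMs are eliminated up
#'   front and can never be selected.
#' @seealso [tidy.threec_screen()], [glance.threec_screen()]
#' @export
screen_cm_importance <- function(cm, dx,
                                 n_forests_threshold = 50,
                                 n_forests_interpretation = 25,
                                 num_trees = 100,
                                 mtry = NULL,
                                 seed = 1) {
  cm <- as_tibble(cm)
  if (ncol(cm) < 2) abort("Screening needs at least 2 CM variables.")
  dx <- droplevels(factor(dx))
  if (nlevels(dx) < 2) abort("Screening needs >= 2 observed DX levels.")
  if (nrow(cm) < 20) abort("Screening needs at least 20 subjects.")
  if (!all(map_lgl(cm, is.numeric))) abort("All CM columns must be numeric.")
  seed <- assert_count(seed, "seed")

  constant <- names(cm)[map_lgl(cm, ~ var(.x) == 0)]
  active <- setdiff(names(cm), constant)
  if (length(active) < 1) abort("All CM variables are constant.")

  x <- as.data.frame(cm[active])

  one_forest <- function(cols, s, importance = "none") {
    ranger::ranger(
      x = x[, cols, drop = FALSE], y = dx,
      num.trees = num_trees, mtry = mtry,
      importance = importance,
      seed = s, num.threads = 1,
      write.forest = FALSE
    )
  }

  # stage 1: thresholding
  imp <- matrix(NA_real_, n_forests_threshold, length(active),
                dimnames = list(NULL, active))
  for (f in seq_len(n_forests_threshold)) {
    fit <- one_forest(active, seed * 1000L + f, importance = "permutation")
    imp[f, ] <- fit$variable.importance[active]
  }
  mean_imp <- colMeans(imp)
  sd_imp <- apply(imp, 2, sd)
  rk <- rank(-mean_imp, ties.method = "first")

  # regression tree of sd-of-importance against rank; its minimum predicted
  # value is the data-driven noise floor (default rpart pruning keeps the
  # leaves large enough that the floor is the noise plateau, not an outlier)
  thr_df <- data.frame(rank = rk, sd = sd_imp)
  tree <- rpart::rpart(sd ~ rank, data = thr_df)
  threshold <- min(predict(tree, thr_df))

  survivors <- active[mean_imp >= threshold]
  if (length(survivors) < 1) {
    warn("No CM passed the thresholding stage; falling back to the top-1 CM.")
    survivors <- active[which.max(mean_imp)]
  }
  survivors <- survivors[order(-mean_imp[survivors])]

  # stage 2: interpretation (nested prefix models)
  m <- length(survivors)
  err_mean <- err_sd <- numeric(m)
  for (j in seq_len(m)) {
    errs <- map_dbl(seq_len(n_forests_interpretation), function(f) {
      one_forest(survivors[seq_len(j)],
                 seed * 1000L + 500L + j * 100L + f)$prediction.error
    })
    err_mean[j] <- mean(errs)
    err_sd[j] <- sd(errs)
  }
  j_star <- which.min(err_mean)
  sel_j <- which(err_mean <= err_mean[j_star] + err_sd[j_star])[1]
  selected <- survivors[seq_len(sel_j)]

  stage <- dplyr::case_when(
    names(cm) %in% selected ~ "kept",
    names(cm) %in% survivors ~ "interpretation",
    names(cm) %in% constant ~ "constant",
    TRUE ~ "threshold"
  )

  importance_tbl <- tibble(
    variable = names(cm),
    mean_importance = ifelse(names(cm) %in% active,
                             unname(mean_imp[names(cm)]), 0),
    sd_importance = ifelse(names(cm) %in% active,
                           unname(sd_imp[names(cm)]), 0),
    rank = rank(-ifelse(names(cm) %in% active,
                        unname(mean_imp[names(cm)]), -Inf),
                ties.method = "first"),
    stage = stage,
    selected = names(cm) %in% selected
  )

  structure(
    list(
      importance = arrange(importance_tbl, rank),
      selected = selected,
      prefix = tibble(size = seq_len(m), variable = survivors,
                      oob_error_mean = err_mean, oob_error_sd = err_sd),
      threshold = threshold,
      params = list(n_forests_threshold = n_forests_threshold,
                    n_forests_interpretation = n_forests_interpretation,
                    num_trees = num_trees, mtry = mtry),
      seed = seed
    ),
    class = "threec_screen"
  )
}

#' @export
print.threec_screen <- function(x, ...) {
  cat(sprintf(
    "<threec_screen> %d/%d CMs selected (threshold %.4g)\n",
    length(x$selected), nrow(x$importance), x$threshold
  ))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a screening result
#'
#' @param x A `threec_screen` object.
#' @param ... Unused.
#' @return Per-CM tibble with mean/sd permutation importance, rank,
#'   elimination stage and selection flag.
#' @method tidy threec_screen
#' @export
tidy.threec_screen <- function(x, ...) x$importance

#' One-row summary of a screening result
#'
#' @param x A `threec_screen` object.
#' @param ... Unused.
#' @return Tibble with CM counts per stage, the importance threshold and
#'   the selected prefix's out-of-bag error.
#' @method glance threec_screen
#' @export
glance.threec_screen <- function(x, ...) {
  tibble(
    n_cm = nrow(x$importance),
    n_survivors = nrow(x$prefix),
    n_selected = length(x$selected),
    threshold = x$threshold,
    oob_error = x$prefix$oob_error_mean[length(x$selected)]
  )
}
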