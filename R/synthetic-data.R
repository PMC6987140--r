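# Synthetic cohort generator with planted ground truth.
#
# Emulates the data regime of a baseline clinical study of the Alzheimer's
# disease spectrum: a crude five-level assigned diagnosis (CN .. AD) derived
# from a latent severity, a minority of clinical measurements carrying the
# true k-cluster structure among many uninformative ones, potential
# biomarkers with cluster-specific location shifts among null biomarkers,
# and missingness whose probability grows with diagnosed severity.

DX_LEVELS <- c("CN", "SMC", "EMCI", "LMCI", "AD")

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a baseline cohort of roughly the scale analysed in
#' published subtype-discovery work on the Alzheimer's spectrum: 650
#' subjects, six planted subtypes, 144 clinical measurements of which a
#' small informative minority (5) carries the cluster structure, and 170
#' potential biomarkers of which 20 carry cluster-specific shifts.
#'
#' @param n_subjects Number of subjects.
#' @param k_true Number of planted clusters (subtypes).
#' @param n_cm_info Number of informative clinical measurements (CMs) whose
#'   cluster-specific means are ordered along the severity axis.
#' @param n_cm_noise Number of noise CMs (iid standard normal, no cluster
#'   effect).
#' @param n_pbm_signal Number of signal potential biomarkers (pBMs), each
#'   shifted in a small designated set of clusters.
#' @param n_pbm_null Number of null pBMs (iid standard normal).
#' @param effect_size Standardized mean separation between adjacent cluster
#'   centers for informative CMs, and the location-shift magnitude (in SD
#'   units) for signal pBMs.
#' @param dx_noise Probability that a subject's diagnosis label is shifted
#'   one severity level (up or down with equal probability).
#' @param missing_rate_base Baseline missing-completely-at-random cell
#'   probability used by [inject_missingness()].
#' @param missing_dx_gradient Additional missingness probability per
#'   diagnosis severity level (0 for CN through 4 for AD).
#' @param heavy_tails If `TRUE`, informative-CM noise is drawn from a
#'   t-distribution with 3 degrees of freedom (scaled to unit variance)
#'   instead of a standard normal; useful for probing the robustness of the
#'   rank-based downstream stages.
#' @param seed Integer seed; generation is reproducible given the seed.
#'
#' @return A list of class `threec_config`.
#' @seealso [simulate_cohort()], [inject_missingness()]
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 120, k_true = 3, n_cm_info = 4,
#'                      n_cm_noise = 10, n_pbm_signal = 3, n_pbm_null = 10,
#'                      seed = 1)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$data)
cohort_config <- function(n_subjects = 650,
                          k_true = 6,
                          n_cm_info = 5,
                          n_cm_noise = 139,
                          n_pbm_signal = 20,
                          n_pbm_null = 150,
                          effect_size = 4,
                          dx_noise = 0.1,
                          missing_rate_base = 0.001,
                          missing_dx_gradient = 0.001,
                          heavy_tails = FALSE,
                          seed = 1) {
  cfg <- list(
    n_subjects = assert_count(n_subjects, "n_subjects"),
    k_true = assert_count(k_true, "k_true", min = 1),
    n_cm_info = assert_count(n_cm_info, "n_cm_info"),
    n_cm_noise = assert_count(n_cm_noise, "n_cm_noise"),
    n_pbm_signal = assert_count(n_pbm_signal, "n_pbm_signal"),
    n_pbm_null = assert_count(n_pbm_null, "n_pbm_null"),
    effect_size = effect_size,
    dx_noise = assert_prob(dx_noise, "dx_noise"),
    missing_rate_base = assert_prob(missing_rate_base, "missing_rate_base"),
    missing_dx_gradient = assert_prob(missing_dx_gradient, "missing_dx_gradient"),
    heavy_tails = isTRUE(heavy_tails),
    seed = assert_count(seed, "seed")
  )
  if (!is.numeric(cfg$effect_size) || cfg$effect_size < 0) {
    abort("`effect_size` must be a non-negative number.")
  }
  structure(cfg, class = "threec_config")
}

#' Simulate a cohort with planted subtype structure
#'
#' Generates a complete (no missing cells) subject-by-variable table, the
#' matching variable catalog, and the planted ground truth. The latent
#' severity of a subject is its cluster index mapped to equally spaced
#' scores plus a within-cluster jitter; the assigned diagnosis (DX) is a
#' five-level quantile cut of that severity with `dx_noise` label-shift
#' errors, so DX is a crude, overlapping surrogate of the planted
#' structure. Informative CMs each measure the same latent severity
#' (cluster centers spaced `effect_size` apart, the shared jitter, and
#' independent unit noise), so they carry the cluster structure jointly and
#' each additional CM refines the severity estimate. Half of the generated
#' variables are oriented "higher is worse" and half "higher is better",
#' forcing explicit direction handling downstream.
#'
#' @param config A [cohort_config()] object.
#'
#' @return A list of class `threec_cohort` with elements:
#'   \describe{
#'     \item{data}{tibble of `n_subjects` rows: `subject_id`, `DX` (factor
#'       CN < SMC < EMCI < LMCI < AD), informative and noise CM columns,
#'       signal and null pBM columns.}
#'     \item{catalog}{variable catalog tibble with columns `variable`,
#'       `category` (DX/CM/PBM), `vartype`, `direction`, `domain`.}
#'     \item{truth}{planted ground truth: `cluster` (integer label per
#'       subject), `informative_cms`, `signal_pbms`, and `signal_pairs`
#'       (per signal pBM, the cluster pairs with a true location
#'       difference).}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "threec_config")) {
    config <- do.call(cohort_config, config)
  }
  n <- config$n_subjects
  k <- config$k_true
  if (n < 1) abort("Invalid config: `n_subjects` must be positive.")
  if (config$n_cm_info + config$n_cm_noise < 1) {
    abort("Invalid config: at least one CM variable is required.")
  }

  set.seed(config$seed)
  cluster <- sample.int(k, n, replace = TRUE)

  # latent severity: equally spaced cluster scores + within-cluster jitter,
  # uniform on (0, 1) when clusters are balanced
  severity <- (cluster - 1 + runif(n)) / k
  dx_level <- pmin(floor(severity * 5), 4L)  # 0 (CN) .. 4 (AD)
  shift <- sample(c(-1L, 1L), n, replace = TRUE) *
    (runif(n) < config$dx_noise)
  dx_level <- pmin(pmax(dx_level + shift, 0L), 4L)
  dx <- factor(DX_LEVELS[dx_level + 1L], levels = DX_LEVELS, ordered = TRUE)

  noise_fun <- if (config$heavy_tails) {
    function(n) rt(n, df = 3) / sqrt(3)
  } else {
    rnorm
  }

  # alternate directions so half the variables read "higher = worse"
  dir_sign <- function(i) if (i %% 2L == 1L) 1 else -1
  dir_label <- function(i) if (i %% 2L == 1L) "higher_worse" else "higher_better"

  # informative CMs track the latent severity: cluster centers spaced
  # effect_size apart plus the subject's within-cluster severity jitter
  # (shared across CMs, so each additional CM genuinely sharpens the
  # severity estimate), plus unit measurement noise
  jitter <- severity * k - (cluster - 1) - 0.5  # = U - 0.5, in (-0.5, 0.5)
  cm_info <- matrix(0, n, config$n_cm_info)
  if (config$n_cm_info > 0) {
    for (j in seq_len(config$n_cm_info)) {
      cm_info[, j] <- dir_sign(j) *
        (config$effect_size * (cluster - 1) + jitter) + noise_fun(n)
    }
  }
  cm_noise <- matrix(rnorm(n * config$n_cm_noise), n, config$n_cm_noise)

  signal_clusters <- list()
  pbm_signal <- matrix(0, n, config$n_pbm_signal)
  if (config$n_pbm_signal > 0) {
    for (j in seq_len(config$n_pbm_signal)) {
      n_aff <- sample(1:min(2L, k), 1)
      affected <- sort(sample.int(k, n_aff))
      signal_clusters[[j]] <- affected
      pbm_signal[, j] <- noise_fun(n) +
        dir_sign(j) * config$effect_size * (cluster %in% affected)
    }
  }
  pbm_null <- matrix(rnorm(n * config$n_pbm_null), n, config$n_pbm_null)

  pad <- function(prefix, m) sprintf("%s_%03d", prefix, seq_len(m))
  cm_info_names <- pad("CM_INFO", config$n_cm_info)
  cm_noise_names <- pad("CM_NOISE", config$n_cm_noise)
  pbm_sig_names <- pad("PBM_SIG", config$n_pbm_signal)
  pbm_null_names <- pad("PBM_NULL", config$n_pbm_null)

  blocks <- cbind(cm_info, cm_noise, pbm_signal, pbm_null)
  colnames(blocks) <- c(cm_info_names, cm_noise_names,
                        pbm_sig_names, pbm_null_names)

  data <- tibble(
    subject_id = sprintf("SUBJ_%04d", seq_len(n)),
    DX = dx
  )
  data <- dplyr::bind_cols(data, as_tibble(blocks))

  catalog <- bind_rows(
    tibble(variable = "DX", category = "DX", vartype = "ordinal",
           direction = "higher_worse", domain = NA_character_),
    tibble(variable = cm_info_names, category = "CM", vartype = "continuous",
           direction = map_chr(seq_along(cm_info_names), dir_label),
           domain = NA_character_),
    tibble(variable = cm_noise_names, category = "CM", vartype = "continuous",
           direction = map_chr(seq_along(cm_noise_names), dir_label),
           domain = NA_character_),
    tibble(variable = pbm_sig_names, category = "PBM", vartype = "continuous",
           direction = map_chr(seq_along(pbm_sig_names), dir_label),
           domain = NA_character_),
    tibble(variable = pbm_null_names, category = "PBM", vartype = "continuous",
           direction = map_chr(seq_along(pbm_null_names), dir_label),
           domain = NA_character_)
  )

  signal_pairs <- map(signal_clusters, function(aff) {
    pairs <- cluster_pairs(as.character(seq_len(k)))
    in_a <- as.integer(pairs$cluster_a) %in% aff
    in_b <- as.integer(pairs$cluster_b) %in% aff
    pairs[xor(in_a, in_b), , drop = FALSE]
  })
  names(signal_pairs) <- pbm_sig_names
  names(signal_clusters) <- pbm_sig_names

  truth <- list(
    cluster = cluster,
    informative_cms = cm_info_names,
    signal_pbms = pbm_sig_names,
    signal_clusters = signal_clusters,
    signal_pairs = signal_pairs
  )

  structure(
    list(data = data, catalog = catalog, truth = truth, config = config),
    class = "threec_cohort"
  )
}

#' @export
print.threec_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<threec_cohort> %d subjects, %d planted clusters\n", cfg$n_subjects,
    cfg$k_true
  ))
  cat(sprintf(
    "  CMs: %d informative + %d noise; pBMs: %d signal + %d null\n",
    cfg$n_cm_info, cfg$n_cm_noise, cfg$n_pbm_signal, cfg$n_pbm_null
  ))
  n_miss <- sum(is.na(x$data))
  cat(sprintf("  missing cells: %d\n", n_miss))
  invisible(x)
}

#' Inject diagnosis-informative missingness
#'
#' Masks measurement cells (CM and pBM columns) independently with
#' probability `missing_rate_base + missing_dx_gradient * s`, where `s` is
#' the subject's diagnosis severity level (0 for CN through 4 for AD). This
#' emulates cohorts in which missingness is informative of diagnosis:
#' severely affected subjects have more assessments recorded missing. The
#' `subject_id` and `DX` columns are never masked (the masking probability
#' conditions on DX).
#'
#' @param cohort A `threec_cohort` from [simulate_cohort()].
#' @param base,gradient Optional overrides for the config's
#'   `missing_rate_base` and `missing_dx_gradient`.
#' @param seed Seed for the masking draw; defaults to the cohort seed + 1.
#'
#' @return The cohort with `data` masked (`NA` cells) and a logical
#'   `missing_mask` tibble (subjects x measurement columns) recording which
#'   cells were masked, so the pre-masking values remain recoverable from
#'   the original cohort object.
#' @export
inject_missingness <- function(cohort, base = NULL, gradient = NULL,
                               seed = NULL) {
  stopifnot(inherits(cohort, "threec_cohort"))
  cfg <- cohort$config
  base <- assert_prob(base %||% cfg$missing_rate_base, "base")
  gradient <- assert_prob(gradient %||% cfg$missing_dx_gradient, "gradient")
  seed <- assert_count(seed %||% (cfg$seed + 1L), "seed")

  sev <- as.integer(cohort$data$DX) - 1L
  p <- base + gradient * sev
  if (any(p > 1)) {
    abort("Invalid config: masking probability exceeds 1 for some subjects.")
  }

  cols <- measurement_cols(cohort$data, cohort$catalog)
  n <- nrow(cohort$data)
  set.seed(seed)
  mask <- matrix(runif(n * length(cols)) < p, n, length(cols))
  colnames(mask) <- cols

  data <- cohort$data
  for (j in seq_along(cols)) {
    data[[cols[j]]][mask[, j]] <- NA_real_
  }
  cohort$data <- data
  cohort$missing_mask <- as_tibble(mask)
  cohort
}
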