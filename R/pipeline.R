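# End-to-end orchestration: simulate (or load) -> preprocess -> categorize
# -> cluster -> classify -> report, with every intermediate artifact,
# provenance (config + seeds + file checksums) and a human-readable log
# written to a run directory. Identical configs produce byte-identical
# artifacts.

#' Assemble a pipeline configuration
#'
#' A single structured configuration mirroring the stage options 1:1. All
#' defaults are echoed into the provenance record, so a run directory fully
#' documents its own settings.
#'
#' @param k Required number of clusters. Gap-statistic candidates
#'   ([choose_k_candidates()]) are advisory; the final k is a deliberate
#'   analyst choice.
#' @param cohort Either a `threec_cohort`, a [cohort_config()] (simulated at
#'   run time), or a list `list(data = <csv path>, catalog = <csv path>)`.
#' @param seed Master seed for stochastic stages.
#' @param preprocess List: `max_var_missing_frac`, `corr_threshold`,
#'   `gini_threshold`, `domain_map`, `transform` (logical).
#' @param screening List passed to [screen_cm_importance()]:
#'   `n_forests_threshold`, `n_forests_interpretation`, `num_trees`.
#' @param fdr List: `q`, `pool_pairs`.
#' @param report List: `level` (CI coverage).
#' @param gap List or `NULL`: `k_range`, `B` to also compute the (advisory,
#'   computationally heavier) gap curve.
#' @param exclude_cm CM variables excluded from clustering (e.g.
#'   demographics reported separately).
#' @return List of class `threec_run_config`.
#' @export
pipeline_config <- function(k,
                            cohort = cohort_config(),
                            seed = 1,
                            preprocess = list(),
                            screening = list(),
                            fdr = list(),
                            report = list(),
                            gap = NULL,
                            exclude_cm = NULL) {
  cfg <- list(
    k = assert_count(k, "k", min = 1),
    cohort = cohort,
    seed = assert_count(seed, "seed"),
    preprocess = utils::modifyList(
      list(max_var_missing_frac = 0.3, corr_threshold = 0.99,
           gini_threshold = 0.05, domain_map = list(), transform = TRUE),
      preprocess
    ),
    screening = utils::modifyList(
      list(n_forests_threshold = 50, n_forests_interpretation = 25,
           num_trees = 100),
      screening
    ),
    fdr = utils::modifyList(list(q = 0.05, pool_pairs = FALSE), fdr),
    report = utils::modifyList(list(level = 0.95), report),
    gap = gap,
    exclude_cm = exclude_cm
  )
  structure(cfg, class = "threec_run_config")
}

#' @noRd
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$k)) abort("Pipeline config: required field `k` is missing.")
  cohort <- raw$cohort
  if (!is.null(cohort$data) || !is.null(cohort$catalog)) {
    for (field in c("data", "catalog")) {
      if (is.null(cohort[[field]])) {
        abort(sprintf("Pipeline config: `cohort$%s` path is missing.", field))
      }
      if (!file.exists(cohort[[field]])) {
        abort(sprintf("Pipeline config: `cohort$%s` file not found: %s",
                      field, cohort[[field]]))
      }
    }
  } else {
    cohort <- do.call(cohort_config, cohort %||% list())
  }
  pipeline_config(
    k = raw$k, cohort = cohort, seed = raw$seed %||% 1,
    preprocess = raw$preprocess %||% list(),
    screening = raw$screening %||% list(),
    fdr = raw$fdr %||% list(),
    report = raw$report %||% list(),
    gap = raw$gap,
    exclude_cm = raw$exclude_cm
  )
}

#' Run the full 3C pipeline
#'
#' Executes simulate/load -> preprocess -> categorize -> cluster ->
#' classify -> report, writing every intermediate artifact, a provenance
#' record (`provenance.json`: config, seeds, stage checksums) and a log to
#' `out_dir`. Rerunning an identical config yields byte-identical
#' artifacts.
#'
#' @param config A [pipeline_config()], or the path of a YAML file with the
#'   same structure.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages. Default `FALSE`.
#'
#' @return (Invisibly) a list with the fitted objects: `cohort`, `clean`,
#'   `catalog`, `categorized`, `screen`, `model`, `gap`, `signatures`,
#'   `profile`, `heatmap`, `summary`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("threec_run_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "threec_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- "setup"
  on.exit(writeLines(log_lines, log_path), add = TRUE)

  result <- tryCatch({
    # -- inputs ----------------------------------------------------------
    stage <- "input"
    ch <- config$cohort
    if (inherits(ch, "threec_cohort")) {
      cohort_data <- ch$data
      catalog <- ch$catalog
      say("input: using supplied cohort (%d subjects)", nrow(cohort_data))
    } else if (inherits(ch, "threec_config")) {
      sim <- simulate_cohort(ch)
      if (ch$missing_rate_base > 0 || ch$missing_dx_gradient > 0) {
        sim <- inject_missingness(sim)
      }
      cohort_data <- sim$data
      catalog <- sim$catalog
      say("input: simulated cohort, %d subjects, seed %d",
          nrow(cohort_data), ch$seed)
    } else {
      cohort_data <- as_tibble(read.csv(ch$data, stringsAsFactors = FALSE))
      catalog <- as_tibble(read.csv(ch$catalog, stringsAsFactors = FALSE))
      say("input: read cohort %s (%d subjects)", ch$data, nrow(cohort_data))
    }
    write.csv(cohort_data, file.path(out_dir, "cohort.csv"), row.names = FALSE)

    # -- preprocess ------------------------------------------------------
    stage <- "preprocess"
    pp <- config$preprocess
    clean <- filter_complete_cases(cohort_data, pp$max_var_missing_frac)
    cc_report <- preprocess_report(clean)
    say("preprocess: complete cases kept %d/%d subjects, dropped %d variables",
        nrow(clean), nrow(cohort_data), nrow(cc_report$variables_dropped))
    clean <- remove_redundant(clean, catalog, pp$corr_threshold,
                              pp$gini_threshold)
    say("preprocess: removed %d redundant variables",
        nrow(preprocess_report(clean)))
    if (length(pp$domain_map) > 0) {
      clean <- add_domain_scores(clean, catalog, pp$domain_map)
      catalog <- cohort_catalog(clean)
      say("preprocess: added %d domain composites", length(pp$domain_map))
    }
    if (isTRUE(pp$transform)) {
      clean <- transform_cohort(clean, catalog)
      tr <- preprocess_report(clean)
      say("preprocess: monotone transforms (%d non-identity)",
          sum(tr$transform != "identity"))
    }
    write.csv(clean, file.path(out_dir, "clean.csv"), row.names = FALSE)
    write.csv(catalog, file.path(out_dir, "catalog.csv"), row.names = FALSE)

    # -- categorize ------------------------------------------------------
    stage <- "categorize"
    cat3 <- categorize(clean, catalog, exclude = config$exclude_cm)
    say("categorize: %d CM, %d pBM, DX levels: %s", ncol(cat3$cm),
        ncol(cat3$pbm), paste(levels(cat3$dx), collapse = "/"))

    # -- cluster ---------------------------------------------------------
    stage <- "cluster"
    sc <- config$screening
    screen <- screen_cm_importance(
      cat3$cm, cat3$dx,
      n_forests_threshold = sc$n_forests_threshold,
      n_forests_interpretation = sc$n_forests_interpretation,
      num_trees = sc$num_trees, seed = config$seed
    )
    say("cluster: screening selected %d/%d CMs: %s",
        length(screen$selected), ncol(cat3$cm),
        paste(screen$selected, collapse = ", "))
    write.csv(tidy(screen), file.path(out_dir, "screening.csv"),
              row.names = FALSE)

    gap <- NULL
    if (!is.null(config$gap)) {
      gcfg <- config$gap
      gap <- gap_statistic(cat3$cm[, screen$selected, drop = FALSE],
                           k_range = gcfg$k_range %||% 1:8,
                           B = gcfg$B %||% 50, seed = config$seed)
      cand <- choose_k_candidates(gap)
      say("cluster: gap-statistic candidate k: %s",
          paste(cand, collapse = ", "))
      write.csv(tidy(gap), file.path(out_dir, "gap.csv"), row.names = FALSE)
    }

    model <- kmedoids_manhattan(cat3$cm[, screen$selected, drop = FALSE],
                                k = config$k, seed = config$seed)
    model$subject_id <- cat3$subject_id
    say("cluster: k = %d, Manhattan cost %.4g, sizes %s", model$k,
        model$cost, paste(tabulate(model$assignment, model$k), collapse = "/"))
    model_json <- list(
      k = model$k, variables = model$variables,
      medoid_subjects = model$subject_id[model$medoid_idx],
      medoids = as.data.frame(model$medoids),
      assignment = tibble(subject_id = model$subject_id,
                          cluster = model$assignment),
      cost = model$cost, seed = model$seed
    )
    jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    # -- classify --------------------------------------------------------
    stage <- "classify"
    sig <- build_signature_table(cat3$pbm, model$assignment,
                                 q = config$fdr$q,
                                 pool_pairs = config$fdr$pool_pairs)
    say("classify: %d/%d pBMs selected; pairwise level %.4g; %d signed calls",
        sig$S, sig$M, sig$adjusted_level, sum(sig$pairs$sign != 0))
    write.csv(tidy(sig), file.path(out_dir, "signatures.csv"),
              row.names = FALSE)

    # -- report ----------------------------------------------------------
    stage <- "report"
    labels <- factor(model$assignment)
    prof <- quantile_profile(clean, catalog, labels,
                             level = config$report$level)
    write.csv(tidy(prof), file.path(out_dir, "profiles.csv"),
              row.names = FALSE)
    heat <- build_heatmap_matrix(sig)
    write.csv(tidy(heat), file.path(out_dir, "heatmap.csv"),
              row.names = FALSE)
    summary_tbl <- characterize_clusters(clean, labels)
    write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    say("report: wrote profiles.csv, heatmap.csv, summary.csv")

    # -- provenance ------------------------------------------------------
    stage <- "provenance"
    artifacts <- list.files(out_dir, pattern = "\\.(csv|json)$")
    checksums <- as.list(tools::md5sum(file.path(out_dir, artifacts)))
    names(checksums) <- artifacts
    provenance <- list(
      package_version = as.character(utils::packageVersion("threec")),
      config = unclass_deep(config),
      seeds = list(master = config$seed),
      checksums = checksums
    )
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(cohort = cohort_data, clean = clean, catalog = catalog,
         categorized = cat3, screen = screen, model = model, gap = gap,
         signatures = sig, profile = prof, heatmap = heat,
         summary = summary_tbl, out_dir = out_dir)
  }, error = function(e) {
    say("ERROR in stage '%s': %s", stage, conditionMessage(e))
    abort(sprintf("Pipeline failed in stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })

  invisible(result)
}

# strip classes so a config serializes cleanly to JSON
#' @noRd
unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}
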