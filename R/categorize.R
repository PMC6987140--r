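# Step 1 of 3C: knowledge-driven partition of variables into assigned
# diagnosis (DX), clinical measurements (CM) and potential biomarkers (pBM).
# Categorization is catalog-driven by design; there is no automatic
# inference of categories.

CATALOG_CATEGORIES <- c("DX", "CM", "PBM")
CATALOG_VARTYPES <- c("continuous", "ordinal", "categorical")
CATALOG_DIRECTIONS <- c("higher_worse", "higher_better", "none")

#' Validate a variable catalog against a cohort table
#'
#' Checks that the catalog covers exactly the non-id columns of the data,
#' that categories/vartypes/directions come from the allowed sets, that
#' every variable appears exactly once (categories partition the variable
#' set), that exactly one DX variable exists, and that every CM variable
#' has a direction. Violations are reported together, with the offending
#' catalog rows named.
#'
#' @param catalog Catalog tibble with columns `variable`, `category`,
#'   `vartype`, `direction` (and optionally `domain`).
#' @param data Cohort tibble the catalog should describe.
#' @param id_col Subject id column, exempt from catalog coverage.
#' @return Invisibly `TRUE`; aborts with an itemized message otherwise.
#' @export
validate_catalog <- function(catalog, data, id_col = "subject_id") {
  problems <- character()
  req <- c("variable", "category", "vartype", "direction")
  missing_cols <- setdiff(req, names(catalog))
  if (length(missing_cols) > 0) {
    abort(sprintf("Catalog lacks required columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }

  dup <- catalog$variable[duplicated(catalog$variable)]
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "variables with multiple catalog entries (categories must partition the variable set): %s",
      paste(unique(dup), collapse = ", ")))
  }

  bad_rows <- which(!(catalog$category %in% CATALOG_CATEGORIES))
  if (length(bad_rows) > 0) {
    problems <- c(problems, sprintf(
      "rows %s: unknown category (allowed: %s)",
      paste(bad_rows, collapse = ", "),
      paste(CATALOG_CATEGORIES, collapse = "/")))
  }
  bad_rows <- which(!(catalog$vartype %in% CATALOG_VARTYPES))
  if (length(bad_rows) > 0) {
    problems <- c(problems, sprintf(
      "rows %s: unknown vartype", paste(bad_rows, collapse = ", ")))
  }
  bad_rows <- which(!(catalog$direction %in% CATALOG_DIRECTIONS))
  if (length(bad_rows) > 0) {
    problems <- c(problems, sprintf(
      "rows %s: unknown direction", paste(bad_rows, collapse = ", ")))
  }

  vars <- setdiff(names(data), id_col)
  uncataloged <- setdiff(vars, catalog$variable)
  if (length(uncataloged) > 0) {
    problems <- c(problems, sprintf(
      "data columns missing from catalog: %s",
      paste(uncataloged, collapse = ", ")))
  }

  n_dx <- sum(catalog$category == "DX" & catalog$variable %in% vars)
  if (n_dx != 1) {
    problems <- c(problems, sprintf(
      "exactly one DX variable required, found %d", n_dx))
  }

  no_dir <- catalog$variable[catalog$category == "CM" &
                               catalog$direction == "none"]
  no_dir <- intersect(no_dir, vars)
  if (length(no_dir) > 0) {
    problems <- c(problems, sprintf(
      "CM variables lacking a severity direction: %s",
      paste(no_dir, collapse = ", ")))
  }

  if (length(problems) > 0) {
    abort(paste0("Invalid variable catalog:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  invisible(TRUE)
}

#' Categorize cohort variables into DX, CM and pBM views
#'
#' Splits the cohort into the diagnosis label vector, the CM block and the
#' pBM block, all sharing subject order. This is the first step of the 3C
#' strategy; the partition is taken from the expert-curated catalog.
#'
#' @param data Cohort tibble.
#' @param catalog Variable catalog (validated with [validate_catalog()]).
#' @param exclude Optional character vector of CM variables to leave out of
#'   the CM block (e.g. demographics reported separately rather than
#'   clustered).
#' @param id_col Subject id column.
#'
#' @return A list of class `threec_categorized`: `dx` (factor with >= 2
#'   observed levels), `cm` (tibble), `pbm` (tibble), `subject_id`,
#'   `excluded` (tibble of excluded CM columns).
#' @export
categorize <- function(data, catalog, exclude = NULL, id_col = "subject_id") {
  data <- as_tibble(data)
  validate_catalog(catalog, data, id_col = id_col)
  vars <- setdiff(names(data), id_col)
  info <- catalog[match(vars, catalog$variable), ]

  dx_var <- info$variable[info$category == "DX"]
  dx <- data[[dx_var]]
  if (!is.factor(dx)) dx <- factor(dx)
  dx <- droplevels(dx)
  if (nlevels(dx) < 2) {
    abort(sprintf("DX variable '%s' has fewer than 2 observed levels.", dx_var))
  }

  cm_vars <- info$variable[info$category == "CM"]
  pbm_vars <- info$variable[info$category == "PBM"]
  excluded <- intersect(exclude %||% character(), cm_vars)

  structure(
    list(
      dx = dx,
      cm = data[, setdiff(cm_vars, excluded), drop = FALSE],
      pbm = data[, pbm_vars, drop = FALSE],
      subject_id = if (id_col %in% names(data)) data[[id_col]] else seq_len(nrow(data)),
      excluded = data[, excluded, drop = FALSE]
    ),
    class = "threec_categorized"
  )
}

#' @export
print.threec_categorized <- function(x, ...) {
  cat(sprintf(
    "<threec_categorized> %d subjects | DX levels: %s | %d CM, %d pBM\n",
    length(x$dx), paste(levels(x$dx), collapse = " < "),
    ncol(x$cm), ncol(x$pbm)
  ))
  invisible(x)
}
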