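test_that("complete-case filtering applies the variables-then-subjects rule", {
  # no missing cells: identity, empty report
  x <- tibble::tibble(subject_id = c("a", "b"), v1 = 1:2, v2 = 3:4)
  y <- filter_complete_cases(x)
  expect_equal(as.data.frame(y), as.data.frame(x), ignore_attr = TRUE)
  expect_equal(nrow(preprocess_report(y)$variables_dropped), 0)
  expect_length(preprocess_report(y)$subjects_dropped, 0)

  # fully-missing column dropped, all subjects kept
  x$v3 <- NA_real_
  y <- filter_complete_cases(x, max_var_missing_frac = 0.3)
  expect_named(y, c("subject_id", "v1", "v2"))
  expect_equal(nrow(y), 2)

  # hand-trace: A missing frac 0.5 > 0.3 dropped first, then subject 3
  x <- tibble::tibble(
    subject_id = as.character(1:4),
    A = c(NA, NA, 1, 2),
    B = c(1, 2, NA, 4),
    C = c(5, 6, 7, 8)
  )
  y <- filter_complete_cases(x, max_var_missing_frac = 0.3)
  expect_named(y, c("subject_id", "B", "C"))
  expect_equal(y$subject_id, c("1", "2", "4"))
  rep <- preprocess_report(y)
  expect_equal(rep$variables_dropped$variable, "A")
  expect_equal(rep$subjects_dropped, "3")

  # everything dropped is an error
  all_na <- tibble::tibble(subject_id = "a", v = NA_real_)
  expect_error(filter_complete_cases(all_na, max_var_missing_frac = 2/3),
               "removed everything")
})

test_that("complete-case output never contains missing cells", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    p <- sample(3:8, 1)
    m <- matrix(rnorm(n * p), n, p)
    m[sample(length(m), round(0.15 * length(m)))] <- NA
    df <- tibble::as_tibble(as.data.frame(m))
    df$subject_id <- as.character(seq_len(n))
    out <- tryCatch(filter_complete_cases(df, max_var_missing_frac = 0.3),
                    error = function(e) NULL)
    if (!is.null(out)) expect_false(anyNA(out))
  }
})

test_that("redundancy removal drops duplicates, low-Gini and constants", {
  set.seed(1)
  n <- 1000
  data <- tibble::tibble(
    subject_id = as.character(1:n),
    DX = factor(sample(c("CN", "AD"), n, TRUE)),
    x1 = rnorm(n),
    x2 = rnorm(n),
    x3 = NA_real_,
    const = 1,
    rare = c(rep("a", 990), rep("b", 10))  # Gini 1 - .99^2 - .01^2 = .0198
  )
  data$x3 <- data$x1  # exact duplicate, later in catalog order
  catalog <- tibble::tibble(
    variable = c("DX", "x1", "x2", "x3", "const", "rare"),
    category = c("DX", "CM", "CM", "CM", "CM", "CM"),
    vartype = c("categorical", "continuous", "continuous", "continuous",
                "continuous", "categorical"),
    direction = c("higher_worse", rep("higher_worse", 5)),
    domain = NA_character_
  )
  out <- remove_redundant(data, catalog)
  expect_named(out, c("subject_id", "DX", "x1", "x2"))
  rep <- preprocess_report(out)
  expect_equal(rep$reason[rep$variable == "x3"], "correlated_with:x1")
  expect_equal(rep$reason[rep$variable == "const"], "constant")
  expect_equal(rep$reason[rep$variable == "rare"], "low_gini")

  # two independent standard normals at n=1000 stay (|r| << 0.99)
  expect_true(all(c("x1", "x2") %in% names(out)))

  # idempotent
  again <- remove_redundant(out, catalog)
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
  expect_equal(nrow(preprocess_report(again)), 0)
})

test_that("a borderline Gini value is kept above threshold", {
  # proportions (0.9, 0.1): Gini = 1 - 0.81 - 0.01 = 0.18 >= 0.05
  data <- tibble::tibble(
    subject_id = as.character(1:100),
    DX = factor(rep(c("CN", "AD"), 50)),
    g = c(rep("a", 90), rep("b", 10))
  )
  catalog <- tibble::tibble(
    variable = c("DX", "g"), category = c("DX", "CM"),
    vartype = c("categorical", "categorical"),
    direction = c("higher_worse", "higher_worse"), domain = NA_character_
  )
  out <- remove_redundant(data, catalog)
  expect_true("g" %in% names(out))
})

test_that("domain composites sum items and inherit a common direction", {
  tiny <- make_tiny_cohort()
  out <- add_domain_scores(tiny$data, tiny$catalog,
                           list(memory = c("cm1", "cm3")))
  expect_equal(out$memory, tiny$data$cm1 + tiny$data$cm3)
  cat2 <- cohort_catalog(out)
  row <- cat2[cat2$variable == "memory", ]
  expect_equal(row$category, "CM")
  expect_equal(row$direction, "higher_worse")

  # empty map: unchanged
  same <- add_domain_scores(tiny$data, tiny$catalog, list())
  expect_equal(as.data.frame(same), as.data.frame(tiny$data), ignore_attr = TRUE)

  # mixed directions error (cm1 higher_worse, cm2 higher_better)
  expect_error(
    add_domain_scores(tiny$data, tiny$catalog, list(bad = c("cm1", "cm2"))),
    "mixed"
  )
})

test_that("ordinal item composites behave sanely", {
  set.seed(9)
  n <- 500
  items <- tibble::as_tibble(as.data.frame(
    matrix(sample(0:2, 3 * n, TRUE), n, 3,
           dimnames = list(NULL, c("i1", "i2", "i3")))
  ))
  items$subject_id <- as.character(1:n)
  items$DX <- factor(rep(c("CN", "AD"), length.out = n))
  catalog <- tibble::tibble(
    variable = c("DX", "i1", "i2", "i3"),
    category = c("DX", "CM", "CM", "CM"),
    vartype = c("categorical", rep("ordinal", 3)),
    direction = c("higher_worse", rep("higher_worse", 3)),
    domain = NA_character_
  )
  out <- add_domain_scores(items, catalog, list(total = c("i1", "i2", "i3")))
  expect_true(all(out$total >= 0 & out$total <= 6))
  for (v in c("i1", "i2", "i3")) expect_gt(cor(out$total, out[[v]]), 0)
})

test_that("monotone transforms reduce skew and never change ranks", {
  # already symmetric: identity chosen
  x <- rep(c(-1, 0, 1), 20)
  y <- monotone_transform(x)
  expect_equal(attr(y, "transform"), "identity")

  # log-normal: log transform chosen, skewness reduced
  set.seed(4)
  z <- exp(rnorm(500))
  w <- monotone_transform(z)
  expect_equal(attr(w, "transform"), "log")
  expect_lt(abs(attr(w, "skewness_after")), abs(attr(w, "skewness_before")))

  # rank preservation, including with ties
  set.seed(5)
  for (i in 1:20) {
    v <- sample(c(rnorm(30), round(rnorm(10), 1)))
    out <- monotone_transform(v)
    expect_equal(order(as.numeric(out)), order(v))
    expect_equal(rank(as.numeric(out)), rank(v))
  }

  # constant vector: degenerate identity
  const <- monotone_transform(rep(2, 10))
  expect_true(attr(const, "degenerate"))
  expect_equal(as.numeric(const), rep(2, 10))

  expect_error(monotone_transform(c(1, NA, 3)), "complete")
  expect_error(monotone_transform(c(1, 2)), "length")
})

test_that("transform_cohort reports per-variable choices", {
  tiny <- make_tiny_cohort()
  tiny$data$cm1 <- exp(tiny$data$cm1)
  out <- transform_cohort(tiny$data, tiny$catalog)
  rep <- preprocess_report(out)
  expect_setequal(rep$variable, c("cm1", "cm2", "cm3", "bm1", "bm2"))
  expect_equal(rep$transform[rep$variable == "cm1"], "log")
  expect_false(anyNA(out))
})
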