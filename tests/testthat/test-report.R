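test_that("empirical quantile transform maps to [0,1] with orientation", {
  expect_equal(empirical_quantile_transform(c(1, 3, 5), "higher_worse"),
               c(0, 0.5, 1))
  expect_equal(empirical_quantile_transform(c(1, 3, 5), "higher_better"),
               c(1, 0.5, 0))
  # midranks with ties: (1.5, 1.5, 3) -> (0.25, 0.25, 1)
  expect_equal(empirical_quantile_transform(c(2, 2, 7), "higher_worse"),
               c(0.25, 0.25, 1))

  expect_warning(q <- empirical_quantile_transform(rep(4, 5), "higher_worse"),
                 "Constant")
  expect_equal(q, rep(0.5, 5))

  # bounds and pooled-mean invariants over random inputs
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1))
    q <- empirical_quantile_transform(x, "higher_worse")
    expect_true(all(q >= 0 & q <= 1))
    expect_equal(mean(q), 0.5)  # exact for tie-free data
    expect_equal(order(q), order(x))
  }
})

test_that("binomial median CI endpoints come from the order statistics", {
  # all equal: zero-width interval
  out <- median_with_binomial_ci(rep(3, 9))
  expect_equal(c(out$lower, out$median, out$upper), c(3, 3, 3))

  # n = 1: degenerate
  out <- median_with_binomial_ci(5)
  expect_true(out$degenerate)
  expect_equal(out$median, 5)

  # n = 25: endpoints match an exhaustive CDF search
  set.seed(15)
  x <- sort(rnorm(25))
  out <- median_with_binomial_ci(x, level = 0.95)
  cdf <- pbinom(0:24, 25, 0.5)
  l_ref <- max(which(cdf <= 0.025))
  u_ref <- min(which(cdf >= 0.975))
  expect_equal(out$lower, x[l_ref])
  expect_equal(out$upper, x[u_ref])

  # median inside the interval; endpoints are observed values
  for (i in 1:20) {
    v <- rnorm(sample(3:60, 1))
    ci <- median_with_binomial_ci(v)
    expect_lte(ci$lower, ci$median)
    expect_gte(ci$upper, ci$median)
    expect_true(ci$lower %in% v && ci$upper %in% v)
  }
  expect_error(median_with_binomial_ci(numeric(0)), "nonempty")
})

test_that("similarity ordering puts like profiles next to each other", {
  # identical columns are adjacent
  m <- cbind(a = c(0.1, 0.5, 0.9), b = c(0.9, 0.5, 0.1),
             a2 = c(0.1, 0.5, 0.9))
  ord <- order_variables_by_similarity(m)
  expect_equal(abs(which(ord == "a") - which(ord == "a2")), 1)

  # two well-separated profile groups form contiguous blocks
  set.seed(16)
  up <- sapply(1:4, function(i) seq(0, 1, length.out = 5) + rnorm(5, 0, 0.02))
  down <- sapply(1:4, function(i) seq(1, 0, length.out = 5) + rnorm(5, 0, 0.02))
  mm <- cbind(up, down)
  colnames(mm) <- c(paste0("up", 1:4), paste0("dn", 1:4))
  ord <- order_variables_by_similarity(mm)
  pos_up <- sort(match(paste0("up", 1:4), ord))
  expect_equal(pos_up, seq(pos_up[1], pos_up[1] + 3))

  # permutation invariance (up to reflection) with canonical leaf order
  perm <- sample(ncol(mm))
  ord2 <- order_variables_by_similarity(mm[, perm])
  expect_true(identical(ord, ord2) || identical(ord, rev(ord2)))
})

test_that("quantile profiles pool subjects and respect directions", {
  tiny <- make_tiny_cohort(n = 60, seed = 20)
  labels <- rep(1:3, each = 20)
  expect_warning(
    prof <- quantile_profile(tiny$data, tiny$catalog, labels),
    regexp = NA
  )
  df <- tidy(prof)
  expect_setequal(levels(df$variable), c("cm1", "cm2", "cm3", "bm1", "bm2"))
  expect_equal(nrow(df), 5 * 3)
  expect_true(all(df$lower <= df$median & df$median <= df$upper))
  expect_true(all(df$lower >= 0 & df$upper <= 1))

  # a variable with direction "none" is excluded with a warning
  cat2 <- tiny$catalog
  cat2$direction[cat2$variable == "bm2"] <- "none"
  expect_warning(p2 <- quantile_profile(tiny$data, cat2, labels), "bm2")
  expect_false("bm2" %in% tidy(p2)$variable)

  expect_s3_class(autoplot(prof), "ggplot")
})

test_that("the signature heatmap matrix has k(k-1)/2 three-state columns", {
  set.seed(22)
  n <- 240
  labels <- rep(1:6, each = 40)
  pbm <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 8), n, 8)))
  names(pbm) <- sprintf("bm%d", 1:8)
  pbm$bm1 <- rnorm(n) + 4 * (labels == 1)
  pbm$bm2 <- rnorm(n) + 4 * (labels == 1)   # same pattern as bm1
  pbm$bm3 <- rnorm(n) - 4 * (labels == 6)
  pbm$bm4 <- rnorm(n) - 4 * (labels == 6)   # same pattern as bm3

  sig <- build_signature_table(pbm, labels, q = 0.05)
  hm <- build_heatmap_matrix(sig)
  expect_equal(ncol(hm$matrix), 15)
  expect_true(all(hm$matrix %in% c(-1, 0, 1)))

  # rows with identical planted patterns cluster together at the top split
  expect_setequal(rownames(hm$matrix), c("bm1", "bm2", "bm3", "bm4"))
  pos <- match(c("bm1", "bm2"), hm$row_order)
  expect_equal(abs(diff(pos)), 1)
  pos2 <- match(c("bm3", "bm4"), hm$row_order)
  expect_equal(abs(diff(pos2)), 1)

  expect_s3_class(autoplot(hm), "ggplot")

  # no rejections: empty but valid
  null_sig <- build_signature_table(
    tibble::tibble(z = rnorm(n)), labels, q = 0.05
  )
  empty <- build_heatmap_matrix(null_sig)
  expect_equal(nrow(empty$matrix), 0)
  expect_equal(ncol(empty$matrix), 15)
})

test_that("heatmap columns for k clusters always number k(k-1)/2", {
  for (k in 2:7) {
    set.seed(k)
    labels <- rep(seq_len(k), each = 30)
    pbm <- tibble::tibble(bm = rnorm(30 * k) + 3 * (labels == 1))
    hm <- build_heatmap_matrix(build_signature_table(pbm, labels))
    expect_equal(ncol(hm$matrix), k * (k - 1) / 2)
  }
})

test_that("cluster characterization summarizes and tests variables", {
  set.seed(24)
  n <- 400
  labels <- rep(1:2, each = n / 2)
  data <- tibble::tibble(
    subject_id = as.character(1:n),
    age = rnorm(n, 70, 5) + 5 * (labels == 2),   # planted 5-year shift
    sex = sample(c("F", "M"), n, TRUE)
  )
  out <- characterize_clusters(data, labels)
  age_rows <- out[out$variable == "age", ]
  expect_equal(unique(age_rows$test), "kruskal_wallis")
  expect_lt(unique(age_rows$p_value), 0.001)
  expect_equal(age_rows$n, c(200, 200))
  sex_rows <- out[out$variable == "sex", ]
  expect_equal(unique(sex_rows$test), "chi_square")
  expect_true(all(c("F", "M") %in% sex_rows$level))

  # identical distributions: H = 0, p = 1
  same <- tibble::tibble(v = rep(c(1, 2, 3, 4), 2))
  out2 <- characterize_clusters(same, rep(1:2, each = 4))
  expect_equal(unique(out2$p_value), 1)

  # single cluster: no tests emitted
  out3 <- characterize_clusters(data, rep(1, n))
  expect_true(all(is.na(out3$p_value)))
})
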