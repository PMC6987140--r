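test_that("Kruskal-Wallis matches the rank formula and its symmetries", {
  # groups {1,2},{3,4},{5,6}: H = 12/42 * (9/2 + 49/2 + 121/2) - 21
  out <- kruskal_wallis(1:6, rep(1:3, each = 2))
  expect_equal(out$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(out$statistic, 4.571429, tolerance = 1e-6)
  expect_equal(out$df, 2)

  # label-permutation symmetry within groups
  set.seed(2)
  x <- rnorm(30)
  g <- rep(1:2, each = 15)
  a <- kruskal_wallis(x, g)
  b <- kruskal_wallis(x, 3 - g)
  expect_equal(a$statistic, b$statistic)

  # constant variable: H = 0, p = 1
  flat <- kruskal_wallis(rep(7, 10), rep(1:2, 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(kruskal_wallis(1:5, rep(1, 5)), "2 groups")
})

test_that("Wilcoxon rank-sum agrees with full enumeration", {
  # x = {1,2}, y = {3,4}: most extreme arrangement, p = 2/6
  out <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(out$exact)
  expect_equal(out$p_value, 1 / 3, tolerance = 1e-12)

  # identical samples: no separation
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # enumeration oracle across small sample sizes (tie-free)
  set.seed(8)
  for (m in 2:5) {
    for (n in 2:5) {
      x <- rnorm(m)
      y <- rnorm(n)
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   enumerate_wilcoxon_p(x, y), tolerance = 1e-12)
    }
  }

  # ties or large samples switch to the corrected normal approximation
  expect_false(wilcoxon_rank_sum(c(1, 1, 2), c(2, 3, 4))$exact)
  expect_false(wilcoxon_rank_sum(rnorm(15), rnorm(15))$exact)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("Benjamini-Hochberg implements the step-up rule", {
  out <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.2), 0.05)
  expect_equal(out$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  expect_false(any(benjamini_hochberg(rep(1, 10), 0.05)$rejected))
  expect_true(benjamini_hochberg(0, 0.01)$rejected)
  expect_error(benjamini_hochberg(c(0.5, 1.2), 0.05), "0, 1")

  # random p-vectors against the literal step-up definition
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    lvl <- runif(1, 0.01, 0.2)
    expect_equal(benjamini_hochberg(p, lvl)$rejected,
                 bh_reject_reference(p, lvl))
  }

  # monotonicity: a smaller level never rejects more
  set.seed(13)
  for (i in 1:20) {
    p <- runif(25)^2
    r1 <- sum(benjamini_hochberg(p, 0.02)$rejected)
    r2 <- sum(benjamini_hochberg(p, 0.10)$rejected)
    expect_lte(r1, r2)
  }
})

test_that("the selection-adjusted testing level is q * S / M", {
  expect_equal(bb_adjusted_level(0.05, 51, 170), 0.015, tolerance = 1e-15)
  expect_equal(bb_adjusted_level(0.05, 170, 170), 0.05)
  expect_equal(bb_adjusted_level(0.05, 0, 170), 0)
  expect_error(bb_adjusted_level(0.05, 171, 170), "exceed")
})

test_that("a planted pBM shift is detected with correctly signed pairs", {
  set.seed(3)
  n <- 300
  labels <- rep(1:3, each = 100)
  pbm <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 10), n, 10)))
  names(pbm) <- sprintf("bm%02d", 1:10)
  pbm$bm01 <- rnorm(n) + 5 * (labels == 1)  # 5 SD shift in cluster 1

  sig <- build_signature_table(pbm, labels, q = 0.05)
  scr <- sig$screening
  expect_true(scr$selected[scr$pbm == "bm01"])

  pr <- sig$pairs[sig$pairs$pbm == "bm01", ]
  expect_equal(nrow(pr), 3)  # k=3 -> 3 pairs
  expect_equal(pr$sign[pr$cluster_a == "1" & pr$cluster_b == "2"], 1)
  expect_equal(pr$sign[pr$cluster_a == "1" & pr$cluster_b == "3"], 1)
  expect_equal(pr$sign[pr$cluster_a == "2" & pr$cluster_b == "3"], 0)

  # signature membership: the shifted pBM marks cluster 1 as elevated
  s1 <- signature_for_cluster(sig, 1)
  expect_true(all(s1$direction[s1$pbm == "bm01"] == 1))
  s2 <- signature_for_cluster(sig, 2)
  expect_true(all(s2$direction[s2$pbm == "bm01"] == -1))
  expect_error(signature_for_cluster(sig, "nope"), "Unknown cluster")
})

test_that("six clusters yield exactly 15 pair rows per selected pBM", {
  set.seed(6)
  n <- 240
  labels <- rep(1:6, each = 40)
  pbm <- tibble::tibble(strong = rnorm(n) + 4 * (labels %in% c(1, 2)),
                        null1 = rnorm(n))
  sig <- build_signature_table(pbm, labels, q = 0.05)
  expect_equal(sum(sig$pairs$pbm == "strong"), 15)
  expect_equal(sig$k * (sig$k - 1) / 2, 15)
})

test_that("tiny clusters are flagged untestable rather than tested", {
  set.seed(7)
  labels <- c(rep(1, 20), rep(2, 20), 3)  # cluster 3 has one subject
  pbm <- tibble::tibble(bm = c(rnorm(20), rnorm(20) + 5, 0))
  sig <- build_signature_table(pbm, labels, q = 0.05)
  pr <- sig$pairs
  with3 <- pr$cluster_a == "3" | pr$cluster_b == "3"
  expect_true(all(!pr$testable[with3]))
  expect_true(all(pr$sign[with3] == 0))
  expect_true(all(is.na(pr$p_value[with3])))
  expect_true(all(pr$testable[!with3]))
})

test_that("signature decisions depend on ranks only", {
  set.seed(9)
  n <- 150
  labels <- rep(1:3, each = 50)
  pbm <- tibble::tibble(a = rnorm(n) + 2 * (labels == 2), b = rnorm(n))
  sig1 <- build_signature_table(pbm, labels, q = 0.05)
  pbm2 <- dplyr::mutate(pbm, a = exp(a), b = b^3)  # strictly monotone maps
  sig2 <- build_signature_table(pbm2, labels, q = 0.05)
  expect_equal(sig1$screening$p_value, sig2$screening$p_value,
               tolerance = 1e-12)
  expect_equal(sig1$pairs$sign, sig2$pairs$sign)
})

test_that("screening FDR stays at the budget under a mixed configuration", {
  # scaled-down Monte-Carlo of the screening stage (the acceptance suite
  # runs the full design): 60 replicates, 5 signal + 40 null pBMs
  set.seed(99)
  fdp <- numeric(60)
  for (r in seq_len(60)) {
    labels <- rep(1:3, each = 40)
    n <- length(labels)
    pbm <- matrix(rnorm(n * 45), n, 45)
    for (j in 1:5) pbm[, j] <- pbm[, j] + 2.5 * (labels == (j %% 3 + 1))
    colnames(pbm) <- sprintf("bm%02d", 1:45)
    sig <- build_signature_table(tibble::as_tibble(as.data.frame(pbm)),
                                 labels, q = 0.05)
    sel <- sig$screening$pbm[sig$screening$selected]
    false_sel <- sum(!(sel %in% sprintf("bm%02d", 1:5)))
    fdp[r] <- if (length(sel) == 0) 0 else false_sel / length(sel)
  }
  mc_se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * mc_se)
})
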