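# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive enumeration for k-medoids and the
# Wilcoxon null, the literal step-up definition for BH, and mclust's
# adjusted Rand index for partition agreement.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# exhaustive k-medoids: minimum Manhattan cost over all medoid subsets
exhaustive_medoid_cost <- function(x, k) {
  x <- as.matrix(x)
  dmat <- as.matrix(dist(x, method = "manhattan"))
  combos <- utils::combn(nrow(x), k)
  costs <- apply(combos, 2, function(meds) {
    sum(apply(dmat[, meds, drop = FALSE], 1, min))
  })
  min(costs)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration over all
# C(m+n, m) group assignments (tie-free data assumed)
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # Mann-Whitney U of x
  combos <- utils::combn(length(pooled), m)
  u <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * (length(y)) / 2
  # two-sided: as extreme or more extreme in |U - mu|
  mean(abs(u - mu) >= abs(w_obs - mu) - 1e-12)
}

# literal BH step-up: reject all p_(i), i <= max{i : p_(i) <= i q / m}
bh_reject_reference <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * level / m)
  rejected <- rep(FALSE, m)
  if (length(ok) > 0) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

# well-separated Gaussian blobs in 2-D
make_blobs <- function(n_per, centers, sd = 1) {
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  list(x = tibble::as_tibble(as.data.frame(x)),
       labels = rep(seq_len(k), each = n_per))
}

# small complete cohort with a hand-built catalog, for categorize/report
make_tiny_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  data <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    DX = factor(sample(c("CN", "MCI", "AD"), n, replace = TRUE)),
    cm1 = rnorm(n), cm2 = rnorm(n), cm3 = rnorm(n),
    bm1 = rnorm(n), bm2 = rnorm(n)
  )
  catalog <- tibble::tibble(
    variable = c("DX", "cm1", "cm2", "cm3", "bm1", "bm2"),
    category = c("DX", "CM", "CM", "CM", "PBM", "PBM"),
    vartype = c("categorical", rep("continuous", 5)),
    direction = c("higher_worse", "higher_worse", "higher_better",
                  "higher_worse", "higher_worse", "higher_better"),
    domain = NA_character_
  )
  list(data = data, catalog = catalog)
}
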