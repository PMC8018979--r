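# Independent enumeration oracle for the exact two-sided Mann-Whitney p:
# all C(n_a + n_b, n_a) group labelings of the pooled sample.
mw_exact_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  mu <- n_a * length(b) / 2
  combos <- utils::combn(seq_along(pooled), n_a)
  u_all <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("Mann-Whitney exact path matches full enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mann_whitney(a, b)
  expect_true(res$exact)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(mw_exact_enumeration(a, b), 0.1)

  set.seed(11)
  for (i in 1:5) {
    x <- round(rnorm(4), 3); y <- round(rnorm(5) + 0.5, 3)
    expect_equal(mann_whitney(x, y)$p_value, mw_exact_enumeration(x, y),
                 tolerance = 1e-12)
  }
})

test_that("identical samples do not differ; empty samples are rejected", {
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1.0)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation tracks the exact p at n = 10 + 10", {
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.3)
    pe <- mann_whitney(a, b, method = "exact")$p_value
    pa <- mann_whitney(a, b, method = "approximate")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("exact Mann-Whitney holds its nominal type-I error", {
  set.seed(99)
  n_sim <- 10000
  rej <- 0
  for (i in seq_len(n_sim)) {
    a <- rnorm(10); b <- rnorm(10)
    rej <- rej + (suppressWarnings(
      stats::wilcox.test(a, b, exact = TRUE)$p.value) < 0.05)
  }
  rate <- rej / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("chi-square matches the printed demographic comparisons", {
  sex <- matrix(c(13, 14, 13, 4), nrow = 2, byrow = TRUE)
  res_sex <- chi_square_independence(sex)
  expect_equal(round(res_sex$p_value, 3), 0.063)
  expect_equal(res_sex$df, 1)

  edu <- matrix(c(1, 6, 20, 3, 6, 8), nrow = 2, byrow = TRUE)
  res_edu <- chi_square_independence(edu)
  expect_equal(round(res_edu$p_value, 3), 0.130)
  expect_equal(res_edu$df, 2)

  flat <- chi_square_independence(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("chi-square statistic equals the from-scratch expected-count formula", {
  set.seed(17)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 12) + 1, nrow = 2)
    res <- chi_square_independence(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               "zero marginal")
  expect_error(chi_square_independence(matrix(c(1.5, 2, 3, 4), 2)),
               "integers")
})

test_that("Spearman hits the monotone extremes and is transform-invariant", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman(x, x^3 + 1)$statistic, 1)
  expect_equal(spearman(x, -log(x))$statistic, -1)
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  r1 <- spearman(a, b)
  r2 <- spearman(exp(a), b)          # strictly monotone transform
  r3 <- spearman(a, rank(b) * 10 - 2)
  expect_equal(r2$statistic, r1$statistic)
  expect_equal(r3$statistic, r1$statistic)
  expect_warning(res <- spearman(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(res$statistic))
})

test_that("t-approximation p stays within 0.05 of exact enumeration at n = 6", {
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    pa <- spearman(x, y, method = "approximate")$p_value
    pe <- spearman(x, y, method = "exact")$p_value
    expect_lt(abs(pa - pe), 0.05)
  }
})

test_that("screening keeps only features that separate the groups", {
  set.seed(8)
  n <- 20
  labels <- rep(c("CNA", "MCI"), each = n)
  tbl <- tibble::tibble(
    FTAP_ntaps_CL1 = c(rnorm(n, 0), rnorm(n, 3)),   # 3 pooled SDs apart
    FTAP_sma_CL1 = rep(0.14, 2 * n),                # identical across groups
    TTHP_ntaps_CL2 = rnorm(2 * n)                   # pure noise
  )
  res <- screen_features(tbl, labels, alpha = 0.05)
  expect_true(res$selected[res$feature_name == "FTAP_ntaps_CL1"])
  expect_false(res$selected[res$feature_name == "FTAP_sma_CL1"])
  expect_equal(nrow(res), 3)

  none <- screen_features(tbl, labels, alpha = 0)
  expect_equal(sum(none$selected), 0)
  expect_error(screen_features(tbl, rep("CNA", 2 * n)), "two groups")
  expect_error(screen_features(tbl[1:3, ], labels[c(1, 2, 21)]), "at least 2")
})

test_that("a 3-SD shift is detected in at least 95 of 100 seeded runs", {
  hits <- 0
  for (s in 1:100) {
    set.seed(2000 + s)
    labels <- rep(c("CNA", "MCI"), each = 20)
    tbl <- tibble::tibble(GAIT_gvel_CL2 = c(rnorm(20), rnorm(20, 3)))
    hits <- hits + screen_features(tbl, labels)$selected[1]
  }
  expect_gte(hits, 95)
})

test_that("MMSE correlation flags undefined cells and finds planted structure", {
  set.seed(19)
  n <- 44
  mmse <- sample(24:30, n, replace = TRUE)
  tbl <- tibble::tibble(
    FTAP_ntaps_CL1 = mmse * 2 + 5,     # monotone in MMSE
    TTHP_sma_CL2 = rnorm(n),
    GAIT_gt_CL3 = rep(7, n)            # constant: undefined rho
  )
  res <- correlate_with_mmse(tbl, mmse)
  expect_equal(res$statistic[res$feature_name == "FTAP_ntaps_CL1"], 1)
  expect_false(res$defined[res$feature_name == "GAIT_gt_CL3"])

  const <- correlate_with_mmse(tbl, rep(28, n))
  expect_true(all(!const$defined))
})

test_that("estimated rho concentrates near a planted 0.4 at n = 44", {
  # oracle simulation of the sampling distribution puts
  # P(|rho_hat - 0.4| < 0.25) near 0.93 at this n
  L <- chol(matrix(c(1, 0.4, 0.4, 1), 2))
  hits <- 0
  for (s in 1:100) {
    set.seed(3000 + s)
    z <- matrix(rnorm(88), 44) %*% L
    r <- spearman(z[, 1], z[, 2])$statistic
    hits <- hits + (abs(r - 0.4) < 0.25)
  }
  expect_gte(hits, 85)
})
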