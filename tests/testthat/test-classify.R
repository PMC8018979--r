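# Brute-force AUC oracle: concordant-pair count with ties worth one half.
auc_pairs <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

test_that("trapezoidal AUC equals the concordant-pair count, ties included", {
  set.seed(12)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    scores <- sample(round(rnorm(30), 1))   # rounding forces ties
    roc <- roc_curve(scores, y)
    expect_equal(roc$auc, auc_pairs(scores, y), tolerance = 1e-12)
  }
})

test_that("ROC endpoints, complements and invariances behave", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  y <- c(1, 1, 0, 0)
  expect_equal(roc_curve(scores, y)$auc, 1.0)
  expect_equal(roc_curve(scores, 1 - y)$auc, 0.0)
  set.seed(6)
  s <- rnorm(40); yy <- rbinom(40, 1, 0.5)
  expect_equal(roc_curve(s, yy)$auc + roc_curve(s, 1 - yy)$auc, 1)
  # invariant under strictly increasing transforms
  expect_equal(roc_curve(exp(s), yy)$auc, roc_curve(s, yy)$auc)
  # monotone along the curve
  pts <- roc_curve(s, yy)$points
  expect_true(all(diff(pts$sensitivity) >= 0))
  expect_true(all(diff(pts$specificity) <= 0))

  const <- roc_curve(rep(1, 10), rep(c(0, 1), 5))
  expect_true(const$degenerate)
  expect_equal(const$auc, 0.5)
})

test_that("the Youden point matches exhaustive threshold search", {
  scores <- c(0.1, 0.3, 0.35, 0.6, 0.8, 0.95)
  y <- c(0, 0, 1, 0, 1, 1)
  roc <- roc_curve(scores, y)
  oop <- optimal_operating_point(roc)
  # brute force over candidate thresholds
  cand <- sort(unique(c(scores, Inf)))
  j <- sapply(cand, function(th) {
    mean(scores[y == 1] >= th) + mean(scores[y == 0] < th) - 1
  })
  expect_equal(oop$youden_j, max(j))
  expect_equal(oop$sensitivity + oop$specificity - 1, max(j))

  perfect <- optimal_operating_point(roc_curve(c(2, 3, 0, 1), c(1, 1, 0, 0)))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  flat <- optimal_operating_point(roc_curve(rep(1, 6), rep(c(0, 1), 3)))
  expect_true(flat$degenerate)
  expect_true(is.nan(flat$threshold))
})

test_that("a separating predictor is flagged and scores perfectly in-sample", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  age <- c(60, 70, 65, 72, 61, 68)
  m <- fit_mcdt_model(data.frame(x = x), age, y)
  expect_true(m$separation)
  expect_true(m$penalized)
  expect_true(all(is.finite(m$coefficients_std)))
  expect_equal(roc_curve(m$scores, y)$auc, 1.0)
  expect_error(fit_mcdt_model(data.frame(x = x), age, rep(1, 6)),
               "single class")
})

test_that("an uninformative predictor gives a near-chance AUC", {
  set.seed(44)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  m <- fit_mcdt_model(data.frame(x = rnorm(n)), rnorm(n, 70, 5), y)
  expect_lt(abs(roc_curve(m$scores, y)$auc - 0.5), 0.1)
})

test_that("two-Gaussian AUC matches the closed form Phi(d / sqrt(2))", {
  set.seed(2718)
  n <- 5000; d <- 1
  y <- rep(c(0, 1), each = n / 2)
  x <- rnorm(n) + d * y
  m <- fit_mcdt_model(data.frame(x = x), rnorm(n, 70, 8), y)
  expect_equal(roc_curve(m$scores, y)$auc, pnorm(d / sqrt(2)),
               tolerance = 0.02)
})

test_that("fitted coefficients recover a known generating model", {
  set.seed(1234)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n); age <- rnorm(n, 70, 8)
  beta <- c(int = -0.5, x1 = 1.2, x2 = -0.8, age = 0.15)
  eta <- beta["int"] + beta["x1"] * x1 + beta["x2"] * x2 +
    beta["age"] * (age - 70)
  y <- rbinom(n, 1, plogis(eta))
  m <- fit_mcdt_model(data.frame(x1 = x1, x2 = x2), age, y)
  est <- m$coefficients_raw[c("x1", "x2", "age")]
  expect_false(m$penalized)
  expect_equal(unname(est["x1"]), 1.2, tolerance = 0.1 * 1.2)
  expect_equal(unname(est["x2"]), -0.8, tolerance = 0.1 * 0.8)
  expect_equal(unname(est["age"]), 0.15, tolerance = 0.1)
})

test_that("the joint model is no worse than its best single predictor", {
  set.seed(55)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  feats <- data.frame(a = rnorm(n) + 0.4 * y, b = rnorm(n) + 0.2 * y)
  age <- rnorm(n, 70, 6)
  m <- fit_mcdt_model(feats, age, y)
  skip_if(m$penalized)   # property stated for converged unpenalised fits
  auc_joint <- roc_curve(m$scores, y)$auc
  best_single <- max(roc_curve(feats$a, y)$auc, roc_curve(feats$b, y)$auc)
  expect_gte(auc_joint, best_single - 1e-9)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(50, 1, 0.5)
  s <- round(rnorm(50), 1)
  ours <- roc_curve(s, y)$auc
  theirs <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, s, direction = "<", quiet = TRUE))))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the model suite fits populated cells and reports skipped ones", {
  set.seed(70)
  n <- 22
  labels <- rep(c("CNA", "MCI"), each = n)
  age <- c(rnorm(n, 65, 8), rnorm(n, 73, 8))
  tbl <- tibble::tibble(subject_id = sprintf("S%02d", 1:(2 * n)))
  screen_rows <- list()
  for (task in mcdt_tasks()) {
    for (load in c("CL1", "CL2", "CL3")) {
      nm <- paste(task, "ntaps", load, sep = "_")
      shifted <- !(task == "FTAP" & load == "CL1")  # leave one cell empty
      tbl[[nm]] <- rnorm(2 * n) + if (shifted) 3 * (labels == "MCI") else 0
      screen_rows[[nm]] <- tibble::tibble(
        feature_name = nm, task = task, feature = "ntaps", is_dtc = FALSE,
        load = load, p_value = if (shifted) 0.001 else 0.8,
        selected = shifted)
    }
  }
  screen <- dplyr::bind_rows(screen_rows)
  suite <- run_model_suite(tbl, labels, age, screen)
  expect_equal(nrow(suite), 9)
  empty_cell <- suite[suite$task == "FTAP" & suite$load == "CL1", ]
  expect_false(empty_cell$fitted)
  expect_match(empty_cell$reason, "no feature")
  fitted <- suite[suite$fitted, ]
  expect_equal(nrow(fitted), 8)
  # 3-SD shifts at n = 22 + 22: strong in-sample discrimination everywhere
  expect_true(all(fitted$auc >= 0.9))
})
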