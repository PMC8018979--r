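# Age-adjusted logistic regression per (task, load) cell, ROC evaluation
# and Youden-optimal operating points.

# Ridge-penalised logistic fit by Newton/IRLS on an already-standardized
# design matrix. Used as the separation guard: with any lambda > 0 the
# penalised likelihood has a finite maximiser even under complete
# separation. The intercept is not penalised.
ridge_logistic <- function(X, y, lambda, max_iter = 200, tol = 1e-10) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Xi, y - mu)) - drop(pen %*% beta)
    H <- crossprod(Xi, Xi * w) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, eta = drop(Xi %*% beta), iterations = iter)
}

#' Fit an age-adjusted logistic screening model
#'
#' Maximum-likelihood logistic regression of clinical status (MCI = 1)
#' on standardized motor predictors with age always included as a
#' covariate. If the unpenalised fit shows signs of complete or
#' quasi-complete separation (divergent coefficients / degenerate fitted
#' probabilities), the model is refitted with a small ridge penalty on
#' the standardized scale so the coefficients stay finite, and the
#' condition is flagged.
#'
#' @param features Data frame / matrix of predictor columns.
#' @param age Age covariate vector.
#' @param labels Binary labels (factor, character or 0/1); the
#'   higher/case level ("MCI") is coded 1.
#' @param ridge Ridge penalty used when separation is detected
#'   (default 1e-4 on the standardized scale).
#' @return An object of class `mcdt_logit`: standardized and raw-scale
#'   coefficients, in-sample scores (linear predictor), flags.
#' @export
fit_mcdt_model <- function(features, age, labels, ridge = 1e-4) {
  X0 <- as.matrix(cbind(features, age = age))
  y <- label_to_binary(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  keep_rows <- stats::complete.cases(X0)
  if (!all(keep_rows)) {
    message(sum(!keep_rows), " row(s) dropped for missing predictor values")
  }
  X0 <- X0[keep_rows, , drop = FALSE]
  y <- y[keep_rows]
  ctr <- colMeans(X0)
  scl <- apply(X0, 2, stats::sd)
  scl[scl == 0] <- 1
  X <- sweep(sweep(X0, 2, ctr), 2, scl, "/")

  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  beta <- fit$coefficients
  separated <- !fit$converged || any(abs(beta[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-10 & y == 0) ||
    any(fit$fitted.values < 1e-10 & y == 1)
  penalized <- FALSE
  if (separated || anyNA(beta)) {
    rf <- ridge_logistic(X, y, lambda = ridge)
    beta <- rf$beta
    penalized <- TRUE
  }
  eta <- drop(cbind(1, X) %*% beta)
  coef_std <- stats::setNames(beta, c("(Intercept)", colnames(X)))
  coef_raw <- coef_std
  coef_raw[-1] <- coef_std[-1] / scl
  coef_raw[1] <- coef_std[1] - sum(coef_std[-1] * ctr / scl)
  structure(list(coefficients_std = coef_std, coefficients_raw = coef_raw,
                 scores = eta, fitted = stats::plogis(eta), y = y,
                 separation = separated, penalized = penalized,
                 ridge = if (penalized) ridge else 0,
                 center = ctr, scale = scl, kept_rows = which(keep_rows),
                 predictors = colnames(X)),
            class = "mcdt_logit")
}

label_to_binary <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("labels must have exactly two levels")
  # alphabetical: "CNA" < "MCI", so the MCI/case class codes to 1
  as.integer(as.character(labels) == lv[2])
}

#' @export
print.mcdt_logit <- function(x, ...) {
  cat(sprintf("<mcdt_logit> %d predictors, n = %d%s%s\n",
              length(x$predictors) - 1, length(x$y),
              if (x$separation) ", separation detected" else "",
              if (x$penalized) sprintf(" (ridge %g)", x$ridge) else ""))
  print(round(x$coefficients_std, 3))
  invisible(x)
}

#' Empirical ROC curve
#'
#' Sweeps all distinct score values as thresholds (predicting the case
#' class when score >= threshold); tied scores collapse onto a single
#' threshold. AUC is the trapezoidal integral of sensitivity over the
#' false-positive rate, which equals the concordant-pair probability
#' with ties counted one half.
#'
#' @param scores Numeric scores, larger = more case-like.
#' @param labels Binary labels (case = 1 after [fit_mcdt_model()]'s
#'   coding rules).
#' @return Object of class `mcdt_roc`: `points` tibble (threshold,
#'   sensitivity, specificity), `auc`, `degenerate` flag.
#' @export
roc_curve <- function(scores, labels) {
  y <- label_to_binary(labels)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(th) mean(scores[y == 1] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(scores[y == 0] < th), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  degenerate <- length(unique(scores)) == 1
  structure(list(points = tibble::tibble(threshold = thr,
                                         sensitivity = sens,
                                         specificity = spec),
                 auc = auc, degenerate = degenerate,
                 evaluation_mode = "in_sample"),
            class = "mcdt_roc")
}

#' @export
print.mcdt_roc <- function(x, ...) {
  cat(sprintf("<mcdt_roc> AUC = %.3f over %d thresholds%s\n", x$auc,
              nrow(x$points), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity.
#'
#' @param roc An `mcdt_roc`.
#' @return One-row tibble: sensitivity, specificity, threshold, J,
#'   `degenerate`.
#' @export
optimal_operating_point <- function(roc) {
  stopifnot(inherits(roc, "mcdt_roc"))
  pts <- roc$points
  if (roc$degenerate) {
    return(tibble::tibble(sensitivity = NA_real_, specificity = NA_real_,
                          threshold = NaN, youden_j = 0, degenerate = TRUE))
  }
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(pts$specificity[best])]
  tibble::tibble(sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 threshold = pts$threshold[best],
                 youden_j = j[best], degenerate = FALSE)
}

# Stratified k-fold out-of-sample scores for the honest-evaluation mode.
cv_scores <- function(features, age, labels, ridge, folds, seed = NULL) {
  y <- label_to_binary(labels)
  n <- length(y)
  scores <- rep(NA_real_, n)
  with_seed(seed, {
    fold_id <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) next
      m <- fit_mcdt_model(features[tr, , drop = FALSE], age[tr], y[tr],
                          ridge = ridge)
      Xte <- as.matrix(cbind(features[!tr, , drop = FALSE], age = age[!tr]))
      Xte <- sweep(sweep(Xte, 2, m$center), 2, m$scale, "/")
      scores[!tr] <- drop(cbind(1, Xte) %*% m$coefficients_std)
    }
  })
  scores
}

#' Fit and evaluate one model per task and dual-task load
#'
#' For each motor task (FTAP, TTHP, GAIT) and dual-task load (CL1-CL3),
#' collects the feature columns selected by [screen_features()] at that
#' cell (base features at that load, their DTC, and the correct-answer
#' count), fits an age-adjusted logistic model and evaluates it by ROC.
#' Cells with no significant feature are skipped and reported with a
#' reason — a load at which a task cannot differentiate the groups
#' yields no model.
#'
#' @param dtc_table Analysis table.
#' @param labels Group labels aligned with the table rows.
#' @param age Age covariate.
#' @param screen Result of [screen_features()].
#' @param ridge Separation-guard ridge penalty.
#' @param evaluation `"in_sample"` (default) or `"cv"` (stratified
#'   k-fold; honest but noisier at small n).
#' @param cv_folds Folds for `"cv"` mode.
#' @param seed Seed for the fold assignment in `"cv"` mode.
#' @return Tibble with one row per (task, load): n features, fitted
#'   flag, skip reason, AUC, operating point; the `model` and `roc`
#'   list-columns hold the full objects.
#' @export
run_model_suite <- function(dtc_table, labels, age, screen, ridge = 1e-4,
                            evaluation = c("in_sample", "cv"), cv_folds = 5,
                            seed = NULL) {
  evaluation <- match.arg(evaluation)
  rows <- list()
  for (task in mcdt_tasks()) {
    for (load in c("CL1", "CL2", "CL3")) {
      sel <- screen$feature_name[screen$selected & screen$task == task &
                                   screen$load == load]
      if (length(sel) == 0) {
        rows[[paste(task, load)]] <- tibble::tibble(
          task = task, load = load, n_features = 0L, fitted = FALSE,
          reason = "no feature differentiates the groups at this load",
          auc = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
          separation = NA, model = list(NULL), roc = list(NULL))
        next
      }
      feats <- dtc_table[, sel, drop = FALSE]
      model <- fit_mcdt_model(feats, age, labels, ridge = ridge)
      scores <- if (evaluation == "cv") {
        cv_scores(feats, age, labels, ridge, cv_folds, seed = seed)
      } else {
        model$scores
      }
      keep <- is.finite(scores)
      y_eval <- label_to_binary(labels)
      if (evaluation == "in_sample") {
        y_eval <- y_eval[model$kept_rows]
        keep <- rep(TRUE, length(model$scores))
      }
      roc <- roc_curve(scores[keep], y_eval[keep])
      roc$evaluation_mode <- evaluation
      oop <- optimal_operating_point(roc)
      rows[[paste(task, load)]] <- tibble::tibble(
        task = task, load = load, n_features = length(sel), fitted = TRUE,
        reason = NA_character_, auc = roc$auc,
        sensitivity = oop$sensitivity, specificity = oop$specificity,
        separation = model$separation, model = list(model),
        roc = list(roc))
    }
  }
  dplyr::bind_rows(rows)
}
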