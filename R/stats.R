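# Nonparametric group comparison, categorical independence and rank
# correlation. Test engines are base R (wilcox.test, chisq.test, cor.test);
# these wrappers fix the conventions used throughout the pipeline (exact
# vs approximate paths, no continuity correction for chi-square, two-sided
# p-values) and return tidy one-row results.

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two samples
#'
#' Two-sided test for equal medians. The exact null distribution is used
#' when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie-corrected variance (and
#' continuity correction) is used. The reported statistic is the
#' Mann-Whitney U for the first sample.
#'
#' @param a,b Numeric samples.
#' @param feature_name Optional label carried into the result.
#' @param method `"auto"` (size-based, default), `"exact"` or
#'   `"approximate"`.
#' @return One-row tibble: test, statistic, p_value, n and mean/SD per
#'   group, and whether the exact path was used.
#' @export
mann_whitney <- function(a, b, feature_name = NA_character_,
                         method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(method,
                  auto = (length(a) + length(b) <= 20) && !ties,
                  exact = TRUE,
                  approximate = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  tibble::tibble(feature_name = feature_name, test = "mann_whitney",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 exact = exact, n_a = length(a), n_b = length(b),
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b))
}

#' Pearson chi-square test of independence
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on an
#' r x c contingency table, df = (r-1)(c-1).
#'
#' @param tab Matrix of non-negative integer counts, at least 2 x 2.
#' @param feature_name Optional label.
#' @return One-row tibble: test, statistic, df, p_value.
#' @export
chi_square_independence <- function(tab, feature_name = NA_character_) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(feature_name = feature_name, test = "chi_square",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Spearman rank correlation
#'
#' Rho from average-ranked data; the two-sided p-value uses the
#' t-distribution approximation by default, or exact enumeration over
#' all permutations of one variable for n of at most 8.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param feature_name Optional label.
#' @param method `"approximate"` (t approximation, default) or
#'   `"exact"` (full permutation enumeration, n <= 8).
#' @return One-row tibble: test, rho, p_value, n. Constant input gives
#'   `NA` rho with a warning.
#' @export
spearman <- function(x, y, feature_name = NA_character_,
                     method = c("approximate", "exact")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(tibble::tibble(feature_name = feature_name, test = "spearman",
                          statistic = NA_real_, p_value = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (method == "exact") {
    if (n > 8) stop("exact permutation path limited to n <= 8")
    perms <- pracma::perms(seq_len(n))
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  tibble::tibble(feature_name = feature_name, test = "spearman",
                 statistic = rho, p_value = p, n = n)
}

# Split "FTAP_exc_mean_DTC_CL2" into task/feature/dtc/load.
parse_feature_column <- function(nm) {
  m <- regmatches(nm, regexec("^(FTAP|TTHP|GAIT)_(.+?)(_DTC)?_(CL[0-3])$", nm))[[1]]
  if (length(m) == 0) return(NULL)
  list(task = m[2], feature = m[3], is_dtc = m[4] == "_DTC", load = m[5])
}

analysis_columns <- function(tbl) {
  nm <- names(tbl)
  nm[grepl("^(FTAP|TTHP|GAIT)_.+_(CL[0-3])$", nm)]
}

#' Screen features by group difference
#'
#' Runs a Mann-Whitney comparison of the two groups for every motor
#' feature column (base and DTC, plus correct-answer counts) of the
#' analysis table and flags those significant at `alpha`. The full
#' result table is returned — not only the selected rows — so the user
#' can apply any multiple-testing correction downstream; none is applied
#' here.
#'
#' @param dtc_table Analysis table from [assemble_dtc_table()].
#' @param labels Group factor/character aligned with the table rows;
#'   the second of the sorted unique values is treated as the case
#'   group.
#' @param alpha Selection threshold on the unadjusted p-value.
#' @return Tibble with one row per feature column: parsed task/load,
#'   group summaries, p_value and `selected`. Attribute `alpha`.
#' @export
screen_features <- function(dtc_table, labels, alpha = 0.05) {
  stopifnot(length(labels) == nrow(dtc_table), alpha >= 0, alpha <= 1)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("need exactly two groups")
  if (min(table(labels)) < 2) stop("need at least 2 subjects per group")
  cols <- analysis_columns(dtc_table)
  rows <- lapply(cols, function(nm) {
    info <- parse_feature_column(nm)
    x <- dtc_table[[nm]]
    a <- x[labels == lv[1]]; b <- x[labels == lv[2]]
    if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2 ||
        (stats::sd(a, na.rm = TRUE) == 0 && stats::sd(b, na.rm = TRUE) == 0 &&
         isTRUE(all.equal(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE))))) {
      return(tibble::tibble(feature_name = nm, task = info$task,
                            feature = info$feature, is_dtc = info$is_dtc,
                            load = info$load, statistic = NA_real_,
                            p_value = NA_real_, n_a = sum(is.finite(a)),
                            n_b = sum(is.finite(b)),
                            mean_a = mean(a, na.rm = TRUE),
                            sd_a = stats::sd(a, na.rm = TRUE),
                            mean_b = mean(b, na.rm = TRUE),
                            sd_b = stats::sd(b, na.rm = TRUE)))
    }
    mw <- mann_whitney(a, b, feature_name = nm)
    tibble::tibble(feature_name = nm, task = info$task,
                   feature = info$feature, is_dtc = info$is_dtc,
                   load = info$load, statistic = mw$statistic,
                   p_value = mw$p_value, n_a = mw$n_a, n_b = mw$n_b,
                   mean_a = mw$mean_a, sd_a = mw$sd_a,
                   mean_b = mw$mean_b, sd_b = mw$sd_b)
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- !is.na(out$p_value) & out$p_value < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Correlate every feature with MMSE
#'
#' Spearman rho and unadjusted two-sided p for every motor feature
#' column (base and DTC) against the MMSE score. No covariate
#' correction is applied at this stage.
#'
#' @param dtc_table Analysis table.
#' @param mmse MMSE scores aligned with the table rows.
#' @return Tibble with one row per feature column: rho (`statistic`),
#'   p_value, n. Constant columns (or constant MMSE) give `NA` rho,
#'   flagged in `defined`.
#' @export
correlate_with_mmse <- function(dtc_table, mmse) {
  stopifnot(length(mmse) == nrow(dtc_table))
  cols <- analysis_columns(dtc_table)
  rows <- lapply(cols, function(nm) {
    info <- parse_feature_column(nm)
    x <- dtc_table[[nm]]
    ok <- is.finite(x) & is.finite(mmse)
    res <- if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(mmse[ok]) == 0) {
      tibble::tibble(feature_name = nm, test = "spearman",
                     statistic = NA_real_, p_value = NA_real_, n = sum(ok))
    } else {
      spearman(x[ok], mmse[ok], feature_name = nm)
    }
    res$task <- info$task; res$feature <- info$feature
    res$is_dtc <- info$is_dtc; res$load <- info$load
    res$defined <- !is.na(res$statistic)
    res
  })
  dplyr::bind_rows(rows)
}
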