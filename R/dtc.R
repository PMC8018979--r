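#' Dual-task cost of a motor parameter
#'
#' Percent change of a motor parameter between single-task (no concurrent
#' counting, CL0) and dual-task performance. Two denominator conventions
#' are in circulation and both are provided:
#' `"st_denominator"` (default) divides the change by the single-task
#' value, \eqn{(P_{DT} - P_{ST}) / P_{ST} \times 100} — the usual
#' dual-task-cost convention; `"dt_denominator"` divides by the
#' dual-task value instead. Near-zero denominators (|d| < 1e-9) yield
#' `NA` with a warning, never infinities.
#'
#' @param p_st Single-task (CL0) parameter value(s).
#' @param p_dt Dual-task parameter value(s).
#' @param mode Denominator convention.
#' @return Numeric vector of costs in percent.
#' @export
dual_task_cost <- function(p_st, p_dt,
                           mode = c("st_denominator", "dt_denominator")) {
  mode <- match.arg(mode)
  denom <- if (mode == "st_denominator") p_st else p_dt
  bad <- is.finite(denom) & abs(denom) < 1e-9
  if (any(bad, na.rm = TRUE)) {
    warning("zero denominator in dual-task cost: returning NA for ",
            sum(bad), " value(s)")
  }
  out <- (p_dt - p_st) / denom * 100
  out[bad] <- NA_real_
  out
}

#' Assemble the full dual-task-cost analysis table
#'
#' Adds, for each of the 38 base features and each dual-task load (CL1,
#' CL2, CL3), a `"{TASK}_{feature}_DTC_{CL}"` column computed against
#' that feature's CL0 value — 114 DTC columns on top of the 152 base
#' columns, 266 motor feature columns in total. The denominator
#' convention is recorded in the `"denominator_mode"` attribute.
#'
#' @param base_features Base table from [build_base_features()].
#' @param mode Denominator convention, see [dual_task_cost()].
#' @return The widened tibble with attributes `denominator_mode`.
#' @export
assemble_dtc_table <- function(base_features,
                               mode = c("st_denominator", "dt_denominator")) {
  mode <- match.arg(mode)
  out <- base_features
  for (task in mcdt_tasks()) {
    for (feat in feature_names(task)) {
      st_col <- paste(task, feat, "CL0", sep = "_")
      if (!st_col %in% names(out)) {
        stop("base table is missing the CL0 column ", st_col)
      }
      for (load in c("CL1", "CL2", "CL3")) {
        dt_col <- paste(task, feat, load, sep = "_")
        new_col <- paste(task, feat, "DTC", load, sep = "_")
        out[[new_col]] <- suppressWarnings(
          dual_task_cost(out[[st_col]], out[[dt_col]], mode = mode))
      }
    }
  }
  attr(out, "denominator_mode") <- mode
  out
}

#' Count motor feature columns in an analysis table
#'
#' Counts columns matching the `"{TASK}_{feature}_{CL}"` and
#' `"{TASK}_{feature}_DTC_{CL}"` schemas; correct-answer columns and
#' metadata are not motor features and are excluded.
#'
#' @param tbl A feature table.
#' @return Integer count (266 for a complete table).
#' @export
n_feature_columns <- function(tbl) {
  nm <- names(tbl)
  motor <- grepl("^(FTAP|TTHP|GAIT)_.+_(CL[0-3])$", nm) &
    !grepl("_correct_answers_", nm)
  sum(motor)
}
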