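#' Feature name schema
#'
#' Names of the kinematic features extracted per recording: 11 for each
#' tapping task (tap count; per-cycle excursion, peak opening and closing
#' velocity, each as mean and cycle-to-cycle SD; signal magnitude area;
#' jerk RMS; skewness and Pearson kurtosis of the acceleration
#' magnitude) and 16 for gait (total walk time, velocity, stride count,
#' stride duration/length/swing/stance mean and SD, cadence, swing-peak
#' velocity mean and SD, symmetry index, normalized jerk) — 38 per
#' cognitive load across the three tasks.
#'
#' @param task `"FTAP"`, `"TTHP"` or `"GAIT"`.
#' @return Character vector of feature names (11 for tapping, 16 for
#'   gait).
#' @export
feature_names <- function(task = c("FTAP", "TTHP", "GAIT")) {
  task <- match.arg(task)
  if (task == "GAIT") {
    c("gt", "gvel", "nstrides", "strd_mean", "strd_sd", "strdl_mean",
      "strdl_sd", "swing_mean", "swing_sd", "stance_mean", "stance_sd",
      "cadence", "swpk_mean", "swpk_sd", "symmetry", "njerk")
  } else {
    c("ntaps", "exc_mean", "exc_sd", "wo_mean", "wo_sd", "wc_mean",
      "wc_sd", "sma", "jerk_rms", "acc_skew", "acc_kurt")
  }
}

#' Full base-feature column schema
#'
#' @return Tibble with `column`, `task`, `feature`, `load` for the
#'   38-features-per-load base set (152 columns).
#' @export
feature_schema <- function() {
  dplyr::bind_rows(lapply(mcdt_tasks(), function(task) {
    tidyr::expand_grid(task = task, feature = feature_names(task),
                       load = mcdt_loads())
  })) |>
    dplyr::mutate(column = paste(task, feature, load, sep = "_")) |>
    dplyr::select("column", "task", "feature", "load")
}

# Jerk as the first difference of the acceleration magnitude, in g/s.
jerk_series <- function(accel, fs) {
  amag <- sqrt(rowSums(accel^2))
  diff(amag) * fs
}

#' Tapping feature vector
#'
#' Computes the 11 tapping features from segmented tap cycles plus the
#' recording's acceleration channels. Cycle aggregates (excursion, peak
#' opening/closing velocity) are means and SDs over cycles; the
#' acceleration block uses the movement window only. The signal
#' magnitude area (SMA) is the time-normalized sum of absolute
#' gravity-removed accelerations, \eqn{(1/T)\sum(|a_x|+|a_y|+|a_z|)\Delta t};
#' gravity is removed by subtracting the static baseline pose. Jerk RMS
#' is the root mean square of the first difference of the acceleration
#' magnitude divided by \eqn{\Delta t}; skewness and kurtosis of the
#' acceleration magnitude use the sample-moment (Pearson, non-excess)
#' conventions.
#'
#' With an empty segment list the tap count is 0 and every
#' cycle-aggregate feature is `NA` (missing, not zero).
#'
#' @param segments Tap segments from [segment_taps()].
#' @param rec The (filtered, baseline-removed) recording the segments
#'   came from.
#' @return One-row tibble: `task`, `load`, the 11 features.
#' @export
tapping_features <- function(segments, rec) {
  stopifnot(inherits(rec, "inertial_recording"))
  n <- nrow(segments)
  pose <- rec$baseline$pose %||% colMeans(rec$accel)
  a_nog <- sweep(rec$accel, 2, pose)
  sma <- mean(rowSums(abs(a_nog)))
  jerk <- jerk_series(rec$accel, rec$fs)
  amag <- sqrt(rowSums(rec$accel^2))
  agg <- function(x, f) if (n == 0) NA_real_ else f(x)
  tibble::tibble(
    task = rec$task, load = rec$load,
    ntaps = n,
    exc_mean = agg(segments$excursion, mean),
    exc_sd = agg(segments$excursion, stats::sd),
    wo_mean = agg(segments$peak_opening_velocity, mean),
    wo_sd = agg(segments$peak_opening_velocity, stats::sd),
    wc_mean = agg(segments$peak_closing_velocity, mean),
    wc_sd = agg(segments$peak_closing_velocity, stats::sd),
    sma = sma,
    jerk_rms = rms(jerk),
    acc_skew = sample_skewness(amag),
    acc_kurt = sample_kurtosis(amag)
  )
}

# Swing window around a stride's peak: indices where |v| stays above
# rel_thr x the stride's own peak, expanded from the peak outward.
swing_window <- function(v, start, end, peak_index, rel_thr = 0.1) {
  thr <- rel_thr * v[peak_index]
  s <- peak_index
  while (s > start && v[s - 1] > thr) s <- s - 1
  e <- peak_index
  while (e < end && v[e + 1] > thr) e <- e + 1
  c(s, e)
}

#' Gait feature vector
#'
#' Computes the 16 gait parameters from retained strides. Total time
#' (`gt`) spans first retained stride start to last retained stride end;
#' gait velocity is `distance_m / gt`. Stride length uses the
#' uniform-allocation convention `distance_m / n_detected` for the mean
#' (a single dorsum-mounted IMU cannot measure length directly) with an
#' SD from duration-proportional allocation of the walkway distance.
#' The swing/stance split places the swing window at the threshold
#' crossings (10% of the stride's own peak) around the mid-swing peak.
#' Cadence is strides per minute; the symmetry index is the ratio of
#' mean odd-stride to mean even-stride duration; normalized jerk is the
#' jerk RMS of the acceleration magnitude scaled by mean stride duration
#' over mean acceleration magnitude (dimensionless smoothness).
#'
#' @param strides Stride segments from [segment_strides()].
#' @param rec The filtered GAIT recording.
#' @param distance_m Walkway length, m (default 10).
#' @return One-row tibble: `task`, `load`, the 16 features.
#' @export
gait_features <- function(strides, rec, distance_m = 10) {
  stopifnot(inherits(rec, "inertial_recording"))
  if (nrow(strides) == 0) stop("no retained strides to compute features from")
  n_detected <- attr(strides, "n_detected") %||% nrow(strides)
  v <- movement_velocity(rec)
  gt <- (strides$end[nrow(strides)] - strides$start[1]) / rec$fs
  dur <- strides$duration
  sw <- t(mapply(function(s, e, p) swing_window(v, s, e, p),
                 strides$start, strides$end, strides$peak_index))
  swing_t <- (sw[, 2] - sw[, 1]) / rec$fs
  stance_t <- dur - swing_t
  # duration-proportional allocation of the walkway over detected strides,
  # evaluated on the retained ones
  strdl <- distance_m * dur / (mean(dur) * n_detected)
  odd <- dur[seq_along(dur) %% 2 == 1]
  even <- dur[seq_along(dur) %% 2 == 0]
  jerk <- jerk_series(rec$accel, rec$fs)
  amag <- sqrt(rowSums(rec$accel^2))
  tibble::tibble(
    task = rec$task, load = rec$load,
    gt = gt,
    gvel = distance_m / gt,
    nstrides = nrow(strides),
    strd_mean = mean(dur), strd_sd = stats::sd(dur),
    strdl_mean = distance_m / n_detected,
    strdl_sd = stats::sd(strdl),
    swing_mean = mean(swing_t), swing_sd = stats::sd(swing_t),
    stance_mean = mean(stance_t), stance_sd = stats::sd(stance_t),
    cadence = 60 / mean(dur),
    swpk_mean = mean(strides$swing_peak_velocity),
    swpk_sd = stats::sd(strides$swing_peak_velocity),
    symmetry = if (length(even) > 0) mean(odd) / mean(even) else NA_real_,
    njerk = rms(jerk) * mean(dur) / mean(amag)
  )
}

# Process one recording through conditioning + segmentation + features.
extract_recording_features <- function(rec, fspec = filter_spec(),
                                       distance_m = 10) {
  rec_f <- lowpass_filter(rec, fspec)
  if (rec$task == "GAIT") {
    strides <- segment_strides(rec_f)
    gait_features(strides, rec_f, distance_m = distance_m)
  } else {
    rec_b <- remove_baseline(rec_f)
    segs <- segment_taps(rec_b)
    tapping_features(segs, rec_b)
  }
}

#' Build the per-subject base feature table
#'
#' Runs every recording of a cohort through filtering, segmentation and
#' feature extraction and assembles one wide row per subject with
#' columns named `"{TASK}_{feature}_{CL}"` — 38 features x 4 loads = 152
#' base columns — plus `"{TASK}_correct_answers_{CL}"` counts for the
#' dual-task loads (not part of the 38-feature motor set). Subjects with
#' an incomplete 3-task x 4-load recording set are flagged and excluded
#' with a message.
#'
#' @param cohort A list with `subjects` and `recordings`, as returned by
#'   [simulate_cohort()].
#' @param fspec A [filter_spec()].
#' @param distance_m Walkway length for gait features, m.
#' @return Tibble: `subject_id`, `group`, 152 base feature columns, 9
#'   correct-answer columns.
#' @export
build_base_features <- function(cohort, fspec = filter_spec(),
                                distance_m = 10) {
  subjects <- cohort$subjects
  recs <- cohort$recordings
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    keys <- as.vector(outer(mcdt_tasks(), mcdt_loads(),
                            function(a, b) paste(sid, a, b, sep = "_")))
    if (!all(keys %in% names(recs))) {
      message("subject ", sid, " has an incomplete recording set: excluded")
      next
    }
    vals <- list(subject_id = sid, group = subjects$group[i])
    for (task in mcdt_tasks()) {
      for (load in mcdt_loads()) {
        rec <- recs[[paste(sid, task, load, sep = "_")]]
        fv <- extract_recording_features(rec, fspec, distance_m)
        feats <- fv[, feature_names(task), drop = FALSE]
        names(feats) <- paste(task, names(feats), load, sep = "_")
        vals <- c(vals, as.list(feats))
        if (load != "CL0") {
          ca <- rec$truth$correct_answers %||% NA_integer_
          vals[[paste(task, "correct_answers", load, sep = "_")]] <- ca
        }
      }
    }
    rows[[i]] <- tibble::as_tibble(vals)
  }
  dplyr::bind_rows(rows)
}
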