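#' Low-pass Butterworth filter specification
#'
#' @param order Filter order (default 4).
#' @param cutoff_hz Cut-off frequency, Hz (default 5).
#' @param phase_mode `"zero_phase"` (forward-backward, default) or
#'   `"causal"` (single forward pass).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 5,
                        phase_mode = c("zero_phase", "causal")) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = "low", phase_mode = phase_mode),
            class = "filter_spec")
}

# Zero-phase IIR filtering with odd-reflection padding at both ends.
# Odd reflection continues the signal anti-symmetrically about its endpoint
# value, so a constant stays constant into the pad and the startup transient
# of the zero-initial-state filter decays inside the pad, not in the data.
zero_phase_filter <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Low-pass filter all six channels of a recording
#'
#' Applies the same digital Butterworth low-pass filter to every
#' accelerometer and gyroscope channel. The default zero-phase mode runs
#' the filter forward and backward so segment boundaries are not
#' lag-shifted; the squared magnitude response leaves DC untouched and
#' attenuates above the cut-off twice as steeply as a single pass.
#'
#' @param rec An `inertial_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered recording.
#' @export
lowpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "inertial_recording"), inherits(spec, "filter_spec"))
  if (spec$cutoff_hz >= rec$fs / 2) {
    stop("filter cut-off must be below the Nyquist frequency ", rec$fs / 2, " Hz")
  }
  n <- n_samples(rec)
  min_len <- 3 * spec$order + 1
  if (n < min_len) {
    stop("signal too short to filter: ", n, " samples, need at least ", min_len)
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (rec$fs / 2), type = "low")
  apply_one <- function(x) {
    if (spec$phase_mode == "zero_phase") {
      # pad long enough that the startup transient (pole radius ~0.85 at
      # 5 Hz / 100 Hz) decays below 1e-12 before the data begins
      zero_phase_filter(x, bf$b, bf$a, pad = min(n - 1, 200L))
    } else {
      as.numeric(signal::filter(bf$b, bf$a, x))
    }
  }
  rec$accel <- apply(rec$accel, 2, apply_one)
  rec$gyro <- apply(rec$gyro, 2, apply_one)
  colnames(rec$accel) <- c("ax_g", "ay_g", "az_g")
  colnames(rec$gyro) <- c("gx_dps", "gy_dps", "gz_dps")
  rec
}

#' Remove the static baseline window
#'
#' Tapping trials begin with a 3-s static hold used to acquire the
#' baseline pose. The gyroscope bias is estimated as the per-channel mean
#' over that window and subtracted from the whole recording; the mean
#' accelerometer vector over the window is stored as the baseline pose
#' (used later for gravity removal). The baseline window itself is
#' dropped from the returned recording so downstream segmentation only
#' sees the movement phase.
#'
#' @param rec An `inertial_recording`.
#' @param baseline_window_s Length of the static window, s (default 3).
#' @return The trimmed recording; `$baseline` holds `pose` (g),
#'   `gyro_bias` (deg/s) and `window_s`.
#' @export
remove_baseline <- function(rec, baseline_window_s = 3.0) {
  stopifnot(inherits(rec, "inertial_recording"))
  m <- round(baseline_window_s * rec$fs)
  if (n_samples(rec) <= m) {
    stop("recording shorter than the ", baseline_window_s, " s baseline window")
  }
  bias <- colMeans(rec$gyro[seq_len(m), , drop = FALSE])
  pose <- colMeans(rec$accel[seq_len(m), , drop = FALSE])
  keep <- (m + 1):n_samples(rec)
  rec$gyro <- sweep(rec$gyro[keep, , drop = FALSE], 2, bias)
  rec$accel <- rec$accel[keep, , drop = FALSE]
  rec$t <- rec$t[keep]
  rec$baseline <- list(pose = pose, gyro_bias = bias,
                       window_s = baseline_window_s)
  rec
}
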