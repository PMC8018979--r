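#' Default per-group generator presets
#'
#' Distributional presets for the two study groups: cognitively normal
#' adults (CNA) and mild cognitive impairment (MCI). Demographics are
#' truncated normals parameterised from group medians and interquartile
#' ranges (sd = IQR / 1.349); motor presets encode group-dependent slowing
#' (longer tap period, longer stride duration), amplitude reduction and
#' cycle-to-cycle variability inflation as multiplicative per-load factors
#' on the CL0 baseline. Between-subject spread parameters
#' (`*_subject_cv`, `*_subject_sd`) give every subject their own motor
#' profile, matching the large between-subject SDs of the group feature
#' summaries. Gait stride-length presets decline from 2.24 m
#' (CNA) / 1.92 m (MCI) at no load to 2.04 / 1.81 m under the hardest
#' counting load. Correct-answer means for counting backwards are per
#' task, group and load.
#'
#' @return A nested list with one entry per group (`CNA`, `MCI`).
#' @export
mcdt_presets <- function() {
  loads <- mcdt_loads()
  lm <- function(x) stats::setNames(x, loads)
  list(
    CNA = list(
      age = list(mean = 65, sd = 9.6, min = 50, max = 95),
      mmse = list(mean = 29, sd = 1.5, min = 24, max = 30),
      stature = list(mean = 168, sd = 9.6, min = 145, max = 200),
      bmi = list(mean = 24.1, sd = 3.6, min = 16, max = 45),
      sex_f_prob = 13 / 27,
      education_prob = c(primary = 1, secondary = 6, superior = 20) / 27,
      frailty_prob = c(not_frail = 13, pre_frail = 12, frail = 0) / 25,
      tapping = list(
        FTAP = list(period_s = 0.45, period_subject_cv = 0.40,
                    period_cycle_sd = 0.035,
                    excursion_deg = 30, excursion_subject_sd = 6,
                    excursion_cycle_sd = 2.11, excursion_cycle_sd_sd = 0.79),
        TTHP = list(period_s = 0.85, period_subject_cv = 0.35,
                    period_cycle_sd = 0.05,
                    excursion_deg = 9, excursion_subject_sd = 2.5,
                    excursion_cycle_sd = 1.2, excursion_cycle_sd_sd = 0.4)
      ),
      load_mult = list(period = lm(c(1, 1.05, 1.15, 1.25)),
                       amplitude = lm(c(1, 0.97, 0.93, 0.88)),
                       variability = lm(c(1, 1.10, 1.25, 1.40))),
      gait = list(stride_length_m = lm(c(2.24, 2.17, 2.10, 2.04)),
                  stride_length_subject_sd = 0.38,
                  stride_duration_s = lm(c(1.08, 1.11, 1.15, 1.20)),
                  stride_duration_subject_sd = 0.15,
                  duration_cycle_sd = 0.04,
                  swing_peak_dps = 250, swing_peak_subject_sd = 30),
      correct_answers = list(
        FTAP = c(CL1 = 16.6, CL2 = 8.19, CL3 = 5.22),
        TTHP = c(CL1 = 16.59, CL2 = 8.70, CL3 = 5.33),
        GAIT = c(CL1 = 14.0, CL2 = 8.07, CL3 = 5.56)
      )
    ),
    MCI = list(
      age = list(mean = 73, sd = 9.5, min = 50, max = 95),
      mmse = list(mean = 27, sd = 1.7, min = 24, max = 30),
      stature = list(mean = 162, sd = 8.5, min = 145, max = 200),
      bmi = list(mean = 25.7, sd = 4.8, min = 16, max = 45),
      sex_f_prob = 13 / 17,
      education_prob = c(primary = 3, secondary = 6, superior = 8) / 17,
      frailty_prob = c(not_frail = 4, pre_frail = 11, frail = 1) / 16,
      tapping = list(
        FTAP = list(period_s = 0.62, period_subject_cv = 0.55,
                    period_cycle_sd = 0.06,
                    excursion_deg = 26, excursion_subject_sd = 6,
                    excursion_cycle_sd = 2.87, excursion_cycle_sd_sd = 1.28),
        TTHP = list(period_s = 1.00, period_subject_cv = 0.40,
                    period_cycle_sd = 0.08,
                    excursion_deg = 8, excursion_subject_sd = 2.5,
                    excursion_cycle_sd = 1.3, excursion_cycle_sd_sd = 0.5)
      ),
      load_mult = list(period = lm(c(1, 1.10, 1.22, 1.38)),
                       amplitude = lm(c(1, 0.94, 0.87, 0.80)),
                       variability = lm(c(1, 1.20, 1.45, 1.70))),
      gait = list(stride_length_m = lm(c(1.92, 1.88, 1.85, 1.81)),
                  stride_length_subject_sd = 0.26,
                  stride_duration_s = lm(c(1.22, 1.27, 1.33, 1.40)),
                  stride_duration_subject_sd = 0.18,
                  duration_cycle_sd = 0.06,
                  swing_peak_dps = 200, swing_peak_subject_sd = 25),
      correct_answers = list(
        FTAP = c(CL1 = 13.4, CL2 = 5.47, CL3 = 2.65),
        TTHP = c(CL1 = 13.35, CL2 = 6.00, CL3 = 3.06),
        GAIT = c(CL1 = 11.0, CL2 = 5.53, CL3 = 2.71)
      )
    )
  )
}

#' Cohort generator configuration
#'
#' @param n_cna,n_mci Number of cognitively normal / MCI subjects.
#' @param seed Integer seed; a fixed seed reproduces the cohort and all
#'   signals exactly.
#' @param presets Per-group parameter presets, see [mcdt_presets()].
#' @param fs Sampling rate, Hz.
#' @param gyro_noise_dps Gyroscope white-noise RMS, deg/s.
#' @param accel_noise_g Accelerometer white-noise RMS, g.
#' @param gyro_bias_sd_dps Per-recording gyroscope bias SD, deg/s.
#' @param dropout_prob Probability that a subject fails to complete the
#'   full protocol (default 0: everyone completes).
#' @param gait_distance_m Walkway length, m.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cna = 27, n_mci = 17, seed = 1,
                             presets = mcdt_presets(), fs = 100,
                             gyro_noise_dps = 0.5, accel_noise_g = 0.01,
                             gyro_bias_sd_dps = 0.3, dropout_prob = 0,
                             gait_distance_m = 10) {
  if (!is.numeric(n_cna) || !is.numeric(n_mci) || n_cna < 0 || n_mci < 0 ||
      n_cna != round(n_cna) || n_mci != round(n_mci)) {
    stop("configuration error: group counts must be non-negative integers")
  }
  stopifnot(fs > 0, gyro_noise_dps >= 0, accel_noise_g >= 0,
            dropout_prob >= 0, dropout_prob <= 1, gait_distance_m > 0)
  structure(list(n_cna = as.integer(n_cna), n_mci = as.integer(n_mci),
                 seed = as.integer(seed), presets = presets, fs = fs,
                 gyro_noise_dps = gyro_noise_dps,
                 accel_noise_g = accel_noise_g,
                 gyro_bias_sd_dps = gyro_bias_sd_dps,
                 dropout_prob = dropout_prob,
                 gait_distance_m = gait_distance_m),
            class = "generator_config")
}

#' Frailty phenotype categorization
#'
#' Maps the number of positive Fried criteria (0-5) onto the standard
#' three-level phenotype: 0 criteria = not frail, 1-2 = pre-frail,
#' 3 or more = frail.
#'
#' @param fried_positive Integer vector of positive-criterion counts.
#' @return Factor with levels `not_frail`, `pre_frail`, `frail`.
#' @export
categorize_frailty <- function(fried_positive) {
  if (any(!is.finite(fried_positive)) ||
      any(fried_positive < 0 | fried_positive > 5) ||
      any(fried_positive != round(fried_positive))) {
    stop("fried_positive must be integers in [0, 5]")
  }
  cut(fried_positive, breaks = c(-0.5, 0.5, 2.5, 5.5),
      labels = c("not_frail", "pre_frail", "frail"))
}

#' Apply the study's eligibility rules
#'
#' Removes subjects with MMSE below 24 (moderate-to-severe impairment)
#' and subjects flagged as not having completed the full physical
#' protocol. Removal counts are reported via `message()` and attached as
#' the `"exclusions"` attribute.
#'
#' @param subjects Subject tibble from [simulate_cohort()].
#' @return Filtered tibble with an `exclusions` attribute.
#' @export
apply_eligibility <- function(subjects) {
  stopifnot("mmse" %in% names(subjects))
  low_mmse <- subjects$mmse < 24
  incomplete <- !subjects$completed_protocol
  keep <- !low_mmse & !incomplete
  message(sprintf("eligibility: %d excluded for MMSE < 24, %d for incomplete protocol, %d retained",
                  sum(low_mmse), sum(incomplete & !low_mmse), sum(keep)))
  out <- subjects[keep, , drop = FALSE]
  attr(out, "exclusions") <- list(mmse = sum(low_mmse),
                                  incomplete = sum(incomplete & !low_mmse),
                                  retained = sum(keep))
  out
}

# ---- signal simulators -----------------------------------------------------

# Raised-cosine lobe sampled on the recording grid: peak velocity chosen so
# the analytic time-integral equals the requested excursion.
raised_cosine_lobe <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))

#' Simulate a tapping recording
#'
#' Generates 3 s of static baseline followed by `active_s` seconds of
#' self-paced tap cycles. Each cycle is a biphasic angular-velocity shape
#' on the flexion axis: a positive raised-cosine opening lobe whose
#' time-integral equals the cycle's excursion angle, followed by a
#' negative closing lobe of equal area, then a rest interval. Period and
#' excursion vary cycle to cycle. Accelerometer channels carry gravity
#' rotated through the integrated flexion angle plus a tangential
#' component from the angular acceleration and white noise; the vertical
#' axis reads 1 g in the rest pose.
#'
#' @param params List: `period_s`, `period_cycle_sd`, `excursion_deg`,
#'   `excursion_cycle_sd`, and optionally `duty_open`, `duty_close`
#'   (lobe fractions of the cycle, defaults 0.35/0.35 for FTAP and
#'   0.45/0.45 for TTHP), `fs` (100), `baseline_s` (3), `active_s` (15),
#'   `gyro_noise_dps`, `accel_noise_g`, `gyro_bias_dps` (length-3),
#'   `lever_arm_m` (0.08).
#' @param task `"FTAP"` or `"TTHP"`.
#' @param load Cognitive load level (metadata only at this level; load
#'   degradation is applied to `params` by the cohort generator).
#' @param seed Optional integer seed.
#' @param subject_id Identifier stored in the recording.
#' @return An `inertial_recording` with truth labels `n_taps`,
#'   `exc_deg`, `wo_dps`, `wc_dps`, `period_s`, `tap_start_s`.
#' @export
simulate_tapping_signal <- function(params, task = c("FTAP", "TTHP"),
                                    load = "CL0", seed = NULL,
                                    subject_id = "sim") {
  task <- match.arg(task)
  fs <- params$fs %||% 100
  baseline_s <- params$baseline_s %||% 3
  active_s <- params$active_s %||% 15
  duty_default <- if (task == "FTAP") 0.35 else 0.45
  duty_open <- params$duty_open %||% duty_default
  duty_close <- params$duty_close %||% duty_default
  stopifnot(params$period_s > 0, params$excursion_deg > 0,
            duty_open + duty_close <= 1)
  if (params$period_s * min(duty_open, duty_close) < 2 / fs) {
    stop("parameter error: tap lobes shorter than 2 samples at fs = ", fs)
  }
  with_seed(seed, {
    n <- round((baseline_s + active_s) * fs)
    t <- (seq_len(n) - 1) / fs
    v <- numeric(n)                       # movement-axis angular velocity
    exc <- wo <- wc <- per <- start_s <- numeric(0)
    cursor <- baseline_s
    end_t <- baseline_s + active_s
    repeat {
      Tk <- max(4 / fs,
                stats::rnorm(1, params$period_s, params$period_cycle_sd %||% 0))
      Ek <- max(0.5,
                stats::rnorm(1, params$excursion_deg,
                             params$excursion_cycle_sd %||% 0))
      d_open <- duty_open * Tk
      d_close <- duty_close * Tk
      if (cursor + d_open + d_close > end_t + 1e-9) break
      i0 <- round(cursor * fs) + 1
      n_open <- max(2, round(d_open * fs))
      n_close <- max(2, round(d_close * fs))
      if (i0 + n_open + n_close - 1 > n) break
      # integral of the sampled lobe is Ek by construction
      vp_open <- Ek * fs / sum(raised_cosine_lobe(n_open))
      vp_close <- Ek * fs / sum(raised_cosine_lobe(n_close))
      v[i0:(i0 + n_open - 1)] <- vp_open * raised_cosine_lobe(n_open)
      v[(i0 + n_open):(i0 + n_open + n_close - 1)] <-
        -vp_close * raised_cosine_lobe(n_close)
      exc <- c(exc, Ek); wo <- c(wo, vp_open); wc <- c(wc, vp_close)
      per <- c(per, Tk); start_s <- c(start_s, cursor)
      cursor <- cursor + Tk
      if (cursor + 1e-9 >= end_t) break
    }
    theta <- cumsum(v) / fs * pi / 180    # flexion angle, rad
    alpha <- c(0, diff(v)) * fs * pi / 180  # angular acceleration, rad/s^2
    lever <- params$lever_arm_m %||% 0.08
    bias <- params$gyro_bias_dps %||% c(0, 0, 0)
    g_noise <- params$gyro_noise_dps %||% 0
    a_noise <- params$accel_noise_g %||% 0
    accel <- cbind(
      sin(theta) + lever * alpha / 9.80665 + stats::rnorm(n, 0, a_noise),
      stats::rnorm(n, 0, a_noise),
      cos(theta) + stats::rnorm(n, 0, a_noise)
    )
    gyro <- cbind(bias[1] + stats::rnorm(n, 0, g_noise),
                  bias[2] + stats::rnorm(n, 0, g_noise),
                  v + bias[3] + stats::rnorm(n, 0, g_noise))
    inertial_recording(
      subject_id = subject_id, task = task, load = load, fs = fs, t = t,
      accel = accel, gyro = gyro, movement_axis = 3L,
      truth = list(n_taps = length(exc), exc_deg = exc, wo_dps = wo,
                   wc_dps = wc, period_s = per, tap_start_s = start_s,
                   baseline_s = baseline_s, active_s = active_s)
    )
  })
}

#' Simulate a 10-m walk recording
#'
#' Sagittal angular velocity of the instrumented foot as a piecewise
#' per-stride template: near-zero flat-foot stance followed by a single
#' dominant raised-cosine swing peak. The number of strides is
#' `ceiling(distance / stride_length)`; stride durations vary cycle to
#' cycle. Standing lead-in/lead-out transients bracket the walk.
#'
#' @param params List: `stride_length_m`, `stride_duration_s`, and
#'   optionally `duration_cycle_sd`, `swing_fraction` (0.38),
#'   `swing_peak_dps` (250), `distance_m` (10), `fs` (100),
#'   `lead_in_s`/`lead_out_s` (1.5/1.0), noise and bias as for tapping.
#' @param load Cognitive load level (metadata).
#' @param seed Optional integer seed.
#' @param subject_id Identifier stored in the recording.
#' @return An `inertial_recording` with truth labels `n_strides`,
#'   `stride_duration_s`, `stride_length_m`, `total_time_s`,
#'   `swing_peak_dps`, `swing_peak_t_s`.
#' @export
simulate_gait_signal <- function(params, load = "CL0", seed = NULL,
                                 subject_id = "sim") {
  fs <- params$fs %||% 100
  distance <- params$distance_m %||% 10
  stopifnot(params$stride_length_m > 0, params$stride_duration_s > 0)
  if (params$stride_length_m > distance) {
    warning("stride length exceeds walk distance: single-stride degenerate walk")
  }
  n_strides <- max(1L, as.integer(ceiling(distance / params$stride_length_m)))
  swing_frac <- params$swing_fraction %||% 0.38
  peak_dps <- params$swing_peak_dps %||% 250
  with_seed(seed, {
    dur <- pmax(0.4, stats::rnorm(n_strides, params$stride_duration_s,
                                  params$duration_cycle_sd %||% 0))
    lead_in <- params$lead_in_s %||% 1.5
    lead_out <- params$lead_out_s %||% 1.0
    total_s <- lead_in + sum(dur) + lead_out
    n <- round(total_s * fs)
    t <- (seq_len(n) - 1) / fs
    v <- numeric(n)
    peak_t <- peak_v <- numeric(n_strides)
    cursor <- lead_in
    for (k in seq_len(n_strides)) {
      stance <- (1 - swing_frac) * dur[k]
      swing <- swing_frac * dur[k]
      i0 <- round((cursor + stance) * fs) + 1
      n_sw <- max(4, round(swing * fs))
      idx <- i0:min(n, i0 + n_sw - 1)
      v[idx] <- peak_dps * raised_cosine_lobe(length(idx))
      peak_t[k] <- cursor + stance + swing / 2
      peak_v[k] <- max(v[idx])
      cursor <- cursor + dur[k]
    }
    bias <- params$gyro_bias_dps %||% c(0, 0, 0)
    g_noise <- params$gyro_noise_dps %||% 0
    a_noise <- params$accel_noise_g %||% 0
    # simple vertical bounce + forward speed fluctuation for the accel part
    step_freq <- 1 / mean(dur)
    walking <- t > lead_in & t < total_s - lead_out
    az <- 1 + 0.08 * sin(2 * pi * 2 * step_freq * t) * walking
    ax <- 0.05 * sin(2 * pi * step_freq * t) * walking
    accel <- cbind(ax + stats::rnorm(n, 0, a_noise),
                   stats::rnorm(n, 0, a_noise),
                   az + stats::rnorm(n, 0, a_noise))
    gyro <- cbind(bias[1] + stats::rnorm(n, 0, g_noise),
                  bias[2] + stats::rnorm(n, 0, g_noise),
                  v + bias[3] + stats::rnorm(n, 0, g_noise))
    inertial_recording(
      subject_id = subject_id, task = "GAIT", load = load, fs = fs, t = t,
      accel = accel, gyro = gyro, movement_axis = 3L,
      truth = list(n_strides = n_strides, stride_duration_s = dur,
                   stride_length_m = rep(distance / n_strides, n_strides),
                   total_time_s = sum(dur), distance_m = distance,
                   swing_peak_dps = peak_v, swing_peak_t_s = peak_t,
                   lead_in_s = lead_in, lead_out_s = lead_out)
    )
  })
}

#' Simulate counting-backwards correct answers
#'
#' Number of correct responses produced during one dual-task trial, drawn
#' from a Poisson distribution whose mean is the group x task x load
#' preset. Counting only happens under dual-task conditions, so `CL0` is
#' rejected.
#'
#' @param load `"CL1"`, `"CL2"` or `"CL3"`.
#' @param group `"CNA"` or `"MCI"`.
#' @param task Motor task the counting accompanies.
#' @param n Number of draws.
#' @param presets See [mcdt_presets()].
#' @param rate_mean Optional explicit mean, overriding the preset.
#' @param seed Optional integer seed.
#' @return Integer vector of non-negative counts.
#' @export
simulate_counting <- function(load, group = c("CNA", "MCI"),
                              task = c("FTAP", "TTHP", "GAIT"), n = 1,
                              presets = mcdt_presets(), rate_mean = NULL,
                              seed = NULL) {
  group <- match.arg(group)
  task <- match.arg(task)
  if (identical(load, "CL0")) {
    stop("correct answers are undefined at CL0 (no concurrent counting task)")
  }
  load <- match.arg(load, c("CL1", "CL2", "CL3"))
  mu <- rate_mean %||% unname(presets[[group]]$correct_answers[[task]][load])
  stopifnot(is.finite(mu), mu >= 0)
  with_seed(seed, stats::rpois(n, mu))
}

# One subject's motor profile, drawn from the group's between-subject
# distributions. The same profile applies at every load (a slow tapper is
# slow under every counting load), which is what makes dual-task costs
# meaningful within subject.
draw_subject_motor <- function(presets_group) {
  p <- presets_group
  prof <- list()
  for (task in c("FTAP", "TTHP")) {
    b <- p$tapping[[task]]
    cv <- b$period_subject_cv %||% 0
    prof[[task]] <- list(
      # lognormal slowing factor, mean-one on the tap-rate (1/period)
      # scale so group mean tap counts sit at the configured rates
      period_factor = exp(stats::rnorm(1, cv^2 / 2, cv)),
      excursion_deg = rnorm_trunc(1, b$excursion_deg,
                                  b$excursion_subject_sd %||% 0,
                                  lower = 0.25 * b$excursion_deg),
      excursion_cycle_sd = rnorm_trunc(1, b$excursion_cycle_sd,
                                       b$excursion_cycle_sd_sd %||% 0,
                                       lower = 0.2)
    )
  }
  g <- p$gait
  prof$gait <- list(
    length_factor = rnorm_trunc(1, 1, (g$stride_length_subject_sd %||% 0) /
                                  g$stride_length_m["CL0"], lower = 0.4),
    duration_factor = rnorm_trunc(1, 1, (g$stride_duration_subject_sd %||% 0) /
                                    g$stride_duration_s["CL0"], lower = 0.5),
    swing_peak_dps = rnorm_trunc(1, g$swing_peak_dps,
                                 g$swing_peak_subject_sd %||% 0, lower = 80)
  )
  prof
}

# Per-subject, per-load effective tapping parameters.
tapping_params_for <- function(config, group, task, load, profile) {
  p <- config$presets[[group]]
  base <- p$tapping[[task]]
  m <- p$load_mult
  pr <- profile[[task]]
  list(period_s = base$period_s * pr$period_factor * m$period[load],
       period_cycle_sd = base$period_cycle_sd * m$variability[load],
       excursion_deg = pr$excursion_deg * m$amplitude[load],
       excursion_cycle_sd = pr$excursion_cycle_sd * m$variability[load],
       fs = config$fs, gyro_noise_dps = config$gyro_noise_dps,
       accel_noise_g = config$accel_noise_g)
}

gait_params_for <- function(config, group, load, profile) {
  p <- config$presets[[group]]$gait
  mvar <- config$presets[[group]]$load_mult$variability[load]
  pr <- profile$gait
  list(stride_length_m = p$stride_length_m[load] * pr$length_factor,
       stride_duration_s = p$stride_duration_s[load] * pr$duration_factor,
       duration_cycle_sd = p$duration_cycle_sd * mvar,
       swing_peak_dps = pr$swing_peak_dps,
       distance_m = config$gait_distance_m, fs = config$fs,
       gyro_noise_dps = config$gyro_noise_dps,
       accel_noise_g = config$accel_noise_g)
}

#' Simulate a full study cohort
#'
#' Draws subject metadata for `n_cna` + `n_mci` subjects (MCI subjects
#' older and with lower MMSE by construction) and, for every subject that
#' completes the protocol, one recording per motor task and cognitive
#' load (3 x 4 = 12 recordings), with correct-answer counts attached to
#' dual-task recordings. Fully reproducible from the configuration seed.
#'
#' @param config A [generator_config()].
#' @param signals Generate the IMU streams (default). With `FALSE` only
#'   the subject metadata table is drawn (identical to the full run),
#'   which is convenient for demographic-scale checks.
#' @return List with `subjects` (tibble) and `recordings` (named list of
#'   `inertial_recording`, keys `"<subject_id>_<task>_<load>"`).
#' @export
simulate_cohort <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  n_total <- config$n_cna + config$n_mci
  groups <- rep(c("CNA", "MCI"), c(config$n_cna, config$n_mci))
  if (n_total == 0) {
    return(list(subjects = empty_subject_table(), recordings = list()))
  }
  subjects <- with_seed(config$seed, {
    rows <- lapply(seq_len(n_total), function(i) {
      p <- config$presets[[groups[i]]]
      edu <- sample(names(p$education_prob), 1, prob = p$education_prob)
      fr_cat <- sample(names(p$frailty_prob), 1, prob = p$frailty_prob)
      fried <- switch(fr_cat, not_frail = 0L,
                      pre_frail = sample(1:2, 1),
                      frail = sample(3:5, 1))
      tibble::tibble(
        subject_id = sprintf("S%03d", i),
        group = groups[i],
        age = round(rnorm_trunc(1, p$age$mean, p$age$sd, p$age$min, p$age$max), 1),
        sex = sample(c("F", "M"), 1, prob = c(p$sex_f_prob, 1 - p$sex_f_prob)),
        stature = round(rnorm_trunc(1, p$stature$mean, p$stature$sd,
                                    p$stature$min, p$stature$max), 1),
        bmi = round(rnorm_trunc(1, p$bmi$mean, p$bmi$sd, p$bmi$min, p$bmi$max), 1),
        education = edu,
        mmse = as.integer(round(rnorm_trunc(1, p$mmse$mean, p$mmse$sd,
                                            p$mmse$min - 0.49, p$mmse$max + 0.49))),
        fried_positive = fried,
        completed_protocol = stats::runif(1) >= config$dropout_prob
      )
    })
    dplyr::bind_rows(rows)
  })
  subjects$mmse <- pmin(pmax(subjects$mmse, 0L), 30L)
  if (!signals) return(list(subjects = subjects, recordings = list()))

  recordings <- list()
  for (i in seq_len(n_total)) {
    if (!subjects$completed_protocol[i]) next
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    profile <- with_seed(child_seed(config$seed, i, 55),
                         draw_subject_motor(config$presets[[grp]]))
    for (task in mcdt_tasks()) {
      for (load in mcdt_loads()) {
        s <- child_seed(config$seed, i, match(task, mcdt_tasks()),
                        match(load, mcdt_loads()))
        bias <- with_seed(child_seed(s, 99),
                          stats::rnorm(3, 0, config$gyro_bias_sd_dps))
        rec <- if (task == "GAIT") {
          prm <- gait_params_for(config, grp, load, profile)
          prm$gyro_bias_dps <- bias
          simulate_gait_signal(prm, load = load, seed = s, subject_id = sid)
        } else {
          prm <- tapping_params_for(config, grp, task, load, profile)
          prm$gyro_bias_dps <- bias
          simulate_tapping_signal(prm, task = task, load = load, seed = s,
                                  subject_id = sid)
        }
        if (load != "CL0") {
          rec$truth$correct_answers <-
            simulate_counting(load, grp, task, n = 1,
                              presets = config$presets,
                              seed = child_seed(s, 7))
        }
        recordings[[paste(sid, task, load, sep = "_")]] <- rec
      }
    }
  }
  list(subjects = subjects, recordings = recordings)
}

empty_subject_table <- function() {
  tibble::tibble(subject_id = character(), group = character(),
                 age = numeric(), sex = character(), stature = numeric(),
                 bmi = numeric(), education = character(), mmse = integer(),
                 fried_positive = integer(), completed_protocol = logical())
}
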