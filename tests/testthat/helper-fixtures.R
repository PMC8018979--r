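# Shared fixtures: noiseless simulator parameter sets and hand-built
# recordings, all generated in code at test time.

noiseless_tap_params <- function(period_s = 1.0, excursion_deg = 30,
                                 n_target = NULL, ...) {
  if (!is.null(n_target)) period_s <- 15 / n_target
  utils::modifyList(
    list(period_s = period_s, period_cycle_sd = 0,
         excursion_deg = excursion_deg, excursion_cycle_sd = 0,
         gyro_noise_dps = 0, accel_noise_g = 0),
    list(...))
}

noiseless_gait_params <- function(stride_length_m = 2.0,
                                  stride_duration_s = 1.2, ...) {
  utils::modifyList(
    list(stride_length_m = stride_length_m,
         stride_duration_s = stride_duration_s, duration_cycle_sd = 0,
         gyro_noise_dps = 0, accel_noise_g = 0),
    list(...))
}

# Recording built directly from channel vectors (defaults: rest pose with
# gravity on the vertical axis, silent gyro).
make_recording <- function(n = 1800, fs = 100, gz = numeric(n),
                           ax = numeric(n), ay = numeric(n),
                           az = rep(1, n), task = "FTAP", load = "CL0",
                           baseline = NULL) {
  inertial_recording(subject_id = "T", task = task, load = load, fs = fs,
                     t = (seq_len(n) - 1) / fs,
                     accel = cbind(ax, ay, az),
                     gyro = cbind(numeric(n), numeric(n), gz),
                     movement_axis = 3L, baseline = baseline)
}

# Small cohort shared across test files (built once per test run).
.small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.small_cohort_cache$cohort)) {
    .small_cohort_cache$cohort <-
      simulate_cohort(generator_config(n_cna = 6, n_mci = 5, seed = 42))
  }
  .small_cohort_cache$cohort
}
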