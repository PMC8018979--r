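#' Inertial recording container
#'
#' A single 6-axis IMU stream (tri-axial accelerometer in g, tri-axial
#' gyroscope in deg/s) for one subject, one motor task and one cognitive
#' load, sampled uniformly at `fs` Hz. The `movement_axis` names the
#' gyroscope channel orthogonal to the movement plane: tap flexion/extension
#' and gait sagittal rotation both live on a single angular-velocity
#' channel in this convention.
#'
#' @param subject_id Opaque subject identifier.
#' @param task One of `"FTAP"`, `"TTHP"`, `"GAIT"`.
#' @param load Cognitive load level, one of `"CL0"`..`"CL3"`.
#' @param fs Sampling frequency in Hz.
#' @param t Numeric vector of sample times in seconds, uniformly spaced.
#' @param accel n x 3 matrix of accelerations in g (columns ax, ay, az).
#' @param gyro n x 3 matrix of angular velocities in deg/s (gx, gy, gz).
#' @param movement_axis Column index (1-3) of the movement gyroscope axis.
#' @param truth Optional list of generator ground-truth labels.
#' @param baseline Optional list describing the removed static baseline.
#'
#' @return An object of class `inertial_recording`.
#' @export
inertial_recording <- function(subject_id, task, load, fs, t, accel, gyro,
                               movement_axis = 3L, truth = NULL,
                               baseline = NULL) {
  task <- match.arg(task, mcdt_tasks())
  load <- match.arg(load, mcdt_loads())
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  stopifnot(is.numeric(fs), fs > 0, length(t) == nrow(accel),
            nrow(accel) == nrow(gyro), ncol(accel) == 3, ncol(gyro) == 3)
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(abs(dt - 1 / fs) > 1e-6)) {
      bad <- which(abs(dt - 1 / fs) > 1e-6)[1]
      stop("non-uniform sampling at index ", bad + 1,
           " (expected dt = ", 1 / fs, ", got ", dt[bad], ")")
    }
  }
  colnames(accel) <- c("ax_g", "ay_g", "az_g")
  colnames(gyro) <- c("gx_dps", "gy_dps", "gz_dps")
  structure(
    list(subject_id = as.character(subject_id), task = task, load = load,
         fs = fs, t = as.numeric(t), accel = accel, gyro = gyro,
         movement_axis = as.integer(movement_axis), truth = truth,
         baseline = baseline),
    class = "inertial_recording"
  )
}

#' @export
print.inertial_recording <- function(x, ...) {
  cat(sprintf("<inertial_recording> %s %s %s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$task, x$load, length(x$t), x$fs,
              length(x$t) / x$fs))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `inertial_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$t)

#' Movement-axis angular velocity
#' @param rec An `inertial_recording`.
#' @return Numeric vector, deg/s.
#' @export
movement_velocity <- function(rec) rec$gyro[, rec$movement_axis]

#' Task and load level sets
#'
#' `mcdt_tasks()` returns the three motor tasks (fore-finger tapping,
#' toe-tapping with pinned heel, 10-m walk); `mcdt_loads()` the four
#' cognitive-load levels and `load_decrement()` the counting-backwards
#' decrement attached to each (0, 1, 3, 7).
#'
#' @return Character vector of levels, or a named integer vector for
#'   `load_decrement()`.
#' @export
mcdt_tasks <- function() c("FTAP", "TTHP", "GAIT")

#' @rdname mcdt_tasks
#' @export
mcdt_loads <- function() c("CL0", "CL1", "CL2", "CL3")

#' @rdname mcdt_tasks
#' @param load Load level(s), e.g. `"CL2"`.
#' @export
load_decrement <- function(load) {
  dec <- c(CL0 = 0L, CL1 = 1L, CL2 = 3L, CL3 = 7L)
  out <- dec[load]
  if (anyNA(out)) stop("unknown cognitive load: ", paste(load[is.na(out)], collapse = ", "))
  out
}

#' Write / read a recording as CSV plus a JSON truth sidecar
#'
#' The on-disk dialect is a plain CSV with columns
#' `t_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps` and a sidecar
#' `<path>.meta.json` holding task, load, sampling rate, movement axis and
#' any ground-truth labels. `read_recording()` validates the header,
#' checks uniform sampling and compares the inferred rate to the declared
#' one.
#'
#' @param rec An `inertial_recording`.
#' @param path CSV file path.
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns an `inertial_recording`.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(t_s = rec$t, rec$accel, rec$gyro, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, task = rec$task, load = rec$load,
               fs = rec$fs, movement_axis = rec$movement_axis,
               truth = rec$truth, baseline = rec$baseline)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such recording file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  want <- c("t_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0) {
    stop("recording schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  t <- df$t_s
  dt <- diff(t)
  if (any(abs(dt - stats::median(dt)) > 1e-6)) {
    bad <- which(abs(dt - stats::median(dt)) > 1e-6)[1]
    stop("non-uniform timestamps at index ", bad + 1)
  }
  fs_inferred <- 1 / stats::median(dt)
  fs <- meta$fs %||% fs_inferred
  if (abs(fs_inferred - fs) > 0.01 * fs) {
    stop("declared sampling rate ", fs, " Hz does not match inferred ",
         signif(fs_inferred, 6), " Hz")
  }
  inertial_recording(
    subject_id = meta$subject_id %||% "unknown",
    task = meta$task %||% "FTAP",
    load = meta$load %||% "CL0",
    fs = fs, t = t,
    accel = as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
    gyro = as.matrix(df[, c("gx_dps", "gy_dps", "gz_dps")]),
    movement_axis = meta$movement_axis %||% 3L,
    truth = meta$truth, baseline = meta$baseline
  )
}
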