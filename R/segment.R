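# Segmentation of conditioned recordings into tap cycles and gait strides.
# All indices are 1-based sample positions into the recording passed in;
# serialization to JSON converts to the 0-based half-open convention.

# Contiguous runs where `cond` is TRUE, as a 2-column matrix [start, end].
runs_where <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# Expand an above-threshold run outward to where the signal leaves the
# stated sign (i.e. to the zero crossings bounding the lobe). Noise can
# split one lobe into several above-threshold runs; after expansion those
# collapse onto identical intervals and are de-duplicated.
expand_to_sign <- function(v, run, positive) {
  s <- run[1]; e <- run[2]
  keep <- if (positive) function(i) v[i] > 0 else function(i) v[i] < 0
  while (s > 1 && keep(s - 1)) s <- s - 1
  while (e < length(v) && keep(e + 1)) e <- e + 1
  c(s, e)
}

lobe_intervals <- function(v, thr, positive) {
  cond <- if (positive) v > thr else v < -thr
  if (!any(cond)) return(matrix(numeric(0), ncol = 2))
  runs <- runs_where(cond)
  ivs <- t(apply(runs, 1, expand_to_sign, v = v, positive = positive))
  unique(ivs)
}

#' Segment a tapping recording into tap cycles
#'
#' A tap cycle is one positive (opening) lobe of the movement-axis
#' angular velocity followed by its paired negative (closing) lobe.
#' Lobes are located as excursions beyond an amplitude threshold relative
#' to the recording's peak absolute velocity, then expanded to their
#' bounding zero crossings. An opening lobe with no closing lobe before
#' the next opening (an incomplete trailing cycle) is discarded.
#'
#' @param rec A filtered, baseline-removed FTAP/TTHP recording.
#' @param min_rel_amplitude Amplitude threshold as a fraction of the
#'   recording's peak absolute movement-axis velocity (default 0.1).
#' @return Tibble with one row per tap: `open_start`, `open_end`,
#'   `close_end` (1-based inclusive sample indices,
#'   `open_start < open_end <= close_end`), `peak_opening_velocity`,
#'   `peak_closing_velocity` (magnitude of the negative lobe, deg/s) and
#'   `excursion` (trapezoidal integral of the opening lobe, deg).
#' @export
segment_taps <- function(rec, min_rel_amplitude = 0.1) {
  stopifnot(inherits(rec, "inertial_recording"))
  v <- movement_velocity(rec)
  peak <- max(abs(v))
  empty <- tibble::tibble(open_start = integer(), open_end = integer(),
                          close_end = integer(),
                          peak_opening_velocity = numeric(),
                          peak_closing_velocity = numeric(),
                          excursion = numeric())
  if (peak == 0) {
    warning("no movement detected: flat movement-axis channel")
    return(empty)
  }
  thr <- min_rel_amplitude * peak
  pos <- lobe_intervals(v, thr, positive = TRUE)
  neg <- lobe_intervals(v, thr, positive = FALSE)
  if (nrow(pos) == 0) {
    warning("no lobe above the amplitude threshold")
    return(empty)
  }
  dt <- 1 / rec$fs
  rows <- vector("list", nrow(pos))
  for (k in seq_len(nrow(pos))) {
    os <- pos[k, 1]; oe <- pos[k, 2]
    next_open <- if (k < nrow(pos)) pos[k + 1, 1] else Inf
    cand <- which(neg[, 1] >= oe & neg[, 1] < next_open)
    if (length(cand) == 0) next  # unpaired opening lobe: dropped
    ce <- neg[cand[1], 2]
    seg <- v[os:oe]
    # trapezoidal integral of the opening lobe; lobe edges sit at zero
    exc <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt
    rows[[k]] <- tibble::tibble(
      open_start = os, open_end = oe, close_end = ce,
      peak_opening_velocity = max(seg),
      peak_closing_velocity = abs(min(v[neg[cand[1], 1]:ce])),
      excursion = exc)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    warning("no complete opening-closing cycle found")
    return(empty)
  }
  out
}

#' Segment a gait recording into strides
#'
#' Strides are anchored on mid-swing peaks of the movement-axis angular
#' velocity (one dominant peak per gait cycle); peaks must exceed a
#' velocity threshold and be separated by a minimum interval. Stride
#' boundaries are placed midway between consecutive swing peaks (half the
#' median inter-peak interval beyond the first/last peak at the ends), so
#' each detected stride contains exactly one swing peak. First and last
#' detected strides are removed by default to discard the acceleration
#' and deceleration phases of the straight walk.
#'
#' @param rec A filtered GAIT recording.
#' @param drop_first_last Drop first and last detected strides (default
#'   TRUE).
#' @param peak_threshold_dps Minimum swing-peak angular velocity, deg/s
#'   (default 50; the template rests near zero in stance, so peak height
#'   and prominence coincide).
#' @param min_separation_s Minimum inter-peak separation, s (default 0.5).
#' @return Tibble with one row per retained stride: `start`, `end`
#'   (sample indices, duration = (end - start) / fs), `duration`,
#'   `peak_index`, `swing_peak_velocity`. The attribute `n_detected`
#'   carries the count before endpoint removal.
#' @export
segment_strides <- function(rec, drop_first_last = TRUE,
                            peak_threshold_dps = 50, min_separation_s = 0.5) {
  stopifnot(inherits(rec, "inertial_recording"))
  v <- movement_velocity(rec)
  pk <- pracma::findpeaks(v, minpeakheight = peak_threshold_dps,
                          minpeakdistance = max(1, round(min_separation_s * rec$fs)))
  if (is.null(pk)) stop("no swing peaks above ", peak_threshold_dps, " deg/s")
  peaks <- sort(pk[, 2])
  n_detected <- length(peaks)
  gap <- if (n_detected > 1) stats::median(diff(peaks)) else round(rec$fs)
  mids <- if (n_detected > 1) {
    round((peaks[-1] + peaks[-n_detected]) / 2)
  } else {
    integer(0)
  }
  starts <- c(max(1L, peaks[1] - round(gap / 2)), mids)
  ends <- c(mids, min(length(v), peaks[n_detected] + round(gap / 2)))
  seg <- tibble::tibble(start = as.integer(starts), end = as.integer(ends),
                        duration = (ends - starts) / rec$fs,
                        peak_index = as.integer(peaks),
                        swing_peak_velocity = v[peaks])
  if (drop_first_last) {
    if (n_detected < 3) {
      stop("fewer than 3 detected strides: nothing left after dropping ",
           "first and last")
    }
    seg <- seg[-c(1, nrow(seg)), , drop = FALSE]
  }
  attr(seg, "n_detected") <- n_detected
  seg
}

#' Serialize segments to the 0-based half-open JSON convention
#'
#' @param segments A segment tibble from [segment_taps()] or
#'   [segment_strides()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- as.list(segments)
  for (col in intersect(names(out), c("open_start", "start"))) {
    out[[col]] <- out[[col]] - 1L           # 0-based start
  }
  # inclusive ends become exclusive under the half-open convention
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
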