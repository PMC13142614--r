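#' Sensor speed from position traces
#'
#' Central-difference velocity per axis (one-sided at the ends) and the
#' Euclidean norm across x, y, z per sensor.
#'
#' @param trace an `msom_kinematics` object.
#' @return object of class `msom_speed`: `time_s`, `speed` (sensor x time,
#'   m/s), `sensor_labels`.
#' @export
sensor_speed <- function(trace) {
  n <- length(trace$time_s)
  if (n < 3) stopf("need at least three time samples")
  tt <- trace$time_s
  ns <- length(trace$sensor_labels)
  speed <- matrix(0, ns, n, dimnames = list(trace$sensor_labels, NULL))
  for (s in seq_len(ns)) {
    v2 <- numeric(n)
    for (a in 1:3) {
      p <- trace$positions[s, a, ]
      v <- numeric(n)
      v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
      v[1] <- (p[2] - p[1]) / (tt[2] - tt[1])
      v[n] <- (p[n] - p[n - 1]) / (tt[n] - tt[n - 1])
      v2 <- v2 + v^2
    }
    speed[s, ] <- sqrt(v2)
  }
  structure(list(time_s = tt, speed = speed,
                 sensor_labels = trace$sensor_labels),
            class = "msom_speed")
}

# aggregate speed over selected sensors (max by default)
aggregate_speed <- function(speed, sensors = NULL) {
  m <- speed$speed
  if (!is.null(sensors)) m <- m[sensors, , drop = FALSE]
  apply(m, 2, max)
}

#' Detect movement bounds around cues
#'
#' For each cue: finds the first speed peak after the cue (a local maximum
#' above the noise floor, 5x the median absolute speed of the whole trace),
#' then traces backward and forward to the last/first crossing of
#' `threshold_fraction` times the peak speed. Cues with no qualifying peak
#' are returned with a `no_movement` flag rather than an error.
#'
#' @param speed an `msom_speed` (aggregated over `sensors`, max rule).
#' @param cue_times visual-cue times (s).
#' @param threshold_fraction onset/offset threshold as a fraction of peak
#'   speed, in (0, 1).
#' @param sensors optional sensor subset.
#' @param max_latency_s how far after the cue to search for the peak.
#' @return data.frame: `cue_t`, `onset_t`, `peak_t`, `offset_t`,
#'   `no_movement`.
#' @export
detect_movement_bounds <- function(speed, cue_times, threshold_fraction = 0.1,
                                   sensors = NULL, max_latency_s = 2) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stopf("threshold_fraction must be in (0, 1)")
  v <- aggregate_speed(speed, sensors)
  tt <- speed$time_s
  n <- length(v)
  floor_v <- 5 * median(abs(v))
  out <- lapply(cue_times, function(cue) {
    if (cue < tt[1] || cue > tt[n]) stopf("cue outside the trace")
    i0 <- which(tt >= cue)[1]
    imax <- max(which(tt <= cue + max_latency_s))
    peak <- NA_integer_
    for (i in max(i0, 2):min(imax, n - 1)) {
      if (v[i] >= v[i - 1] && v[i] >= v[i + 1] && v[i] > floor_v) {
        peak <- i; break
      }
    }
    if (is.na(peak))
      return(data.frame(cue_t = cue, onset_t = NA_real_, peak_t = NA_real_,
                        offset_t = NA_real_, no_movement = TRUE))
    thr <- threshold_fraction * v[peak]
    below_before <- which(v[seq_len(peak - 1)] < thr)
    onset <- if (length(below_before)) tt[max(below_before)] else tt[1]
    after <- peak + which(v[(peak + 1):n] < thr)
    offset <- if (length(after)) tt[min(after)] else tt[n]
    data.frame(cue_t = cue, onset_t = onset, peak_t = tt[peak],
               offset_t = offset, no_movement = FALSE)
  })
  do.call(rbind, out)
}

#' Apply manually corrected movement bounds
#'
#' Deterministic onset detection replaces the manual verification used with
#' real recordings; corrections are supplied as an override table (TSV with
#' columns `trial_id`, `onset_s`, `offset_s`) whose rows replace the
#' detected bounds of the matching trials.
#'
#' @param trials trial table with `trial`, `onset_t`, `offset_t`.
#' @param override data.frame or TSV path with `trial_id`, `onset_s`,
#'   `offset_s`.
#' @return the trial table with overridden bounds.
#' @export
apply_bounds_override <- function(trials, override) {
  if (is.character(override)) override <- read_tsv(override)
  for (i in seq_len(nrow(override))) {
    j <- which(trials$trial == override$trial_id[i])
    if (!length(j)) stopf("override refers to unknown trial %s",
                          override$trial_id[i])
    if (override$onset_s[i] >= override$offset_s[i])
      stopf("override for trial %s has onset >= offset",
            override$trial_id[i])
    trials$onset_t[j] <- override$onset_s[i]
    trials$offset_t[j] <- override$offset_s[i]
  }
  trials
}

#' Velocity-based trial exclusion
#'
#' Applies the two 4-standard-deviation rules with statistics pooled across
#' all supplied trials: (1) hand speed in the baseline part of the trial
#' epoch (before -250 ms or after +750 ms relative to onset) exceeding the
#' pooled baseline mean + 4 SD marks extraneous movement
#' (`baseline_velocity`); (2) the magnitude of the hand-wrist speed
#' difference inside (-250, +750) ms exceeding its pooled mean + 4 SD marks
#' excessive arm movement (`arm_velocity`). With zero pooled SD the
#' threshold equals the mean and the strict `>` excludes nothing. Excluded
#' trials are flagged, not dropped: they remain usable for decoding.
#'
#' @param trials trial table with `onset_t`.
#' @param hand_speed,wrist_speed `msom_speed` objects (single aggregated
#'   sensor each) covering every trial's +/- 2 s epoch.
#' @param epoch_s half-width of the trial epoch (s).
#' @return the trial table with updated `excluded` / `exclusion_reason`.
#' @export
exclude_trials <- function(trials, hand_speed, wrist_speed, epoch_s = 2) {
  tt <- hand_speed$time_s
  hv <- aggregate_speed(hand_speed)
  wv <- aggregate_speed(wrist_speed)
  if (!isTRUE(all.equal(tt, wrist_speed$time_s)))
    stopf("hand and wrist speeds must share a time base")
  base_idx <- list(); move_idx <- list()
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_t[i]
    if (on - epoch_s < tt[1] - 1e-9 || on + epoch_s > tt[length(tt)] + 1e-9)
      stopf("trial %d epoch extends beyond the kinematic trace", i)
    ep <- which(tt >= on - epoch_s & tt <= on + epoch_s)
    rel <- tt[ep] - on
    base_idx[[i]] <- ep[rel < -0.25 | rel > 0.75]
    move_idx[[i]] <- ep[rel >= -0.25 & rel <= 0.75]
  }
  base_pool <- hv[unlist(base_idx)]
  diff_pool <- abs(hv - wv)[unlist(move_idx)]
  thr1 <- mean(base_pool) + 4 * sd(base_pool)
  thr2 <- mean(diff_pool) + 4 * sd(diff_pool)
  if (is.na(thr1)) thr1 <- mean(base_pool)
  if (is.na(thr2)) thr2 <- mean(diff_pool)
  trials$excluded <- FALSE
  trials$exclusion_reason <- "none"
  for (i in seq_len(nrow(trials))) {
    if (any(hv[base_idx[[i]]] > thr1)) {
      trials$excluded[i] <- TRUE
      trials$exclusion_reason[i] <- "baseline_velocity"
    } else if (any(abs(hv - wv)[move_idx[[i]]] > thr2)) {
      trials$excluded[i] <- TRUE
      trials$exclusion_reason[i] <- "arm_velocity"
    }
  }
  trials
}

#' Rest-segment derivation for self-paced sessions
#'
#' Greedy left-to-right selection of `duration_s` windows in which the
#' max-over-sensors speed stays at or below the 1st percentile of that
#' statistic over the full recording, each window at least
#' `min_gap_to_movement_s` away from any detected movement interval and at
#' least `min_separation_s` after the previously accepted window.
#'
#' @param speed an `msom_speed`.
#' @param movements optional 2-column matrix of movement (onset, offset)
#'   intervals to stay clear of.
#' @param duration_s rest window length.
#' @param percentile speed percentile defining "quiet" (0-100).
#' @param min_gap_to_movement_s,min_separation_s spacing rules (s).
#' @return 2-column matrix of (start, end) rest windows; zero rows (with a
#'   warning) when nothing qualifies.
#' @export
find_rest_segments <- function(speed, movements = NULL, duration_s = 0.5,
                               percentile = 1, min_gap_to_movement_s = 1.0,
                               min_separation_s = 0.5) {
  tt <- speed$time_s
  if (tt[length(tt)] - tt[1] < duration_s)
    stopf("trace shorter than one rest window")
  v <- aggregate_speed(speed)
  thr <- quantile(v, percentile / 100, names = FALSE)
  quiet <- v <= thr + 1e-15
  dt <- median(diff(tt))
  wlen <- round(duration_s / dt)
  ok_start <- function(i) {
    j <- i + wlen
    if (j > length(tt)) return(FALSE)
    if (!all(quiet[i:j])) return(FALSE)
    if (!is.null(movements) && nrow(movements) > 0) {
      a <- tt[i]; b <- tt[j]
      gaps <- pmax(movements[, 1] - b, a - movements[, 2])
      if (any(gaps < min_gap_to_movement_s)) return(FALSE)
    }
    TRUE
  }
  starts <- numeric(0); ends <- numeric(0)
  i <- 1L
  last_end <- -Inf
  while (i + wlen <= length(tt)) {
    if (tt[i] >= last_end + min_separation_s - 1e-9 && ok_start(i)) {
      starts <- c(starts, tt[i]); ends <- c(ends, tt[i + wlen])
      last_end <- tt[i + wlen]
      i <- i + wlen
    } else {
      i <- i + 1L
    }
  }
  if (!length(starts)) {
    warning("no qualifying rest windows found")
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  }
  cbind(start_s = starts, end_s = ends)
}
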