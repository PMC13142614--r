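make_trace <- function(pos_fun, fs = 100, dur = 10, sensors = "hand") {
  tt <- seq(0, dur, by = 1 / fs)
  pos <- array(0, dim = c(length(sensors), 3, length(tt)),
               dimnames = list(sensors, c("x", "y", "z"), NULL))
  for (s in seq_along(sensors)) {
    p <- pos_fun(tt, sensors[s])
    for (a in 1:3) pos[s, a, ] <- p[[a]]
  }
  structure(list(time_s = tt, positions = pos, sensor_labels = sensors),
            class = "msom_kinematics")
}

test_that("sensor speed is the Euclidean norm of the velocity", {
  tr <- make_trace(function(tt, s) list(3e-3 * tt, 4e-3 * tt, 0 * tt))
  sp <- sensor_speed(tr)
  expect_equal(unname(sp$speed[1, ]), rep(5e-3, length(tr$time_s)),
               tolerance = 1e-9)                       # 3-4-5 norm
  tr0 <- make_trace(function(tt, s) list(tt * 0 + 1, tt * 0, tt * 0))
  expect_true(all(sensor_speed(tr0)$speed == 0))
  short <- make_trace(function(tt, s) list(tt, tt, tt), dur = 0.01)
  expect_error(sensor_speed(short), "three")
})

test_that("movement bounds bracket the first post-cue peak", {
  sch <- make_gesture_schedule(6, seed = 2)
  kin <- simulate_kinematics(sch, noise_amp = 0, seed = 3,
                             sample_rate_hz = 200)
  sp <- sensor_speed(kin)
  b <- detect_movement_bounds(sp, sch$visual_cue_t, threshold_fraction = 0.1)
  expect_false(any(b$no_movement))
  # noiseless minimum-jerk: recovered bounds within ~ the 10% threshold
  # crossing of the planted profile (tau where v = 0.1 v_peak)
  expect_true(all(abs(b$onset_t - sch$onset_t) < 0.06))
  expect_true(all(abs(b$offset_t - sch$offset_t) < 0.06))
  expect_true(all(b$onset_t < b$peak_t & b$peak_t < b$offset_t))
})

test_that("flat traces yield a no-movement flag, not an error", {
  tr <- make_trace(function(tt, s) list(tt * 0, tt * 0, tt * 0))
  sp <- sensor_speed(tr)
  b <- detect_movement_bounds(sp, cue_times = 2)
  expect_true(b$no_movement)
})

test_that("bounds anchor to the first of two post-cue peaks", {
  tt <- seq(0, 10, by = 0.01)
  v <- numeric(length(tt))
  pk1 <- tt > 3 & tt < 3.4
  pk2 <- tt > 5 & tt < 5.4
  v[pk1] <- sin(pi * (tt[pk1] - 3) / 0.4)
  v[pk2] <- 2 * sin(pi * (tt[pk2] - 5) / 0.4)
  # build a trace whose x-position integrates this speed profile
  tr <- make_trace(function(ttt, s) list(cumsum(v) * 0.01, ttt * 0, ttt * 0))
  sp <- sensor_speed(tr)
  b <- detect_movement_bounds(sp, cue_times = 2, threshold_fraction = 0.1)
  expect_lt(abs(b$peak_t - 3.2), 0.05)
  expect_lt(b$offset_t, 4)
})

test_that("4-SD exclusion rules flag outlier trials and keep quiet ones", {
  fs <- 100
  n_tr <- 50
  onsets <- seq(5, 5 + 3 * (n_tr - 1), by = 3)
  dur <- max(onsets) + 5
  tt <- seq(0, dur, by = 1 / fs)
  # smooth low-amplitude speeds (iid noise would trip the any-sample rule)
  hand <- 0.01 + 1e-4 * sin(2 * pi * 0.2 * tt)
  wrist <- 0.01 + 1e-4 * cos(2 * pi * 0.25 * tt)
  # trial 7: large hand speed in its baseline (1.5 s before onset)
  bad <- tt > onsets[7] - 1.6 & tt < onsets[7] - 1.1
  hand[bad] <- 0.5
  mk <- function(v) structure(list(time_s = tt,
                                   speed = matrix(v, 1,
                                                  dimnames = list("s", NULL)),
                                   sensor_labels = "s"),
                              class = "msom_speed")
  trials <- data.frame(trial = seq_len(n_tr), onset_t = onsets)
  out <- exclude_trials(trials, mk(hand), mk(wrist))
  expect_true(out$excluded[7])
  expect_equal(out$exclusion_reason[7], "baseline_velocity")
  # the burst also sits in the tail of trial 6's +/- 2 s epoch
  expect_equal(which(out$excluded), c(6, 7))
  # excluded trials are retained in the table (usable for decoding)
  expect_equal(nrow(out), n_tr)
  # all-identical quiet trials: SD = 0, strict > excludes none
  h0 <- mk(rep(0.01, length(tt))); w0 <- mk(rep(0.01, length(tt)))
  out0 <- exclude_trials(trials, h0, w0)
  expect_false(any(out0$excluded))
  # arm rule: hand-wrist divergence inside the movement window
  hand2 <- rep(0.01, length(tt)); wrist2 <- rep(0.01, length(tt))
  mv <- tt > onsets[3] & tt < onsets[3] + 0.5
  hand2[mv] <- 0.4
  out2 <- exclude_trials(trials, mk(hand2), mk(wrist2))
  expect_true(out2$excluded[3])
  expect_equal(out2$exclusion_reason[3], "arm_velocity")
})

test_that("override tables replace detected bounds", {
  trials <- data.frame(trial = 1:3, onset_t = c(1, 4, 7),
                       offset_t = c(1.5, 4.5, 7.5))
  ov <- data.frame(trial_id = 2, onset_s = 4.1, offset_s = 4.4)
  out <- apply_bounds_override(trials, ov)
  expect_equal(out$onset_t, c(1, 4.1, 7))
  expect_equal(out$offset_t, c(1.5, 4.4, 7.5))
  expect_error(apply_bounds_override(trials,
                                     data.frame(trial_id = 9, onset_s = 1,
                                                offset_s = 2)), "unknown")
  expect_error(apply_bounds_override(trials,
                                     data.frame(trial_id = 1, onset_s = 2,
                                                offset_s = 1)), "onset")
})

test_that("rest segments tile quiet recordings and avoid movements", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  sp <- structure(list(time_s = tt,
                       speed = matrix(0, 1, length(tt),
                                      dimnames = list("s", NULL)),
                       sensor_labels = "s"), class = "msom_speed")
  rw <- find_rest_segments(sp)
  # 0.5 s windows + 0.5 s separation -> one start per second
  expect_equal(rw[, "start_s"], seq(0, 9, by = 1))
  # continuous high speed -> empty with warning
  sp2 <- sp; sp2$speed[] <- 1 + seq_along(tt) / 1000
  expect_warning(rw2 <- find_rest_segments(sp2), "no qualifying")
  expect_equal(nrow(rw2), 0)
  # windows keep a 1 s buffer from movements
  mv <- matrix(c(4, 4.5), 1)
  rw3 <- find_rest_segments(sp, movements = mv)
  gaps <- pmax(mv[1, 1] - rw3[, "end_s"], rw3[, "start_s"] - mv[1, 2])
  expect_true(all(gaps >= 1 - 1e-9))
})

test_that("onset detection recovers planted schedules on noiseless traces", {
  sch <- make_gesture_schedule(10, seed = 5)
  kin <- simulate_kinematics(sch, noise_amp = 0, seed = 6,
                             sample_rate_hz = 100)
  sp <- sensor_speed(kin)
  b <- detect_movement_bounds(sp, sch$visual_cue_t, threshold_fraction = 0.02)
  # with a 2% threshold the crossing is within ~2 kinematic samples of the
  # planted onset for every trial
  expect_true(all(abs(b$onset_t - sch$onset_t) <= 0.02 + 1e-9))
  expect_true(all(abs(b$offset_t - sch$offset_t) <= 0.02 + 1e-9))
})
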