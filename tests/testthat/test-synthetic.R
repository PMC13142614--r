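test_that("gesture schedules balance away-gestures and obey cue timing", {
  s <- make_gesture_schedule(4, "balanced_random", seed = 1)
  expect_equal(sum(grepl("paper", s$label)), 2)
  expect_equal(sum(grepl("scissors", s$label)), 2)
  # rock->X trials are extensions, X->rock flexions
  expect_true(all(s$direction[grepl("^rock", s$label)] == "extension"))
  expect_true(all(s$direction[grepl("rock$", s$label)] == "flexion"))
  delays <- s$visual_cue_t - s$sound_cue_t
  expect_true(all(delays >= 1 & delays <= 1.5))
  expect_true(all(s$onset_t < s$offset_t))
  # balance holds (difference <= 1) for odd trial counts too
  s7 <- make_gesture_schedule(7, "balanced_random", seed = 3)
  n_p <- sum(grepl("paper", s7$label)); n_s <- sum(grepl("scissors", s7$label))
  expect_lte(abs(n_p - n_s), 2)   # 7 transitions = 4 away (diff <= 1) + backs
  expect_error(make_gesture_schedule(1), "n_trials")
})

test_that("fixed schedules are deterministic; seeds reproduce randomness", {
  f1 <- make_gesture_schedule(10, "fixed", seed = 1)
  f2 <- make_gesture_schedule(10, "fixed", seed = 99)
  expect_equal(f1$label, f2$label)
  r1 <- make_gesture_schedule(10, "balanced_random", seed = 7)
  r2 <- make_gesture_schedule(10, "balanced_random", seed = 7)
  expect_identical(r1, r2)
})

test_that("nested footprints have geometrically growing, nested masks", {
  g <- tiny_geometry(16, 16)
  fps <- make_nested_footprints(g, c("digits", "wrist", "forearm"),
                                base_scale = 1.5, growth = 1.5)
  scales <- vapply(fps, function(f) f$spatial_scale_cells, 0)
  expect_equal(scales, 1.5 * 1.5^(0:2))
  masks <- lapply(fps, true_mask, geometry = g)
  sizes <- vapply(masks, sum, 0)
  expect_true(all(diff(sizes) > 0))
  for (i in 1:2)
    expect_true(all(!masks[[i]] | masks[[i + 1]]))   # containment
  # near-unity growth: masks nearly equal but containment still holds
  fps2 <- make_nested_footprints(g, c("a", "b"), base_scale = 2,
                                 growth = 1.0001)
  m2 <- lapply(fps2, true_mask, geometry = g)
  expect_true(all(!m2[[1]] | m2[[2]]))
  expect_lte(sum(m2[[2]]) - sum(m2[[1]]), 1)
  expect_error(make_nested_footprints(g, c("a", "b"), growth = 1), "growth")
  # single effector is trivially nested
  expect_length(make_nested_footprints(g, "only"), 1)
})

test_that("null sessions give near-zero movement-vs-rest dB", {
  g <- tiny_geometry(8, 8)
  sch <- make_gesture_schedule(20, seed = 2)
  sim <- simulate_session(g, list(), sch, seed = 31)
  mr <- movement_rest_power(sim$session)
  db <- 10 * log10(rowMeans(mr$power[, mr$labels == 1]) /
                     rowMeans(mr$power[, mr$labels == 0]))
  se <- sd(db) / sqrt(length(db))
  expect_lt(abs(mean(db)), 3 * se + 0.05)
})

test_that("planted amplitude is recovered at the footprint center", {
  px <- planted_session()
  mr <- movement_rest_power(px$sim$session)
  w <- msom:::footprint_weights(px$fp, px$geometry)
  ctr <- which.max(w)
  db <- 10 * log10(rowMeans(mr$power[, mr$labels == 1]) /
                     rowMeans(mr$power[, mr$labels == 0]))
  expect_lt(abs(db[ctr] - px$fp$amplitude_db), 0.5)
})

test_that("simulation is seed-deterministic", {
  g <- tiny_geometry(4, 4)
  sch <- make_gesture_schedule(4, seed = 5)
  a <- simulate_session(g, list(), sch, seed = 9)
  b <- simulate_session(g, list(), sch, seed = 9)
  expect_identical(a$session$voltage, b$session$voltage)
  c2 <- simulate_session(g, list(), sch, seed = 10)
  expect_false(identical(a$session$voltage, c2$session$voltage))
})

test_that("generated noise has the requested spectral slope", {
  g <- build_default_geometry(2, 2)
  sch <- make_gesture_schedule(6, seed = 1)
  for (beta in c(1, 1.5)) {
    sim <- simulate_session(g, list(), sch,
                            noise = list(pink_exponent = beta,
                                         shared_fraction = 0),
                            seed = 40 + round(10 * beta))
    v <- sim$session$voltage
    # average log-log periodogram slope across channels, 2-150 Hz
    slopes <- apply(v, 1, function(x) {
      sp <- Mod(fft(x))^2
      n <- length(x)
      f <- (seq_len(n) - 1) * 500 / n
      sel <- f > 2 & f < 150
      lf <- log10(f[sel]); lp <- log10(sp[sel])
      # bin-average to stabilise the fit
      br <- cut(lf, 30)
      coef(lm(tapply(lp, br, mean) ~ tapply(lf, br, mean)))[2]
    })
    expect_lt(abs(mean(slopes) + beta), 0.1)
  }
})

test_that("kinematics follow minimum-jerk with peak speed at midpoint", {
  sch <- make_gesture_schedule(5, seed = 3)
  kin <- simulate_kinematics(sch, noise_amp = 0, seed = 4,
                             sample_rate_hz = 200)
  sp <- sensor_speed(kin)
  v <- apply(sp$speed, 2, max)
  # zero outside trials
  in_trial <- rep(FALSE, length(sp$time_s))
  for (i in seq_len(nrow(sch)))
    in_trial <- in_trial |
      (sp$time_s > sch$onset_t[i] - 0.01 & sp$time_s < sch$offset_t[i] + 0.01)
  expect_lt(max(v[!in_trial]), 1e-9)
  # peak at the movement midpoint (closed-form minimum-jerk velocity)
  for (i in c(1, 3)) {
    sel <- which(sp$time_s >= sch$onset_t[i] & sp$time_s <= sch$offset_t[i])
    mid <- (sch$onset_t[i] + sch$offset_t[i]) / 2
    expect_lt(abs(sp$time_s[sel][which.max(v[sel])] - mid), 1 / 200 + 1e-9)
  }
})

test_that("overlapping schedules are rejected", {
  g <- tiny_geometry(4, 4)
  sch <- make_gesture_schedule(4, seed = 5)
  bad <- sch
  bad$onset_t[2] <- bad$onset_t[1] - 0.5
  bad$offset_t[2] <- bad$offset_t[1]
  expect_error(simulate_session(g, list(), bad, seed = 1), "overlap|unordered")
})
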