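test_that("spectral parameters follow the taper-count formulas", {
  p <- spectral_params()                       # 0.1 s windows, F = 40 Hz
  expect_equal(p$nw, 0.1 * 40 / 2)             # NW = window * F / 2 = 2
  expect_equal(p$n_tapers, 2 * p$nw - 1)       # T = 2 NW - 1 = 3
  expect_equal(p$hop_s, 0.1 * (1 - 0.9))
  expect_error(spectral_params(window_s = 0.01, freq_resolution_hz = 40),
               "tapers")
})

test_that("impedance mask excludes strictly above 2 MOhm", {
  expect_false(impedance_mask(2.5e6))
  expect_true(all(impedance_mask(rep(1e5, 8))))
  expect_true(impedance_mask(2e6))             # exactly at threshold: kept
  expect_error(impedance_mask(-1), "non-negative")
})

test_that("common average reference removes the included-channel mean", {
  v <- rbind(c(1, 5), c(3, 7))
  out <- common_average_reference(v, c(TRUE, TRUE))
  expect_equal(out, rbind(c(-1, -1), c(1, 1)))
  # identical included signals become zero
  v2 <- rbind(c(2, 2, 2), c(2, 2, 2), c(9, 9, 9))
  out2 <- common_average_reference(v2, c(TRUE, TRUE, FALSE))
  expect_equal(out2[1:2, ], matrix(0, 2, 3))
  expect_equal(out2[3, ], rep(0, 3))           # excluded channel zero-imputed
  # defining property on random data
  set.seed(1)
  v3 <- matrix(rnorm(5 * 100), 5)
  inc <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  out3 <- common_average_reference(v3, inc)
  expect_lt(max(abs(colMeans(out3[inc, ]))), 1e-12)
  expect_error(common_average_reference(v3, rep(FALSE, 5)), "included")
})

test_that("multitaper power is flat for white noise and peaks at tones", {
  set.seed(2)
  fs <- 500
  x <- rnorm(fs * 4)
  mt <- multitaper_power(x, fs)
  pw <- mt$power[1, , ]
  pm <- colMeans(pw)                 # mean over bins per frequency
  inner <- mt$freqs > 30 & mt$freqs < 220
  se <- apply(pw[, inner], 2, sd) / sqrt(nrow(pw))
  expect_true(all(abs(pm[inner] - mean(pm[inner])) < 3.5 * se +
                    0.05 * mean(pm[inner])))
  # pure tone peaks in its bin
  tone <- sin(2 * pi * 100 * seq_len(fs * 2) / fs)
  mt2 <- multitaper_power(tone, fs)
  expect_equal(mt2$freqs[which.max(colMeans(mt2$power[1, , ]))], 100)
  expect_error(multitaper_power(rnorm(10), fs), "shorter")
})

test_that("single-taper limit matches a plain tapered periodogram", {
  set.seed(3)
  fs <- 500
  x <- rnorm(fs)
  p1 <- spectral_params(window_s = 0.1, overlap_fraction = 0,
                        freq_resolution_hz = 20)    # NW = 1 -> T = 1
  mt <- multitaper_power(x, fs, p1)
  L <- 50
  tap <- dpss_tapers(L, 1, 1)
  seg <- x[1:L] * tap[, 1]
  ref <- Mod(fft(seg)[1:26])^2
  expect_equal(mt$power[1, 1, ], ref, tolerance = 1e-10)
})

test_that("dpss tapers are orthonormal and concentrated", {
  tap <- dpss_tapers(50, 2, 3)
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-10)
  # concentration in the +/- NW/L band decreases with taper order
  conc <- apply(tap, 2, function(w) {
    sp <- Mod(fft(c(w, rep(0, 950))))^2
    f <- (0:999) / 1000
    sum(sp[f <= 0.04 | f >= 0.96]) / sum(sp)
  })
  expect_true(all(diff(conc) < 0))
  expect_gt(conc[1], 0.999)
})

test_that("1/f normalization divides out the mean spectrum", {
  set.seed(4)
  pow <- array(rexp(2 * 30 * 5, 1), dim = c(2, 30, 5))
  pow[1, , 3] <- pow[1, , 3] * 10          # uneven spectrum
  norm <- normalize_one_over_f(pow)
  expect_equal(apply(norm, c(1, 3), mean),
               matrix(1, 2, 5), tolerance = 1e-12)
  # input with power ~ 1/f becomes flat across frequency
  f <- 1:5
  pw2 <- array(rep(1 / f, each = 2 * 30), dim = c(2, 30, 5))
  n2 <- normalize_one_over_f(pw2)
  expect_true(all(abs(n2 - 1) < 1e-12))
  bad <- pow; bad[1, , 2] <- 0
  expect_error(normalize_one_over_f(bad), "zero mean")
})

test_that("dB conversion references the pooled baseline", {
  # two channels, constant power; second bin 10x baseline on channel 1
  pow <- array(1, dim = c(2, 10, 4))
  pow[1, 6:10, ] <- 10
  mt <- list(power = pow, bin_times_s = seq(0.1, 1, by = 0.1),
             freqs = c(80, 120, 160, 200),
             params = spectral_params())
  hg <- highgamma_db(mt, c(80, 200), baseline_windows = c(0, 0.5))
  expect_equal(hg$values[1, 1], 0)
  expect_equal(hg$values[1, 10], 10)           # 10x -> 10 dB
  expect_equal(hg$values[2, ], rep(0, 10))
  # half the baseline -> -3.0103 dB
  pow2 <- array(1, dim = c(1, 10, 4))
  pow2[1, 6:10, ] <- 0.5
  mt2 <- mt; mt2$power <- pow2
  hg2 <- highgamma_db(mt2, c(80, 200), baseline_windows = c(0, 0.5))
  expect_equal(hg2$values[1, 10], 10 * log10(0.5), tolerance = 1e-9)
  expect_error(highgamma_db(mt, c(80, 200),
                            baseline_windows = matrix(numeric(0), ncol = 2)),
               "non-empty")
})

test_that("dB is invariant to voltage gain", {
  px <- planted_session()
  s1 <- px$sim$session
  m1 <- movement_rest_power(s1)
  db_of <- function(m) 10 * log10(rowMeans(m$power[, m$labels == 1]) /
                                    rowMeans(m$power[, m$labels == 0]))
  db1 <- db_of(m1)
  # a global gain cancels exactly in the movement/baseline ratio
  s2 <- s1; s2$voltage <- s2$voltage * 3.7
  expect_equal(db_of(movement_rest_power(s2)), db1, tolerance = 1e-9)
  # per-channel gains interact only through the common average (and break
  # common-mode cancellation, so use a session without shared noise)
  g <- tiny_geometry(6, 6)
  sch <- make_gesture_schedule(12, seed = 7)
  s4 <- simulate_session(g, list(), sch,
                         noise = list(shared_fraction = 0), seed = 8)$session
  m4 <- db_of(movement_rest_power(s4))
  set.seed(6)
  s5 <- s4; s5$voltage <- s5$voltage * runif(nrow(s5$voltage), 0.5, 2)
  expect_lt(max(abs(db_of(movement_rest_power(s5)) - m4)), 0.2)
})
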