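test_that("signed R^2 matches term-by-term evaluation of the formula", {
  # perfectly separated balanced case attains exactly 1
  expect_equal(signed_r2(c(2, 2), c(0, 0)), 1)
  expect_equal(signed_r2(c(1, 1), c(1, 1)), 0)
  # antisymmetry: swapping conditions flips only the sign
  set.seed(1)
  for (i in 1:20) {
    m <- rnorm(7, 1); r <- rnorm(5)
    expect_equal(signed_r2(m, r), -signed_r2(r, m))
    # independent term-by-term oracle
    u <- c(m, r)
    s2 <- mean(u^2) - mean(u)^2
    d <- mean(m) - mean(r)
    oracle <- sign(d) * d^2 * 7 * 5 / (s2 * 12^2)
    expect_equal(signed_r2(m, r), oracle, tolerance = 1e-12)
    expect_true(abs(signed_r2(m, r)) <= 1)
  }
  expect_error(signed_r2(numeric(0), 1:3), "empty")
})

test_that("signed R^2 equals signed eta-squared for balanced conditions", {
  set.seed(2)
  for (i in 1:10) {
    m <- rnorm(6, 0.5); r <- rnorm(6)
    u <- c(m, r)
    groups <- factor(rep(1:2, each = 6))
    ss_tot <- sum((u - mean(u))^2)
    ss_b <- 6 * (mean(m) - mean(u))^2 + 6 * (mean(r) - mean(u))^2
    eta2 <- ss_b / ss_tot
    expect_equal(abs(signed_r2(m, r)), eta2, tolerance = 1e-12)
  }
})

test_that("vectorised signed R^2 map agrees with the scalar op", {
  set.seed(3)
  pw <- matrix(rexp(5 * 12), 5)
  labels <- c(rep(1, 7), rep(0, 5))
  m <- signed_r2_map <- msom:::signed_r2_map(pw, labels)
  for (ch in 1:5)
    expect_equal(m[ch], signed_r2(pw[ch, labels == 1], pw[ch, labels == 0]),
                 tolerance = 1e-12)
})

test_that("TFCE matches the single-cell closed form and the all-zero map", {
  g <- tiny_geometry(8, 8)
  stat <- rep(0, nrow(g$contacts))
  expect_true(all(tfce_map(stat, geometry = g) == 0, na.rm = TRUE))
  # isolated cell at 1.0: sum_{k=1..10} (0.1 k)^2 * 1 * 0.1
  m <- matrix(0, 8, 8); m[4, 4] <- 1
  sc <- tfce_map(m)
  expect_equal(sc[4, 4], sum((0.1 * (1:10))^2 * 0.1), tolerance = 1e-12)
})

test_that("TFCE equals the brute-force threshold integration on random maps", {
  set.seed(4)
  for (i in 1:25) {
    m <- matrix(rnorm(64, 0.2, 0.5), 8, 8)
    m[sample(64, 5)] <- NA               # unmapped cells
    expect_equal(tfce_map(m), tfce_bruteforce(m), tolerance = 1e-12)
  }
})

test_that("merging two peaks into one component raises their TFCE", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1; m[7, 7] <- 1            # disconnected equal peaks
  s1 <- tfce_map(m)
  expect_equal(s1[2, 2], s1[7, 7])
  bridge <- m
  bridge[cbind(2:7, 2:7)] <- 1          # 8-connected diagonal blob
  s2 <- tfce_map(bridge)
  expect_gt(s2[2, 2], s1[2, 2])
  expect_gt(s2[7, 7], s1[7, 7])
})

test_that("permutation p-values follow the (k+1)/(n+1) rule and reproduce", {
  g <- tiny_geometry(4, 4)
  set.seed(5)
  C <- nrow(g$contacts)
  # huge planted effect on every channel: observed TFCE beats all null maxima
  pw <- cbind(matrix(rexp(C * 10, 1) + 50, C), matrix(rexp(C * 10, 1), C))
  labels <- rep(c(1, 0), each = 10)
  em <- permutation_fwer(pw, labels, g, n_perm = 200, seed = 6)
  mapped <- !is.na(em$p_pos)
  expect_equal(min(em$p_pos[mapped]), 1 / 201)
  expect_true(all(em$significant[mapped]))
  em2 <- permutation_fwer(pw, labels, g, n_perm = 200, seed = 6)
  expect_identical(em$p_pos, em2$p_pos)
  expect_error(permutation_fwer(pw[, 1, drop = FALSE], 1, g), "two trials")
})

test_that("t-statistic option gives the same ranking as signed R^2", {
  g <- tiny_geometry(4, 4)
  set.seed(7)
  C <- nrow(g$contacts)
  pw <- matrix(rexp(C * 24), C)
  pw[3, 1:12] <- pw[3, 1:12] + 2
  labels <- rep(c(1, 0), each = 12)
  e_r <- permutation_fwer(pw, labels, g, n_perm = 100, seed = 8)
  e_t <- permutation_fwer(pw, labels, g, n_perm = 100, seed = 8, stat = "t")
  mapped <- !is.na(e_r$signed_r2) | TRUE
  expect_equal(order(e_r$signed_r2), order(e_t$signed_r2))
})

test_that("EoA sums significant positive effects only", {
  fake <- list(signed_r2 = c(0.1, 0.2, -0.3, 0.5),
               significant = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(eoa(fake), 0.3)
  fake$significant <- rep(FALSE, 4)
  expect_equal(eoa(fake), 0)
  fake2 <- list(signed_r2 = c(0.2, 0.4, -0.3, 0.5),
                significant = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fake2$signed_r2[1:2] * 2,
               c(0.4, 0.8))
  expect_equal(eoa(list(signed_r2 = c(0.4, 0.8, -0.3, 0.5),
                        significant = c(TRUE, TRUE, TRUE, FALSE))),
               2 * eoa(list(signed_r2 = c(0.2, 0.4, -0.3, 0.5),
                            significant = c(TRUE, TRUE, TRUE, FALSE))))
})

test_that("EoA timecourse flags onset, peak and tie-breaks deterministically", {
  g <- tiny_geometry(4, 4)
  C <- nrow(g$contacts)
  set.seed(9)
  nt <- 12; nb <- 6
  null_pow <- array(rexp(nt * C * nb), dim = c(nt, C, nb))
  rest <- matrix(rexp(nt * C), nt, C)
  tc <- eoa_timecourse(null_pow, rest, seq(0.1, 0.6, by = 0.1), g,
                       n_perm = 100, seed = 10)
  expect_true(all(tc$eoa == 0))
  expect_true(is.na(tc$onset_t))
  # constant series peaks at the first bin by the tie rule
  expect_equal(tc$peak_t, 0.1)
  # planted effect from bin 3 onward
  pow2 <- null_pow
  pow2[, , 3:6] <- pow2[, , 3:6] + 5
  tc2 <- eoa_timecourse(pow2, rest, seq(0.1, 0.6, by = 0.1), g,
                        n_perm = 100, seed = 11)
  expect_equal(tc2$onset_t, 0.3)
  expect_gte(tc2$peak_t, tc2$onset_t)
  expect_equal(tc2$latency, tc2$peak_t - tc2$onset_t)
})

test_that("trial-window averages recover planted flexion/extension asymmetry", {
  g <- tiny_geometry(6, 6)
  sch <- make_gesture_schedule(24, seed = 12)
  ext <- footprint("extension_fp", c(2.5, 2.5), 2, amplitude_db = 2)
  # separate footprints keyed to trial labels via direction-specific labels
  sim <- simulate_session(g, list(), sch, seed = 13)
  hg <- epoched_hg_db(sim$session, t_range = c(-0.3, 0.4), hop_s = 0.05)
  twa <- trial_window_average(hg, lag_t = -0.2)
  expect_equal(nrow(twa), 24)
  # constant map sanity: a null session's averages hover near zero
  expect_lt(abs(mean(twa$value)), 0.5)
  # single-bin window equals that bin's channel mean (hand-built cube)
  db <- array(seq_len(2 * 3 * 3), dim = c(2, 3, 3))
  fake <- list(db = db, bin_times_s = c(0.1, 0.2, 0.3),
               trials = data.frame(trial = 1:2, label = "m",
                                   direction = "n/a",
                                   onset_t = c(1, 2), offset_t = c(1.2, 2.2)),
               included_channels = rep(TRUE, 3))
  one <- trial_window_average(fake, lag_t = 0.2)
  expect_equal(one$value[1], mean(db[1, , 2]))
  # constant map scores the constant
  fake$db[] <- 1
  expect_equal(trial_window_average(fake, lag_t = 0.1)$value, c(1, 1))
})
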