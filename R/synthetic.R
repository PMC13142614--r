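#' Gesture trial schedules
#'
#' Builds a transition-gesture schedule in which every trial is a hand
#' transition starting from and returning to the closed-hand baseline gesture
#' ("rock"): odd trials move away (rock -> paper or rock -> scissors,
#' extension), even trials move back (flexion). Under the `balanced_random`
#' paradigm the away gestures are drawn so the final paper/scissors counts
#' differ by at most one; `fixed` repeats the deterministic sequence
#' paper, scissors, paper, ... independent of the seed.
#'
#' Each trial carries an audio cue, a visual cue 1-1.5 s later (uniform, per
#' the task design), a movement onset `reaction_s` after the visual cue and an
#' offset `movement_s` later; the next audio cue follows after `iti_s`.
#'
#' @param n_trials number of transition trials (>= 2).
#' @param paradigm `"balanced_random"` or `"fixed"`.
#' @param seed RNG seed (scoped; the caller's RNG stream is untouched).
#' @param cue_delay_range audio-to-visual cue delay range in seconds.
#' @param reaction_s,movement_s,iti_s,start_s timing parameters in seconds.
#' @return a `data.frame` of class `msom_schedule` with one row per trial:
#'   `trial`, `label` (e.g. `"rock->paper"`), `direction`
#'   (`extension`/`flexion`), `sound_cue_t`, `visual_cue_t`, `onset_t`,
#'   `offset_t` (seconds from recording start).
#' @export
make_gesture_schedule <- function(n_trials, paradigm = c("balanced_random", "fixed"),
                                  seed = NULL, cue_delay_range = c(1, 1.5),
                                  reaction_s = 0.15, movement_s = 0.35,
                                  iti_s = 0.6, start_s = 1.0) {
  paradigm <- match.arg(paradigm)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 2L) stopf("n_trials must be >= 2")
  with_seed(seed, {
    n_away <- ceiling(n_trials / 2)
    if (paradigm == "fixed") {
      away <- rep(c("paper", "scissors"), length.out = n_away)
    } else {
      pool <- rep(c("paper", "scissors"), ceiling(n_away / 2))[seq_len(n_away)]
      away <- sample(pool)
    }
    labels <- character(n_trials)
    direction <- character(n_trials)
    for (i in seq_len(n_trials)) {
      g <- away[ceiling(i / 2)]
      if (i %% 2L == 1L) {
        labels[i] <- paste0("rock->", g); direction[i] <- "extension"
      } else {
        labels[i] <- paste0(g, "->rock"); direction[i] <- "flexion"
      }
    }
    delay <- runif(n_trials, cue_delay_range[1], cue_delay_range[2])
    sound <- numeric(n_trials)
    t0 <- start_s
    visual <- onset <- offset <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      sound[i] <- t0
      visual[i] <- sound[i] + delay[i]
      onset[i] <- visual[i] + reaction_s
      offset[i] <- onset[i] + movement_s
      t0 <- offset[i] + iti_s
    }
    structure(
      data.frame(trial = seq_len(n_trials), label = labels,
                 direction = direction, sound_cue_t = sound,
                 visual_cue_t = visual, onset_t = onset, offset_t = offset,
                 stringsAsFactors = FALSE),
      paradigm = paradigm, class = c("msom_schedule", "data.frame")
    )
  })
}

#' Self-paced isolated-joint schedules
#'
#' Emulates the isolated-joint task: blocks of repeated self-paced movements
#' of single effectors, separated by quiet gaps, with no cue structure (cue
#' columns are set to the movement onset). Rest epochs for such sessions are
#' derived from the kinematics afterwards rather than from a cued baseline.
#'
#' @param effectors character vector of joint labels, ordered distal to
#'   proximal.
#' @param reps movements per effector.
#' @param movement_s,gap_s,block_gap_s,start_s timing in seconds.
#' @param jitter_s uniform jitter added to each inter-movement gap.
#' @param seed RNG seed.
#' @return a `data.frame` of class `msom_schedule` (direction is `"n/a"`).
#' @export
make_joint_schedule <- function(effectors, reps = 8, movement_s = 0.4,
                                gap_s = 1.0, block_gap_s = 3.0, start_s = 2.0,
                                jitter_s = 0.2, seed = NULL) {
  if (length(effectors) < 1) stopf("need at least one effector")
  with_seed(seed, {
    rows <- list()
    t0 <- start_s
    k <- 0L
    for (eff in effectors) {
      for (r in seq_len(reps)) {
        k <- k + 1L
        onset <- t0
        offset <- onset + movement_s
        rows[[k]] <- data.frame(trial = k, label = eff, direction = "n/a",
                                sound_cue_t = onset, visual_cue_t = onset,
                                onset_t = onset, offset_t = offset,
                                stringsAsFactors = FALSE)
        t0 <- offset + gap_s + runif(1, 0, jitter_s)
      }
      t0 <- t0 + block_gap_s
    }
    structure(do.call(rbind, rows), paradigm = "self_paced",
              class = c("msom_schedule", "data.frame"))
  })
}

#' Ground-truth activation footprints
#'
#' A footprint is an isotropic Gaussian spatial weight on the grid,
#' `w(d) = exp(-d^2 / (2 scale^2))` with `d` in grid-cell units, combined
#' with a temporal envelope that rises over `ramp_s` starting `lead_s` before
#' movement onset, stays at 1 until movement offset, and decays over
#' `decay_s`. `amplitude_db` is the high-gamma power increase planted at the
#' footprint center during movement.
#'
#' @param effector_label movement label the footprint responds to, or
#'   `"all"` to respond to every trial.
#' @param center_cell `(row, col)` 0-based grid cell of the center.
#' @param spatial_scale_cells Gaussian spatial scale in cells (> 0).
#' @param amplitude_db planted dB increase at the center (>= 0).
#' @param lead_s envelope start before movement onset (s).
#' @param decay_s envelope decay after movement offset (s).
#' @param ramp_s envelope rise time (s).
#' @return an object of class `msom_footprint`.
#' @export
footprint <- function(effector_label, center_cell, spatial_scale_cells,
                      amplitude_db = 3, lead_s = 0.25, decay_s = 0.1,
                      ramp_s = 0.02) {
  if (spatial_scale_cells <= 0) stopf("spatial_scale_cells must be > 0")
  if (amplitude_db < 0) stopf("amplitude_db must be >= 0")
  structure(list(effector_label = effector_label,
                 center_cell = as.numeric(center_cell),
                 spatial_scale_cells = spatial_scale_cells,
                 amplitude_db = amplitude_db, lead_s = lead_s,
                 decay_s = decay_s, ramp_s = ramp_s),
            class = "msom_footprint")
}

footprint_weights <- function(fp, geometry) {
  ct <- geometry$contacts
  w <- rep(0, nrow(ct))
  mapped <- !is.na(ct$grid_row)
  d2 <- (ct$grid_row[mapped] - fp$center_cell[1])^2 +
        (ct$grid_col[mapped] - fp$center_cell[2])^2
  w[mapped] <- exp(-d2 / (2 * fp$spatial_scale_cells^2))
  w
}

# Planted dB at each contact: the carrier adds w * (10^(A/10) - 1) times the
# baseline band power, so planted_db = 10 log10(1 + w * (10^(A/10) - 1)).
planted_db <- function(fp, geometry) {
  w <- footprint_weights(fp, geometry)
  10 * log10(1 + w * (10^(fp$amplitude_db / 10) - 1))
}

#' Half-maximum ground-truth mask of a footprint
#'
#' Channels whose planted dB is at least half the center amplitude; the
#' recovery target for significance masks.
#'
#' @param fp an [footprint()] object.
#' @param geometry the array geometry.
#' @return logical per-channel vector.
#' @export
true_mask <- function(fp, geometry) {
  planted_db(fp, geometry) >= fp$amplitude_db / 2
}

#' Concentrically nested footprints for an ordered effector hierarchy
#'
#' Builds one footprint per effector, sharing a center, with the spatial
#' scale growing geometrically by `growth` from distal to proximal so the
#' half-maximum masks are nested supersets in effector order (a synthetic
#' restatement of concentric distal-to-proximal cortical territories).
#'
#' @param geometry array geometry.
#' @param effectors labels ordered distal -> proximal.
#' @param base_scale spatial scale (cells) of the first (most distal) effector.
#' @param growth scale multiplier per step (> 1).
#' @param center shared center cell; default the grid center.
#' @param amplitude_db,lead_s,decay_s passed to [footprint()].
#' @return list of `msom_footprint`.
#' @export
make_nested_footprints <- function(geometry, effectors, base_scale = 1.5,
                                   growth = 1.5, center = NULL,
                                   amplitude_db = 5, lead_s = 0.25,
                                   decay_s = 0.1) {
  if (growth <= 1) stopf("growth must be > 1")
  if (is.null(center))
    center <- c((geometry$n_rows - 1) / 2, (geometry$n_cols - 1) / 2)
  lapply(seq_along(effectors), function(i) {
    footprint(effectors[i], center, base_scale * growth^(i - 1),
              amplitude_db = amplitude_db, lead_s = lead_s, decay_s = decay_s)
  })
}

# Amplitude spectrum (over the two-sided FFT grid of length nf) for noise
# with power ~ 1/f^exponent, scaled so the synthesized signal has variance
# `scale^2`. Returns list(amp, band_fraction) where band_fraction is the
# fraction of variance inside `band_hz`.
pink_amp <- function(nf, fs, exponent, scale, band_hz = c(80, 200)) {
  f <- fs * (seq_len(nf) - 1) / nf
  ffold <- pmin(f, fs - f)
  amp <- ifelse(ffold > 0, ffold^(-exponent / 2), 0)
  s2 <- sum(amp^2)
  band <- ffold >= band_hz[1] & ffold <= band_hz[2]
  list(amp = amp * scale * nf / sqrt(s2),
       band_fraction = sum(amp[band]^2) / s2)
}

band_amp <- function(nf, fs, band_hz, scale) {
  f <- fs * (seq_len(nf) - 1) / nf
  ffold <- pmin(f, fs - f)
  amp <- as.numeric(ffold >= band_hz[1] & ffold <= band_hz[2])
  amp * scale * nf / sqrt(sum(amp^2))
}

# Expected response of the multitaper band-power measurement to processes
# with the given synthesis spectra: for each retained band bin b, the
# expected tapered periodogram is sum_k amp2[k] |W(f_k - f_b)|^2 with W the
# taper transfer function. Returns the per-bin noise and carrier responses,
# used to calibrate carrier variance so planted dB amplitudes are met by the
# measurement chain (taper leakage at the band edges and the 1/f-weighted
# band average included).
band_response <- function(nf, fs, params, amp_noise, amp_carrier) {
  L <- round(params$window_s * fs)
  tap <- dpss_tapers(L, params$nw, params$n_tapers)
  freqs <- (0:(L %/% 2)) * fs / L
  bsel <- which(freqs >= params$band_hz[1] & freqs <= params$band_hz[2])
  shift <- round(freqs[bsel] / fs * nf)
  a2n <- amp_noise^2
  a2c <- amp_carrier^2
  rn <- rc <- numeric(length(bsel))
  for (k in seq_len(params$n_tapers)) {
    W <- Mod(fft(c(tap[, k], rep(0, nf - L))))^2
    for (bi in seq_along(bsel)) {
      idx <- ((seq_len(nf) - 1 - shift[bi]) %% nf) + 1
      rn[bi] <- rn[bi] + sum(a2n * W[idx])
      rc[bi] <- rc[bi] + sum(a2c * W[idx])
    }
  }
  list(noise = rn, carrier = rc)
}

# Carrier variance that produces a measured movement-vs-rest band-power
# ratio of `target` at the footprint center, given that the 1/f reference
# spectrum is itself estimated from the recording and therefore contains a
# fraction `phi` of movement windows.
calibrate_carrier_var <- function(resp, target, phi) {
  f <- function(v) {
    g <- resp$noise + phi * v * resp$carrier
    mean((resp$noise + v * resp$carrier) / g) / mean(resp$noise / g) - target
  }
  vmax <- 2 * (target - 1) / mean(resp$carrier / resp$noise) + 1e-12
  stats::uniroot(f, c(0, max(vmax, 1e-9)), tol = 1e-12)$root
}

footprint_envelope <- function(fp, schedule, n, fs) {
  env <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  trials <- if (identical(fp$effector_label, "all")) seq_len(nrow(schedule))
            else which(schedule$label == fp$effector_label)
  for (i in trials) {
    on <- schedule$onset_t[i]; off <- schedule$offset_t[i]
    a <- on - fp$lead_s
    idx <- which(tt >= a & tt <= off + fp$decay_s)
    e <- numeric(length(idx))
    ti <- tt[idx]
    e[ti >= a + fp$ramp_s & ti <= off] <- 1
    r <- ti < a + fp$ramp_s
    e[r] <- (ti[r] - a) / fp$ramp_s
    d <- ti > off
    e[d] <- pmax(0, 1 - (ti[d] - off) / max(fp$decay_s, 1e-9))
    env[idx] <- pmax(env[idx], e)
  }
  env
}

#' Simulate a surface-array recording session with known ground truth
#'
#' Per-channel voltage is 1/f ("pink") background noise plus a shared
#' (common-mode) pink component plus, for each footprint, band-limited
#' 80-200 Hz carrier noise amplitude-modulated by the footprint's spatial
#' weight and temporal envelope. The carrier gain is calibrated analytically
#' against the expected in-band noise power so the measured movement-vs-rest
#' change at the footprint center is `amplitude_db` within sampling error.
#'
#' @param geometry array geometry (its full contact count defines the channel
#'   count; the unmapped reference receives noise only).
#' @param footprints list of [footprint()] objects (empty = global null).
#' @param schedule an `msom_schedule`.
#' @param noise list with `pink_exponent` (spectral slope), `noise_scale`
#'   (per-channel RMS, volts) and `shared_fraction` (common-mode RMS as a
#'   fraction of `noise_scale`; removed by common-average referencing).
#' @param sample_rate_hz sampling rate (> 400 so the 200 Hz band is
#'   Nyquist-safe).
#' @param seed RNG seed (scoped).
#' @param tail_s quiet tail appended after the last trial.
#' @return list with `session` (class `msom_session`: `sample_rate_hz`,
#'   `voltage` channels x samples, `impedance_ohm`, `events`, `trials`,
#'   `geometry`) and `ground_truth` (footprints, per-effector half-max masks,
#'   schedule, seed).
#' @export
simulate_session <- function(geometry, footprints = list(), schedule,
                             noise = list(), sample_rate_hz = 500,
                             seed = NULL, tail_s = 1.0) {
  if (sample_rate_hz <= 400) stopf("sample_rate_hz must exceed 400")
  noise <- utils::modifyList(
    list(pink_exponent = 1, noise_scale = 2e-5, shared_fraction = 0.5), noise)
  if (any(diff(schedule$onset_t) <= 0) ||
      any(schedule$onset_t[-1] < schedule$offset_t[-nrow(schedule)]))
    stopf("schedule trials overlap or are unordered")
  if (inherits(footprints, "msom_footprint")) footprints <- list(footprints)

  fs <- sample_rate_hz
  dur <- max(schedule$offset_t) + tail_s
  n <- ceiling(dur * fs)
  nf <- next_fast_len(n)
  C <- n_contacts(geometry)

  with_seed(seed, {
    pk <- pink_amp(nf, fs, noise$pink_exponent, noise$noise_scale)
    # channels x samples; the common-mode component is added inside
    v <- cpp_colored_noise(n, C, pk$amp, noise$shared_fraction)
    if (length(footprints) > 0) {
      c_amp <- band_amp(nf, fs, c(80, 200), 1)
      carrier <- cpp_colored_noise(n, C, c_amp)
      resp <- band_response(nf, fs, spectral_params(), pk$amp, c_amp)
      # movement fraction of the analysis windows entering the 1/f reference
      mov_s <- sum(schedule$offset_t - schedule$onset_t)
      phi <- mov_s / (mov_s + 0.5 * nrow(schedule))
      gain2 <- matrix(0, C, n)                        # added band variance
      for (fp in footprints) {
        w <- footprint_weights(fp, geometry)
        v1 <- calibrate_carrier_var(resp, 10^(fp$amplitude_db / 10), phi)
        vvar <- w * v1
        env <- footprint_envelope(fp, schedule, n, fs)
        nz <- which(env > 0)
        if (length(nz))
          gain2[, nz] <- gain2[, nz] + outer(vvar, env[nz])
      }
      nzc <- which(colSums(gain2) > 0)
      if (length(nzc))
        v[, nzc] <- v[, nzc] + carrier[, nzc] * sqrt(gain2[, nzc, drop = FALSE])
    }

    events <- rbind(
      data.frame(time_s = schedule$sound_cue_t, event_type = "sound_cue",
                 label = schedule$label, stringsAsFactors = FALSE),
      data.frame(time_s = schedule$visual_cue_t, event_type = "visual_cue",
                 label = schedule$label, stringsAsFactors = FALSE))
    events <- events[order(events$time_s), ]

    trials <- as.data.frame(schedule)
    trials$excluded <- FALSE
    trials$exclusion_reason <- "none"

    session <- structure(list(
      sample_rate_hz = fs,
      voltage = v,
      impedance_ohm = rep(1e5, C),
      events = events,
      trials = trials,
      kinematics = NULL,
      geometry = geometry
    ), class = "msom_session")

    masks <- lapply(footprints, true_mask, geometry = geometry)
    names(masks) <- vapply(footprints, function(f) f$effector_label, "")
    list(session = session,
         ground_truth = list(footprints = footprints, true_mask = masks,
                             schedule = schedule, seed = seed,
                             noise = noise))
  })
}

#' @export
print.msom_session <- function(x, ...) {
  cat(sprintf("<msom_session> %d channels x %d samples @ %g Hz, %d trials\n",
              nrow(x$voltage), ncol(x$voltage), x$sample_rate_hz,
              nrow(x$trials)))
  invisible(x)
}

# Minimum-jerk displacement profile on [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate motion-capture traces for a schedule
#'
#' Moving sensors follow a minimum-jerk displacement between each trial's
#' onset and offset along a per-trial random direction; all sensors carry
#' additive Gaussian position noise of amplitude `noise_amp` meters. For
#' gesture trials the index/pinky/hand sensors move; for joint trials the
#' sensor named by the trial label moves (when present among `sensors`).
#'
#' @param schedule an `msom_schedule`.
#' @param sensors sensor labels.
#' @param sample_rate_hz kinematic sampling rate.
#' @param amplitude_m movement displacement magnitude in meters.
#' @param noise_amp position noise standard deviation in meters.
#' @param seed RNG seed.
#' @param tail_s seconds recorded after the last offset.
#' @return object of class `msom_kinematics`: `time_s`, `positions` (sensor x
#'   axis x time array, meters), `sensor_labels`.
#' @export
simulate_kinematics <- function(schedule,
                                sensors = c("hand_index", "hand_pinky",
                                            "hand", "wrist"),
                                sample_rate_hz = 100, amplitude_m = 0.05,
                                noise_amp = 0, seed = NULL, tail_s = 1.0) {
  if (length(sensors) < 1) stopf("need at least one sensor")
  fs <- sample_rate_hz
  n <- ceiling((max(schedule$offset_t) + tail_s) * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    pos <- array(0, dim = c(length(sensors), 3L, n),
                 dimnames = list(sensors, c("x", "y", "z"), NULL))
    gesture_movers <- intersect(c("hand_index", "hand_pinky", "hand"), sensors)
    for (i in seq_len(nrow(schedule))) {
      movers <- if (identical(schedule$direction[i], "n/a"))
        intersect(schedule$label[i], sensors) else gesture_movers
      if (!length(movers)) next
      dirvec <- rnorm(3); dirvec <- dirvec / sqrt(sum(dirvec^2))
      on <- schedule$onset_t[i]; off <- schedule$offset_t[i]
      # minimum-jerk reach: displacement persists after offset (the posture
      # changes; the next trial moves the sensor again from wherever it is)
      tau <- pmin(pmax((tt - on) / (off - on), 0), 1)
      disp <- amplitude_m * min_jerk(tau)
      for (s in movers)
        for (a in 1:3)
          pos[s, a, ] <- pos[s, a, ] + disp * dirvec[a]
    }
    if (noise_amp > 0) {
      # sensor noise is slow (tracking drift), not sample-to-sample jitter:
      # smooth white noise with a ~0.25 s moving average
      k <- max(1L, round(0.25 * fs))
      for (s in seq_along(sensors)) for (a in 1:3) {
        e <- rnorm(n + k, sd = noise_amp * sqrt(k))
        pos[s, a, ] <- pos[s, a, ] +
          (cumsum(e)[(k + 1):(n + k)] - cumsum(e)[1:n]) / k
      }
    }
    structure(list(time_s = tt, positions = pos, sensor_labels = sensors),
              class = "msom_kinematics")
  })
}

#' Synthetic multi-participant gradient cohort
#'
#' Per participant, channel coordinates are drawn uniformly in a cortical
#' patch and activation is `beta` times the planted axis coordinate plus
#' Gaussian noise; the other axes carry no planted effect.
#'
#' @param n_participants,n_channels cohort shape.
#' @param beta planted slope (dB per mm) on the planted axis.
#' @param planted_axis one of `"x"`, `"y"`, `"z"`.
#' @param noise_sd activation noise SD (dB).
#' @param extent_mm linear extent of the simulated patch.
#' @param seed RNG seed.
#' @return data.frame: participant, channel, x_mm, y_mm, z_mm, activation_db.
#' @export
simulate_gradient_cohort <- function(n_participants = 10, n_channels = 200,
                                     beta = 0.1, planted_axis = "x",
                                     noise_sd = 1, extent_mm = 12,
                                     seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(n_participants), function(p) {
      co <- matrix(runif(n_channels * 3, 0, extent_mm), ncol = 3)
      colnames(co) <- c("x_mm", "y_mm", "z_mm")
      act <- beta * co[, paste0(planted_axis, "_mm")] +
        rnorm(n_channels, sd = noise_sd)
      data.frame(participant = p, channel = seq_len(n_channels), co,
                 activation_db = act)
    })
    do.call(rbind, out)
  })
}
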