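#' Multitaper spectral parameters
#'
#' The time-bandwidth product is `NW = window_s * F / 2` where `F` is the
#' frequency resolution (smoothing bandwidth) in Hz, and the taper count is
#' `T = 2 NW - 1`. Defaults (100 ms windows at 90% overlap, F = 40 Hz) give
#' NW = 2 and 3 tapers.
#'
#' @param window_s sliding window length (s).
#' @param overlap_fraction fractional window overlap in `[0, 1)`.
#' @param freq_resolution_hz multitaper smoothing bandwidth F (Hz).
#' @param band_hz broadband high-gamma band edges (Hz), inclusive.
#' @return list of class `msom_spectral_params` with derived `nw`,
#'   `n_tapers` and `hop_s`.
#' @export
spectral_params <- function(window_s = 0.1, overlap_fraction = 0.9,
                            freq_resolution_hz = 40, band_hz = c(80, 200)) {
  nw <- window_s * freq_resolution_hz / 2
  n_tapers <- floor(2 * nw - 1 + 1e-9)
  if (n_tapers < 1) stopf("parameters give %d tapers; need >= 1", n_tapers)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stopf("overlap_fraction must be in [0, 1)")
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 freq_resolution_hz = freq_resolution_hz, nw = nw,
                 n_tapers = as.integer(n_tapers),
                 hop_s = window_s * (1 - overlap_fraction),
                 band_hz = band_hz),
            class = "msom_spectral_params")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the DPSS: diagonal `((n-1-2t)/2)^2 cos(2 pi W)`,
#' off-diagonal `t (n - t) / 2`, with `W = nw / n`. Tapers are unit-energy;
#' signs follow the usual convention (even tapers have positive mean, odd
#' tapers a positive initial lobe).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return `n` x `k` matrix, columns ordered by decreasing concentration.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k < 1 || k > n) stopf("invalid taper count")
  W <- nw / n
  tvec <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * W)
  off <- tvec[-1] * (n - tvec[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (j %% 2 == 1) {
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else {
      if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
    }
  }
  tap
}

#' Impedance-based channel inclusion
#'
#' Channels with impedance strictly above the threshold (default 2 MOhm) are
#' excluded; a channel at exactly the threshold is included.
#'
#' @param impedance_ohm per-channel impedance (Ohm), finite and non-negative.
#' @param threshold_ohm exclusion threshold (Ohm).
#' @return logical inclusion flags.
#' @export
impedance_mask <- function(impedance_ohm, threshold_ohm = 2e6) {
  if (any(!is.finite(impedance_ohm)) || any(impedance_ohm < 0))
    stopf("impedances must be finite and non-negative")
  impedance_ohm <= threshold_ohm
}

#' Common-average referencing with zero-imputation
#'
#' Subtracts, at every sample, the mean voltage over included (low-impedance)
#' channels from every channel, then imputes excluded channels with zeros so
#' they pass inertly through spectral estimation.
#'
#' @param voltage channels x samples matrix.
#' @param include logical inclusion flags (at least one `TRUE`).
#' @return referenced channels x samples matrix.
#' @export
common_average_reference <- function(voltage, include = NULL) {
  if (is.null(include)) include <- rep(TRUE, nrow(voltage))
  if (!any(include)) stopf("no included channels")
  avg <- colMeans(voltage[include, , drop = FALSE])
  out <- sweep(voltage, 2, avg, "-")
  out[!include, ] <- 0
  out
}

#' Multitaper sliding-window power
#'
#' DPSS-tapered periodograms averaged over tapers in sliding windows. Bin
#' timestamps follow the causal convention: each bin is stamped with its
#' window's end time, so a bin at time `t` uses only samples up to `t`.
#'
#' @param voltage channels x samples matrix (a vector is treated as one
#'   channel).
#' @param sample_rate_hz sampling rate (Hz).
#' @param params [spectral_params()].
#' @return list: `power` (channels x bins x freqs array), `bin_times_s`
#'   (window end times), `freqs` (0 to Nyquist), `params`.
#' @export
multitaper_power <- function(voltage, sample_rate_hz, params = spectral_params()) {
  if (is.vector(voltage)) voltage <- matrix(voltage, nrow = 1)
  fs <- sample_rate_hz
  L <- round(params$window_s * fs)
  n <- ncol(voltage)
  if (n < L) stopf("signal shorter than one window")
  hop <- max(1L, round(L * (1 - params$overlap_fraction)))
  starts <- seq(1L, n - L + 1L, by = hop)
  tap <- dpss_tapers(L, params$nw, params$n_tapers)
  nfreq <- L %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * fs / L
  C <- nrow(voltage)
  pow <- array(0, dim = c(C, length(starts), nfreq))
  idx <- outer(seq_len(L) - 1L, starts, "+")
  for (ch in seq_len(C)) {
    seg <- matrix(voltage[ch, ][idx], nrow = L)
    acc <- matrix(0, nfreq, ncol(seg))
    for (k in seq_len(params$n_tapers)) {
      ft <- mvfft(seg * tap[, k])[seq_len(nfreq), , drop = FALSE]
      acc <- acc + (Mod(ft)^2) / params$n_tapers
    }
    pow[ch, , ] <- t(acc)
  }
  list(power = pow, bin_times_s = (starts - 1L + L) / fs, freqs = freqs,
       params = params)
}

#' 1/f spectral normalization
#'
#' Divides power at each channel and frequency by that frequency's mean over
#' all time bins (the whole recording), correcting the characteristic 1/f
#' decay; the temporal mean of the output is 1 at every retained frequency.
#'
#' @param mt output of [multitaper_power()], or a bare channels x bins x
#'   freqs array.
#' @return same structure with normalized power.
#' @export
normalize_one_over_f <- function(mt) {
  pow <- if (is.list(mt)) mt$power else mt
  g <- apply(pow, c(1, 3), mean)            # channels x freqs
  if (any(g == 0))
    stopf("zero mean power at some frequency; cannot normalize")
  pow <- pow / aperm(array(g, dim = c(dim(pow)[1], dim(pow)[3], dim(pow)[2])),
                     c(1, 3, 2))
  if (is.list(mt)) { mt$power <- pow; mt } else pow
}

#' Baseline-referenced broadband high-gamma power map
#'
#' Averages (1/f-normalized) power over the high-gamma band (band edges
#' inclusive) and converts to decibels against each channel's mean baseline
#' band power pooled across all supplied baseline windows:
#' `dB = 10 log10(bin power / pooled baseline power)`.
#'
#' @param mt output of [multitaper_power()] (normalize first with
#'   [normalize_one_over_f()] for the standard chain).
#' @param band_hz band edges (Hz), inclusive; defaults to the params' band.
#' @param baseline_windows 2-column matrix of `(start, end)` times in
#'   seconds; bins whose windows fall entirely inside any baseline window
#'   form the baseline pool.
#' @param alignment label stored with the map.
#' @return object of class `msom_hgmap`: `values` (channels x bins, dB),
#'   `bin_times_s`, `alignment`, `baseline_power` (per channel), `band_hz`.
#' @export
highgamma_db <- function(mt, band_hz = NULL, baseline_windows,
                         alignment = "recording") {
  band_hz <- band_hz %||% mt$params$band_hz
  baseline_windows <- matrix(baseline_windows, ncol = 2)
  if (nrow(baseline_windows) == 0) stopf("baseline windows must be non-empty")
  bsel <- mt$freqs >= band_hz[1] & mt$freqs <= band_hz[2]
  if (!any(bsel)) stopf("band outside the frequency axis")
  bp <- apply(mt$power[, , bsel, drop = FALSE], c(1, 2), mean)
  if (is.null(dim(bp))) bp <- matrix(bp, nrow = dim(mt$power)[1])
  wlen <- mt$params$window_s
  in_base <- rep(FALSE, length(mt$bin_times_s))
  for (i in seq_len(nrow(baseline_windows)))
    in_base <- in_base |
      (mt$bin_times_s - wlen >= baseline_windows[i, 1] - 1e-9 &
       mt$bin_times_s <= baseline_windows[i, 2] + 1e-9)
  if (!any(in_base)) stopf("no bins inside the baseline windows")
  base <- rowMeans(bp[, in_base, drop = FALSE])
  vals <- 10 * log10(sweep(bp, 1, base, "/"))
  structure(list(values = vals, bin_times_s = mt$bin_times_s,
                 alignment = alignment, baseline_power = base,
                 band_hz = band_hz, params = mt$params),
            class = "msom_hgmap")
}

# --- fast epoch-restricted band power --------------------------------------

# DFT rows restricted to the band bins of an L-sample window.
band_dft <- function(L, fs, band_hz) {
  freqs <- (0:(L %/% 2)) * fs / L
  sel <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (!length(sel)) stopf("band outside frequency axis for this window")
  k <- sel - 1
  ang <- -2 * pi * outer(k, 0:(L - 1)) / L
  list(re = cos(ang), im = sin(ang), freqs = freqs[sel])
}

# Band power per analysis window for a set of epochs, with per-channel 1/f
# correction estimated from all extracted windows. Common-average
# referencing and zero-imputation are fused into the compiled windowing
# kernel. Returns an epochs x channels matrix of epoch-mean normalized band
# power (zero for excluded channels).
#
# voltage: channels x samples (raw); epochs: 2-col matrix of (start_s,
# end_s); windows inside an epoch advance by `epoch_overlap` fractional
# overlap (0 = non-overlapping).
epoch_band_power <- function(voltage, fs, epochs, params = spectral_params(),
                             epoch_overlap = 0, include = NULL, car = TRUE) {
  if (is.null(include)) include <- rep(TRUE, nrow(voltage))
  if (!any(include)) stopf("no included channels")
  L <- round(params$window_s * fs)
  hop <- max(1L, round(L * (1 - epoch_overlap)))
  starts <- integer(0)
  epoch_of <- integer(0)
  n <- ncol(voltage)
  for (i in seq_len(nrow(epochs))) {
    a <- max(0L, round(epochs[i, 1] * fs))
    b <- min(n, round(epochs[i, 2] * fs))
    if (b - a < L) stopf("epoch %d shorter than one window", i)
    st <- seq(a, b - L, by = hop)
    starts <- c(starts, st)
    epoch_of <- c(epoch_of, rep(i, length(st)))
  }
  car_mean <- if (car) colMeans(voltage[include, , drop = FALSE]) else numeric(0)
  tap <- dpss_tapers(L, params$nw, params$n_tapers)
  bd <- band_dft(L, fs, params$band_hz)
  # (n_windows * channels) x n_band_bins power
  pw <- cpp_window_band_power(voltage, starts, tap, bd$re, bd$im,
                              car_mean, as.integer(include))
  nw <- length(starts); C <- nrow(voltage)
  ne <- nrow(epochs)
  out <- matrix(0, ne, C)
  cnt <- tabulate(epoch_of, nbins = ne)
  for (ch in which(include)) {
    p <- pw[(ch - 1) * nw + seq_len(nw), , drop = FALSE]
    g <- colMeans(p)                        # recording-mean per frequency
    if (all(g > 0)) p <- sweep(p, 2, g, "/")
    bpow <- rowMeans(p)                     # band average per window
    out[, ch] <- as.vector(rowsum(bpow, epoch_of)) / cnt
  }
  out
}

#' Movement-vs-rest per-trial band power
#'
#' The per-trial inputs of the effect-size and inference stage: for each
#' non-excluded trial, the common-average-referenced, 1/f-corrected
#' multitaper band power averaged over the movement epoch (onset to offset)
#' and over a rest epoch. Rest epochs are 500 ms baselines anchored at the
#' audio cue (default) or at movement onset, or an explicit set of rest
#' windows (e.g. from [find_rest_segments()] for self-paced sessions).
#'
#' @param session an `msom_session`.
#' @param params [spectral_params()].
#' @param baseline `"sound_cue"` or `"onset"` anchoring of per-trial
#'   baselines.
#' @param baseline_s baseline window length (s).
#' @param rest_windows optional explicit rest windows (2-column matrix of
#'   start/end seconds) replacing per-trial baselines.
#' @param epoch_overlap fractional overlap of analysis windows within an
#'   epoch (0 = non-overlapping).
#' @param use_excluded keep kinematically excluded trials.
#' @return list: `power` (channels x trials), `labels` (1 movement / 0
#'   rest), `trials` (table rows used), `included_channels`.
#' @export
movement_rest_power <- function(session, params = spectral_params(),
                                baseline = c("sound_cue", "onset"),
                                baseline_s = 0.5, rest_windows = NULL,
                                epoch_overlap = 0, use_excluded = FALSE) {
  baseline <- match.arg(baseline)
  trials <- session$trials
  keep <- if (use_excluded) rep(TRUE, nrow(trials)) else !trials$excluded
  trials <- trials[keep, , drop = FALSE]
  include <- impedance_mask(session$impedance_ohm)
  mov <- cbind(trials$onset_t, trials$offset_t)
  rest <- if (!is.null(rest_windows)) matrix(rest_windows, ncol = 2)
          else if (baseline == "sound_cue")
            cbind(trials$sound_cue_t - baseline_s, trials$sound_cue_t)
          else cbind(trials$onset_t - baseline_s, trials$onset_t)
  ep <- rbind(mov, rest)
  pw <- epoch_band_power(session$voltage, session$sample_rate_hz, ep, params,
                         epoch_overlap, include = include)
  labels <- c(rep(1L, nrow(mov)), rep(0L, nrow(rest)))
  list(power = t(pw), labels = labels, trials = trials,
       included_channels = include)
}

#' Onset-aligned high-gamma dB cube
#'
#' Time-resolved per-trial broadband high-gamma power for decoding and
#' timecourse analyses: trials x channels x bins arrays where bin end-times
#' run over `t_range` (relative to movement onset) in steps of `hop_s`
#' (causal convention: a bin at `t` uses only samples up to `t`). Values are
#' common-average-referenced, 1/f-corrected multitaper band power, as raw
#' normalized power (`power`) and as dB against the channel's pooled
#' baseline (`db`); `trial_baseline` holds each trial's own baseline power.
#' Excluded (high-impedance) channels propagate as 0 dB.
#'
#' @param session an `msom_session`.
#' @param t_range bin end-time range (s, relative to onset).
#' @param hop_s bin spacing (s).
#' @param params [spectral_params()].
#' @param baseline,baseline_s per-trial baseline anchoring as in
#'   [movement_rest_power()].
#' @param use_excluded keep kinematically excluded trials (they remain
#'   usable for decoding).
#' @return list: `db`, `power` (trials x channels x bins),
#'   `trial_baseline` (trials x channels), `bin_times_s`, `trials`,
#'   `baseline_power`, `params`, `included_channels`.
#' @export
epoched_hg_db <- function(session, t_range = c(-1, 1), hop_s = 0.01,
                          params = spectral_params(),
                          baseline = c("sound_cue", "onset"),
                          baseline_s = 0.5, use_excluded = TRUE) {
  baseline <- match.arg(baseline)
  fs <- session$sample_rate_hz
  L <- round(params$window_s * fs)
  trials <- session$trials
  if (!use_excluded) trials <- trials[!trials$excluded, , drop = FALSE]
  include <- impedance_mask(session$impedance_ohm)
  v <- session$voltage
  bin_t <- seq(t_range[1], t_range[2], by = hop_s)
  nb <- length(bin_t); nt <- nrow(trials); C <- nrow(v)
  # window starts (0-based samples) for every trial x bin, then baselines
  starts <- integer(0)
  for (i in seq_len(nt)) {
    st <- round((trials$onset_t[i] + bin_t) * fs) - L
    if (any(st < 0) || any(st + L > ncol(v)))
      stopf("epoch range extends beyond the recording for trial %d", i)
    starts <- c(starts, st)
  }
  anchor <- if (baseline == "sound_cue") trials$sound_cue_t else trials$onset_t
  bstarts <- integer(0)
  nbw <- max(1L, floor(baseline_s / params$window_s))
  for (i in seq_len(nt)) {
    a <- round((anchor[i] - baseline_s) * fs)
    bstarts <- c(bstarts, a + (seq_len(nbw) - 1L) * L)
  }
  all_starts <- c(starts, bstarts)
  car_mean <- colMeans(v[include, , drop = FALSE])
  tap <- dpss_tapers(L, params$nw, params$n_tapers)
  bd <- band_dft(L, fs, params$band_hz)
  pw <- cpp_window_band_power(v, as.integer(all_starts), tap, bd$re, bd$im,
                              car_mean, as.integer(include))
  nwin <- length(all_starts)
  db <- array(0, dim = c(nt, C, nb))
  pow <- array(0, dim = c(nt, C, nb))
  trial_base <- matrix(0, nt, C)
  base_pow <- numeric(C)
  for (ch in which(include)) {
    p <- pw[(ch - 1) * nwin + seq_len(nwin), , drop = FALSE]
    g <- colMeans(p)
    if (all(g > 0)) p <- sweep(p, 2, g, "/")
    bpow <- rowMeans(p)
    trial_p <- matrix(bpow[seq_len(nt * nb)], nrow = nb)   # bins x trials
    bwin <- matrix(bpow[nt * nb + seq_len(nt * nbw)], nrow = nbw)
    trial_base[, ch] <- colMeans(bwin)
    base <- mean(bwin)
    base_pow[ch] <- base
    pow[, ch, ] <- t(trial_p)
    db[, ch, ] <- t(10 * log10(trial_p / base))
  }
  list(db = db, power = pow, trial_baseline = trial_base,
       bin_times_s = bin_t, trials = trials,
       baseline_power = base_pow, params = params,
       included_channels = include)
}
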