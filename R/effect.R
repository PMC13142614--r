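#' TFCE parameters
#'
#' Height exponent `H = 2`, extent exponent `E = 1`, threshold step
#' `dh = 0.1`, with 8-neighbour grid connectivity. The threshold set starts
#' at `dh` and cells enter a component when their statistic is `>= h`.
#'
#' @param H,E,dh TFCE height/extent exponents and integration step.
#' @return list of class `msom_tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 1, dh = 0.1) {
  if (dh <= 0) stopf("dh must be positive")
  if (H < 0 || E < 0) stopf("exponents must be >= 0")
  structure(list(H = H, E = E, dh = dh), class = "msom_tfce_params")
}

#' Signed R-squared effect size
#'
#' The fraction of variance in per-trial band power explained by the
#' movement/rest partition, signed by the direction of the mean difference
#' and penalized for unbalanced trial counts:
#' `sign(m - r) (m - r)^2 N_m N_r / (sigma^2 N^2)` with `sigma^2` the pooled
#' variance over the union of both conditions and `N = N_m + N_r`. With the
#' population (divide-by-N) variance convention the statistic is bounded in
#' `[-1, 1]` and reaches 1 for perfectly separated balanced samples.
#'
#' @param movement,rest numeric vectors of per-trial values.
#' @param var_type `"population"` (default) or `"sample"` variance for the
#'   pooled denominator.
#' @return scalar in `[-1, 1]`.
#' @export
signed_r2 <- function(movement, rest, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  if (!length(movement) || !length(rest)) stopf("empty condition")
  nm <- length(movement); nr <- length(rest)
  u <- c(movement, rest)
  n <- nm + nr
  s2 <- if (var_type == "population") mean(u^2) - mean(u)^2
        else stats::var(u)
  d <- mean(movement) - mean(rest)
  if (s2 <= 0) return(0)
  sign(d) * d^2 * nm * nr / (s2 * n^2)
}

# Vectorized per-channel signed R^2 over a channels x trials power matrix.
signed_r2_map <- function(power, labels, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  mov <- labels == 1
  nm <- sum(mov); nr <- sum(!mov)
  if (nm == 0 || nr == 0) stopf("both conditions must be non-empty")
  n <- nm + nr
  mbar <- rowMeans(power[, mov, drop = FALSE])
  rbar <- rowMeans(power[, !mov, drop = FALSE])
  mu <- rowMeans(power)
  s2 <- rowMeans(power^2) - mu^2
  if (var_type == "sample") s2 <- s2 * n / (n - 1)
  d <- mbar - rbar
  out <- sign(d) * d^2 * nm * nr / (s2 * n^2)
  out[s2 <= 0] <- 0
  out
}

#' Threshold-free cluster enhancement on the electrode grid
#'
#' For each cell, integrates `h^H * extent(c, h)^E * dh` over thresholds
#' `h = dh, 2dh, ...` up to the map maximum, where `extent(c, h)` is the size
#' of the 8-connected component of supra-threshold cells containing `c`.
#' Only the positive direction is scored; pass `-stat` for the negative
#' direction.
#'
#' @param stat per-channel statistic (with `geometry`) or a grid matrix
#'   (NA = unoccupied cell).
#' @param params [tfce_params()].
#' @param geometry required when `stat` is a per-channel vector.
#' @return TFCE scores in the same shape as the input (per-channel vector or
#'   grid matrix; unmapped channels score NA).
#' @export
tfce_map <- function(stat, params = tfce_params(), geometry = NULL) {
  if (is.matrix(stat)) return(cpp_tfce(stat, params$H, params$E, params$dh))
  if (is.null(geometry)) stopf("geometry required for per-channel input")
  if (any(!is.finite(stat[cell_index(geometry) >= 0])))
    stopf("statistic must be finite on mapped channels")
  g <- grid_embed(stat, geometry)
  grid_extract(cpp_tfce(g, params$H, params$E, params$dh), geometry)
}

#' Directional max-statistic permutation inference with TFCE
#'
#' Computes the observed signed-R^2 map and its TFCE scores in both
#' directions, then builds directional null distributions by shuffling
#' movement/rest labels over the pooled trials (`n_perm` times), recomputing
#' the statistic map and TFCE, and recording the maximum TFCE score over all
#' electrodes per direction. Per-channel p-values follow the
#' `(k + 1) / (n_perm + 1)` rule against the directional maxima, and a
#' channel is significant when either directional p-value falls below
#' `alpha` (default 0.025 per direction, i.e. two-tailed family-wise 0.05).
#'
#' @param power channels x trials matrix of per-trial band power.
#' @param labels per-trial 1 (movement) / 0 (rest) flags.
#' @param geometry array geometry for the spatial embedding.
#' @param params [tfce_params()].
#' @param n_perm number of permutations.
#' @param alpha per-direction significance level.
#' @param seed RNG seed for the shuffles (scoped).
#' @param stat `"signed_r2"` (default) or `"t"` (pooled-variance t map).
#' @return object of class `msom_effect_map`: `signed_r2`, `tfce_pos`,
#'   `tfce_neg`, `p_pos`, `p_neg`, `significant`, `max_pos`, `max_neg`
#'   (null maxima), `n_perm`, `alpha`, `seed`.
#' @export
permutation_fwer <- function(power, labels, geometry, params = tfce_params(),
                             n_perm = 5000, alpha = 0.025, seed = NULL,
                             stat = c("signed_r2", "t")) {
  stat <- match.arg(stat)
  if (ncol(power) < 2) stopf("need at least two trials")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  labels <- as.integer(labels)
  with_seed(seed, {
    perms <- t(replicate(n_perm, sample(labels)))
    res <- cpp_perm_max_tfce(power, labels, perms, cell_index(geometry),
                             geometry$n_rows, geometry$n_cols,
                             params$H, params$E, params$dh,
                             if (stat == "signed_r2") 0L else 1L)
    obs <- res$observed
    tp <- tfce_map(obs, params, geometry)
    tn <- tfce_map(-obs, params, geometry)
    p_pos <- (vapply(tp, function(x) sum(res$max_pos >= x), 0) + 1) /
      (n_perm + 1)
    p_neg <- (vapply(tn, function(x) sum(res$max_neg >= x), 0) + 1) /
      (n_perm + 1)
    p_pos[is.na(tp)] <- NA; p_neg[is.na(tn)] <- NA
    structure(list(
      signed_r2 = obs, tfce_pos = tp, tfce_neg = tn,
      p_pos = p_pos, p_neg = p_neg,
      significant = !is.na(p_pos) & (pmin(p_pos, p_neg) < alpha),
      max_pos = res$max_pos, max_neg = res$max_neg,
      n_perm = n_perm, alpha = alpha, seed = seed, stat = stat,
      geometry = geometry
    ), class = "msom_effect_map")
  })
}

#' @export
print.msom_effect_map <- function(x, ...) {
  cat(sprintf(
    "<msom_effect_map> %d channels, %d significant (alpha = %g/direction, %d perms)\n",
    length(x$signed_r2), sum(x$significant, na.rm = TRUE), x$alpha, x$n_perm))
  invisible(x)
}

#' Extent of activation
#'
#' Sum of signed R^2 over channels that are both TFCE-significant and
#' positively modulated; zero when no channel qualifies.
#'
#' @param effect an `msom_effect_map`, or a list with `signed_r2` and
#'   `significant`.
#' @return scalar EoA.
#' @export
eoa <- function(effect) {
  sel <- !is.na(effect$significant) & effect$significant &
    effect$signed_r2 > 0
  if (!any(sel)) return(0)
  sum(effect$signed_r2[sel])
}

#' Time-resolved extent of activation
#'
#' Runs the movement-vs-rest permutation test independently at every time
#' bin of an onset-aligned power cube, sharing one set of label shuffles
#' across bins and taking the null maxima over channels *and* bins so the
#' family-wise error rate is controlled over the whole channels x time map.
#' Returns the EoA series with its onset (first bin with any significant
#' channel), peak (earliest argmax) and onset-to-peak latency.
#'
#' @param bin_power trials x channels x bins array of movement band power
#'   (normalized), e.g. `epoched_hg_db(...)$power`.
#' @param rest_power trials x channels matrix of per-trial baseline band
#'   power.
#' @param bin_times_s bin end-times relative to movement onset.
#' @param geometry array geometry.
#' @param params,n_perm,alpha,seed,stat as in [permutation_fwer()].
#' @return list of class `msom_eoa_timecourse`: `times`, `eoa`,
#'   `n_significant`, `onset_t`, `peak_t`, `latency`, `signed_r2`
#'   (channels x bins), `significant` (channels x bins).
#' @export
eoa_timecourse <- function(bin_power, rest_power, bin_times_s, geometry,
                           params = tfce_params(), n_perm = 1000,
                           alpha = 0.025, seed = NULL,
                           stat = c("signed_r2", "t")) {
  stat <- match.arg(stat)
  nb <- dim(bin_power)[3]
  nt <- dim(bin_power)[1]
  C <- dim(bin_power)[2]
  labels <- c(rep(1L, nt), rep(0L, nt))
  stat_code <- if (stat == "signed_r2") 0L else 1L
  cells <- cell_index(geometry)
  with_seed(seed, {
    perms <- t(replicate(n_perm, sample(labels)))
    max_pos <- max_neg <- matrix(0, n_perm, nb)
    obs <- tp <- tn <- matrix(0, C, nb)
    for (b in seq_len(nb)) {
      pw <- cbind(t(bin_power[, , b]), t(rest_power))
      res <- cpp_perm_max_tfce(pw, labels, perms, cells,
                               geometry$n_rows, geometry$n_cols,
                               params$H, params$E, params$dh, stat_code)
      obs[, b] <- res$observed
      tp[, b] <- tfce_map(res$observed, params, geometry)
      tn[, b] <- tfce_map(-res$observed, params, geometry)
      max_pos[, b] <- res$max_pos
      max_neg[, b] <- res$max_neg
    }
    gp <- apply(max_pos, 1, max)        # maxima over channels AND bins
    gn <- apply(max_neg, 1, max)
    p_pos <- (matrix(vapply(tp, function(x) sum(gp >= x), 0), C, nb) + 1) /
      (n_perm + 1)
    p_neg <- (matrix(vapply(tn, function(x) sum(gn >= x), 0), C, nb) + 1) /
      (n_perm + 1)
    sig <- !is.na(tp) & (p_pos < alpha | p_neg < alpha)
    eoa_series <- vapply(seq_len(nb), function(b) {
      sel <- sig[, b] & obs[, b] > 0
      if (any(sel)) sum(obs[sel, b]) else 0
    }, 0)
    n_sig <- colSums(sig)
    onset_t <- if (any(n_sig > 0)) bin_times_s[which(n_sig > 0)[1]] else NA_real_
    peak_t <- bin_times_s[which.max(eoa_series)]   # earliest bin on ties
    structure(list(times = bin_times_s, eoa = eoa_series,
                   n_significant = n_sig, onset_t = onset_t, peak_t = peak_t,
                   latency = if (is.na(onset_t)) NA_real_ else peak_t - onset_t,
                   signed_r2 = obs, significant = sig,
                   n_perm = n_perm, alpha = alpha),
              class = "msom_eoa_timecourse")
  })
}

#' Per-trial window-averaged high-gamma power
#'
#' Averages each trial's dB values over the window from the first
#' statistically significant lag (from the pooled TFCE analysis) to that
#' trial's movement end, first over time bins and then over channels,
#' yielding one scalar per trial labelled by its flexion/extension
#' direction. Trials with an empty window are dropped with a warning.
#'
#' @param hg output of `epoched_hg_db()` (uses its `db` cube, bin times and
#'   trial table).
#' @param lag_t start of the averaging window (s, relative to onset).
#' @param channels optional channel subset (default all included channels).
#' @return data.frame: `trial`, `label`, `direction`, `value` (dB).
#' @export
trial_window_average <- function(hg, lag_t, channels = NULL) {
  trials <- hg$trials
  if (is.null(channels)) channels <- which(hg$included_channels)
  out <- lapply(seq_len(nrow(trials)), function(i) {
    end_t <- trials$offset_t[i] - trials$onset_t[i]
    sel <- hg$bin_times_s >= lag_t - 1e-9 & hg$bin_times_s <= end_t + 1e-9
    if (!any(sel)) {
      warning(sprintf("trial %d has an empty averaging window; skipped",
                      trials$trial[i]))
      return(NULL)
    }
    # equal weights: bins-then-channels averaging equals the grand mean
    val <- mean(hg$db[i, channels, sel])
    data.frame(trial = trials$trial[i], label = trials$label[i],
               direction = trials$direction[i], value = val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
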