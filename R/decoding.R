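#' Causal window features for time-resolved decoding
#'
#' At each decoding timepoint `t` (every 50 ms from -1 s to +1 s around
#' movement onset by default), the feature vector is the 100 ms of
#' high-gamma bins *ending* at `t` (10 bins at 10 ms resolution), flattened
#' channel-major, so features at `t` never use samples after `t`.
#'
#' @param hg output of `epoched_hg_db()` with 10 ms bin spacing (uses the
#'   `db` cube).
#' @param t_range decoding time range (s, relative to onset).
#' @param step decoding timepoint spacing (s).
#' @param window integration window length (s).
#' @return object of class `msom_windows`: `times`, `features` (list of
#'   trials x (channels * window bins) matrices), `n_channels`,
#'   `window_bins`.
#' @export
causal_windows <- function(hg, t_range = c(-1, 1), step = 0.05,
                           window = 0.1) {
  bt <- hg$bin_times_s
  hop <- stats::median(diff(bt))
  wb <- round(window / hop)
  times <- seq(t_range[1], t_range[2], by = step)
  nt <- dim(hg$db)[1]; C <- dim(hg$db)[2]
  feats <- lapply(times, function(t0) {
    sel <- which(bt > t0 - window + 1e-9 & bt <= t0 + 1e-9)
    if (length(sel) != wb)
      stopf("epoch does not cover the window ending at %g s", t0)
    m <- matrix(0, nt, C * wb)
    for (ch in seq_len(C))
      m[, (ch - 1) * wb + seq_len(wb)] <- hg$db[, ch, sel]
    m
  })
  structure(list(times = times, features = feats, n_channels = C,
                 window_bins = wb, labels_hint = hg$trials$label),
            class = "msom_windows")
}

#' Class balancing by undersampling
#'
#' If the ratio between the most and least frequent class exceeds
#' `ratio_threshold` (1.2), every class is randomly subsampled without
#' replacement to the smallest class count; otherwise all trials are kept.
#'
#' @param labels per-trial class labels.
#' @param ratio_threshold imbalance ratio triggering undersampling.
#' @param seed RNG seed (scoped).
#' @return sorted indices of the kept trials.
#' @export
balance_classes <- function(labels, ratio_threshold = 1.2, seed = NULL) {
  cnt <- table(labels)
  if (length(cnt) < 2) stopf("need at least two classes")
  if (any(cnt == 0)) stopf("empty class")
  if (max(cnt) / min(cnt) <= ratio_threshold) return(seq_along(labels))
  m <- min(cnt)
  with_seed(seed, {
    kept <- unlist(lapply(names(cnt), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
    sort(kept)
  })
}

# stratified fold assignment (shared across all train times)
stratified_folds <- function(labels, folds) {
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    f[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  f
}

# rank-based (Mann-Whitney) AUC of scores for binary truth
auc_binary <- function(scores, truth) {
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Temporal-generalization decoding with sparse linear classifiers
#'
#' Trains an L1-regularized logistic model (one-vs-rest for more than two
#' classes; inverse regularization strength `C = 0.1`) at every training
#' timepoint under 5-fold stratified cross-validation, and evaluates
#' accuracy and macro one-vs-rest AUC at every testing timepoint on the
#' held-out folds. Features are standardized per dimension with
#' training-fold statistics only; multi-class predictions take the argmax of
#' the per-class decision values (ties to the earlier class). Fold
#' assignment is shared across training times.
#'
#' @param windows an [causal_windows()] object.
#' @param labels per-trial class labels.
#' @param C inverse regularization strength (glmnet lambda is
#'   `1 / (C * n_train)`).
#' @param folds cross-validation folds.
#' @param seed RNG seed (scoped; governs folds).
#' @param diagonal_only evaluate only same-time decoding (faster).
#' @return object of class `msom_generalization`: `times`, `accuracy` and
#'   `auc` (train x test matrices), `confusion` (true x predicted
#'   proportions, diagonal-time, averaged over folds), `chance`, `classes`.
#' @export
temporal_generalization <- function(windows, labels, C = 0.1, folds = 5,
                                    seed = NULL, diagonal_only = FALSE) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  k <- length(classes)
  if (k < 2) stopf("need at least two classes")
  if (min(table(labels)) < folds)
    stopf("every class needs at least as many trials as folds")
  nt <- length(windows$times)
  with_seed(seed, {
    fold <- stratified_folds(labels, folds)
    acc <- auc <- matrix(NA_real_, nt, nt)
    conf <- array(0, dim = c(folds, k, k),
                  dimnames = list(NULL, classes, classes))
    for (i in seq_len(nt)) {
      Xi <- windows$features[[i]]
      test_range <- if (diagonal_only) i else seq_len(nt)
      acc_f <- auc_f <- matrix(0, folds, length(test_range))
      for (f in seq_len(folds)) {
        tr <- fold != f
        mu <- colMeans(Xi[tr, , drop = FALSE])
        sdv <- apply(Xi[tr, , drop = FALSE], 2, sd)
        sdv[sdv == 0] <- 1
        Xtr <- scale(Xi[tr, , drop = FALSE], mu, sdv)
        lam <- 1 / (C * sum(tr))
        # one-vs-rest coefficient matrix (p x k) + intercepts
        coefs <- vapply(classes, function(cl) {
          fit <- glmnet::glmnet(Xtr, factor(labels[tr] == cl, c(FALSE, TRUE)),
                                family = "binomial", alpha = 1, lambda = lam,
                                standardize = FALSE)
          as.vector(as.matrix(stats::coef(fit)))
        }, numeric(ncol(Xtr) + 1))
        for (jj in seq_along(test_range)) {
          j <- test_range[jj]
          Xte <- scale(windows$features[[j]][!tr, , drop = FALSE], mu, sdv)
          dec <- sweep(Xte %*% coefs[-1, , drop = FALSE], 2,
                       coefs[1, ], "+")
          pred <- classes[max.col(dec, ties.method = "first")]
          truth <- labels[!tr]
          acc_f[f, jj] <- mean(pred == truth)
          auc_f[f, jj] <- mean(vapply(seq_len(k), function(ci)
            auc_binary(dec[, ci], truth == classes[ci]), 0), na.rm = TRUE)
          if (j == i)
            for (ci in seq_len(k)) {
              sel <- truth == classes[ci]
              if (any(sel))
                conf[f, ci, ] <- conf[f, ci, ] +
                  vapply(classes, function(p) mean(pred[sel] == p), 0)
            }
        }
      }
      acc[i, test_range] <- colMeans(acc_f)
      auc[i, test_range] <- colMeans(auc_f)
    }
    conf <- conf / nt                      # averaged over diagonal times
    structure(list(times = windows$times, accuracy = acc, auc = auc,
                   confusion = apply(conf, c(2, 3), mean),
                   confusion_per_fold = conf,
                   chance = 1 / k, classes = classes, folds = folds),
              class = "msom_generalization")
  })
}

#' Symmetrized pairwise confusion rates
#'
#' Averages the off-diagonal confusion entries `(i, j)` and `(j, i)`; the
#' diagonal is left NA.
#'
#' @param confusion square true x predicted proportion matrix.
#' @return symmetric matrix of pairwise confusion rates.
#' @export
symmetric_confusion <- function(confusion) {
  if (nrow(confusion) != ncol(confusion)) stopf("confusion must be square")
  out <- (confusion + t(confusion)) / 2
  diag(out) <- NA_real_
  out
}

#' Encoding-decoding coupling
#'
#' Interpolates an EoA timecourse to the decoding time axis with a cubic
#' spline (values outside the EoA range set to zero) and returns the Pearson
#' correlation with the decoding series.
#'
#' @param eoa_times,eoa_values encoding (EoA) series.
#' @param dec_times,dec_values decoding series (accuracy or AUC).
#' @return list: `r`, `p`, `interpolated` (EoA on the decoding grid);
#'   `r` is NA with a `degenerate` flag when either series is constant.
#' @export
encode_decode_coupling <- function(eoa_times, eoa_values, dec_times,
                                   dec_values) {
  if (length(dec_times) < 3) stopf("need at least three decoding timepoints")
  f <- splinefun(eoa_times, eoa_values, method = "natural")
  interp <- f(dec_times)
  interp[dec_times < min(eoa_times) - 1e-9 |
           dec_times > max(eoa_times) + 1e-9] <- 0
  if (sd(interp) == 0 || sd(dec_values) == 0)
    return(list(r = NA_real_, p = NA_real_, interpolated = interp,
                degenerate = TRUE))
  ct <- cor.test(interp, dec_values)
  list(r = unname(ct$estimate), p = ct$p.value, interpolated = interp,
       degenerate = FALSE)
}
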