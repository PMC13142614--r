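#' Coordinate-activation correlation along one anatomical axis
#'
#' Pearson product-moment correlation between per-electrode coordinates on
#' one standard-space axis and trial-averaged activation.
#'
#' @param coords_mm per-channel axis coordinate (mm).
#' @param activation_db per-channel activation (dB).
#' @return scalar r, or NA (with a message) when either input is constant.
#' @export
axis_correlation <- function(coords_mm, activation_db) {
  ok <- is.finite(coords_mm) & is.finite(activation_db)
  if (sum(ok) < 3) stopf("need at least three channels with valid values")
  x <- coords_mm[ok]; y <- activation_db[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    message("constant coordinate or activation; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Fisher-z pooling of per-participant correlations
#'
#' Transforms `z = atanh(r)`, averages across participants, back-transforms
#' the pooled mean, forms a 95% CI from the normal approximation on z
#' (`mean z +/- 1.96 SE`), and tests the pooled z against zero with a
#' one-sample t-test on n - 1 degrees of freedom.
#'
#' @param rs per-participant correlation coefficients, all strictly inside
#'   (-1, 1).
#' @param ci_method `"normal"` (default, +/- 1.96 SE on z) or `"t"`.
#' @return list: `r` (pooled, back-transformed), `ci95`, `t`, `df`, `p`,
#'   `z_mean`, `n`. With zero variance across participants `t` and `p` are
#'   NA and flagged `degenerate`.
#' @export
fisher_pool <- function(rs, ci_method = c("normal", "t")) {
  ci_method <- match.arg(ci_method)
  if (length(rs) < 2) stopf("need at least two participants")
  if (any(abs(rs) >= 1)) stopf("|r| must be < 1 for the Fisher transform")
  z <- atanh(rs)
  n <- length(z)
  zm <- mean(z)
  se <- sd(z) / sqrt(n)
  crit <- if (ci_method == "normal") 1.96 else qt(0.975, n - 1)
  ci <- tanh(zm + c(-1, 1) * crit * se)
  if (se == 0) {
    return(list(r = tanh(zm), ci95 = ci, t = NA_real_, df = n - 1,
                p = NA_real_, z_mean = zm, n = n, degenerate = TRUE))
  }
  tval <- zm / se
  list(r = tanh(zm), ci95 = ci, t = tval, df = n - 1,
       p = 2 * pt(-abs(tval), n - 1), z_mean = zm, n = n,
       degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1 (delegates
#' to [stats::p.adjust()]).
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' First-order partial correlation
#'
#' Correlation of `x` and `y` after removing the linear effect of
#' `control`: `(r_xy - r_xc r_yc) / sqrt((1 - r_xc^2)(1 - r_yc^2))`.
#'
#' @param x,y,control numeric vectors (>= 4 observations).
#' @return scalar partial r, or NA (flagged by a message) when `control` is
#'   collinear with `x` or `y`.
#' @export
partial_correlation <- function(x, y, control) {
  if (length(x) < 4) stopf("need at least four observations")
  rxy <- cor(x, y); rxc <- cor(x, control); ryc <- cor(y, control)
  den <- (1 - rxc^2) * (1 - ryc^2)
  if (!is.finite(den) || den <= 1e-12) {
    message("control collinear with x or y; partial correlation undefined")
    return(NA_real_)
  }
  (rxy - rxc * ryc) / sqrt(den)
}

#' Cross-participant spatial-gradient analysis
#'
#' For each participant, correlates per-electrode standard-space coordinates
#' with activation along the three anatomical axes (medial-lateral,
#' anterior-posterior, inferior-superior); pools each axis across
#' participants with [fisher_pool()] and corrects the three axis p-values
#' with [bh_fdr()]. Medial-lateral is operationalized as `|x|` by default so
#' both hemispheres pool with a consistent sign (`mode = "signedx"` keeps
#' the signed coordinate).
#'
#' @param cohort data.frame with columns `participant`, `x_mm`, `y_mm`,
#'   `z_mm`, `activation_db`.
#' @param mode `"absx"` or `"signedx"` handling of the mediolateral axis.
#' @return list: `per_participant` (participant x axis r matrix), `pooled`
#'   (data.frame: axis, r, ci_lo, ci_hi, t, df, p_raw, p_fdr).
#' @export
gradient_analysis <- function(cohort, mode = c("absx", "signedx")) {
  mode <- match.arg(mode)
  axes <- c("medial-lateral" = "x_mm", "anterior-posterior" = "y_mm",
            "inferior-superior" = "z_mm")
  parts <- sort(unique(cohort$participant))
  rmat <- matrix(NA_real_, length(parts), length(axes),
                 dimnames = list(parts, names(axes)))
  for (pi in seq_along(parts)) {
    d <- cohort[cohort$participant == parts[pi], ]
    for (ai in seq_along(axes)) {
      co <- d[[axes[ai]]]
      if (axes[ai] == "x_mm" && mode == "absx") co <- abs(co)
      rmat[pi, ai] <- axis_correlation(co, d$activation_db)
    }
  }
  pooled <- lapply(seq_along(axes), function(ai) {
    fp <- fisher_pool(rmat[, ai])
    data.frame(axis = names(axes)[ai], r = fp$r, ci_lo = fp$ci95[1],
               ci_hi = fp$ci95[2], t = fp$t, df = fp$df, p_raw = fp$p,
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, pooled)
  pooled$p_fdr <- bh_fdr(pooled$p_raw)
  list(per_participant = rmat, pooled = pooled)
}
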