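#' Per-effector effect maps for a multi-movement session
#'
#' Runs the movement-vs-rest TFCE permutation analysis once per movement
#' label, sharing a single rest pool (per-trial baselines, or explicit rest
#' windows for self-paced sessions).
#'
#' @param session an `msom_session`.
#' @param rest_windows optional 2-column matrix of rest (start, end) times;
#'   when omitted, per-trial cue-anchored baselines are used.
#' @param labels movement labels to map (default: all unique trial labels).
#' @param params,n_perm,alpha,seed,stat passed to [permutation_fwer()].
#' @param spec_params [spectral_params()] for the power extraction.
#' @return named list of `msom_effect_map` objects.
#' @export
map_effectors <- function(session, rest_windows = NULL, labels = NULL,
                          params = tfce_params(), n_perm = 1000,
                          alpha = 0.025, seed = NULL,
                          spec_params = spectral_params(),
                          stat = c("signed_r2", "t")) {
  stat <- match.arg(stat)
  mr <- movement_rest_power(session, params = spec_params,
                            rest_windows = rest_windows)
  labels <- labels %||% unique(mr$trials$label)
  rest_cols <- which(mr$labels == 0)
  out <- lapply(seq_along(labels), function(i) {
    mov_cols <- which(mr$labels == 1)[mr$trials$label == labels[i]]
    if (!length(mov_cols)) stopf("no trials labelled %s", labels[i])
    pw <- mr$power[, c(mov_cols, rest_cols), drop = FALSE]
    lab <- c(rep(1L, length(mov_cols)), rep(0L, length(rest_cols)))
    permutation_fwer(pw, lab, session$geometry, params = params,
                     n_perm = n_perm, alpha = alpha,
                     seed = if (is.null(seed)) NULL else seed + i,
                     stat = stat)
  })
  names(out) <- labels
  out
}

#' One-shot single-session effect map
#'
#' Convenience wrapper chaining [movement_rest_power()] and
#' [permutation_fwer()] with the default spectral and TFCE parameters.
#'
#' @inheritParams map_effectors
#' @param ... passed to [movement_rest_power()].
#' @return an `msom_effect_map`.
#' @export
session_effect_map <- function(session, params = tfce_params(),
                               n_perm = 1000, alpha = 0.025, seed = NULL,
                               spec_params = spectral_params(), ...) {
  mr <- movement_rest_power(session, params = spec_params, ...)
  permutation_fwer(mr$power, mr$labels, session$geometry, params = params,
                   n_perm = n_perm, alpha = alpha, seed = seed)
}
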