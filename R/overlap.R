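#' Binary activation mask of an effect map
#'
#' Channels that are TFCE-significant with positive signed R^2, on the grid
#' of the map's geometry. Each electrode is modelled as a disc of radius
#' 0.2 mm (half the 400 um pitch), about 0.126 mm^2 per electrode.
#'
#' @param effect an `msom_effect_map`.
#' @param label movement label carried by the mask.
#' @param electrode_radius_mm disc radius per electrode.
#' @return object of class `msom_mask`: logical per-channel `channels`,
#'   logical grid `cells`, `label`, `electrode_radius_mm`, `geometry`.
#' @export
activation_mask <- function(effect, label = "movement",
                            electrode_radius_mm = 0.2) {
  ch <- !is.na(effect$significant) & effect$significant & effect$signed_r2 > 0
  structure(list(channels = ch,
                 cells = grid_embed(as.numeric(ch), effect$geometry, 0) > 0,
                 label = label, electrode_radius_mm = electrode_radius_mm,
                 geometry = effect$geometry),
            class = "msom_mask")
}

mask_size <- function(mask) sum(mask$cells)

#' Activation area of a mask
#'
#' `|cells| * pi * r^2` with the default electrode radius of 0.2 mm, i.e.
#' about 0.126 mm^2 per active electrode.
#'
#' @param mask an [activation_mask()].
#' @return area in mm^2.
#' @export
activation_area <- function(mask) {
  mask_size(mask) * pi * mask$electrode_radius_mm^2
}

#' Dice coefficient of two activation masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, ranging from 0 (disjoint) to 1
#' (identical); defined as 0 when both masks are empty.
#'
#' @param a,b masks on the same grid.
#' @return coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a$cells) == dim(b$cells))) stopf("masks on different grids")
  na <- sum(a$cells); nb <- sum(b$cells)
  if (na + nb == 0) {
    message("both masks empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a$cells & b$cells) / (na + nb)
}

#' Area / overlap / non-overlap matrix
#'
#' Upper triangle: pairwise Dice coefficients. Diagonal: per-mask activation
#' area (mm^2). Lower triangle: non-overlapping area, the symmetric
#' difference `|A xor B|` times the per-electrode disc area.
#'
#' @param masks list of at least two [activation_mask()] objects.
#' @return labelled square matrix.
#' @export
overlap_matrix <- function(masks) {
  k <- length(masks)
  if (k < 2) stopf("need at least two masks")
  labs <- vapply(masks, function(m) m$label, "")
  out <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    out[i, i] <- activation_area(masks[[i]])
    if (i < k) for (j in (i + 1):k) {
      out[i, j] <- dice(masks[[i]], masks[[j]])
      sym_diff <- sum(xor(masks[[i]]$cells, masks[[j]]$cells))
      out[j, i] <- sym_diff * pi * masks[[i]]$electrode_radius_mm^2
    }
  }
  out
}

#' Binned mediolateral EoA profile
#'
#' Partitions the grid columns into `n_bins` contiguous bands ordered
#' medial to lateral (per the geometry's `medial_edge`) and sums significant
#' positive signed R^2 within each band, per movement.
#'
#' @param effects a single `msom_effect_map` or a named list of them (one
#'   per movement), sharing a geometry.
#' @param n_bins number of mediolateral bands (<= number of columns).
#' @return matrix movements x bins of banded EoA.
#' @export
mediolateral_profile <- function(effects, n_bins) {
  if (inherits(effects, "msom_effect_map")) effects <- list(effects)
  geometry <- effects[[1]]$geometry
  if (n_bins > geometry$n_cols) stopf("n_bins exceeds the column count")
  edges <- seq(0, geometry$n_cols, length.out = n_bins + 1)
  cols <- geometry$contacts$grid_col
  band <- findInterval(cols, edges, rightmost.closed = TRUE)
  if (identical(geometry$medial_edge, "right")) band <- n_bins + 1 - band
  out <- t(vapply(effects, function(e) {
    sel <- !is.na(e$significant) & e$significant & e$signed_r2 > 0
    vapply(seq_len(n_bins), function(b) {
      s <- sel & !is.na(band) & band == b
      if (any(s)) sum(e$signed_r2[s]) else 0
    }, 0)
  }, numeric(n_bins)))
  rownames(out) <- names(effects) %||% paste0("movement", seq_along(effects))
  colnames(out) <- paste0("band", seq_len(n_bins))
  out
}
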