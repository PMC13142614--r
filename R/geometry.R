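#' Build the default surface-array geometry
#'
#' Constructs the contact table of a dense surface microelectrode array laid
#' out on an `n_rows` x `n_cols` grid (default 33 x 31 at 400 um pitch,
#' matching a 1.2 x 1.2 cm aperture). Micro and macro contacts occupy the
#' non-corner grid cells (macros on an evenly spaced sublattice), four
#' reference contacts are mapped to the four corner cells, and one additional
#' reference contact is left unmapped ("excluded"): with the defaults this
#' yields 1024 contacts of which 1023 occupy grid cells.
#'
#' Grid indices are 0-based and row-major with row 0 at the array's posterior
#' edge; columns run medial to lateral unless `medial_edge = "right"`.
#'
#' @param n_rows,n_cols grid dimensions (rows x columns).
#' @param pitch_um center-to-center contact spacing in micrometers.
#' @param macro_fraction fraction of non-corner cells assigned to macro
#'   contacts; the default reproduces 42 macros among 1019 grid contacts.
#' @param medial_edge which column edge ("left" = column 0) faces medially.
#' @return an object of class `msom_geometry`: a list with the contact table
#'   (`contacts`), grid dimensions, pitch, the mapped reference channel ids
#'   and the excluded reference id.
#' @export
build_default_geometry <- function(n_rows = 33L, n_cols = 31L, pitch_um = 400,
                                   macro_fraction = 42 / 1019,
                                   medial_edge = c("left", "right")) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stopf("grid dimensions must be positive integers")
  if (!is.finite(pitch_um) || pitch_um <= 0) stopf("pitch_um must be positive")
  medial_edge <- match.arg(medial_edge)

  n_cells <- n_rows * n_cols
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)   # row-major order
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  corner <- (rows %in% c(0L, n_rows - 1L)) & (cols %in% c(0L, n_cols - 1L))
  has_refs <- sum(corner) == 4L                       # degenerate grids: none

  kind <- rep("micro", n_cells)
  if (has_refs) kind[corner] <- "reference"
  noncorner_idx <- which(kind != "reference")
  n_macro <- round(length(noncorner_idx) * macro_fraction)
  if (n_macro > 0 && length(noncorner_idx) > 0) {
    sub <- unique(round(seq(1, length(noncorner_idx), length.out = n_macro)))
    kind[noncorner_idx[sub]] <- "macro"
  }

  diam <- c(micro = 50, macro = 380, reference = 500)
  contacts <- data.frame(
    channel_id = seq_len(n_cells),
    kind = kind,
    diameter_um = unname(diam[kind]),
    grid_row = rows,
    grid_col = cols,
    stringsAsFactors = FALSE
  )
  mapped_ref_ids <- if (has_refs) contacts$channel_id[corner] else integer(0)
  excluded_id <- NA_integer_
  if (has_refs) {
    # the fifth (unmapped) reference: physically farthest from any corner
    excluded_id <- n_cells + 1L
    contacts <- rbind(contacts, data.frame(
      channel_id = excluded_id, kind = "reference",
      diameter_um = 500, grid_row = NA_integer_, grid_col = NA_integer_
    ))
  }
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
      contacts = contacts,
      mapped_reference_ids = mapped_ref_ids,
      excluded_reference_id = excluded_id,
      medial_edge = medial_edge
    ),
    class = "msom_geometry"
  )
}

#' @export
print.msom_geometry <- function(x, ...) {
  cat(sprintf("<msom_geometry> %d x %d grid, %g um pitch, %d contacts\n",
              x$n_rows, x$n_cols, x$pitch_um, nrow(x$contacts)))
  print(table(x$contacts$kind))
  invisible(x)
}

n_contacts <- function(geometry) nrow(geometry$contacts)

# 0-based column-major cell index per channel (r + c * n_rows), -1 unmapped.
# This is the layout the compiled TFCE kernel expects.
cell_index <- function(geometry) {
  ct <- geometry$contacts
  idx <- ifelse(is.na(ct$grid_row), -1L,
                ct$grid_row + ct$grid_col * geometry$n_rows)
  as.integer(idx)
}

#' Embed per-channel values onto the array grid
#'
#' Places one value per contact at its grid cell; the unmapped (excluded)
#' reference is dropped and empty cells take `fill`. [grid_extract()] is the
#' inverse on mapped channels.
#'
#' @param values numeric vector, one value per contact of `geometry`.
#' @param geometry an [build_default_geometry()] object.
#' @param fill value for unoccupied cells.
#' @return an `n_rows` x `n_cols` matrix.
#' @export
grid_embed <- function(values, geometry, fill = NA_real_) {
  ct <- geometry$contacts
  if (length(values) != nrow(ct))
    stopf("length(values) = %d but geometry has %d contacts",
          length(values), nrow(ct))
  m <- matrix(fill, geometry$n_rows, geometry$n_cols)
  mapped <- !is.na(ct$grid_row)
  m[cbind(ct$grid_row[mapped] + 1L, ct$grid_col[mapped] + 1L)] <-
    values[mapped]
  m
}

#' @rdname grid_embed
#' @param grid a matrix as produced by [grid_embed()].
#' @return `grid_extract`: per-channel vector (NA for unmapped contacts).
#' @export
grid_extract <- function(grid, geometry) {
  ct <- geometry$contacts
  if (!all(dim(grid) == c(geometry$n_rows, geometry$n_cols)))
    stopf("grid dimensions do not match geometry")
  out <- rep(NA_real_, nrow(ct))
  mapped <- !is.na(ct$grid_row)
  out[mapped] <- grid[cbind(ct$grid_row[mapped] + 1L, ct$grid_col[mapped] + 1L)]
  out
}
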