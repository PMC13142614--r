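# Session and result readers/writers. Everything is plain text: TSV tables
# with full-precision floats, a JSON metadata sidecar for the signal matrix,
# and Newick for trees, so files round-trip exactly through their paired
# readers.

fmt_num <- function(x) {
  # 17 significant digits round-trips IEEE doubles exactly
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("missing required file: %s", path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Save a session to a directory of plain-text files
#'
#' Writes the electrode table (`electrodes.tsv`), the voltage matrix
#' (`signals.tsv`, samples x channels), signal metadata (`signals.json`),
#' events (`events.tsv`), trials (`trials.tsv`) and, when present,
#' kinematics (`kinematics.tsv`, one `<sensor>_<axis>` column set in
#' meters).
#'
#' @param session an `msom_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create directory %s", dir)
  geo <- session$geometry
  et <- geo$contacts
  et$impedance_ohm <- session$impedance_ohm
  if (!is.null(session$coords_mm)) {        # standard-space coordinates
    et$x_mm <- session$coords_mm[, 1]
    et$y_mm <- session$coords_mm[, 2]
    et$z_mm <- session$coords_mm[, 3]
  }
  write_tsv(et, file.path(dir, "electrodes.tsv"))
  jsonlite::write_json(
    list(sample_rate_hz = session$sample_rate_hz,
         n_channels = nrow(session$voltage),
         n_samples = ncol(session$voltage),
         n_rows = geo$n_rows, n_cols = geo$n_cols,
         pitch_um = geo$pitch_um, medial_edge = geo$medial_edge,
         grid_origin = "row 0 = posterior edge, 0-based row-major indices"),
    file.path(dir, "signals.json"), auto_unbox = TRUE, digits = NA)
  sig <- as.data.frame(t(session$voltage))
  names(sig) <- paste0("ch", geo$contacts$channel_id)
  # the signal matrix is by far the largest table: fwrite emits the shortest
  # exactly round-tripping decimal per value at ~50x write.table speed
  data.table::fwrite(sig, file.path(dir, "signals.tsv"), sep = "\t")
  write_tsv(session$events, file.path(dir, "events.tsv"))
  write_tsv(as.data.frame(session$trials), file.path(dir, "trials.tsv"))
  if (!is.null(session$kinematics)) {
    kin <- session$kinematics
    kd <- data.frame(time_s = kin$time_s)
    for (s in kin$sensor_labels)
      for (a in c("x", "y", "z"))
        kd[[paste0(s, "_", a)]] <- kin$positions[s, a, ]
    write_tsv(kd, file.path(dir, "kinematics.tsv"))
  }
  invisible(dir)
}

#' Load a session saved by [save_session()]
#'
#' Validates the schema on load: the signal channel count must match the
#' electrode table, and event times must fall inside the recording.
#'
#' @param dir session directory.
#' @return an `msom_session`.
#' @export
load_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "signals.json"),
                              simplifyVector = TRUE)
  et <- read_tsv(file.path(dir, "electrodes.tsv"))
  if (!file.exists(file.path(dir, "signals.tsv")))
    stopf("missing required file: %s", file.path(dir, "signals.tsv"))
  sig <- data.table::fread(file.path(dir, "signals.tsv"), sep = "\t",
                           data.table = FALSE)
  if (ncol(sig) != nrow(et))
    stopf("schema error: %d signal channels but %d electrode rows",
          ncol(sig), nrow(et))
  voltage <- t(as.matrix(sig))
  dimnames(voltage) <- NULL
  events <- read_tsv(file.path(dir, "events.tsv"))
  dur <- ncol(voltage) / meta$sample_rate_hz
  if (any(events$time_s < 0) || any(events$time_s >= dur))
    stopf("schema error: event times outside the recording (0, %g s)", dur)
  trials <- read_tsv(file.path(dir, "trials.tsv"))
  corner <- !is.na(et$grid_row) & et$kind == "reference"
  geometry <- structure(list(
    n_rows = meta$n_rows, n_cols = meta$n_cols, pitch_um = meta$pitch_um,
    contacts = et[, c("channel_id", "kind", "diameter_um", "grid_row",
                      "grid_col")],
    mapped_reference_ids = et$channel_id[corner],
    excluded_reference_id =
      if (any(is.na(et$grid_row) & et$kind == "reference"))
        et$channel_id[is.na(et$grid_row) & et$kind == "reference"][1]
      else NA_integer_,
    medial_edge = meta$medial_edge %||% "left"
  ), class = "msom_geometry")
  kin <- NULL
  kin_path <- file.path(dir, "kinematics.tsv")
  if (file.exists(kin_path)) {
    kd <- read_tsv(kin_path)
    sensors <- unique(sub("_[xyz]$", "", setdiff(names(kd), "time_s")))
    pos <- array(0, dim = c(length(sensors), 3, nrow(kd)),
                 dimnames = list(sensors, c("x", "y", "z"), NULL))
    for (s in sensors)
      for (a in c("x", "y", "z"))
        pos[s, a, ] <- kd[[paste0(s, "_", a)]]
    kin <- structure(list(time_s = kd$time_s, positions = pos,
                          sensor_labels = sensors),
                     class = "msom_kinematics")
  }
  coords <- NULL
  if (all(c("x_mm", "y_mm", "z_mm") %in% names(et)))
    coords <- as.matrix(et[, c("x_mm", "y_mm", "z_mm")])
  structure(list(
    sample_rate_hz = meta$sample_rate_hz, voltage = voltage,
    impedance_ohm = et$impedance_ohm, events = events, trials = trials,
    kinematics = kin, geometry = geometry, coords_mm = coords
  ), class = "msom_session")
}

#' Save pipeline results as plain-text files
#'
#' Dispatches on the result type: effect maps become TSV tables (columns
#' `channel`, `signed_r2`, `tfce`, `p_pos`, `p_neg`, `significant`, plus the
#' negative-direction TFCE score), RDMs become labelled TSV matrices,
#' dendrograms become Newick strings, and every call writes a JSON sidecar
#' (`<stem>_meta.json`) with run metadata.
#'
#' @param x an `msom_effect_map`, `msom_rdm`, or `hclust` tree.
#' @param path output file path (TSV for tables, `.nwk` for trees).
#' @param meta named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
save_results <- function(x, path, meta = list()) {
  sidecar <- sub("\\.[A-Za-z]+$", "", path)
  sidecar <- paste0(sidecar, "_meta.json")
  base_meta <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      package_version = as.character(
                        utils::packageVersion("msom"))), meta)
  if (inherits(x, "msom_effect_map")) {
    df <- data.frame(channel = seq_along(x$signed_r2),
                     signed_r2 = x$signed_r2, tfce = x$tfce_pos,
                     p_pos = x$p_pos, p_neg = x$p_neg,
                     significant = x$significant, tfce_neg = x$tfce_neg)
    write_tsv(df, path)
    base_meta <- c(base_meta, list(n_perm = x$n_perm, alpha = x$alpha,
                                   seed = x$seed, stat = x$stat))
  } else if (inherits(x, "msom_rdm")) {
    df <- as.data.frame(x$distances)
    names(df) <- x$labels
    df <- cbind(data.frame(label = x$labels), df)
    write_tsv(df, path)
  } else if (inherits(x, "hclust")) {
    tree_newick(x, path)
  } else {
    stopf("unsupported result type: %s", paste(class(x), collapse = "/"))
  }
  jsonlite::write_json(base_meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RDM written by [save_results()]
#'
#' @param path TSV path.
#' @return an `msom_rdm`.
#' @export
load_rdm <- function(path) {
  df <- read_tsv(path)
  labels <- df$label
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(labels, labels)
  structure(list(distances = m, labels = labels), class = "msom_rdm")
}

#' Read an effect-map TSV written by [save_results()]
#'
#' @param path TSV path.
#' @return data.frame with the effect-map columns.
#' @export
load_effect_table <- function(path) read_tsv(path)
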