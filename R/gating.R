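#' Event-level cytometry matrix
#'
#' Container for one specimen: an events x channels matrix of non-negative
#' fluorescence / scatter intensities plus a channel-to-marker map. Channels
#' are the physical column names (e.g. "FL3"); markers are biological names
#' ("CD34"). The map need not be one-to-one with the panel: any channels
#' mapping to the six core markers plus CD45 make the specimen classifiable.
#'
#' @param intensities numeric matrix, events in rows, channels in columns;
#'   must carry column names and contain no NaN/NA.
#' @param channel_map named character vector, names = channel identifiers
#'   (column names of `intensities`), values = marker names. Defaults to the
#'   identity map over the column names.
#' @param specimen_id opaque specimen identifier.
#' @return object of class `event_matrix`.
#' @export
event_matrix <- function(intensities, channel_map = NULL, specimen_id = "specimen") {
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(colnames(intensities))) {
    slaml_stop("event matrix columns must be named channels", "slaml_channel_error")
  }
  if (anyNA(intensities)) {
    slaml_stop("event intensities must not contain NA/NaN", "slaml_argument_error")
  }
  if (is.null(channel_map)) {
    channel_map <- setNames(colnames(intensities), colnames(intensities))
  }
  unknown <- setdiff(names(channel_map), colnames(intensities))
  if (length(unknown)) {
    slaml_stop(paste("channel_map refers to absent channels:",
                     paste(unknown, collapse = ", ")), "slaml_channel_error")
  }
  structure(list(intensities = intensities,
                 channel_map = channel_map,
                 specimen_id = specimen_id),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %s: %d events x %d channels (%s)\n",
              x$specimen_id, nrow(x$intensities), ncol(x$intensities),
              paste(unname(x$channel_map), collapse = ", ")))
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$intensities)

# internal: intensity column for a marker, via the channel map
marker_column <- function(events, marker) {
  hit <- names(events$channel_map)[events$channel_map == marker]
  if (length(hit) == 0) {
    slaml_stop(sprintf("no channel mapped to marker '%s'", marker),
               "slaml_channel_error")
  }
  events$intensities[, hit[1]]
}

has_marker <- function(events, marker) marker %in% events$channel_map

#' Blast gate parameters
#'
#' The blast gate is a rectangle in (CD45, SSC): CD45-dim (above the
#' unstained floor, below the bright lymphocyte mode) and low/intermediate
#' side scatter. Defaults match the synthetic intensity world of
#' [default_intensity_model()], where blasts sit near 150 CD45 units and
#' lymphocytes near 1500.
#'
#' @param cd45_range length-2 numeric, inclusive CD45-dim interval.
#' @param ssc_range length-2 numeric, inclusive SSC interval.
#' @param min_blasts events below which the low-count flag is raised
#'   (acquisition targets at least 1e4 blasts per specimen).
#' @return list of gate parameters.
#' @export
gate_params <- function(cd45_range = c(20, 700),
                        ssc_range = c(0, 1200),
                        min_blasts = 10000) {
  stopifnot(length(cd45_range) == 2, length(ssc_range) == 2,
            cd45_range[1] < cd45_range[2], ssc_range[1] < ssc_range[2])
  list(cd45_range = cd45_range, ssc_range = ssc_range, min_blasts = min_blasts)
}

#' Gate CD45-dim mononuclear blasts
#'
#' Selects events inside the CD45-dim x SSC-low/intermediate rectangle.
#'
#' @param events [event_matrix()] with a channel mapped to CD45 (SSC
#'   optional: if absent, the gate is CD45-only).
#' @param params [gate_params()].
#' @return object of class `gate_result`: `indices` (unique, in-range event
#'   rows), `definition`, `fraction_retained`, `n_retained`, and `low_count`
#'   flag set when fewer than `min_blasts` events are retained.
#' @export
gate_blasts <- function(events, params = gate_params()) {
  if (!inherits(events, "event_matrix")) {
    slaml_stop("gate_blasts() expects an event_matrix", "slaml_argument_error")
  }
  if (!has_marker(events, "CD45")) {
    slaml_stop("CD45 channel required for the blast gate", "slaml_channel_error")
  }
  n <- nrow(events$intensities)
  if (n == 0) {
    keep <- integer(0)
  } else {
    cd45 <- marker_column(events, "CD45")
    inside <- cd45 >= params$cd45_range[1] & cd45 <= params$cd45_range[2]
    if (has_marker(events, "SSC")) {
      ssc <- marker_column(events, "SSC")
      inside <- inside & ssc >= params$ssc_range[1] & ssc <= params$ssc_range[2]
    }
    keep <- which(inside)
  }
  structure(list(
    indices = keep,
    definition = params,
    n_retained = length(keep),
    fraction_retained = if (n == 0) NA_real_ else length(keep) / n,
    low_count = length(keep) < params$min_blasts
  ), class = "gate_result")
}

#' Subset an event matrix to gated events
#'
#' @param events [event_matrix()].
#' @param gate [gate_blasts()] result (or integer indices).
#' @return an `event_matrix` restricted to the gated events.
#' @export
apply_gate <- function(events, gate) {
  idx <- if (inherits(gate, "gate_result")) gate$indices else as.integer(gate)
  event_matrix(events$intensities[idx, , drop = FALSE],
               events$channel_map, events$specimen_id)
}

#' Percent of gated blasts positive for a marker
#'
#' Positivity at the event level is strict: intensity strictly greater than
#' the cutoff counts positive, events exactly at the cutoff count negative
#' (bit-reproducible convention). An empty gate yields `NA_real_`, never a
#' division error.
#'
#' @param events a gated [event_matrix()].
#' @param marker marker name present in the channel map.
#' @param cutoff non-negative intensity threshold.
#' @return percentage in \[0, 100\], or NA for an empty gate.
#' @export
percent_positive <- function(events, marker, cutoff = 150) {
  if (!has_marker(events, marker)) {
    slaml_stop(sprintf("unknown marker '%s'", marker), "slaml_channel_error")
  }
  stopifnot(is.numeric(cutoff), cutoff >= 0)
  n <- nrow(events$intensities)
  if (n == 0) return(NA_real_)
  100 * sum(marker_column(events, marker) > cutoff) / n
}

#' Positivity cutoffs from a negative-control population
#'
#' Event-level cutoffs default to the 99.5th percentile of a supplied
#' negative control per marker; alternatively pass a fixed named vector (or
#' single number) directly wherever cutoffs are consumed.
#'
#' @param control [event_matrix()] of negative-control events.
#' @param markers markers to derive cutoffs for.
#' @param q quantile (default 0.995).
#' @return named numeric vector of cutoffs.
#' @export
positivity_cutoffs <- function(control, markers, q = 0.995) {
  vapply(markers, function(m) {
    unname(quantile(marker_column(control, m), q, names = FALSE, type = 7))
  }, numeric(1))
}

# internal: resolve a cutoff spec (scalar or named vector) for one marker
cutoff_for <- function(cutoffs, marker) {
  if (length(cutoffs) == 1 && is.null(names(cutoffs))) return(cutoffs)
  if (!marker %in% names(cutoffs)) {
    slaml_stop(sprintf("no cutoff supplied for marker '%s'", marker),
               "slaml_channel_error")
  }
  cutoffs[[marker]]
}

#' Reduce an event-level specimen to a per-patient marker profile
#'
#' Applies the blast gate, then [percent_positive()] for every marker in the
#' channel map other than CD45/SSC, recording the number of blasts analyzed.
#'
#' @param events [event_matrix()] with CD45 plus the six core markers mapped.
#' @param cutoffs scalar or named per-marker intensity cutoffs.
#' @param params [gate_params()].
#' @return one-row data.frame of class `marker_profile`: `patient_id`,
#'   `n_blasts`, `low_count`, and one percentage column per marker.
#' @export
marker_profile_from_events <- function(events, cutoffs = 150,
                                       params = gate_params()) {
  for (m in c("CD45", core_markers())) {
    if (!has_marker(events, m)) {
      slaml_stop(sprintf("marker '%s' missing from channel map", m),
                 "slaml_channel_error")
    }
  }
  gate <- gate_blasts(events, params)
  gated <- apply_gate(events, gate)
  markers <- setdiff(unname(events$channel_map), c("CD45", "SSC"))
  vals <- vapply(markers, function(m) {
    percent_positive(gated, m, cutoff_for(cutoffs, m))
  }, numeric(1))
  out <- data.frame(patient_id = events$specimen_id,
                    n_blasts = gate$n_retained,
                    low_count = gate$low_count,
                    stringsAsFactors = FALSE)
  out[markers] <- as.list(vals)
  class(out) <- c("marker_profile", class(out))
  out
}

#' CD34+CD38-CD123+ leukemic stem cell fraction of gated blasts
#'
#' @param events a gated [event_matrix()] with CD34, CD38 and CD123 mapped.
#' @param cutoffs scalar or named per-marker cutoffs.
#' @return percentage of gated blasts that are CD34-positive, CD38-negative
#'   and CD123-positive; NA for an empty gate.
#' @export
lsc_fraction <- function(events, cutoffs = 150) {
  for (m in c("CD34", "CD38", "CD123")) {
    if (!has_marker(events, m)) {
      slaml_stop(sprintf("marker '%s' required for LSC quantification", m),
                 "slaml_channel_error")
    }
  }
  n <- nrow(events$intensities)
  if (n == 0) return(NA_real_)
  cd34 <- marker_column(events, "CD34") > cutoff_for(cutoffs, "CD34")
  cd38 <- marker_column(events, "CD38") > cutoff_for(cutoffs, "CD38")
  cd123 <- marker_column(events, "CD123") > cutoff_for(cutoffs, "CD123")
  100 * sum(cd34 & !cd38 & cd123) / n
}

#' Read a tabular event file (columns = channels) as an event matrix
#'
#' CSV fallback for specimens exported outside FCS; a channel map may be
#' supplied when column names are physical channel ids.
#'
#' @param path CSV file, one row per event, numeric columns.
#' @param channel_map optional named character vector.
#' @param specimen_id defaults to the file name.
#' @return [event_matrix()].
#' @export
read_event_csv <- function(path, channel_map = NULL, specimen_id = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (is.null(specimen_id)) specimen_id <- basename(path)
  event_matrix(as.matrix(df), channel_map, specimen_id)
}

#' Write an event matrix as CSV (marker-named columns)
#'
#' @param events [event_matrix()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_event_csv <- function(events, path) {
  m <- events$intensities
  colnames(m) <- unname(events$channel_map[colnames(m)])
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
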