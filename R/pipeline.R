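# End-to-end pipeline helpers binding the package together: construct all
# channel maps of one or more sessions on a shared geometry, write the
# descriptor tables, rendered PNGs and serialized maps, and compare maps by
# overlap and relative EMD. These are the functions the command-line front
# end is a thin wrapper around.

#' Construct maps for several channels/sessions on one shared geometry
#'
#' Fits one sphere and one patch of interest to the union of all stimulation
#' points, then constructs every requested channel map of every session on
#' that shared geometry, so that all results are mutually comparable.
#'
#' @param sessions a `tms_session` or list of them.
#' @param channels channels to map; default all channels of the first session.
#' @param config a [map_config()].
#' @return list with `geometry` and `maps` (named `subject/session/channel`).
#' @export
construct_maps <- function(sessions, channels = NULL, config = map_config()) {
  if (inherits(sessions, "tms_session")) sessions <- list(sessions)
  sessions <- lapply(sessions, as_session)
  if (is.null(channels)) channels <- sessions[[1]]$channels
  geometry <- map_geometry(sessions, config = config)
  maps <- list()
  for (s in sessions) {
    for (ch in intersect(channels, s$channels)) {
      key <- paste(s$session, ch, sep = "/")
      maps[[key]] <- motor_map(s, ch, config = config, geometry = geometry)
    }
  }
  list(geometry = geometry, maps = maps)
}

#' Run the full construction pipeline and persist all outputs
#'
#' Reads the input session(s), constructs raw and thresholded maps for every
#' channel on a shared geometry, and writes per-map JSON containers, PNG
#' renderings, a statistics workbook and a parameter log into `out_dir`.
#' All outputs are deterministic for given inputs and configuration.
#'
#' @param inputs session file path(s) (`.xlsx` or nbe text) or `tms_session`
#'   objects.
#' @param out_dir output directory (created if needed).
#' @param channels channels to map (default: all).
#' @param config a [map_config()].
#' @return invisibly, a list with `maps`, `summaries`, `files`.
#' @export
run_construct <- function(inputs, out_dir, channels = NULL,
                          config = map_config()) {
  sessions <- lapply(if (is.character(inputs)) as.list(inputs) else
    if (inherits(inputs, "tms_session")) list(inputs) else inputs,
    function(x) if (is.character(x)) read_session(x) else as_session(x))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  built <- construct_maps(sessions, channels = channels, config = config)
  summaries <- list()
  files <- character(0)
  for (key in names(built$maps)) {
    m <- built$maps[[key]]
    th <- threshold_map(m)
    summaries[[key]] <- summary(th)
    stem <- gsub("[^A-Za-z0-9_.-]", "_", key)
    fm <- file.path(out_dir, paste0(stem, "_map.json"))
    write_map(th, fm)
    fp <- file.path(out_dir, paste0(stem, ".png"))
    render_map_2d(m, fp)
    files <- c(files, fm, fp)
  }
  ft <- file.path(out_dir, "results.xlsx")
  write_results(list(maps = stats_table(summaries)), ft)
  flog <- file.path(out_dir, "parameters.txt")
  writeLines(c(
    sprintf("motormap construction log"),
    sprintf("inputs: %s", paste(vapply(sessions, function(s)
      paste(s$subject, s$session, sep = "/"), character(1)), collapse = ", ")),
    sprintf("channels: %s", paste(names(built$maps), collapse = ", ")),
    vapply(names(unclass(config)), function(k)
      sprintf("%s: %s", k, format(config[[k]])), character(1))
  ), flog)
  invisible(list(maps = built$maps, geometry = built$geometry,
                 summaries = summaries, files = c(files, ft, flog)))
}

#' Compare two maps: overlap statistics and relative EMD
#'
#' Constructs (or accepts) two thresholded maps on one shared geometry built
#' from the union of the supplied sessions, computes their overlap map with
#' its full statistics, and the relative EMD normalized by the subject's
#' active-area diameter.
#'
#' @param sessions session(s) carrying the stimulation data of both maps.
#' @param channel_a,channel_b channel of the first/second map; when two
#'   sessions are given, map A comes from the first and map B from the second.
#' @param config a [map_config()].
#' @param emd_mode `"cells"` or `"points"` (see [emd_relative()]).
#' @return list with `map_a`, `map_b`, `overlap`, `overlap_summary`, `emd`,
#'   `active`.
#' @export
run_compare <- function(sessions, channel_a, channel_b,
                        config = map_config(), emd_mode = "cells") {
  if (inherits(sessions, "tms_session")) sessions <- list(sessions)
  sessions <- lapply(sessions, function(x)
    if (is.character(x)) read_session(x) else as_session(x))
  geometry <- map_geometry(sessions, config = config)
  sa <- sessions[[1]]
  sb <- if (length(sessions) > 1L) sessions[[2]] else sessions[[1]]
  a <- threshold_map(motor_map(sa, channel_a, config = config, geometry = geometry))
  b <- threshold_map(motor_map(sb, channel_b, config = config, geometry = geometry))
  ov <- overlap_maps(a, b)
  act <- active_area(sessions, geometry, threshold = config$threshold)
  emd <- if (n_active(a) > 0L && n_active(b) > 0L)
    emd_relative(a, b, act, mode = emd_mode) else NULL
  list(map_a = a, map_b = b, overlap = ov,
       overlap_summary = if (n_active(ov) > 0L) summary(ov) else NULL,
       emd = emd, active = act)
}
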