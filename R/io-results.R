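# Results tables: one row of descriptors per map, pairwise tables for
# overlaps and EMD, written as a spreadsheet with one sheet per table.

#' Tabulate map statistics
#'
#' @param summaries list of [summary.motor_map()] results (or a single one).
#' @return data frame with one row per map: identification, threshold, area,
#'   volume, CoG and hotspot coordinates.
#' @export
stats_table <- function(summaries) {
  if (inherits(summaries, "motor_map_summary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    v3 <- function(v) if (is.null(v)) rep(NA_real_, 3) else as.numeric(v)
    hr <- if (is.null(s$hotspot_raw)) rep(NA_real_, 3) else s$hotspot_raw$world
    hm <- if (is.null(s$hotspot_map)) rep(NA_real_, 3) else s$hotspot_map$world
    data.frame(
      subject = s$subject, session = s$session, channel = s$channel,
      kind = s$kind, threshold = s$threshold,
      area_mm2 = s$area, volume = s$volume, n_cells = s$n_active,
      cog_raw_x = v3(s$cog_raw)[1], cog_raw_y = v3(s$cog_raw)[2],
      cog_raw_z = v3(s$cog_raw)[3],
      cog_map_x = v3(s$cog_map)[1], cog_map_y = v3(s$cog_map)[2],
      cog_map_z = v3(s$cog_map)[3],
      hotspot_raw_x = hr[1], hotspot_raw_y = hr[2], hotspot_raw_z = hr[3],
      hotspot_map_x = hm[1], hotspot_map_y = hm[2], hotspot_map_z = hm[3],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Tabulate pairwise EMD results
#'
#' @param pairs list of lists with fields `a`, `b` (labels) and `emd`
#'   (a `tms_emd`).
#' @return data frame with one row per comparison.
#' @export
emd_table <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(map_a = p$a, map_b = p$b, raw_emd_mm = p$emd$raw_emd,
               d_max_mm = p$emd$d_max, relative_percent = p$emd$relative,
               mode = p$emd$mode, stringsAsFactors = FALSE)
  }))
}

#' Write results tables to a spreadsheet
#'
#' One sheet per table; numeric cells stay numeric at full precision, so
#' re-reading the workbook reproduces every number exactly.
#'
#' @param tables named list of data frames (e.g. `maps`, `overlaps`, `emd`).
#' @param path output `.xlsx` file.
#' @return `path`, invisibly.
#' @export
write_results <- function(tables, path) {
  if (!is.list(tables) || length(tables) == 0L)
    stop("no results to write")
  if (all(vapply(tables, is.data.frame, logical(1)))) {
    write_xlsx_sheets(tables, path)
  } else stop("tables must be a named list of data frames")
  invisible(path)
}
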