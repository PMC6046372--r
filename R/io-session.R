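# Stimulation-session input: a spreadsheet (.xlsx) with one row per stimulus,
# or the documented open navigation-text dialect (".nbe"-style). Coordinates
# are world mm and pass through untouched; responses are nonnegative, blanks
# are missing (not zero).

COIL_COLS <- c("coil_x", "coil_y", "coil_z")
EF_COLS <- c("ef_x", "ef_y", "ef_z")

new_session <- function(points, subject = "subject", session = "session",
                        coordinate_space = c("scanner", "template"),
                        channels = NULL) {
  coordinate_space <- match.arg(coordinate_space)
  stopifnot(is.data.frame(points), nrow(points) >= 1L)
  if (!"id" %in% names(points)) points$id <- as.character(seq_len(nrow(points)))
  missing_coil <- setdiff(COIL_COLS, names(points))
  if (length(missing_coil))
    stop(sprintf("missing mandatory column(s): %s", paste(missing_coil, collapse = ", ")))
  if (!all(EF_COLS %in% names(points))) points[EF_COLS] <- NA_real_
  if (is.null(channels))
    channels <- setdiff(names(points), c("id", COIL_COLS, EF_COLS, "valid"))
  if (length(channels) < 1L) stop("session has no response channels")
  if (!"valid" %in% names(points)) points$valid <- TRUE
  for (cc in c(COIL_COLS, EF_COLS, channels)) {
    if (!is.numeric(points[[cc]]))
      stop(sprintf("column '%s' must be numeric", cc))
  }
  if (any(!is.finite(as.matrix(points[COIL_COLS]))))
    stop("non-finite coil coordinates")
  resp <- as.matrix(points[channels])
  if (any(!is.na(resp) & resp < 0))
    stop("negative response values are not allowed")
  structure(list(
    subject = subject, session = session,
    points = points[c("id", COIL_COLS, EF_COLS, channels, "valid")],
    channels = channels, coordinate_space = coordinate_space
  ), class = "tms_session")
}

#' @export
print.tms_session <- function(x, ...) {
  cat(sprintf("TMS session '%s' / '%s': %d stimulation points, channels: %s\n",
              x$subject, x$session, nrow(x$points),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

# per-point stimulation location: EF maximum when present, coil otherwise
session_locations <- function(session) {
  p <- session$points
  ef_ok <- stats::complete.cases(p[EF_COLS])
  loc <- as.matrix(p[COIL_COLS])
  loc[ef_ok, ] <- as.matrix(p[EF_COLS])[ef_ok, , drop = FALSE]
  colnames(loc) <- c("x", "y", "z")
  loc
}

#' Read a stimulation session
#'
#' Dispatches on the file extension: `.xlsx` spreadsheets via
#' [read_session_xlsx()], anything else via [read_nbe()].
#'
#' @param path input file.
#' @param ... passed on to the format reader.
#' @return a `tms_session`.
#' @export
read_session <- function(path, ...) {
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) read_session_xlsx(path, ...)
  else read_nbe(path, ...)
}

#' Read a stimulation session from a spreadsheet
#'
#' The first sheet must carry a header row `id, coil_x, coil_y, coil_z`,
#' optionally `ef_x, ef_y, ef_z`, followed by one column per response channel.
#' Blank response cells become missing values; negative responses and
#' non-numeric coordinates are rejected.
#'
#' @param path an `.xlsx` file.
#' @param subject,session,coordinate_space session metadata; when `NULL`, a
#'   `meta` sheet written by [write_session_xlsx()] is consulted, falling back
#'   to generic tokens.
#' @return a `tms_session`.
#' @export
read_session_xlsx <- function(path, subject = NULL, session = NULL,
                              coordinate_space = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  meta <- list()
  if ("meta" %in% tryCatch(readxl::excel_sheets(path), error = function(e) character(0))) {
    md <- as.data.frame(readxl::read_excel(path, sheet = "meta",
                                           col_types = "text"))
    meta <- as.list(stats::setNames(md$value, md$key))
  }
  subject <- subject %||% meta$subject %||% "subject"
  session <- session %||% meta$session %||% "session"
  coordinate_space <- coordinate_space %||% meta$coordinate_space %||% "scanner"
  df <- suppressWarnings(as.data.frame(
    readxl::read_excel(path, sheet = 1, col_types = "text"),
    stringsAsFactors = FALSE))
  if (nrow(df) == 0L) stop("empty sheet: no stimulation points")
  missing_coil <- setdiff(COIL_COLS, names(df))
  if (length(missing_coil))
    stop(sprintf("missing mandatory column(s): %s", paste(missing_coil, collapse = ", ")))
  num_cols <- setdiff(names(df), "id")
  for (cc in num_cols) {
    raw <- trimws(df[[cc]])
    raw[raw == ""] <- NA
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   cc, bad[1], raw[bad[1]]))
    if (cc %in% COIL_COLS && anyNA(val))
      stop(sprintf("missing coordinate in column '%s', row %d", cc, which(is.na(val))[1]))
    df[[cc]] <- val
  }
  df$id <- as.character(df$id)
  new_session(df, subject = subject, session = session,
              coordinate_space = coordinate_space)
}

NBE_VERSION <- "nbe v1"

#' Read a navigation-text session file
#'
#' Reads the documented open text dialect standing in for vendor navigation
#' exports: UTF-8, `#`-prefixed header lines carrying the version, metadata
#' and channel names, then semicolon-separated rows
#' `id; coil x;y;z; [ef x;y;z;] responses...`. Blank response fields are
#' missing values.
#'
#' @param path text file in the dialect written by [write_nbe()].
#' @return a `tms_session`.
#' @export
read_nbe <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^#", lines)
  header <- sub("^#\\s*", "", lines[hdr])
  body <- lines[!hdr]
  if (length(header) == 0L || header[1] != NBE_VERSION)
    stop(sprintf("unsupported dialect: expected '# %s' header", NBE_VERSION))
  getmeta <- function(key, default = NULL) {
    m <- grep(paste0("^", key, ":"), header, value = TRUE)
    if (length(m) == 0L) return(default)
    trimws(sub(paste0("^", key, ":"), "", m[1]))
  }
  channels <- strsplit(getmeta("channels", ""), ";", fixed = TRUE)[[1]]
  channels <- trimws(channels)
  if (length(channels) == 0L || !nzchar(channels[1]))
    stop("unsupported dialect: no channels declared in header")
  has_ef <- identical(getmeta("ef", "yes"), "yes")
  nfield <- 4L + (if (has_ef) 3L else 0L) + length(channels)
  if (length(body) == 0L) stop("empty file: no stimulation rows")
  rows <- strsplit(body, ";", fixed = TRUE)
  line_no <- which(!hdr)
  parsed <- vector("list", length(rows))
  for (r in seq_along(rows)) {
    f <- trimws(rows[[r]])
    if (length(f) != nfield)
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   line_no[r], nfield, length(f)))
    num <- suppressWarnings(as.numeric(f[-1]))
    coords_n <- 3L + (if (has_ef) 3L else 0L)
    if (any(is.na(num[1:3])))
      stop(sprintf("parse error at line %d: non-numeric coil coordinates", line_no[r]))
    resp_raw <- f[-1][(coords_n + 1):(nfield - 1L)]
    resp <- num[(coords_n + 1):(nfield - 1L)]
    if (any(!is.na(resp_raw) & nzchar(resp_raw) & is.na(resp)))
      stop(sprintf("parse error at line %d: non-numeric response", line_no[r]))
    parsed[[r]] <- c(list(id = f[1]), as.list(num))
  }
  mat <- do.call(rbind, lapply(parsed, function(p) unlist(p[-1])))
  df <- data.frame(id = vapply(parsed, function(p) p$id, character(1)),
                   stringsAsFactors = FALSE)
  df[COIL_COLS] <- mat[, 1:3, drop = FALSE]
  if (has_ef) df[EF_COLS] <- mat[, 4:6, drop = FALSE]
  df[channels] <- mat[, (if (has_ef) 7L else 4L):ncol(mat), drop = FALSE]
  new_session(df, subject = getmeta("subject", "subject"),
              session = getmeta("session", "session"),
              coordinate_space = getmeta("space", "scanner"),
              channels = channels)
}

#' Write a session in the navigation-text dialect
#'
#' @param session a `tms_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nbe <- function(session, path) {
  stopifnot(inherits(session, "tms_session"))
  p <- session$points
  has_ef <- any(stats::complete.cases(p[EF_COLS]))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  cols <- c(COIL_COLS, if (has_ef) EF_COLS, session$channels)
  rows <- apply(p[cols], 1, function(r) paste(fmt(as.numeric(r)), collapse = ";"))
  lines <- c(
    paste0("# ", NBE_VERSION),
    paste0("# subject: ", session$subject),
    paste0("# session: ", session$session),
    paste0("# space: ", session$coordinate_space),
    paste0("# ef: ", if (has_ef) "yes" else "no"),
    paste0("# channels: ", paste(session$channels, collapse = ";")),
    paste0(p$id, ";", rows)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a session as a spreadsheet
#'
#' @param session a `tms_session`.
#' @param path output `.xlsx` file.
#' @return `path`, invisibly.
#' @export
write_session_xlsx <- function(session, path) {
  stopifnot(inherits(session, "tms_session"))
  p <- session$points
  has_ef <- any(stats::complete.cases(p[EF_COLS]))
  cols <- c("id", COIL_COLS, if (has_ef) EF_COLS, session$channels)
  meta <- data.frame(key = c("subject", "session", "coordinate_space"),
                     value = c(session$subject, session$session,
                               session$coordinate_space),
                     stringsAsFactors = FALSE)
  write_xlsx_sheets(list(points = p[cols], meta = meta), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
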