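# Color-coded 2D map rendering: the unwrapped-plane height field rasterized
# with a continuous blue (minimum response) to red (maximum response) scale,
# a color bar, and min/max annotations, written as a deterministic PNG.

#' Continuous blue-to-red response palette
#'
#' @param n number of colors.
#' @return vector of hex colors from blue (minimum) to red (maximum).
#' @export
response_palette <- function(n = 256) {
  grDevices::colorRampPalette(c("blue", "cyan", "green", "yellow", "red"))(n)
}

# 3 x 5 bitmap glyphs for numeric annotations
GLYPHS <- list(
  "0" = c(7, 5, 5, 5, 7), "1" = c(2, 6, 2, 2, 7), "2" = c(7, 1, 7, 4, 7),
  "3" = c(7, 1, 7, 1, 7), "4" = c(5, 5, 7, 1, 1), "5" = c(7, 4, 7, 1, 7),
  "6" = c(7, 4, 7, 5, 7), "7" = c(7, 1, 1, 2, 2), "8" = c(7, 5, 7, 5, 7),
  "9" = c(7, 5, 7, 1, 7), "." = c(0, 0, 0, 0, 2), "-" = c(0, 0, 7, 0, 0),
  "+" = c(0, 2, 7, 2, 0), "e" = c(0, 7, 7, 4, 7), " " = c(0, 0, 0, 0, 0)
)

# stamp text into an rgb array (3 channels in [0,1]) at pixel (row, col)
stamp_text <- function(img, text, row, col, value = 0) {
  chars <- strsplit(text, "")[[1]]
  for (ch in chars) {
    g <- GLYPHS[[ch]]
    if (!is.null(g)) {
      for (r in 1:5) for (c in 1:3) {
        if (bitwAnd(g[r], bitwShiftL(1L, 3L - c)) != 0) {
          rr <- row + r - 1L; cc <- col + c - 1L
          if (rr >= 1 && rr <= dim(img)[1] && cc >= 1 && cc <= dim(img)[2])
            img[rr, cc, ] <- value
        }
      }
    }
    col <- col + 4L
  }
  img
}

#' Render a map as a color-coded 2D PNG
#'
#' Rasterizes the unwrapped-plane height field over the POI with the
#' blue-to-red response scale, adds a color bar, and annotates the scale
#' bounds (in response units) along the bottom strip. Output is deterministic
#' for a given map and scale.
#'
#' @param map a `motor_map` with at least one active cell.
#' @param path output `.png` file.
#' @param zlim color scale bounds; defaults to the active height range.
#' @param scale integer pixel size of one grid cell.
#' @return invisibly, a list with `path`, `zlim` and the raster size.
#' @export
render_map_2d <- function(map, path, zlim = NULL, scale = 3L) {
  stopifnot(inherits(map, "motor_map"))
  if (n_active(map) == 0L) stop("cannot render an empty map")
  grid <- map$geometry$grid
  hts <- ifelse(map$active, map$heights, NA_real_)
  if (is.null(zlim)) zlim <- range(hts, na.rm = TRUE)
  pal <- response_palette(256)
  idx_color <- function(h) {
    if (diff(zlim) <= 0) rep(256L, length(h))
    else pmax(1L, pmin(256L, 1L + floor(255 * (h - zlim[1]) / diff(zlim))))
  }
  rgbpal <- grDevices::col2rgb(pal) / 255

  nx <- grid$nx; ny <- grid$ny
  body <- array(1, dim = c(ny, nx, 3))          # white background
  # below-threshold POI cells in light gray, active cells colored
  cells <- grid$cells
  rows <- ny - ((cells$idx - 1L) %/% nx)        # flip y so +y is up
  cols <- (cells$idx - 1L) %% nx + 1L
  for (ch in 1:3) {
    plane <- body[, , ch]
    plane[cbind(rows, cols)] <- 0.88
    act <- !is.na(hts)
    plane[cbind(rows[act], cols[act])] <- rgbpal[ch, idx_color(hts[act])]
    body[, , ch] <- plane
  }
  # upscale
  body <- body[rep(seq_len(ny), each = scale), rep(seq_len(nx), each = scale), , drop = FALSE]
  H <- dim(body)[1]

  # color bar: 4 px gap, 10 px bar
  bar <- array(1, dim = c(H, 14, 3))
  bar_rows <- seq_len(H)
  bar_idx <- rev(pmax(1L, pmin(256L, ceiling(256 * bar_rows / H))))
  for (ch in 1:3) bar[, 5:14, ch] <- matrix(rgbpal[ch, bar_idx], H, 10)
  img <- array(1, dim = c(H, dim(body)[2] + 14, 3))
  img[, seq_len(dim(body)[2]), ] <- body
  img[, dim(body)[2] + (1:14), ] <- bar

  # bottom annotation strip: "<zmin>  <zmax>" in response units
  strip <- array(1, dim = c(9, dim(img)[2], 3))
  lab <- function(v) sprintf("%.4g", v)
  strip <- stamp_text(strip, lab(zlim[1]), 3L, 2L)
  txt <- lab(zlim[2])
  strip <- stamp_text(strip, txt, 3L, dim(strip)[2] - 4L * nchar(txt) - 1L)
  img <- array(c(rbind(matrix(img[, , 1], dim(img)[1]), matrix(strip[, , 1], 9)),
                 rbind(matrix(img[, , 2], dim(img)[1]), matrix(strip[, , 2], 9)),
                 rbind(matrix(img[, , 3], dim(img)[1]), matrix(strip[, , 3], 9))),
               dim = c(dim(img)[1] + 9, dim(img)[2], 3))
  png::writePNG(img, path)
  invisible(list(path = path, zlim = zlim, size = dim(img)[1:2]))
}
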