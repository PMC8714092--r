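#' Visual-search task geometry and gaze windows
#'
#' Builds the screen layout of the search task in screen-centred degrees of
#' visual angle (+x right, +y up): 12 environmental fractals in three
#' radially symmetric rings of four (inner ring at 6 deg eccentricity rotated
#' -22.5 deg from the cardinal axes, middle at 15 deg rotated +22.5 deg,
#' outer at 17.5 deg rotated -22.5 deg), four possible target locations at
#' 12 deg eccentricity canted at 40, 130, 220 and 310 deg, and the central
#' start position.
#'
#' The analysis grid is 100 x 100 bins spanning a 61 x 61 deg square centred
#' on the screen centre (bin edge 0.61 deg). Each object's gaze window is the
#' 77 grid bins whose centres are nearest to the object centre, approximately
#' a 3-degree-radius disc. Windows of nearby objects can share bins (the
#' target locations sit ~5.1 deg from the nearest middle-ring fractal);
#' sample assignment resolves such overlaps by the fixed priority
#' target > start > environmental.
#'
#' @param grid_bins Bins per axis. Default 100.
#' @param grid_extent Side length of the analysis square in degrees.
#'   Default 61.
#' @param window_bins Number of grid bins per object window. Default 77.
#' @return An object of class `"task_geometry"`: object coordinate tables,
#'   grid definition, and per-object window bin indices.
#' @examples
#' geo <- task_geometry()
#' geo$fractals          # 12 environmental fractal centres
#' @export
task_geometry <- function(grid_bins = 100L, grid_extent = 61,
                          window_bins = 77L) {
  ring <- function(ecc, rot_deg) {
    ang <- (c(0, 90, 180, 270) + rot_deg) * pi / 180
    data.frame(x = ecc * cos(ang), y = ecc * sin(ang))
  }
  fr <- rbind(cbind(ring(6, -22.5), ring = "inner"),
              cbind(ring(15, 22.5), ring = "middle"),
              cbind(ring(17.5, -22.5), ring = "outer"))
  fr$fractal <- seq_len(nrow(fr))
  tang <- c(40, 130, 220, 310) * pi / 180
  tg <- data.frame(x = 12 * cos(tang), y = 12 * sin(tang),
                   location = 1:4, angle_deg = c(40, 130, 220, 310))

  half <- grid_extent / 2
  edges <- seq(-half, half, length.out = grid_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  cx <- rep(centers, times = grid_bins)   # column-major: x varies fastest
  cy <- rep(centers, each = grid_bins)

  nearest_bins <- function(x0, y0) {
    d2 <- (cx - x0)^2 + (cy - y0)^2
    order(d2)[seq_len(window_bins)]
  }
  win_fr <- lapply(seq_len(nrow(fr)),
                   function(i) nearest_bins(fr$x[i], fr$y[i]))
  win_tg <- lapply(seq_len(nrow(tg)),
                   function(i) nearest_bins(tg$x[i], tg$y[i]))
  win_start <- nearest_bins(0, 0)

  structure(list(fractals = fr, targets = tg,
                 start = data.frame(x = 0, y = 0),
                 grid_bins = grid_bins, grid_extent = grid_extent,
                 bin_size = grid_extent / grid_bins, edges = edges,
                 window_bins = window_bins,
                 windows = list(fractal = win_fr, target = win_tg,
                                start = win_start)),
            class = "task_geometry")
}

#' @export
print.task_geometry <- function(x, ...) {
  cat("<task_geometry>\n")
  cat(sprintf("  12 environmental fractals (3 rings), 4 target locations\n"))
  cat(sprintf("  grid %d x %d bins over %.3g x %.3g deg (bin %.3g deg); %d-bin windows\n",
              x$grid_bins, x$grid_bins, x$grid_extent, x$grid_extent,
              x$bin_size, x$window_bins))
  invisible(x)
}

# Linear bin index (1..grid_bins^2, column-major in x) of positions; NA when
# outside the grid.
grid_bin_index <- function(geometry, x, y) {
  g <- geometry$grid_bins
  half <- geometry$grid_extent / 2
  ix <- floor((x + half) / geometry$bin_size) + 1
  iy <- floor((y + half) / geometry$bin_size) + 1
  ok <- !is.na(x) & !is.na(y) & ix >= 1 & ix <= g & iy >= 1 & iy <= g
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(ix[ok] + (iy[ok] - 1) * g)
  out
}
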