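#' Detect saccades in an eye-position trace
#'
#' Velocity-threshold saccade detection: the trace is linearly interpolated
#' to 1-millisecond spacing, velocity is taken as the sample-to-sample
#' displacement, smoothed with a 15-ms-wide centred moving mean, and any
#' contiguous super-threshold period (default 0.025 deg/ms) is a candidate
#' saccade. Candidates covering less than `min_amplitude` degrees between
#' their start and end positions (default 1 deg) are discarded, so drift and
#' within-object micro-movements are ignored.
#'
#' @param trace A gaze trace data frame with columns `t_ms`, `x_deg`,
#'   `y_deg` and optionally `valid` (logical; invalid samples are dropped
#'   before interpolation).
#' @param velocity_threshold Threshold in degrees per millisecond.
#'   Default 0.025.
#' @param smooth_ms Width of the moving-mean velocity smoother in ms.
#'   Default 15.
#' @param min_amplitude Minimum start-to-end distance in degrees. Default 1.
#' @return A data frame, one row per saccade: `t_start`, `t_end` (ms),
#'   `x_start`, `y_start`, `x_end`, `y_end` (deg), `amplitude` (deg) and
#'   `peak_velocity` (deg/ms). Zero rows when no saccade is found.
#' @export
detect_saccades <- function(trace, velocity_threshold = 0.025,
                            smooth_ms = 15L, min_amplitude = 1) {
  req <- c("t_ms", "x_deg", "y_deg")
  if (!all(req %in% names(trace)))
    stop("trace must have columns ", paste(req, collapse = ", "))
  if (!is.null(trace$valid)) trace <- trace[as.logical(trace$valid), ]
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      x_start = numeric(0), y_start = numeric(0),
                      x_end = numeric(0), y_end = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0))
  if (nrow(trace) < 2L) return(empty)
  if (is.unsorted(trace$t_ms, strictly = TRUE))
    stop("trace timestamps must be strictly increasing")

  t0 <- ceiling(min(trace$t_ms)); t1 <- floor(max(trace$t_ms))
  if (t1 - t0 < smooth_ms)
    stop("trace is shorter than the velocity smoothing window")
  tt <- seq(t0, t1, by = 1)
  x <- stats::approx(trace$t_ms, trace$x_deg, xout = tt)$y
  y <- stats::approx(trace$t_ms, trace$y_deg, xout = tt)$y

  vel <- sqrt(diff(x)^2 + diff(y)^2)          # deg per ms
  sm <- stats::filter(vel, rep(1 / smooth_ms, smooth_ms), sides = 2)
  sm <- as.numeric(sm)
  above <- !is.na(sm) & sm > velocity_threshold

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    # velocity sample i spans positions i..i+1
    data.frame(t_start = tt[i1], t_end = tt[i2 + 1L],
               x_start = x[i1], y_start = y[i1],
               x_end = x[i2 + 1L], y_end = y[i2 + 1L],
               amplitude = sqrt((x[i2 + 1L] - x[i1])^2 +
                                  (y[i2 + 1L] - y[i1])^2),
               peak_velocity = max(vel[i1:i2]))
  })
  out <- if (length(out)) do.call(rbind, out) else empty
  out[out$amplitude >= min_amplitude, , drop = FALSE]
}

#' Classify the initial saccade of a search trial
#'
#' The first saccade beginning inside the trial's search period is "direct"
#' if its endpoint lands within `radius` degrees (default 1.5) of the target
#' centre. The endpoint's angular direction is reported relative to the
#' target's direction from the screen centre.
#'
#' @param trial One row of a trial table (needs `target_location`,
#'   `search_start_ms`, `search_end_ms`).
#' @param saccades A saccade table from [detect_saccades()].
#' @param geometry A [task_geometry()].
#' @param radius Direct-saccade radius in degrees. Default 1.5.
#' @return List with `response` (`"direct"`, `"indirect"`, or
#'   `"no_response"` when no saccade falls in the search period),
#'   `angle_deg` (signed angle between the saccade endpoint direction and
#'   the target direction; NA for no response) and `t_start`.
#' @export
classify_initial_saccade <- function(trial, saccades, geometry,
                                     radius = 1.5) {
  stopifnot(inherits(geometry, "task_geometry"))
  s <- saccades[saccades$t_start >= trial$search_start_ms &
                  saccades$t_start < trial$search_end_ms, , drop = FALSE]
  if (nrow(s) == 0L)
    return(list(response = "no_response", angle_deg = NA_real_,
                t_start = NA_real_))
  s <- s[1L, ]
  tg <- geometry$targets[trial$target_location, ]
  d <- sqrt((s$x_end - tg$x)^2 + (s$y_end - tg$y)^2)
  ang <- (atan2(s$y_end, s$x_end) - atan2(tg$y, tg$x)) * 180 / pi
  ang <- ((ang + 180) %% 360) - 180
  list(response = if (d <= radius) "direct" else "indirect",
       angle_deg = ang, t_start = s$t_start)
}
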