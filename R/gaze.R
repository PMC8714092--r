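# Interpolate a trace onto the 1-ms grid covering [t0, t1) and return
# per-millisecond positions plus validity.
regularize_trace <- function(trace, t0, t1) {
  tt <- if (ceiling(t1) - 1 < ceiling(t0)) numeric(0)
        else seq(ceiling(t0), ceiling(t1) - 1)
  if (length(tt) == 0L)
    return(data.frame(t_ms = numeric(0), x = numeric(0), y = numeric(0),
                      valid = logical(0)))
  valid <- if (is.null(trace$valid)) rep(TRUE, nrow(trace))
           else as.logical(trace$valid)
  tr <- trace[valid, , drop = FALSE]
  if (nrow(tr) < 2L)
    return(data.frame(t_ms = tt, x = NA_real_, y = NA_real_, valid = FALSE))
  x <- stats::approx(tr$t_ms, tr$x_deg, xout = tt)$y
  y <- stats::approx(tr$t_ms, tr$y_deg, xout = tt)$y
  # a millisecond is valid when bracketed by valid samples
  vfun <- stats::approx(trace$t_ms, as.numeric(valid), xout = tt,
                        method = "constant", f = 0)$y
  vnext <- stats::approx(trace$t_ms, as.numeric(valid), xout = tt,
                         method = "constant", f = 1)$y
  ok <- !is.na(x) & !is.na(y) & vfun > 0 & vnext > 0
  data.frame(t_ms = tt, x = x, y = y, valid = ok)
}

# Per-millisecond component labels for one trial's search period:
# "target" > "start" > "environmental" > "other" (priority order).
gaze_component_labels <- function(trace, trial, geometry) {
  reg <- regularize_trace(trace, trial$search_start_ms, trial$search_end_ms)
  bin <- grid_bin_index(geometry, reg$x, reg$y)
  in_set <- function(bins) !is.na(bin) & bin %in% bins
  lab <- rep("other", nrow(reg))
  env_bins <- unique(unlist(geometry$windows$fractal))
  lab[in_set(env_bins)] <- "environmental"
  lab[in_set(geometry$windows$start)] <- "start"
  lab[in_set(geometry$windows$target[[trial$target_location]])] <- "target"
  lab[!reg$valid] <- "other"        # blinks and track loss
  list(t_ms = reg$t_ms, label = lab, reg = reg, bin = bin)
}

#' Decompose a trial's search duration into gaze components
#'
#' Assigns every millisecond of the search period (search-array onset to the
#' start of the successful terminal fixation; the terminal hold is excluded)
#' to exactly one of four components by gaze-window membership: gaze at the
#' target fractal, gaze at the central start position, gaze at any of the 12
#' environmental fractals, and all other search time. Overlapping windows
#' are resolved by the priority target > start > environmental; invalid
#' (blink/track-loss) samples count as other. The four components sum to the
#' search duration exactly.
#'
#' @param trace Gaze samples for the trial (`t_ms`, `x_deg`, `y_deg`,
#'   optional `valid`).
#' @param trial One trial-table row (needs `target_location`,
#'   `search_start_ms`, `search_end_ms`).
#' @param geometry A [task_geometry()].
#' @return A one-row data frame with `environmental`, `target`, `start`,
#'   `other` and `total` durations in seconds.
#' @export
assign_gaze_components <- function(trace, trial, geometry) {
  stopifnot(inherits(geometry, "task_geometry"))
  lab <- gaze_component_labels(trace, trial, geometry)$label
  n <- length(lab)
  data.frame(environmental = sum(lab == "environmental") / 1000,
             target = sum(lab == "target") / 1000,
             start = sum(lab == "start") / 1000,
             other = sum(lab == "other") / 1000,
             total = n / 1000)
}

#' Count environmental fractals inspected in a trial
#'
#' Number of distinct environmental fractals whose gaze window contained the
#' gaze for at least `min_ms` cumulative milliseconds (default 50) during
#' the search period.
#'
#' @inheritParams assign_gaze_components
#' @param min_ms Minimum cumulative dwell per fractal in ms. Default 50.
#' @return Integer count in 0..12.
#' @export
count_inspected_fractals <- function(trace, trial, geometry, min_ms = 50) {
  stopifnot(inherits(geometry, "task_geometry"))
  reg <- regularize_trace(trace, trial$search_start_ms, trial$search_end_ms)
  bin <- grid_bin_index(geometry, reg$x, reg$y)
  bin[!reg$valid] <- NA_integer_
  sum(vapply(geometry$windows$fractal,
             function(b) sum(bin %in% b, na.rm = TRUE) >= min_ms,
             logical(1)))
}

#' Per-trial gaze heatmap over the analysis grid
#'
#' Accumulates the number of milliseconds gaze spent in each grid bin during
#' each trial's search period, divided by the number of trials: a
#' `grid_bins` x `grid_bins` matrix of ms per trial.
#'
#' @param traces List of gaze-sample data frames, one per trial (or a single
#'   data frame with a `trial_id` column).
#' @param trials Trial table with one row per element of `traces`.
#' @param geometry A [task_geometry()].
#' @return Numeric matrix (`grid_bins` x `grid_bins`; rows index x bins,
#'   columns y bins) of mean milliseconds per trial.
#' @export
gaze_heatmap <- function(traces, trials, geometry) {
  stopifnot(inherits(geometry, "task_geometry"))
  if (is.data.frame(traces)) {
    if (is.null(traces$trial_id))
      stop("a single traces data frame needs a `trial_id` column")
    traces <- split(traces, traces$trial_id)[
      as.character(trials$trial_id)]
  }
  if (length(traces) != nrow(trials))
    stop("need one trace per trial")
  if (nrow(trials) == 0L) stop("need at least one trial")
  acc <- numeric(geometry$grid_bins^2)
  for (i in seq_len(nrow(trials))) {
    reg <- regularize_trace(traces[[i]], trials$search_start_ms[i],
                            trials$search_end_ms[i])
    bin <- grid_bin_index(geometry, reg$x, reg$y)
    bin <- bin[reg$valid & !is.na(bin)]
    if (length(bin)) {
      tab <- tabulate(bin, nbins = length(acc))
      acc <- acc + tab
    }
  }
  matrix(acc / nrow(trials), geometry$grid_bins, geometry$grid_bins)
}

#' Fraction of the search period spent near a location
#'
#' Proportion of the trial's search-period milliseconds during which gaze
#' was within `radius` degrees (default 1.5) of a location — e.g. a novel
#' distractor fractal.
#'
#' @inheritParams assign_gaze_components
#' @param center Length-2 numeric `c(x, y)` in degrees.
#' @param radius Radius in degrees. Default 1.5.
#' @return Proportion in `[0, 1]`; `NA` (with a warning) for a zero-length
#'   search period.
#' @export
gaze_fraction_at_location <- function(trace, trial, center, radius = 1.5) {
  reg <- regularize_trace(trace, trial$search_start_ms, trial$search_end_ms)
  if (nrow(reg) == 0L) {
    warning("zero-length search period; fraction undefined")
    return(NA_real_)
  }
  d <- sqrt((reg$x - center[1])^2 + (reg$y - center[2])^2)
  mean(!is.na(d) & reg$valid & d <= radius)
}

#' Remaining search duration after a broken direct fixation
#'
#' For trials whose initial saccade landed directly on the target, the time
#' from when gaze first left the target zone (first sample farther than
#' `radius` degrees from the target centre after the direct saccade's end)
#' until the end of the search period. Returns `NA` when gaze never left the
#' target zone.
#'
#' @inheritParams assign_gaze_components
#' @param t_arrival Time (ms) the direct saccade ended on the target.
#' @param radius Target zone radius in degrees. Default 1.5.
#' @return Remaining search duration in seconds, or `NA`.
#' @export
remaining_search_duration <- function(trace, trial, geometry, t_arrival,
                                      radius = 1.5) {
  stopifnot(inherits(geometry, "task_geometry"))
  reg <- regularize_trace(trace, max(t_arrival, trial$search_start_ms),
                          trial$search_end_ms)
  if (nrow(reg) == 0L) return(NA_real_)
  tg <- geometry$targets[trial$target_location, ]
  d <- sqrt((reg$x - tg$x)^2 + (reg$y - tg$y)^2)
  away <- which(!is.na(d) & d > radius)
  if (length(away) == 0L) return(NA_real_)
  (trial$search_end_ms - reg$t_ms[away[1L]]) / 1000
}
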