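#' Parameters of the synthetic session generator
#'
#' Bundles the trial-structure constants of the search task (5-second search
#' limit, 0.75-second target hold, 1-2 s inter-trial intervals, ~25%
#' interleaved single-fractal trials, environments with reward-target
#' probabilities 0/25/50/75/100%) with the injected behavioral structure the
#' analyses are meant to recover:
#'
#' * search durations are truncated log-normal with a negative target-value
#'   effect (`beta_value`) and a positive environment-probability effect
#'   (`beta_prob`) on the log scale;
#' * the non-environmental gaze components (start, target, other) have
#'   roughly condition-independent means, so the injected effects are
#'   carried almost entirely by the environmental-gaze component (the
#'   remainder);
#' * search errors (failing to fixate the target within the limit) are more
#'   likely on no-reward trials;
#' * the probability of a direct initial saccade falls with environment
#'   reward probability and rises with target value.
#'
#' The default effect sizes are calibrated so the reward/no-reward search
#' duration ROC area is approximately 0.73.
#'
#' @param n_trials Number of trials. Default 2000.
#' @param frac_single Fraction of single-fractal trials. Default 0.25.
#' @param p_reward Environment reward-target probabilities.
#' @param log_mu0 Baseline log-mean search duration (s) for a no-reward
#'   target in the 0% environment. Default `log(0.45)`.
#' @param beta_value Target-value effect on log duration (negative).
#' @param beta_prob Environment-probability effect on log duration
#'   (positive).
#' @param sigma_log Log-scale SD of search durations.
#' @param log_mu0_single,beta_value_single,sigma_log_single Analogous
#'   single-fractal-task parameters (no environment effect there).
#' @param err_base,err_value Search-error probability `err_base +
#'   err_value * (1 - target_value)` on search trials.
#' @param start_mean,start_sd,target_mean,target_sd,other_mean,other_sd
#'   Means/SDs (s) of the non-environmental component targets.
#' @param direct_b0,direct_bvalue,direct_bprob Logistic coefficients of the
#'   direct-initial-saccade model.
#' @param max_search Search limit in seconds. Default 5.
#' @param fix_hold Terminal fixation hold in seconds. Default 0.75.
#' @param outcome_delay Delay from hold completion to outcome. Default 0.5.
#' @param iti_range Inter-trial interval range in seconds. Default 1-2.
#' @param gaze_sd Fixational jitter SD in degrees. Default 0.15.
#' @param jitter_knot_ms Spacing of the smooth jitter knots. Default 50.
#' @return An object of class `"generator_params"`.
#' @export
generator_params <- function(n_trials = 2000L,
                             frac_single = 0.25,
                             p_reward = c(0, 0.25, 0.5, 0.75, 1),
                             log_mu0 = log(0.45),
                             beta_value = -0.68,
                             beta_prob = 0.55,
                             sigma_log = 0.45,
                             log_mu0_single = log(0.35),
                             beta_value_single = -0.15,
                             sigma_log_single = 0.3,
                             err_base = 0.03,
                             err_value = 0.12,
                             start_mean = 0.18, start_sd = 0.04,
                             target_mean = 0.12, target_sd = 0.03,
                             other_mean = 0.08, other_sd = 0.02,
                             direct_b0 = 1.9, direct_bvalue = 1.2,
                             direct_bprob = -1.6,
                             max_search = 5, fix_hold = 0.75,
                             outcome_delay = 0.5,
                             iti_range = c(1, 2),
                             gaze_sd = 0.15, jitter_knot_ms = 50) {
  p <- as.list(environment())
  stopifnot(p$n_trials >= 1, p$frac_single >= 0, p$frac_single <= 1,
            all(p$p_reward >= 0), all(p$p_reward <= 1),
            p$sigma_log > 0, p$max_search > 0, p$fix_hold > 0,
            length(p$iti_range) == 2L, p$gaze_sd >= 0)
  structure(p, class = "generator_params")
}

# duration of a schematic saccade of given amplitude (deg), in ms;
# amplitude/duration always exceeds the 0.025 deg/ms detection threshold
saccade_ms <- function(amplitude) pmax(12, round(20 + 2 * amplitude))

truncated_lnorm <- function(n, mu, sigma, cap) {
  u <- stats::runif(n) * stats::plnorm(cap, mu, sigma)
  stats::qlnorm(u, mu, sigma)
}

#' Generate a synthetic behavioral session
#'
#' Draws a trial table (and optionally per-trial gaze traces) with the task
#' structure and injected effects described in [generator_params()], plus a
#' ground-truth record sufficient to predict every analysis output. After a
#' search error the next trial repeats the same condition (`repeat_flag`).
#'
#' @param params A [generator_params()].
#' @param seed Integer seed; the session is a deterministic function of
#'   `(params, seed)`.
#' @param gaze Generate millisecond gaze traces for each trial? (The trial
#'   table alone suffices for duration-level analyses and is much faster.)
#' @param geometry A [task_geometry()] (built on demand when `NULL`).
#' @return An object of class `"synthetic_session"`: `trials` (trial table),
#'   `gaze` (data frame of samples with `trial_id`, or NULL), and
#'   `ground_truth` (params plus per-trial latent components).
#' @export
generate_session <- function(params = generator_params(), seed = 1L,
                             gaze = FALSE, geometry = NULL) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(as.integer(seed))
  if (gaze && is.null(geometry)) geometry <- task_geometry()
  n <- params$n_trials
  n_env <- length(params$p_reward)

  task <- character(n); env <- integer(n); value <- integer(n)
  loc <- integer(n); dur <- numeric(n); err <- logical(n)
  rep_flag <- logical(n)
  comp <- matrix(0, n, 4L,
                 dimnames = list(NULL, c("start", "target", "other",
                                         "environmental")))
  direct <- logical(n)

  for (i in seq_len(n)) {
    if (i > 1L && err[i - 1L]) {            # repeat the failed condition
      task[i] <- task[i - 1L]; env[i] <- env[i - 1L]
      value[i] <- value[i - 1L]; rep_flag[i] <- TRUE
    } else {
      task[i] <- if (stats::runif(1) < params$frac_single) "single"
                 else "search"
      env[i] <- sample.int(n_env, 1L)
      value[i] <- stats::rbinom(1L, 1L, params$p_reward[env[i]])
    }
    loc[i] <- sample.int(4L, 1L)
    p <- params$p_reward[env[i]]
    if (task[i] == "search") {
      perr <- params$err_base + params$err_value * (1 - value[i])
      err[i] <- stats::runif(1) < perr
      mu <- params$log_mu0 + params$beta_value * value[i] +
        params$beta_prob * p
      sg <- params$sigma_log
    } else {
      perr <- params$err_base / 3
      err[i] <- stats::runif(1) < perr
      mu <- params$log_mu0_single + params$beta_value_single * value[i]
      sg <- params$sigma_log_single
    }
    dur[i] <- if (err[i]) params$max_search
              else truncated_lnorm(1L, mu, sg, params$max_search)
    dur[i] <- max(0.002, round(dur[i] * 1000) / 1000)   # whole-ms timing

    if (task[i] == "search") {
      st <- max(0.05, stats::rnorm(1, params$start_mean, params$start_sd))
      tg <- max(0.03, stats::rnorm(1, params$target_mean, params$target_sd))
      ot <- max(0.02, stats::rnorm(1, params$other_mean, params$other_sd))
      fixed <- st + tg + ot
      if (fixed >= dur[i]) {
        sc <- dur[i] / fixed
        st <- st * sc; tg <- tg * sc; ot <- ot * sc
      }
      comp[i, ] <- c(st, tg, ot, max(0, dur[i] - st - tg - ot))
    } else {
      st <- min(dur[i] * 0.6, 0.25)
      comp[i, ] <- c(st, dur[i] - st, 0, 0)
    }
    eta <- params$direct_b0 + params$direct_bvalue * value[i] +
      params$direct_bprob * p
    direct[i] <- stats::runif(1) < stats::plogis(eta)
  }

  iti <- stats::runif(n, params$iti_range[1], params$iti_range[2])
  post <- ifelse(err, params$max_search + iti,
                 dur + params$fix_hold + params$outcome_delay + iti)
  # session clock: searches start after the preceding trial fully ends
  search_start <- round(cumsum(c(0, utils::head(post, -1) + 0.9)) * 1000)
  search_end <- search_start + round(dur * 1000)

  trials <- data.frame(
    session = 1L, trial_id = seq_len(n), task = task, env = env,
    reward_probability = params$p_reward[env], target_value = value,
    target_location = loc,
    search_start_ms = search_start, search_end_ms = search_end,
    outcome = ifelse(err, "search_error", "correct"),
    repeat_flag = rep_flag,
    search_duration = (search_end - search_start) / 1000,
    post_array_time = post)

  gaze_df <- NULL
  realized <- NULL
  if (gaze) {
    per <- vector("list", n)
    n_env_fix <- rep(NA_integer_, n)
    realized <- matrix(NA_real_, n, 4L,
                       dimnames = list(NULL, c("start", "target", "other",
                                               "environmental")))
    for (i in seq_len(n)) {
      fp <- fixation_plan(trials[i, ], comp[i, ], direct[i], params,
                          geometry)
      realized[i, names(fp$realized)] <- fp$realized
      n_env_fix[i] <- fp$n_env_fix
      tr <- generate_gaze_trace(fp$plan, params, seed = NULL,
                                t0 = trials$search_start_ms[i])
      tr$trial_id <- trials$trial_id[i]
      per[[i]] <- tr
    }
    gaze_df <- do.call(rbind, per)
  }

  structure(list(
    trials = trials, gaze = gaze_df,
    ground_truth = list(params = params, seed = as.integer(seed),
                        components = as.data.frame(comp),
                        realized_components =
                          if (gaze) as.data.frame(realized) else NULL,
                        n_env_fixations = if (gaze) n_env_fix else NULL,
                        direct = direct)),
    class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d trials (%d search, %d single), %s gaze\n",
              nrow(x$trials), sum(x$trials$task == "search"),
              sum(x$trials$task == "single"),
              if (is.null(x$gaze)) "no" else "with"))
  invisible(x)
}

# Build the scripted fixation sequence realizing one trial's planned
# component durations. Saccadic flight time is paid out of the "other"
# budget (flights land outside every gaze window for the window analysis,
# as in real data), borrowing from the environmental/target/start dwells
# only when "other" cannot cover it. Returns the plan plus the realized
# component allocation (what the window analysis should recover).
fixation_plan <- function(trial, comp, direct, params, geometry) {
  tg <- geometry$targets[trial$target_location, ]
  blank <- c(22, 22)                       # far from every gaze window
  total <- trial$search_end_ms - trial$search_start_ms
  st_ms <- round(comp["start"] * 1000)
  tg_ms <- round(comp["target"] * 1000)
  env_ms <- round(comp["environmental"] * 1000)

  # fixation sequence: start -> (direct target visit) -> environmental
  # fractals -> target revisit -> blank filler
  fx <- list(data.frame(x = 0, y = 0, label = "start"))
  tg1 <- if (direct) 1L else 0L
  if (tg1) fx <- c(fx, list(data.frame(x = tg$x, y = tg$y,
                                       label = "target")))
  n_fix <- 0L
  if (env_ms >= 60 && trial$task == "search") {
    n_fix <- max(1L, min(12L, round(env_ms / 200)))
    idx <- sample.int(12L, n_fix)
    for (j in idx)
      fx <- c(fx, list(data.frame(x = geometry$fractals$x[j],
                                  y = geometry$fractals$y[j],
                                  label = "environmental")))
  }
  # non-direct trials foveate near, not on, the target: 2.5 deg off-centre
  # stays inside the 3-deg gaze window but outside the 1.5-deg direct zone
  if (tg1) { tvx <- tg$x; tvy <- tg$y } else {
    th <- atan2(tg$y, tg$x) + pi / 2
    tvx <- tg$x + 2.5 * cos(th); tvy <- tg$y + 2.5 * sin(th)
  }
  if (!tg1 || tg_ms > 2) fx <- c(fx, list(data.frame(x = tvx, y = tvy,
                                                     label = "target")))
  fx <- c(fx, list(data.frame(x = blank[1], y = blank[2],
                              label = "other")))
  plan <- do.call(rbind, fx)

  transit <- if (nrow(plan) > 1L)
    sum(saccade_ms(sqrt(diff(plan$x)^2 + diff(plan$y)^2))) else 0
  blank_ms <- total - transit - st_ms - tg_ms - env_ms
  if (blank_ms < 0) {                      # borrow, environmental first
    for (nm in c("env_ms", "tg_ms", "st_ms")) {
      take <- min(get(nm), -blank_ms)
      assign(nm, get(nm) - take)
      blank_ms <- blank_ms + take
      if (blank_ms >= 0) break
    }
    blank_ms <- max(0, blank_ms)
  }

  dw <- numeric(nrow(plan))
  dw[plan$label == "start"] <- st_ms
  if (tg1) {
    t1 <- round(tg_ms * 0.6)
    dw[plan$label == "target"] <- c(t1, tg_ms - t1)[
      seq_len(sum(plan$label == "target"))]
  } else dw[plan$label == "target"] <- tg_ms
  if (n_fix > 0) {
    e <- floor(env_ms / n_fix)
    dw[plan$label == "environmental"] <- c(rep(e, n_fix - 1L),
                                           env_ms - e * (n_fix - 1L))
  }
  dw[plan$label == "other"] <- blank_ms
  plan$dwell_ms <- dw
  plan <- plan[plan$dwell_ms >= 2, , drop = FALSE]

  realized <- c(start = unname(st_ms), target = unname(tg_ms),
                other = unname(total - st_ms - tg_ms - env_ms),
                environmental = unname(env_ms)) / 1000
  n_fix <- sum(plan$label == "environmental")
  # terminal fixation (the successful hold) begins at search end
  hold <- data.frame(x = tg$x, y = tg$y, label = "hold",
                     dwell_ms = round(params$fix_hold * 1000))
  list(plan = rbind(plan, hold), realized = realized, n_env_fix = n_fix)
}

#' Render a fixation plan as a millisecond gaze trace
#'
#' Converts a sequence of planned fixations into 1-ms eye-position samples:
#' stationary smooth jitter around each fixation centre (Gaussian knots
#' every `jitter_knot_ms` ms, linearly interpolated, so fixational velocity
#' stays far below the saccade detection threshold) and constant-velocity
#' saccadic transitions between fixations whose peak velocity always
#' exceeds 0.025 deg/ms. Every planned fixation of at least 50 ms is
#' recoverable by the detection and window analyses.
#'
#' @param plan Data frame with columns `x`, `y`, `dwell_ms` (one row per
#'   fixation, in order); dwells below 2 ms are an error.
#' @param params A [generator_params()] (for `gaze_sd`, `jitter_knot_ms`).
#' @param seed Optional integer seed.
#' @param t0 Timestamp (ms) of the first sample. Default 0.
#' @return Data frame with `t_ms`, `x_deg`, `y_deg`, `valid`.
#' @export
generate_gaze_trace <- function(plan, params = generator_params(),
                                seed = NULL, t0 = 0) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (any(plan$dwell_ms < 2)) stop("fixation dwells must be at least 2 ms")
  xs <- list(); ys <- list()
  n_fix <- nrow(plan)
  jitter <- function(ms) {
    if (params$gaze_sd == 0) return(cbind(rep(0, ms), rep(0, ms)))
    kn <- max(2L, ceiling(ms / params$jitter_knot_ms) + 1L)
    kt <- seq(1, ms, length.out = kn)
    jx <- stats::approx(kt, stats::rnorm(kn, 0, params$gaze_sd),
                        xout = seq_len(ms))$y
    jy <- stats::approx(kt, stats::rnorm(kn, 0, params$gaze_sd),
                        xout = seq_len(ms))$y
    cbind(jx, jy)
  }
  for (i in seq_len(n_fix)) {
    ms <- plan$dwell_ms[i]
    j <- jitter(ms)
    xs[[length(xs) + 1L]] <- plan$x[i] + j[, 1L]
    ys[[length(ys) + 1L]] <- plan$y[i] + j[, 2L]
    if (i < n_fix) {
      amp <- sqrt((plan$x[i + 1L] - plan$x[i])^2 +
                    (plan$y[i + 1L] - plan$y[i])^2)
      sm <- saccade_ms(amp)
      f <- seq_len(sm) / (sm + 1)
      xs[[length(xs) + 1L]] <- plan$x[i] + f * (plan$x[i + 1L] - plan$x[i])
      ys[[length(ys) + 1L]] <- plan$y[i] + f * (plan$y[i + 1L] - plan$y[i])
    }
  }
  x <- unlist(xs); y <- unlist(ys)
  data.frame(t_ms = t0 + seq_along(x) - 1, x_deg = x, y_deg = y,
             valid = TRUE)
}
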