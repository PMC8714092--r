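# Table schemas shared by the readers/writers and the generator.
.trial_required <- c("session", "trial_id", "task", "env",
                     "reward_probability", "target_value",
                     "target_location", "search_start_ms", "search_end_ms",
                     "outcome")
.gaze_required <- c("trial_id", "t_ms", "x_deg", "y_deg", "valid")

#' Read or write a trial table
#'
#' Trial tables are plain CSV with one row per trial and columns `session`,
#' `trial_id`, `task` (`search`/`single`), `env`, `reward_probability`,
#' `target_value` (0/1), `target_location` (1-4), `search_start_ms`,
#' `search_end_ms`, `outcome` (`correct`/`search_error`), plus optional
#' `repeat_flag`, `search_duration`, `post_array_time`,
#' `novel_fractal_location`. Reading validates the schema and the
#' categorical fields.
#'
#' @param path CSV file path.
#' @param trials A trial table data frame (for writing).
#' @return `read_trial_table()` returns the validated data frame;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_required, names(df))
  if (length(missing))
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!df$task %in% c("search", "single"))
  if (length(bad))
    stop("unparseable `task` value in row ", bad[1L])
  bad <- which(!df$outcome %in% c("correct", "search_error"))
  if (length(bad))
    stop("unparseable `outcome` value in row ", bad[1L])
  bad <- which(!df$target_value %in% c(0, 1))
  if (length(bad))
    stop("unparseable `target_value` value in row ", bad[1L])
  if (is.null(df$search_duration))
    df$search_duration <- (df$search_end_ms - df$search_start_ms) / 1000
  df
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a gaze-sample table
#'
#' Gaze tables are plain CSV with columns `trial_id`, `t_ms`, `x_deg`,
#' `y_deg`, `valid` — millisecond-order eye positions in screen-centred
#' degrees.
#'
#' @param path CSV file path.
#' @param gaze A gaze table data frame (for writing).
#' @return The validated data frame, or `path` invisibly for the writer.
#' @export
read_gaze_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.gaze_required, names(df))
  if (length(missing))
    stop("gaze table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$valid <- as.logical(df$valid)
  df
}

#' @rdname read_gaze_table
#' @export
write_gaze_table <- function(gaze, path) {
  utils::write.csv(gaze, path, row.names = FALSE)
  invisible(path)
}

#' Export a solved policy as tidy tables
#'
#' Writes a solver result as a JSON summary (global reward rate, iteration
#' history, per-slice decision thresholds) and a CSV state table (one row
#' per state: environment, inspections, revealed multiset, values, action).
#'
#' @param config The [foraging_config()] that was solved.
#' @param result A [optimize_policy()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_solver_result <- function(config, result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ws <- foraging_workspace(config)
  states <- data.frame(
    env = ws$env, n_inspected = ws$n,
    revealed = vapply(ws$revealed, paste, character(1), collapse = " "),
    v_inspect = result$v_inspect, v_consume = result$v_consume,
    v = result$v,
    action = ifelse(result$inspect, "inspect", "consume_and_leave"),
    consume_count = result$consume_count)
  csv <- file.path(dir, "states.csv")
  utils::write.csv(states, csv, row.names = FALSE)
  thr <- extract_thresholds(config, result)
  js <- file.path(dir, "solution.json")
  jsonlite::write_json(
    list(r_global = result$r_global,
         iterations_used = result$iterations_used,
         converged = result$converged,
         rate_history = result$rate_history,
         thresholds = as.data.frame(thr)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(states = csv, solution = js))
}

#' Run the analysis pipeline end to end
#'
#' Executes the named stages in dependency order against one configuration:
#' `"solve"` (optimal and restricted policies), `"probe"` (the forced
#' reward/no-reward search-task probe), `"generate"` (a synthetic session),
#' and `"analyze"` (duration statistics on the generated or supplied
#' session). All randomness derives from `seed`; a run manifest sufficient
#' to reproduce the outputs exactly is returned and, when `out_dir` is
#' given, everything is also written to disk as CSV/JSON.
#'
#' @param stages Character vector of stages (any subset of
#'   `c("solve", "probe", "generate", "analyze")`).
#' @param config A [foraging_config()] for the model stages.
#' @param policies Which policies to solve (subset of P1-P4).
#' @param params A [generator_params()] for the generate stage.
#' @param trials Optional pre-existing trial table for `"analyze"`.
#' @param seed Integer master seed.
#' @param out_dir Optional output directory.
#' @return List with one element per executed stage plus `manifest`.
#' @export
run_pipeline <- function(stages = c("solve", "probe", "generate", "analyze"),
                         config = foraging_config(),
                         policies = "P4",
                         params = generator_params(),
                         trials = NULL,
                         seed = 1L,
                         out_dir = NULL) {
  known <- c("solve", "probe", "generate", "analyze")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(known, collapse = ", "), ")")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  solved <- NULL

  if ("solve" %in% stages) {
    solved <- lapply(policies, function(p)
      optimize_policy(config, policy_features(p)))
    names(solved) <- policies
    out$solve <- solved
    if (!is.null(out_dir))
      for (p in policies)
        write_solver_result(config, solved[[p]],
                            file.path(out_dir, paste0("solve_", p)))
  }
  if ("probe" %in% stages) {
    if (is.null(solved))
      stop("stage `probe` requires stage `solve`")
    probes <- lapply(names(solved), function(p) {
      pr <- search_task_probe(config, solved[[p]])
      pr$policy <- p
      pr
    })
    out$probe <- do.call(rbind, probes)
    if (!is.null(out_dir))
      utils::write.csv(out$probe, file.path(out_dir, "probe.csv"),
                       row.names = FALSE)
  }
  if ("generate" %in% stages) {
    out$generate <- generate_session(params, seed = seed)
    trials <- out$generate$trials
    if (!is.null(out_dir))
      write_trial_table(trials, file.path(out_dir, "trials.csv"))
  }
  if ("analyze" %in% stages) {
    if (is.null(trials))
      stop("stage `analyze` needs generated or supplied trials")
    out$analyze <- analyze_trials(trials, seed = seed + 1L)
    if (!is.null(out_dir)) {
      utils::write.csv(out$analyze,
                       file.path(out_dir, "statistics.csv"),
                       row.names = FALSE)
      jsonlite::write_json(out$analyze, file.path(out_dir,
                                                  "statistics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out$manifest <- list(
    stages = stages, seed = as.integer(seed),
    policies = policies,
    config = unclass(config),
    generator = if ("generate" %in% stages) unclass(params) else NULL,
    package_version = as.character(utils::packageVersion("patchforage")),
    timestamp = format(Sys.time(), tz = "UTC"),
    out_dir = out_dir)
  if (!is.null(out_dir))
    jsonlite::write_json(out$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  out
}

#' Duration-level statistics of one session
#'
#' Computes the core reward-related statistics of a trial table: the
#' reward/no-reward ROC area of search durations, Spearman permutation
#' correlations between duration and environment reward probability within
#' each target value, the two-regressor OLS reward-effect fit, and the
#' reward-rate ratio. A tidy one-row-per-statistic table.
#'
#' @param trials A trial table (see [read_trial_table()]).
#' @param n_perm Permutations for the correlation tests. Default 2000.
#' @param n_boot Bootstrap resamples for the RRR CI. Default 0 (point
#'   estimate only).
#' @param seed Integer seed.
#' @return Data frame with columns `statistic`, `stratum`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, `n`.
#' @export
analyze_trials <- function(trials, n_perm = 2000L, n_boot = 0L, seed = 1L) {
  search <- trials[trials$task == "search" &
                     trials$outcome == "correct", ]
  dur <- search$search_duration
  rew <- search$target_value == 1
  row <- function(statistic, stratum, estimate, ci = c(NA, NA), p = NA,
                  n = NA)
    data.frame(statistic = statistic, stratum = stratum,
               estimate = estimate, ci_low = ci[1], ci_high = ci[2],
               p = p, n = n)
  out <- list()
  out[[1]] <- row("roc_area", "reward_vs_no_reward",
                  roc_area(dur[rew], dur[!rew]), n = length(dur))
  sp_r <- spearman_perm(search$reward_probability[rew], dur[rew],
                        n_perm = n_perm, seed = seed)
  sp_n <- spearman_perm(search$reward_probability[!rew], dur[!rew],
                        n_perm = n_perm, seed = seed + 1L)
  out[[2]] <- row("spearman_rho", "reward", sp_r$rho, p = sp_r$p,
                  n = sum(rew))
  out[[3]] <- row("spearman_rho", "no_reward", sp_n$rho, p = sp_n$p,
                  n = sum(!rew))
  fit <- fit_reward_effects(search, dur)
  out[[4]] <- row("ols_coef_preward", "total", fit$coef_preward,
                  n = nrow(search))
  out[[5]] <- row("ols_coef_reward", "total", fit$coef_reward,
                  n = nrow(search))
  rrr <- reward_rate_ratio(trials[trials$task == "search", ],
                           n_boot = n_boot, seed = seed + 2L)
  out[[6]] <- row("reward_rate_ratio", "search",
                  rrr$rrr,
                  ci = if (is.null(rrr$ci)) c(NA, NA) else rrr$ci,
                  n = sum(trials$task == "search"))
  do.call(rbind, out)
}
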