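#' ROC area between two duration distributions
#'
#' Area under the receiver operating characteristic for discriminating
#' `group_b` from `group_a`: the probability that a random draw from
#' `group_b` exceeds one from `group_a`, with half credit for ties. Equal to
#' the Mann-Whitney U statistic divided by `n_a * n_b` (midrank
#' formulation).
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return Area in `[0, 1]`; 0.5 for exchangeable groups.
#' @examples
#' roc_area(c(1, 2, 3), c(2, 3, 4))   # 7/9: 6 wins + 2 half-credit ties
#' @export
roc_area <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  r <- rank(c(group_a, group_b))
  n_a <- length(group_a); n_b <- length(group_b)
  u <- sum(r[n_a + seq_len(n_b)]) - n_b * (n_b + 1) / 2
  u / (n_a * n_b)
}

#' Spearman correlation with a permutation test
#'
#' Spearman's rho with a two-sided permutation p-value: pairings of `y` are
#' shuffled `n_perm` times (default 10,000) and
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)`, which is never
#' zero.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @param n_perm Number of permutations. Default 10000.
#' @param seed Optional integer seed.
#' @return List with `rho`, `p`, and `n_perm`. Constant input yields
#'   `rho = NA` with a warning.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, seed = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n_perm = n_perm))
  }
  rho <- stats::cor(rx, ry)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    rp <- stats::cor(rx, sample(ry))
    if (abs(rp) >= abs(rho)) hits <- hits + 1L
  }
  list(rho = rho, p = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Bootstrap confidence interval for a difference of group statistics
#'
#' Percentile bootstrap interval for
#' `statistic(samples_a) - statistic(samples_b)` (or any two-sample
#' statistic via `statistic(a, b)` when `paired_statistic = TRUE`), with
#' within-group resampling with replacement.
#'
#' @param statistic Function of one group (or of both groups when
#'   `paired_statistic`).
#' @param samples_a,samples_b Numeric vectors.
#' @param n_boot Number of bootstrap resamples. Default 20000.
#' @param level Confidence level. Default 0.999.
#' @param seed Optional integer seed.
#' @param paired_statistic If `TRUE`, `statistic(a, b)` is resampled as a
#'   whole rather than differenced.
#' @return List with `estimate`, `ci` (length-2), `level`, `n_boot`.
#' @export
bootstrap_diff_ci <- function(statistic, samples_a, samples_b,
                              n_boot = 20000L, level = 0.999, seed = NULL,
                              paired_statistic = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stat2 <- if (paired_statistic) statistic
           else function(a, b) statistic(a) - statistic(b)
  est <- stat2(samples_a, samples_b)
  na <- length(samples_a); nb <- length(samples_b)
  boots <- vapply(seq_len(n_boot), function(i) {
    stat2(samples_a[sample.int(na, na, replace = TRUE)],
          samples_b[sample.int(nb, nb, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  list(estimate = est,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha),
                                   na.rm = TRUE)),
       level = level, n_boot = n_boot)
}

# Means of total (or residual) search duration over the 8 reward-related
# conditions: reward x {25,50,75,100}% plus no-reward x {0,25,50,75}%.
condition_means <- function(trials, values) {
  combos <- rbind(data.frame(target_value = 1, p = c(.25, .5, .75, 1)),
                  data.frame(target_value = 0, p = c(0, .25, .5, .75)))
  m <- mapply(function(v, p) {
    sel <- trials$target_value == v &
      abs(trials$reward_probability - p) < 1e-9
    if (!any(sel)) NA_real_ else mean(values[sel])
  }, combos$target_value, combos$p)
  combos$mean <- m
  combos
}

#' Reward-related variance explained by a search component
#'
#' The reward-related variance of total search duration is the variance of
#' its 8 condition means (target value x environment reward probability).
#' The percentage explained by one component is the percentage by which that
#' variance drops when the component is subtracted from the total:
#' `100 * (Var(means of total) - Var(means of total - component)) /
#' Var(means of total)`. Percentages across components can sum above 100
#' when components covary.
#'
#' @param trials Trial table with `target_value` (0/1),
#'   `reward_probability`, and `total` search durations.
#' @param component Per-trial component durations (same length).
#' @return Percentage (can be negative if subtracting the component
#'   increases condition variance).
#' @export
reward_variance_explained <- function(trials, component) {
  tot <- condition_means(trials, trials$total)
  if (anyNA(tot$mean))
    stop("all 8 reward-related conditions must be populated")
  res <- condition_means(trials, trials$total - component)
  v0 <- stats::var(tot$mean)
  if (v0 == 0) {
    warning("zero reward-related variance; percentage undefined")
    return(NA_real_)
  }
  100 * (v0 - stats::var(res$mean)) / v0
}

#' Linear reward-effect fit for one search component
#'
#' Ordinary least squares of single-trial component durations on the two
#' reward-related regressors: the environment's reward probability
#' (`p_reward`, in `[0, 1]`) and the target's value (`reward`, 0/1). Main
#' effects only.
#'
#' @param trials Trial table with `target_value` and `reward_probability`.
#' @param durations Per-trial durations of the component (or total).
#' @return List with `intercept`, `coef_preward`, `coef_reward`, and the
#'   underlying `fit` ([stats::lm()] object).
#' @export
fit_reward_effects <- function(trials, durations) {
  df <- data.frame(y = durations, p_reward = trials$reward_probability,
                   reward = trials$target_value)
  if (length(unique(df$p_reward)) < 2L || length(unique(df$reward)) < 2L)
    stop("both regressors must vary")
  fit <- stats::lm(y ~ p_reward + reward, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("degenerate (collinear) design")
  list(intercept = unname(cf[1]), coef_preward = unname(cf["p_reward"]),
       coef_reward = unname(cf["reward"]), fit = fit)
}

# Reward rate and its behave-as-on-reward-trials counterfactual from a
# trial table. Times are seconds spent after search-array onset.
rrr_rates <- function(trials) {
  correct <- trials$outcome == "correct"
  reward <- trials$target_value == 1
  n_corr <- sum(correct)
  if (n_corr == 0L || !any(correct & reward) || !any(correct & !reward))
    stop("need correct trials in both target-value strata")
  e_reward <- mean(reward[correct])
  e_time_corr <- mean(trials$post_array_time[correct])
  err_per_corr <- sum(!correct) / n_corr
  e_time_err <- if (any(!correct)) mean(trials$post_array_time[!correct])
                else 0
  actual <- e_reward / (e_time_corr + err_per_corr * e_time_err)

  # substitute no-reward behavior (mean correct search duration, error
  # rate) with reward-trial behavior
  ms_r <- mean(trials$search_duration[correct & reward])
  ms_nr <- mean(trials$search_duration[correct & !reward])
  err_rate_r <- if (any(reward)) mean(trials$outcome[reward] != "correct")
                else 0
  f_nr <- mean(!reward[correct])
  e_time_corr_th <- e_time_corr + f_nr * (ms_r - ms_nr)
  err_per_corr_th <- err_rate_r / (1 - err_rate_r)
  theoretical <- e_reward / (e_time_corr_th + err_per_corr_th * e_time_err)
  c(actual = actual, theoretical = theoretical)
}

#' Reward-rate ratio (RRR)
#'
#' Ratio of the reward rate actually achieved after search-array onset to
#' the theoretical rate that would have been achieved had behavior on
#' no-reward trials matched behavior on reward trials (same mean correct
#' search duration and search-error rate). The actual rate is
#' `E[reward | correct] / (E[post-array time | correct] +
#' E[#errors per correct] * E[post-array time | error])`. Values below 1
#' quantify the reward-rate cost of the reward-related bias.
#'
#' @param trials Trial table with columns `target_value` (0/1), `outcome`
#'   (`"correct"`/`"search_error"`), `search_duration` and `post_array_time`
#'   (seconds).
#' @param n_boot Bootstrap resamples for the percentile CI (resampling unit
#'   is the trial). Default 20000; set to 0 to skip the CI.
#' @param level CI level. Default 0.999.
#' @param seed Optional integer seed.
#' @return List with `rrr`, `actual_rate`, `theoretical_rate`, and `ci`
#'   (NULL when `n_boot = 0`).
#' @export
reward_rate_ratio <- function(trials, n_boot = 20000L, level = 0.999,
                              seed = NULL) {
  rt <- rrr_rates(trials)
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- nrow(trials)
    boots <- vapply(seq_len(n_boot), function(i) {
      b <- trials[sample.int(n, n, replace = TRUE), ]
      out <- tryCatch(rrr_rates(b), error = function(e) c(NA, NA))
      out[1] / out[2]
    }, numeric(1))
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(rrr = unname(rt["actual"] / rt["theoretical"]),
       actual_rate = unname(rt["actual"]),
       theoretical_rate = unname(rt["theoretical"]), ci = ci)
}
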