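test_that("generated sessions are deterministic and structurally valid", {
  pars <- generator_params(n_trials = 400)
  s1 <- generate_session(pars, seed = 21)
  s2 <- generate_session(pars, seed = 21)
  expect_identical(s1$trials, s2$trials)
  tr <- s1$trials
  expect_equal(nrow(tr), 400L)
  expect_true(all(tr$task %in% c("search", "single")))
  # roughly a quarter single-fractal trials
  expect_gt(mean(tr$task == "single"), 0.15)
  expect_lt(mean(tr$task == "single"), 0.35)
  expect_true(all(tr$reward_probability %in% c(0, .25, .5, .75, 1)))
  # value consistent with the environment's probability
  expect_true(all(tr$target_value[tr$reward_probability == 0] == 0))
  expect_true(all(tr$target_value[tr$reward_probability == 1] == 1))
  # durations in (0, 5]; error trials at the cap
  expect_true(all(tr$search_duration > 0 & tr$search_duration <= 5))
  expect_true(all(tr$search_duration[tr$outcome == "search_error"] == 5))
  # a trial after an error repeats its condition
  errs <- which(tr$outcome == "search_error")
  errs <- errs[errs < nrow(tr)]
  expect_true(all(tr$repeat_flag[errs + 1]))
  expect_true(all(tr$env[errs + 1] == tr$env[errs]))
  # planned components sum to the search duration
  comp <- s1$ground_truth$components
  expect_equal(rowSums(comp), tr$search_duration, tolerance = 1e-9)
})

test_that("a null generator produces no reward-related structure", {
  pars <- generator_params(n_trials = 1500, beta_value = 0, beta_prob = 0,
                           err_value = 0)
  tr <- generate_session(pars, seed = 5)$trials
  s <- tr$task == "search" & tr$outcome == "correct"
  roc <- roc_area(tr$search_duration[s & tr$target_value == 1],
                  tr$search_duration[s & tr$target_value == 0])
  expect_equal(roc, 0.5, tolerance = 0.05)
  sp <- spearman_perm(tr$reward_probability[s], tr$search_duration[s],
                      n_perm = 300, seed = 1)
  expect_lt(abs(sp$rho), 0.08)
  rrr <- reward_rate_ratio(tr[tr$task == "search", ], n_boot = 0)
  expect_equal(rrr$rrr, 1, tolerance = 0.06)
})

test_that("default effects reproduce the qualitative search-duration pattern", {
  tr <- generate_session(generator_params(n_trials = 5000),
                         seed = 31)$trials
  s <- tr$task == "search" & tr$outcome == "correct"
  d <- tr$search_duration[s]; v <- tr$target_value[s]
  p <- tr$reward_probability[s]
  # no-reward searches stochastically longer; ROC near the 0.73 calibration
  roc <- roc_area(d[v == 1], d[v == 0])
  expect_gt(roc, 0.68)
  expect_lt(roc, 0.78)
  # durations rise with environment probability within each target value
  for (vv in 0:1) {
    sp <- spearman_perm(p[v == vv], d[v == vv], n_perm = 300, seed = vv)
    expect_gt(sp$rho, 0)
    expect_lt(sp$p, 0.05)
  }
  # the environmental component carries the injected condition effects
  comp <- generate_session(generator_params(n_trials = 5000),
                           seed = 31)$ground_truth$components
  tt <- tr[s, ]; tt$total <- d
  ve <- vapply(c("environmental", "start", "target", "other"),
               function(cn) reward_variance_explained(tt, comp[s, cn]),
               numeric(1))
  expect_gt(ve["environmental"], 85)
  expect_true(all(ve[c("start", "target", "other")] < 30))
  # OLS effects on the environmental component: negative value effect,
  # positive probability effect, larger than for other components
  fe <- fit_reward_effects(tt, comp[s, "environmental"])
  expect_lt(fe$coef_reward, 0)
  expect_gt(fe$coef_preward, 0)
  fs <- fit_reward_effects(tt, comp[s, "start"])
  expect_gt(abs(fe$coef_reward), abs(fs$coef_reward))
  expect_gt(abs(fe$coef_preward), abs(fs$coef_preward))
})

test_that("gaze traces realize the fixation plan recoverably", {
  geo <- task_geometry()
  pars <- generator_params(n_trials = 60)
  ses <- generate_session(pars, seed = 13, gaze = TRUE, geometry = geo)
  tr <- ses$trials
  gt <- ses$ground_truth
  # every planned environmental fixation (>= 50 ms dwell) is recovered
  idx <- which(tr$task == "search" & tr$outcome == "correct" &
                 tr$search_duration > 0.8)
  for (i in idx[seq_len(min(10, length(idx)))]) {
    g <- ses$gaze[ses$gaze$trial_id == i, ]
    cnt <- count_inspected_fractals(g, tr[i, ], geo)
    expect_equal(cnt, gt$n_env_fixations[i])
    cc <- assign_gaze_components(g, tr[i, ], geo)
    # exact partition
    expect_equal(cc$environmental + cc$target + cc$start + cc$other,
                 cc$total)
    expect_equal(cc$total, tr$search_duration[i], tolerance = 2e-3)
    # recovered components near the realized plan (saccadic flights
    # through windows cause bounded contamination)
    rz <- gt$realized_components[i, ]
    expect_lt(abs(cc$environmental - rz$environmental), 0.25)
    expect_lt(abs(cc$start - rz$start), 0.1)
  }
  # byte-identical gaze on regeneration
  ses2 <- generate_session(pars, seed = 13, gaze = TRUE, geometry = geo)
  expect_identical(ses$gaze, ses2$gaze)
})

test_that("scripted fixation plans render as detectable traces", {
  geo <- task_geometry()
  pars <- generator_params(gaze_sd = 0)
  fr <- geo$fractals
  plan <- data.frame(
    x = c(0, fr$x[1], fr$x[6], fr$x[10], geo$targets$x[1]),
    y = c(0, fr$y[1], fr$y[6], fr$y[10], geo$targets$y[1]),
    dwell_ms = c(300, 180, 180, 180, 400))
  trace <- generate_gaze_trace(plan, pars, seed = 3)
  trial <- gaze_trial(0, nrow(trace), target_location = 1L)
  # all four saccades detected, endpoints at the planned centers
  sac <- detect_saccades(trace)
  expect_equal(nrow(sac), 4L)
  expect_lt(max(abs(sac$x_end - plan$x[-1])), 0.61)
  expect_lt(max(abs(sac$y_end - plan$y[-1])), 0.61)
  expect_equal(count_inspected_fractals(trace, trial, geo), 3L)
  # plan without environmental fixations has no environmental gaze
  plan2 <- data.frame(x = c(0, geo$targets$x[1]),
                      y = c(0, geo$targets$y[1]),
                      dwell_ms = c(300, 500))
  trace2 <- generate_gaze_trace(plan2, pars, seed = 3)
  cc2 <- assign_gaze_components(trace2, gaze_trial(0, nrow(trace2)), geo)
  # near zero: the flight to the target may clip an inner-ring window
  expect_lt(cc2$environmental, 0.02)
  expect_error(generate_gaze_trace(data.frame(x = 0, y = 0, dwell_ms = 1),
                                   pars), "at least 2 ms")
})

test_that("direct-saccade ground truth scales with the injected model", {
  pars <- generator_params(n_trials = 4000)
  ses <- generate_session(pars, seed = 17)
  tr <- ses$trials
  direct <- ses$ground_truth$direct
  s <- tr$task == "search"
  # decreasing in environment probability for no-reward targets
  nr <- s & tr$target_value == 0
  frac_by_p <- tapply(direct[nr], tr$reward_probability[nr], mean)
  expect_lt(frac_by_p[length(frac_by_p)], frac_by_p[1])
  # higher for reward than no-reward targets at matched probability
  for (p in c(0.25, 0.5, 0.75)) {
    sel <- s & tr$reward_probability == p
    expect_gt(mean(direct[sel & tr$target_value == 1]),
              mean(direct[sel & tr$target_value == 0]) - 0.05)
  }
  # recovered direct fraction from rendered gaze on a subsample
  geo <- task_geometry()
  small <- generate_session(generator_params(n_trials = 80), seed = 23,
                            gaze = TRUE, geometry = geo)
  st <- small$trials
  idx <- which(st$task == "search" & st$outcome == "correct" &
                 st$search_duration > 0.4)
  hits <- 0L; n_eval <- 0L
  for (i in idx) {
    g <- small$gaze[small$gaze$trial_id == i, ]
    sac <- detect_saccades(g)
    if (nrow(sac) == 0) next
    cls <- classify_initial_saccade(st[i, ], sac, geo)
    if (cls$response == "no_response") next
    n_eval <- n_eval + 1L
    hits <- hits +
      ((cls$response == "direct") == small$ground_truth$direct[i])
  }
  expect_gt(n_eval, 10)
  expect_gt(hits / n_eval, 0.9)
})
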