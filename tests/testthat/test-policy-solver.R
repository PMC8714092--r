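test_that("state enumeration matches the combinatorial count", {
  expect_equal(nrow(enumerate_states(foraging_config())), 25025L)
  # closed form: n_envs * sum_n C(n + K, K)
  cfg <- foraging_config(n_envs = 3, n_objects = 4, p_max = rep(.5, 3),
                         max_size = 2, size_dist = c(.5, .5))
  expect_equal(nrow(enumerate_states(cfg)),
               3 * sum(choose(0:4 + 2, 2)))
  # tiny cases enumerated by hand
  cfg1 <- foraging_config(n_envs = 1, n_objects = 0, p_max = 0.5, tau = 0)
  expect_equal(nrow(enumerate_states(cfg1)), 1L)
  cfg2 <- foraging_config(n_envs = 2, n_objects = 1, p_max = c(.2, .8),
                          max_size = 1, size_dist = 1)
  st <- enumerate_states(cfg2)
  expect_equal(nrow(st), 6L)   # 2 envs x (empty + {0} + {1})
  expect_false(any(duplicated(paste(st$env, st$n_inspected,
                                    sapply(st$revealed, paste,
                                           collapse = ",")))))
})

test_that("consume_value evaluates the discounted-consumption formula", {
  cfg <- foraging_config()
  fresh <- consume_value(cfg, patch_state(1), r_global = 0)
  expect_equal(fresh$value, 0)
  expect_equal(fresh$best_consume_count, 0L)

  one <- consume_value(cfg, patch_state(3, 3L), r_global = 0)
  expect_equal(one$value, 3 * 0.725^(0.5 + 1.25) / 23.75, tolerance = 1e-12)
  expect_equal(one$best_consume_count, 1L)

  # consuming a revealed zero only wastes time
  zero <- consume_value(cfg, patch_state(3, 0L), r_global = 0.2)
  expect_equal(zero$best_consume_count, 0L)

  expect_error(consume_value(cfg, structure(list(env = 1, n_inspected = 2,
                                                 revealed = c(1, 3)),
                                            class = "patch_state"), 0),
               "non-increasing")
})

test_that("inspect_value is the probability-weighted successor value", {
  cfg <- foraging_config()
  s <- patch_state(4, c(2L, 0L))
  # constant successor values collapse to that constant
  expect_equal(inspect_value(cfg, s, function(st) 7), 7)
  # deterministic transition when rewards are impossible
  cfg0 <- foraging_config(p_max = rep(0, 5))
  v <- inspect_value(cfg0, patch_state(1, 0L),
                     function(st) sum(st$revealed == 0) * 1.5)
  expect_equal(v, 3)
  # toy two-object config against a hand-built expectation tree
  tc <- foraging_config(n_envs = 1, n_objects = 2, p_max = 0.6, tau = 1,
                        max_size = 1, size_dist = 1)
  vals <- list("1" = 10, "0" = 2)
  v <- inspect_value(tc, patch_state(1),
                     function(st) vals[[as.character(st$revealed[1])]])
  expect_equal(v, 0.6 * 10 + 0.4 * 2)
  expect_error(inspect_value(cfg, s, function(st) NA), "missing successor")
})

test_that("the DP value table is internally consistent", {
  cfg <- foraging_config()
  res <- optimize_policy(cfg)
  ws <- patchforage:::foraging_workspace(cfg)
  term <- ws$n == cfg$n_objects
  # terminal states always consume; non-terminal v = max of the two values
  expect_true(all(!res$inspect[term]))
  expect_equal(res$v[!term],
               pmax(res$v_inspect[!term], res$v_consume[!term]))
  expect_true(all(res$inspect[!term] ==
                    (res$v_inspect[!term] > res$v_consume[!term])))
  # per-state consume_value agrees with the vectorized table on a sample
  set.seed(42)
  for (id in sample(ws$n_states, 25)) {
    cv <- consume_value(cfg, patch_state(ws$env[id], ws$revealed[[id]]),
                        res$r_global)
    expect_equal(cv$value, res$v_consume[id], tolerance = 1e-10)
  }
  # value is non-decreasing in any single revealed reward size
  for (id in sample(which(ws$n > 0), 50)) {
    rev <- ws$revealed[[id]]
    j <- which(rev < cfg$max_size)
    if (!length(j)) next
    rev2 <- sort(replace(rev, j[1], rev[j[1]] + 1L), decreasing = TRUE)
    id2 <- patchforage:::ws_state_id(
      ws, ws$env[id], ws$n[id],
      tabulate(rev2 + 1L, nbins = cfg$max_size + 1L))
    expect_gte(res$v[id2], res$v[id] - 1e-12)
  }
})

test_that("rate iteration converges and is self-consistent at the fixed point", {
  cfg <- foraging_config()
  res <- optimize_policy(cfg, max_iter = 40, tol = 1e-6)
  expect_true(res$converged)
  expect_lte(res$iterations_used, 40)
  h <- res$rate_history
  expect_lt(abs(h[length(h)] - h[length(h) - 1]), 1e-6)
  # re-evaluating the returned policy reproduces r_global
  expect_equal(evaluate_global_rate(cfg, res), res$r_global,
               tolerance = 1e-9)
  # mean fresh-patch value equals the global rate (renewal consistency)
  ws <- patchforage:::foraging_workspace(cfg)
  expect_equal(mean(res$v[ws$level_ids[[1]]]), res$r_global,
               tolerance = 1e-9)

  # rewardless world: zero rate after one iteration
  cfg0 <- foraging_config(p_max = rep(0, 5))
  res0 <- optimize_policy(cfg0)
  expect_equal(res0$r_global, 0)
  expect_lte(res0$iterations_used, 2)
})

test_that("trivial policies evaluate to the expected rates", {
  cfg <- foraging_config()
  ws <- patchforage:::foraging_workspace(cfg)
  # consume immediately everywhere: no reward, time = t_travel, rate 0
  pol <- list(inspect = rep(FALSE, ws$n_states),
              consume_count = rep(0L, ws$n_states))
  expect_equal(evaluate_global_rate(cfg, pol), 0)
  # any policy in a rewardless world earns 0
  cfg0 <- foraging_config(p_max = rep(0, 5))
  res0 <- solve_dp(cfg0, r_global = 0)
  expect_equal(evaluate_global_rate(cfg0, res0), 0)
})

test_that("DP matches brute-force policy enumeration on toy worlds", {
  for (cfg in list(
    toy_config(n_envs = 1L, n_objects = 3L, p_max = 0.7, tau = 0.8),
    toy_config(n_envs = 2L, n_objects = 2L, p_max = c(0.3, 0.8)),
    toy_config(n_envs = 2L, n_objects = 2L, p_max = c(0.1, 0.9),
               tau = 0, t_travel = 2))) {
    res <- optimize_policy(cfg, tol = 1e-10)
    oracle <- brute_force_best_rate(cfg)
    expect_equal(res$r_global, oracle, tolerance = 1e-7)
  }
})

test_that("exact rate evaluation matches Monte-Carlo simulation", {
  cfg <- toy_config(n_envs = 2L, n_objects = 3L, p_max = c(0.3, 0.8),
                    max_size = 2L)
  res <- optimize_policy(cfg)
  n_sim <- 20000L
  set.seed(99)
  rew <- numeric(n_sim); tim <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    tr <- simulate_patch(cfg, res)
    rew[i] <- tr$reward; tim[i] <- tr$duration
  }
  rate_mc <- sum(rew) / sum(tim)
  # delta-method SE of the ratio estimator
  mr <- mean(rew); mt <- mean(tim)
  se <- sqrt(stats::var(rew - (mr / mt) * tim) / n_sim) / mt
  expect_lt(abs(rate_mc - res$r_global), 3 * se + 1e-9)
})

test_that("restricted policies order by information content", {
  cfg <- foraging_config()
  rates <- vapply(paste0("P", 1:4), function(p)
    optimize_policy(cfg, policy_features(p))$r_global, numeric(1))
  expect_gte(rates["P4"], rates["P3"] - 1e-12)
  expect_gte(rates["P3"], rates["P1"] - 1e-12)
  expect_gte(rates["P4"], rates["P2"] - 1e-12)
  expect_gte(rates["P2"], rates["P1"] - 1e-12)
})

test_that("thresholds separate the optimal policy exactly and rank by richness", {
  cfg <- foraging_config()
  res <- optimize_policy(cfg)
  thr <- extract_thresholds(cfg, res)     # errors if not separable
  ex <- thr[thr$kind == "exact", ]
  expect_gt(nrow(ex), 0)
  # at fixed n_inspected, richer environments have higher thresholds
  for (n in unique(ex$n_inspected)) {
    sl <- thr[thr$n_inspected == n, ]
    if (nrow(sl) == 5)
      expect_true(all(diff(sl$threshold[order(sl$env)]) > -1e-12))
  }
  # thresholds non-increasing with inspections within each environment
  for (e in 1:5) {
    sl <- ex[ex$env == e, ]
    if (nrow(sl) > 1)
      expect_true(all(diff(sl$threshold[order(sl$n_inspected)]) < 1e-9))
  }
  # null model: environments indistinguishable, thresholds identical
  cfgE <- environment_variants("E")
  resE <- optimize_policy(cfgE)
  thrE <- extract_thresholds(cfgE, resE)
  for (n in unique(thrE$n_inspected)) {
    sl <- thrE[thrE$n_inspected == n, ]
    expect_lt(max(sl$threshold) - min(sl$threshold), 1e-12)
  }
})

test_that("beliefs follow exact Bayesian updating", {
  cfg <- foraging_config()
  expect_equal(belief_posterior(cfg, 0, integer(0))$posterior, rep(0.2, 5))
  post1 <- belief_posterior(cfg, 1, 3L)$posterior
  expect_equal(post1, c(0.1, 0.3, 0.5, 0.7, 0.9) / 2.5)
  post0 <- belief_posterior(cfg, 1, 0L)$posterior
  expect_equal(post0, c(0.9, 0.7, 0.5, 0.3, 0.1) / 2.5)
  expect_equal(sum(belief_posterior(cfg, 4, c(5, 2, 0, 0))$posterior), 1)
  # impossible evidence
  cfg100 <- foraging_config(p_max = rep(1, 5), tau = 0)
  expect_error(belief_posterior(cfg100, 1, 0L), "zero likelihood")
})

test_that("solver results serialize to CSV and JSON", {
  cfg <- toy_config()
  res <- optimize_policy(cfg)
  dir <- file.path(tempdir(), "solved")
  paths <- write_solver_result(cfg, res, dir)
  st <- utils::read.csv(paths["states"])
  expect_equal(nrow(st), nrow(enumerate_states(cfg)))
  js <- jsonlite::read_json(paths["solution"], simplifyVector = TRUE)
  expect_equal(js$r_global, res$r_global, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
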