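# Shared small fixtures. Toy configurations keep the state space tiny so
# brute-force oracles stay exact and fast.

toy_config <- function(n_envs = 2L, n_objects = 2L,
                       p_max = c(0.3, 0.8), tau = 0.5,
                       max_size = 1L, ...) {
  foraging_config(n_envs = n_envs, n_objects = n_objects, p_max = p_max,
                  tau = tau, max_size = max_size,
                  size_dist = rep(1 / max_size, max_size), ...)
}

# A scripted gaze trace: exact 1-ms dwells at given centers with
# instantaneous jumps between them (no flight samples). Useful when a test
# needs millisecond-exact window dwell times.
scripted_trace <- function(centers, dwell_ms, t0 = 0) {
  stopifnot(nrow(centers) == length(dwell_ms))
  xs <- rep(centers[, 1], dwell_ms)
  ys <- rep(centers[, 2], dwell_ms)
  data.frame(t_ms = t0 + seq_along(xs) - 1, x_deg = xs, y_deg = ys,
             valid = TRUE)
}

# Minimal one-row trial table for gaze-level operations.
gaze_trial <- function(search_start_ms, search_end_ms, target_location = 1L) {
  data.frame(session = 1L, trial_id = 1L, task = "search", env = 3L,
             reward_probability = 0.5, target_value = 1L,
             target_location = target_location,
             search_start_ms = search_start_ms,
             search_end_ms = search_end_ms, outcome = "correct",
             repeat_flag = FALSE,
             search_duration = (search_end_ms - search_start_ms) / 1000,
             post_array_time = 3)
}

# Exhaustive-enumeration oracle for tiny configurations: maximises
# E[discounted reward] / E[patch time] over all deterministic full-state
# policies, evaluating each policy exactly over the complete outcome tree.
# Per-environment policies are enumerated independently and combined via
# the ratio of summed expectations.
brute_force_best_rate <- function(config) {
  N <- config$n_objects; K <- config$max_size
  k <- config$k; ti <- config$t_inspect; tc <- config$t_consume
  tt <- config$t_travel

  # states within one env: list of revealed vectors (sorted desc) per level
  states_by_level <- lapply(0:N, function(n) {
    M <- patchforage:::multiset_counts(n, K)
    lapply(seq_len(nrow(M)), function(r) patchforage:::counts_to_desc(M[r, ]))
  })
  state_key <- function(n, rev) paste(n, paste(rev, collapse = ","))

  # all action options per state: 0 = inspect, i+1 = consume i rewards
  env_policies <- function(e) {
    keys <- list(); opts <- list()
    for (n in 0:N) for (rev in states_by_level[[n + 1]]) {
      keys[[length(keys) + 1]] <- state_key(n, rev)
      o <- 1:(n + 1)                      # consume 0..n
      if (n < N) o <- c(0, o)             # or inspect
      opts[[length(opts) + 1]] <- o
    }
    list(keys = unlist(keys), opts = opts)
  }

  # exact E[reward], E[time] for one env policy by outcome-tree recursion
  eval_env_policy <- function(e, action_of) {
    recur <- function(n, rev) {
      a <- action_of[[state_key(n, rev)]]
      if (a > 0) {                        # consume a-1 rewards
        i <- a - 1
        rew <- if (i > 0)
          sum(rev[seq_len(i)] * (1 - k)^(n * ti + seq_len(i) * tc))
        else 0
        return(c(rew, n * ti + i * tc + tt))
      }
      p <- object_reward_probability(config, e, n + 1)
      out <- c(0, 0)
      for (v in 0:K) {
        pr <- if (v == 0) 1 - p else p * config$size_dist[e, v]
        if (pr > 0)
          out <- out + pr * recur(n + 1, sort(c(rev, v), decreasing = TRUE))
      }
      out
    }
    recur(0, integer(0))
  }

  per_env <- lapply(seq_len(config$n_envs), function(e) {
    ep <- env_policies(e)
    combos <- expand.grid(lapply(ep$opts, identity))
    vals <- matrix(0, nrow(combos), 2)
    for (r in seq_len(nrow(combos))) {
      action_of <- as.list(unlist(combos[r, ]))
      names(action_of) <- ep$keys
      vals[r, ] <- eval_env_policy(e, action_of)
    }
    vals
  })

  # combine per-env choices: rate = sum ER_e / sum ET_e, max over product
  if (config$n_envs == 1L) {
    v <- per_env[[1]]
    return(max(v[, 1] / v[, 2]))
  }
  if (config$n_envs == 2L) {
    er <- outer(per_env[[1]][, 1], per_env[[2]][, 1], `+`)
    et <- outer(per_env[[1]][, 2], per_env[[2]][, 2], `+`)
    return(max(er / et))
  }
  stop("oracle supports at most 2 environments")
}
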