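#' Simulate one patch visit under a solved policy
#'
#' Draws inspection outcomes from the model's transition distribution,
#' follows the policy's inspect/consume decisions, consumes the chosen
#' number of revealed rewards one by one in descending size order (each
#' discounted by the elapsed time at its consumption), and travels to the
#' next patch.
#'
#' @param config A [foraging_config()].
#' @param policy A [optimize_policy()] result (or any per-state
#'   `inspect`/`consume_count` pair over the full state space).
#' @param seed Optional integer seed for reproducibility.
#' @param env Optional environment index; drawn uniformly when `NULL`.
#' @return An object of class `"trial_trajectory"`: the environment, a step
#'   table (action, object index, revealed size, elapsed seconds), a
#'   consumption table with discounted values, total duration (including
#'   travel) and total discounted reward.
#' @export
simulate_patch <- function(config, policy, seed = NULL, env = NULL) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("`seed` must be a single number")
    set.seed(as.integer(seed))
  }
  ws <- foraging_workspace(config)
  if (length(policy$inspect) != ws$n_states)
    stop("policy does not cover this configuration's state space")
  if (is.null(env)) env <- sample.int(config$n_envs, 1L)
  K <- config$max_size
  counts <- integer(K + 1L)
  n <- 0L
  elapsed <- 0
  steps <- list()
  repeat {
    id <- ws_state_id(ws, env, n, counts)
    if (n >= config$n_objects || !policy$inspect[id]) {
      n_consume <- policy$consume_count[id]
      break
    }
    p <- object_reward_probability(config, env, n + 1L)
    v <- if (stats::runif(1) < p) {
      sample.int(K, 1L, prob = config$size_dist[env, ])
    } else 0L
    elapsed <- elapsed + config$t_inspect
    steps[[length(steps) + 1L]] <-
      data.frame(action = "inspect", object = n + 1L, revealed = v,
                 t_elapsed = elapsed)
    counts[v + 1L] <- counts[v + 1L] + 1L
    n <- n + 1L
  }
  desc <- counts_to_desc(counts)
  consumed <- data.frame(size = integer(0), t_delay = numeric(0),
                         value = numeric(0))
  if (n_consume > 0) {
    sizes <- desc[seq_len(n_consume)]
    t_delay <- n * config$t_inspect + seq_len(n_consume) * config$t_consume
    consumed <- data.frame(size = sizes, t_delay = t_delay,
                           value = discounted_reward(sizes, t_delay, config$k))
  }
  duration <- n * config$t_inspect + n_consume * config$t_consume +
    config$t_travel
  structure(list(env = env,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(action = character(0),
                                         object = integer(0),
                                         revealed = integer(0),
                                         t_elapsed = numeric(0)),
                 consumed = consumed,
                 n_inspected = n, n_consumed = as.integer(n_consume),
                 reward = sum(consumed$value), duration = duration),
            class = "trial_trajectory")
}

#' Visual-search-style probe of a solved policy
#'
#' Mimics the structure of the search task inside the foraging model: the
#' first inspected object (the "target") reveals either a mid-sized reward
#' (`reward_size`, default 3) or nothing, and every later inspection reveals
#' nothing. Outcomes are forced (not sampled), so the probe is
#' deterministic: for each environment and condition it reports how many
#' objects the policy inspects before consuming. The first object is always
#' inspected.
#'
#' @param config A [foraging_config()].
#' @param policy A [optimize_policy()] result.
#' @param reward_size Forced reward size of the target in the reward
#'   condition. Defaults to 3 (the median of the 1-5 size range), capped at
#'   the configuration's `max_size`.
#' @return A data frame with columns `env`, `condition`
#'   (`"reward"`/`"no_reward"`) and `n_inspected`.
#' @export
search_task_probe <- function(config, policy, reward_size = NULL) {
  ws <- foraging_workspace(config)
  if (length(policy$inspect) != ws$n_states)
    stop("policy does not cover this configuration's state space")
  if (is.null(reward_size)) reward_size <- min(3L, config$max_size)
  reward_size <- as.integer(reward_size)
  stopifnot(reward_size >= 1L, reward_size <= config$max_size)
  K <- config$max_size
  grid <- expand.grid(env = seq_len(config$n_envs),
                      condition = c("reward", "no_reward"),
                      stringsAsFactors = FALSE)
  grid$n_inspected <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    env <- grid$env[r]
    counts <- integer(K + 1L)
    # the target object is always inspected
    first <- if (grid$condition[r] == "reward") reward_size else 0L
    counts[first + 1L] <- 1L
    n <- 1L
    while (n < config$n_objects) {
      id <- ws_state_id(ws, env, n, counts)
      if (!policy$inspect[id]) break
      counts[1L] <- counts[1L] + 1L        # forced: later objects reveal 0
      n <- n + 1L
    }
    grid$n_inspected[r] <- n
  }
  grid
}

#' Preset model configurations for rich-versus-poor environments
#'
#' Returns the named variants of the foraging world that differ in *how*
#' environments are rich versus poor:
#'
#' * `"A"` (reference, also `"modelA"`): richness via the best object's
#'   reward probability, `p_max = (0.1, 0.3, 0.5, 0.7, 0.9)`, common decay
#'   `tau = 0.7`, uniform reward sizes 1-5.
#' * `"B"`: common `p_max = 0.9`; richness via the decay rate, richer
#'   environments decaying more slowly.
#' * `"C1"`: common exponentially decaying reward probabilities; richness via
#'   reward-size distributions tilted toward large sizes.
#' * `"C2"`: as C1 but with a constant (rank-independent) reward
#'   probability.
#' * `"D"`: all three manipulations combined, each spanning one third of its
#'   original extent.
#' * `"E"`: null model; environments identical, every object with the same
#'   reward probability and a fixed reward size.
#'
#' Variants B-D involve numeric choices that are not pinned down by the
#' reference analysis; the values here are documented provisional choices
#' and can be edited freely via [foraging_config()]. The same presets ship
#' as YAML files under `system.file("extdata", package = "patchforage")`
#' for use with [read_foraging_config()].
#'
#' @param model_id One of `"A"`, `"B"`, `"C1"`, `"C2"`, `"D"`, `"E"`
#'   (optionally prefixed `"model"`).
#' @return A [foraging_config()].
#' @export
environment_variants <- function(model_id) {
  id <- sub("^model", "", as.character(model_id))
  tilt <- function(beta) {
    w <- exp(beta * ((1:5) - 3))
    w / sum(w)
  }
  switch(
    id,
    A = foraging_config(),
    B = foraging_config(p_max = rep(0.9, 5),
                        tau = 0.7 * 2^(2:-2)),
    C1 = foraging_config(p_max = rep(0.5, 5), tau = 0.7,
                         size_dist = t(vapply(c(-0.8, -0.4, 0, 0.4, 0.8),
                                              tilt, numeric(5)))),
    C2 = foraging_config(p_max = rep(0.2, 5), tau = 0,
                         size_dist = t(vapply(c(-1, -0.5, 0, 0.5, 1),
                                              tilt, numeric(5)))),
    D = foraging_config(p_max = 0.5 + (-2:2) * (0.8 / 3) / 4,
                        tau = 0.7 * 2^((2:-2) / 3),
                        size_dist = t(vapply(c(-0.8, -0.4, 0, 0.4, 0.8) / 3,
                                             tilt, numeric(5)))),
    E = foraging_config(p_max = rep(0.5, 5), tau = 0,
                        size_dist = c(0, 0, 1, 0, 0)),
    stop("unknown model id '", model_id,
         "'; valid ids: A, B, C1, C2, D, E"))
}
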