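#' Configuration of the object-inspection foraging world
#'
#' Builds a validated description of a model world in which an agent enters a
#' patch drawn uniformly from `n_envs` environments, may sequentially inspect
#' up to `n_objects` objects (best first) to reveal their probabilistic
#' rewards, and then consumes a chosen number of the revealed rewards in
#' descending size order before travelling to a new patch.
#'
#' Object `i` (1-based) of environment `env` yields a reward with probability
#' `p_max[env] * 2^(-tau[env] * (i - 1))`; when a reward occurs its integer
#' size is drawn from `size_dist[env, ]` over sizes `1..max_size`, and a
#' failed inspection reveals size 0. A reward of size `r` consumed after a
#' delay of `t` seconds from patch entry is worth `r * (1 - k)^t`.
#'
#' @param n_envs Number of environments (patch types). Default 5.
#' @param n_objects Objects per patch. Default 9.
#' @param p_max Numeric vector (length `n_envs`) of reward probabilities for
#'   the best object of each environment. Default `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param tau Per-environment exponential decay rate of reward probability
#'   with object rank. Scalar values are recycled. Default 0.7.
#' @param size_dist Either a probability vector over reward sizes
#'   `1..max_size` shared by all environments, or an `n_envs x max_size`
#'   matrix with one row per environment. Default uniform over `1..5`.
#' @param max_size Largest reward size. Default 5.
#' @param t_inspect Seconds spent per inspection. Default 0.5.
#' @param t_consume Seconds spent per act of consumption. Default 1.25.
#' @param t_travel Seconds spent travelling between patches. Default 8.
#' @param k Temporal discount rate per second, strictly in (0, 1).
#'   Default 0.275, i.e. a reward loses half its value in ~2.2 s.
#' @param T_max Normalization horizon in seconds for state-action values.
#'   Defaults to `n_objects * (t_inspect + t_consume) + t_travel`, the longest
#'   possible single patch visit.
#'
#' @return An object of class `"foraging_config"` (a validated list).
#' @seealso [object_reward_probability()], [discounted_reward()],
#'   [enumerate_states()], [optimize_policy()], [environment_variants()]
#' @examples
#' cfg <- foraging_config()
#' cfg$T_max                          # 23.75
#' object_reward_probability(cfg, 5, 1)  # 0.9
#' @export
foraging_config <- function(n_envs = 5L,
                            n_objects = 9L,
                            p_max = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            tau = 0.7,
                            size_dist = NULL,
                            max_size = 5L,
                            t_inspect = 0.5,
                            t_consume = 1.25,
                            t_travel = 8,
                            k = 0.275,
                            T_max = NULL) {
  n_envs <- as.integer(n_envs)
  n_objects <- as.integer(n_objects)
  max_size <- as.integer(max_size)
  stopifnot(n_envs >= 1L, n_objects >= 0L, max_size >= 1L)
  if (length(p_max) == 1L) p_max <- rep(p_max, n_envs)
  if (length(tau) == 1L) tau <- rep(tau, n_envs)
  if (length(p_max) != n_envs)
    stop("`p_max` must have length n_envs (", n_envs, ")")
  if (length(tau) != n_envs)
    stop("`tau` must have length n_envs (", n_envs, ")")
  if (any(p_max < 0) || any(p_max > 1))
    stop("all reward probabilities must lie in [0, 1]")
  if (any(tau < 0)) stop("`tau` must be non-negative")

  if (is.null(size_dist)) size_dist <- rep(1 / max_size, max_size)
  if (is.vector(size_dist))
    size_dist <- matrix(size_dist, n_envs, length(size_dist), byrow = TRUE)
  size_dist <- as.matrix(size_dist)
  if (nrow(size_dist) != n_envs || ncol(size_dist) != max_size)
    stop("`size_dist` must be n_envs x max_size")
  if (any(size_dist < 0))
    stop("`size_dist` entries must be non-negative")
  if (any(abs(rowSums(size_dist) - 1) > 1e-6))
    stop("each row of `size_dist` must sum to 1")
  size_dist <- size_dist / rowSums(size_dist)

  for (nm in c("t_inspect", "t_consume", "t_travel")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 1)
    stop("`k` must lie strictly in (0, 1)")

  default_T_max <- n_objects * (t_inspect + t_consume) + t_travel
  if (is.null(T_max)) T_max <- default_T_max
  if (T_max <= 0) stop("`T_max` must be positive")

  structure(
    list(n_envs = n_envs, n_objects = n_objects, p_max = as.numeric(p_max),
         tau = as.numeric(tau), size_dist = unname(size_dist),
         max_size = max_size, t_inspect = t_inspect, t_consume = t_consume,
         t_travel = t_travel, k = k, T_max = T_max),
    class = "foraging_config")
}

#' @export
print.foraging_config <- function(x, ...) {
  cat("<foraging_config>\n")
  cat(sprintf("  %d environments x %d objects, reward sizes 1..%d (+0)\n",
              x$n_envs, x$n_objects, x$max_size))
  cat("  p_max:", paste(signif(x$p_max, 3), collapse = " "), "\n")
  cat("  tau:  ", paste(signif(x$tau, 3), collapse = " "), "\n")
  cat(sprintf("  t_inspect %.3g s, t_consume %.3g s, t_travel %.3g s\n",
              x$t_inspect, x$t_consume, x$t_travel))
  cat(sprintf("  discount k = %.3g /s, horizon T_max = %.4g s\n", x$k, x$T_max))
  invisible(x)
}

#' Reward probability of an object
#'
#' Probability that object `i` (ranked best to worst, 1-based) of environment
#' `env` yields a reward: `p_max[env] * 2^(-tau[env] * (i - 1))`.
#'
#' @param config A [foraging_config()].
#' @param env Environment index in `1..n_envs`.
#' @param i Object index in `1..n_objects` (vectorized).
#' @return Numeric vector of probabilities.
#' @export
object_reward_probability <- function(config, env, i) {
  stopifnot(inherits(config, "foraging_config"))
  if (any(env < 1L) || any(env > config$n_envs))
    stop("`env` out of range 1..", config$n_envs)
  if (any(i < 1L) || any(i > config$n_objects))
    stop("`i` out of range 1..", config$n_objects)
  config$p_max[env] * 2^(-config$tau[env] * (i - 1))
}

#' Temporally discounted reward value
#'
#' Value of a reward of size `r` consumed `t_delay` seconds after patch
#' entry: `r * (1 - k)^t_delay`.
#'
#' @param r Reward size(s), non-negative.
#' @param t_delay Delay(s) in seconds, non-negative.
#' @param k Discount rate per second in (0, 1).
#' @return Discounted value(s).
#' @examples
#' discounted_reward(3, 0, 0.275)     # 3: no delay, no loss
#' log(0.5) / log(1 - 0.275)          # ~2.2 s half-value delay
#' @export
discounted_reward <- function(r, t_delay, k) {
  if (any(r < 0)) stop("`r` must be non-negative")
  if (any(t_delay < 0)) stop("`t_delay` must be non-negative")
  if (any(k <= 0) || any(k >= 1)) stop("`k` must lie in (0, 1)")
  r * (1 - k)^t_delay
}

#' Read or write a foraging configuration file
#'
#' Configurations serialize to YAML or JSON with keys matching the
#' [foraging_config()] fields (chosen by file extension; `.yml`/`.yaml` or
#' `.json`).
#'
#' @param path File path.
#' @param config A [foraging_config()] (for writing).
#' @return `read_foraging_config()` returns a validated [foraging_config()];
#'   `write_foraging_config()` returns `path` invisibly.
#' @export
read_foraging_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$size_dist) && is.list(raw$size_dist))
    raw$size_dist <- do.call(rbind, raw$size_dist)
  keep <- intersect(names(raw), names(formals(foraging_config)))
  do.call(foraging_config, raw[keep])
}

#' @rdname read_foraging_config
#' @export
write_foraging_config <- function(config, path) {
  stopifnot(inherits(config, "foraging_config"))
  out <- unclass(config)
  out$size_dist <- lapply(seq_len(nrow(config$size_dist)),
                          function(e) unname(config$size_dist[e, ]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path, precision = 15L)
  }
  invisible(path)
}
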