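#' A single patch state
#'
#' One state of the object-inspection Markov decision process: the
#' environment identity, the number of objects inspected so far, and the
#' non-increasing multiset of reward sizes revealed by those inspections
#' (zeros record inspections that revealed no reward).
#'
#' @param env Environment index (integer >= 1).
#' @param revealed Integer vector of revealed reward sizes, sorted
#'   non-increasing; its length is the number of inspections so far.
#' @return An object of class `"patch_state"`.
#' @examples
#' patch_state(5, c(4, 3, 0))  # three inspections, two rewards revealed
#' @export
patch_state <- function(env, revealed = integer(0)) {
  env <- as.integer(env)
  revealed <- as.integer(revealed)
  stopifnot(length(env) == 1L, env >= 1L)
  if (any(revealed < 0L)) stop("revealed sizes must be non-negative")
  if (is.unsorted(rev(revealed)))
    stop("`revealed` must be sorted non-increasing")
  structure(list(env = env, n_inspected = length(revealed),
                 revealed = revealed),
            class = "patch_state")
}

#' @export
print.patch_state <- function(x, ...) {
  cat(sprintf("<patch_state> env %d, %d inspected [%s]\n", x$env,
              x$n_inspected, paste(x$revealed, collapse = " ")))
  invisible(x)
}

# All count vectors (c_0, ..., c_k) with sum n, in lexicographic order.
# Rows index the canonical multisets of size n over k+1 distinct values.
multiset_counts <- function(n, k) {
  if (k == 0L) return(matrix(n, 1L, 1L))
  out <- vector("list", n + 1L)
  for (c0 in 0:n) {
    rest <- multiset_counts(n - c0, k - 1L)
    out[[c0 + 1L]] <- cbind(c0, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

counts_key <- function(m) apply(m, 1L, paste, collapse = ",")

# Descending value sequence from a counts row c_0..c_k (values 0..k).
counts_to_desc <- function(counts) {
  k <- length(counts) - 1L
  rep.int(k:0, rev(counts))
}

#' Enumerate the full state space
#'
#' Lists every combination of environment, number of objects inspected
#' (0..`n_objects`), and sorted multiset of revealed reward sizes drawn from
#' `{0, 1, ..., max_size}`. With the default configuration (5 environments,
#' 9 objects, sizes 0-5) this yields 25,025 states. States are ordered by
#' `n_inspected`, then environment, then multiset (lexicographic in the size
#' counts) — a deterministic canonical ordering.
#'
#' @param config A [foraging_config()].
#' @return A data frame with columns `env`, `n_inspected`, and `revealed`
#'   (a list column of non-increasing integer vectors).
#' @examples
#' nrow(enumerate_states(foraging_config()))  # 25025
#' @export
enumerate_states <- function(config) {
  stopifnot(inherits(config, "foraging_config"))
  ws <- foraging_workspace(config)
  data.frame(env = ws$env, n_inspected = ws$n,
             revealed = I(ws$revealed))
}

#' Transition distribution of the inspect action
#'
#' Inspecting the next-best object (index `n_inspected + 1`) reveals its
#' outcome: with probability `p_i` a reward size `m` in `1..max_size` drawn
#' from the environment's size distribution, and with probability `1 - p_i` a
#' zero. The revealed size joins the sorted multiset.
#'
#' @param config A [foraging_config()].
#' @param state A [patch_state()] with `n_inspected < n_objects`.
#' @return A list of `list(state = <patch_state>, prob = <numeric>)` pairs
#'   (at most `max_size + 1`); probabilities sum to 1.
#' @export
transition_distribution <- function(config, state) {
  stopifnot(inherits(config, "foraging_config"),
            inherits(state, "patch_state"))
  if (state$n_inspected >= config$n_objects)
    stop("inspect is illegal in a terminal state (all objects inspected)")
  if (state$env > config$n_envs) stop("state env out of range")
  if (length(state$revealed) && max(state$revealed) > config$max_size)
    stop("revealed sizes exceed max_size")
  p <- object_reward_probability(config, state$env, state$n_inspected + 1L)
  sizes <- 0:config$max_size
  probs <- c(1 - p, p * config$size_dist[state$env, ])
  keep <- probs > 0
  mapply(function(m, pr) {
    list(state = patch_state(state$env,
                             sort(c(state$revealed, m), decreasing = TRUE)),
         prob = pr)
  }, sizes[keep], probs[keep], SIMPLIFY = FALSE)
}
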