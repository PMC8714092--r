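#' Observation model for a foraging policy
#'
#' Declares which components of the patch state a policy may condition on.
#' The number of objects inspected is always observable; the environment
#' identity and the revealed reward multiset can each be hidden, in which
#' case decisions are taken under the exact Bayesian belief over the hidden
#' components (a POMDP restriction of the full problem).
#'
#' Four named policies are conventional:
#' `P1 = {n_inspected}`, `P2 = {env, n_inspected}`,
#' `P3 = {revealed, n_inspected}`, `P4 = {env, revealed, n_inspected}`
#' (the fully observable, overall-optimal case).
#'
#' @param env Can the policy observe the environment identity?
#' @param revealed Can the policy observe the revealed reward sizes?
#' @return An object of class `"observable_spec"`.
#' @examples
#' policy_features("P3")  # revealed rewards visible, environment hidden
#' @export
observable_spec <- function(env = TRUE, revealed = TRUE) {
  stopifnot(is.logical(env), is.logical(revealed))
  structure(list(env = env, revealed = revealed, n_inspected = TRUE),
            class = "observable_spec")
}

#' @rdname observable_spec
#' @param id One of `"P1"`, `"P2"`, `"P3"`, `"P4"`.
#' @export
policy_features <- function(id) {
  switch(as.character(id),
         P1 = observable_spec(env = FALSE, revealed = FALSE),
         P2 = observable_spec(env = TRUE, revealed = FALSE),
         P3 = observable_spec(env = FALSE, revealed = TRUE),
         P4 = observable_spec(env = TRUE, revealed = TRUE),
         stop("unknown policy id '", id, "' (expected P1, P2, P3 or P4)"))
}

# Group states that share an observable signature. Groups never span levels.
# For each level: local group index `lg`, normalized belief weight `w`
# (p(state | signature)), and the level's state ids.
make_groups <- function(ws, observable) {
  stopifnot(inherits(observable, "observable_spec"))
  N <- ws$config$n_objects
  out <- vector("list", N + 1L)
  for (n in 0:N) {
    ids <- ws$level_ids[[n + 1L]]
    sig <- rep(1L, length(ids))
    if (observable$env && observable$revealed) {
      sig <- seq_along(ids)
    } else if (observable$env) {
      sig <- ws$env[ids]
    } else if (observable$revealed) {
      sig <- ws$rank[ids]
    }
    lg <- match(sig, unique(sig))
    wp <- ws$wprior[ids]
    tot <- rowsum(wp, lg)[, 1L]
    w <- wp / tot[lg]
    dead <- !is.finite(w)            # group of probability-zero states
    if (any(dead)) {
      cnt <- rowsum(rep(1, length(lg)), lg)[, 1L]
      w[dead] <- 1 / cnt[lg][dead]
    }
    out[[n + 1L]] <- list(ids = ids, lg = lg, w = w,
                          n_groups = max(lg))
  }
  out
}

# One dynamic-programming sweep given a global reward rate. Backward
# induction over levels; states sharing an observable signature share one
# action and one consumption count, chosen to maximize belief-weighted value.
solve_dp_ws <- function(ws, r_global, groups) {
  cfg <- ws$config
  N <- cfg$n_objects
  Tm <- cfg$T_max
  VC <- (ws$CUM + r_global * (Tm - ws$TIME)) / Tm

  V <- numeric(ws$n_states)
  v_inspect <- rep(NA_real_, ws$n_states)
  v_consume <- numeric(ws$n_states)
  inspect <- logical(ws$n_states)
  consume_count <- integer(ws$n_states)

  for (n in N:0) {
    g <- groups[[n + 1L]]
    ids <- g$ids
    VCl <- VC[ids, seq_len(n + 1L), drop = FALSE]
    # per-state unconstrained consumption value (the MDP V(s, consume))
    ci <- max.col(VCl, ties.method = "first")
    v_consume[ids] <- VCl[cbind(seq_along(ids), ci)]
    # group-level consumption plan: one count per observable signature
    qc <- rowsum(VCl * g$w, g$lg)
    gci <- max.col(qc, ties.method = "first")
    qc_best <- qc[cbind(seq_len(nrow(qc)), gci)]
    vc_pol <- VCl[cbind(seq_along(ids), gci[g$lg])]

    if (n == N) {
      inspect[ids] <- FALSE
      consume_count[ids] <- gci[g$lg] - 1L
      V[ids] <- vc_pol
    } else {
      S <- ws$succ[ids, , drop = FALSE]
      Vs <- matrix(V[S], nrow = length(ids))
      p <- ws$pnext[ids]
      sd <- cfg$size_dist[ws$env[ids], , drop = FALSE]
      vi <- (1 - p) * Vs[, 1L] +
        p * rowSums(Vs[, -1L, drop = FALSE] * sd)
      v_inspect[ids] <- vi
      qi <- rowsum(vi * g$w, g$lg)[, 1L]
      act <- qi > qc_best                      # ties resolve to consume
      inspect[ids] <- act[g$lg]
      consume_count[ids] <- gci[g$lg] - 1L
      V[ids] <- ifelse(act[g$lg], vi, vc_pol)
    }
  }
  list(v = V, v_inspect = v_inspect, v_consume = v_consume,
       inspect = inspect, consume_count = consume_count)
}

# Exact policy evaluation: forward propagation of state probabilities from a
# uniform-random environment entry; returns expected discounted reward per
# patch divided by expected patch time (including travel).
evaluate_rate_ws <- function(ws, inspect, consume_count) {
  cfg <- ws$config
  N <- cfg$n_objects
  prob <- numeric(ws$n_states)
  fresh <- ws$level_ids[[1L]]
  prob[fresh] <- 1 / cfg$n_envs
  ER <- 0; ET <- 0
  for (n in 0:N) {
    ids <- ws$level_ids[[n + 1L]]
    pr <- prob[ids]
    live <- pr > 0
    if (!any(live)) next
    ids <- ids[live]; pr <- pr[live]
    act <- inspect[ids]
    if (any(!act)) {
      cid <- ids[!act]
      i1 <- consume_count[cid] + 1L
      ER <- ER + sum(pr[!act] * ws$CUM[cbind(cid, i1)])
      ET <- ET + sum(pr[!act] * ws$TIME[cbind(cid, i1)])
    }
    if (any(act) && n < N) {
      iid <- ids[act]
      p <- ws$pnext[iid]
      sd <- cfg$size_dist[ws$env[iid], , drop = FALSE]
      mass <- cbind(1 - p, p * sd) * pr[act]
      tgt <- as.vector(ws$succ[iid, , drop = FALSE])
      agg <- rowsum(as.vector(mass), tgt)
      at <- as.integer(rownames(agg))
      prob[at] <- prob[at] + agg[, 1L]
    }
  }
  if (ET <= 0) return(0)
  ER / ET
}

#' Solve the inspect/consume dynamic program for a given global reward rate
#'
#' Backward induction over the number of objects inspected. The value of
#' consuming in state `s` is the time-discounted reward of the `i` largest
#' revealed rewards plus the opportunity value `r_global` of the remaining
#' horizon, maximized over `i` and normalized by the horizon `T_max`; the
#' value of inspecting is the transition-probability-weighted value of the
#' successor states. Under a restricted [observable_spec()], all states
#' sharing an observable signature receive one action and one consumption
#' count, chosen to maximize the belief-weighted value; with full
#' observability this reduces to the per-state argmax.
#'
#' @param config A [foraging_config()].
#' @param r_global Assumed global reward rate (reward per second).
#' @param observable An [observable_spec()]; default full observability.
#' @return A list of per-state vectors in [enumerate_states()] order:
#'   `v` (value under the policy), `v_inspect`, `v_consume` (the
#'   unconstrained consumption value `V(s, consume)`), `inspect` (logical
#'   action; `FALSE` means consume-and-leave) and `consume_count`
#'   (the policy's consumption-count plan).
#' @export
solve_dp <- function(config, r_global,
                     observable = observable_spec()) {
  stopifnot(r_global >= 0)
  ws <- foraging_workspace(config)
  solve_dp_ws(ws, r_global, make_groups(ws, observable))
}

#' Exact global reward rate of a policy
#'
#' Propagates state probabilities forward from a uniform-random environment
#' entry under the policy's actions, and returns the expected discounted
#' reward per patch divided by the expected patch time including travel.
#' No sampling is involved.
#'
#' @param config A [foraging_config()].
#' @param policy A list with per-state `inspect` and `consume_count` vectors
#'   (as returned by [solve_dp()] or found in a [optimize_policy()] result).
#' @return Reward rate in reward units per second.
#' @export
evaluate_global_rate <- function(config, policy) {
  ws <- foraging_workspace(config)
  if (length(policy$inspect) != ws$n_states)
    stop("policy is not defined over the full state space")
  evaluate_rate_ws(ws, policy$inspect, policy$consume_count)
}

#' Optimal policy by iterated reward-rate improvement
#'
#' The value of consuming depends on the global reward rate, which itself
#' depends on the policy. Starting from `r_global = 0`, this alternates
#' (a) solving the dynamic program for the best policy given the current
#' rate with (b) exactly re-evaluating the true global rate of that policy,
#' until the policy is unchanged between iterations and the rate moves by
#' less than `tol`, or `max_iter` iterations are reached. At the fixed point
#' the policy maximizes reward per second among policies measurable with
#' respect to `observable`.
#'
#' @inheritParams solve_dp
#' @param max_iter Maximum number of solve/evaluate iterations. Default 40.
#' @param tol Convergence tolerance on the global reward rate. Default 1e-6.
#' @return An object of class `"solver_result"`: the final value/policy
#'   vectors plus `r_global`, `iterations_used`, `rate_history`, and
#'   `converged`.
#' @examples
#' \donttest{
#' res <- optimize_policy(foraging_config())
#' res$r_global
#' }
#' @export
optimize_policy <- function(config, observable = observable_spec(),
                            max_iter = 40L, tol = 1e-6) {
  stopifnot(max_iter >= 1L, tol > 0)
  ws <- foraging_workspace(config)
  groups <- make_groups(ws, observable)
  r <- 0
  history <- numeric(0)
  prev <- NULL
  converged <- FALSE
  iterations <- max_iter
  for (it in seq_len(max_iter)) {
    sol <- solve_dp_ws(ws, r, groups)
    r_new <- evaluate_rate_ws(ws, sol$inspect, sol$consume_count)
    history[it] <- r_new
    stable <- !is.null(prev) &&
      identical(prev$inspect, sol$inspect) &&
      identical(prev$consume_count, sol$consume_count)
    if (stable && abs(r_new - r) < tol) {
      converged <- TRUE
      iterations <- it
      r <- r_new
      break
    }
    prev <- sol
    r <- r_new
  }
  structure(
    list(config = config, observable = observable,
         v = sol$v, v_inspect = sol$v_inspect, v_consume = sol$v_consume,
         inspect = sol$inspect, consume_count = sol$consume_count,
         r_global = r, iterations_used = iterations,
         rate_history = history, converged = converged),
    class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  feat <- c("n_inspected",
            if (x$observable$env) "env",
            if (x$observable$revealed) "revealed")
  cat("<solver_result>\n")
  cat("  observables:", paste(feat, collapse = ", "), "\n")
  cat(sprintf("  r_global = %.6g reward/s after %d iteration(s)%s\n",
              x$r_global, x$iterations_used,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Consumption-value decision thresholds
#'
#' For each (environment, number inspected) slice of the state space, finds
#' the consumption value `V(s, consume)` that exactly separates states where
#' the policy inspects (below) from states where it consumes (above). Errors
#' if any slice is not threshold-separable.
#'
#' @param config A [foraging_config()].
#' @param result A [optimize_policy()] result.
#' @param tol Absolute tolerance for the separability check. Default 1e-12.
#' @return A data frame (`"threshold_curve"`) with columns `env`,
#'   `n_inspected`, `threshold`, and `kind` (`"exact"` when both actions
#'   occur in the slice; `"lower"`/`"upper"` boundary values when the slice
#'   is all-inspect/all-consume).
#' @export
extract_thresholds <- function(config, result, tol = 1e-12) {
  stopifnot(inherits(result, "solver_result"))
  ws <- foraging_workspace(config)
  if (length(result$inspect) != ws$n_states)
    stop("result does not match this configuration's state space")
  rows <- list()
  for (e in seq_len(config$n_envs)) {
    for (n in 0:(config$n_objects - 1L)) {
      # restrict to reachable states: actions on probability-zero states
      # (revealed sizes the environment cannot produce) are arbitrary
      sel <- which(ws$env == e & ws$n == n & ws$wprior > 0)
      vc <- result$v_consume[sel]
      ins <- result$inspect[sel]
      if (any(ins) && any(!ins)) {
        lo <- max(vc[ins]); hi <- min(vc[!ins])
        if (lo - hi > tol)
          stop(sprintf(
            "policy is not threshold-separable at env %d, n_inspected %d",
            e, n))
        thr <- (lo + hi) / 2
        kind <- "exact"
      } else if (all(ins)) {
        thr <- max(vc); kind <- "lower"
      } else {
        thr <- min(vc); kind <- "upper"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(env = e, n_inspected = n, threshold = thr, kind = kind)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_curve", class(out))
  out
}

#' Posterior belief over the environment
#'
#' Exact Bayesian posterior over the environment identity given the number
#' of objects inspected and the sorted multiset of revealed reward sizes,
#' starting from a uniform prior. The likelihood marginalizes over which of
#' the first `n_inspected` objects yielded reward (a Poisson-binomial over
#' the index-dependent reward probabilities) and multiplies the size
#' likelihoods where the size distributions differ between environments.
#'
#' @param config A [foraging_config()].
#' @param n_inspected Number of objects inspected so far.
#' @param evidence Integer vector of revealed reward sizes (order
#'   irrelevant); must have length `n_inspected`.
#' @return An object of class `"belief_state"`: list with `posterior`
#'   (probability vector over environments) and `evidence`.
#' @examples
#' cfg <- foraging_config()
#' belief_posterior(cfg, 0, integer(0))$posterior   # uniform prior
#' belief_posterior(cfg, 1, 3)$posterior            # reward seen: rich likelier
#' @export
belief_posterior <- function(config, n_inspected, evidence) {
  stopifnot(inherits(config, "foraging_config"))
  n_inspected <- as.integer(n_inspected)
  evidence <- as.integer(evidence)
  if (length(evidence) != n_inspected)
    stop("`evidence` must contain one revealed size per inspection")
  if (n_inspected > config$n_objects)
    stop("cannot have inspected more than n_objects objects")
  E <- config$n_envs
  like <- numeric(E)
  nz <- evidence[evidence > 0]
  if (length(nz) && max(nz) > config$max_size)
    stop("evidence contains a size larger than max_size")
  for (e in seq_len(E)) {
    p <- if (n_inspected > 0)
      object_reward_probability(config, e, seq_len(n_inspected))
    else numeric(0)
    pb <- poisson_binomial(p)[length(nz) + 1L]
    like[e] <- pb * prod(config$size_dist[e, nz])
  }
  if (sum(like) == 0)
    stop("evidence has zero likelihood under every environment")
  structure(list(posterior = like / sum(like), evidence = sort(evidence,
                                                               decreasing = TRUE),
                 n_inspected = n_inspected),
            class = "belief_state")
}

#' Value of consuming in a single state
#'
#' Direct evaluation of the consumption value: the best choice of how many
#' of the revealed rewards to consume, each discounted by the elapsed time
#' at its moment of consumption, plus the global-rate value of the remaining
#' horizon, normalized by `T_max`.
#'
#' @param config A [foraging_config()].
#' @param state A [patch_state()] (revealed sorted non-increasing).
#' @param r_global Global reward rate used as the opportunity cost.
#' @return List with `value` (reward/s) and `best_consume_count`.
#' @export
consume_value <- function(config, state, r_global) {
  stopifnot(inherits(state, "patch_state"), r_global >= 0)
  if (is.unsorted(rev(state$revealed)))
    stop("`revealed` must be sorted non-increasing")
  n <- state$n_inspected
  k <- config$k; ti <- config$t_inspect; tc <- config$t_consume
  i <- 0:n
  cum <- c(0, cumsum(state$revealed * (1 - k)^(n * ti + seq_len(n) * tc)))
  used <- n * ti + i * tc + config$t_travel
  val <- (cum + r_global * (config$T_max - used)) / config$T_max
  best <- which.max(val)
  list(value = val[best], best_consume_count = i[best])
}

#' Value of inspecting in a single state
#'
#' Probability-weighted average of successor-state values under the inspect
#' action.
#'
#' @param config A [foraging_config()].
#' @param state A non-terminal [patch_state()].
#' @param value_lookup Function mapping a [patch_state()] to its value.
#' @return The expected successor value.
#' @export
inspect_value <- function(config, state, value_lookup) {
  succ <- transition_distribution(config, state)
  sum(vapply(succ, function(sp) {
    v <- value_lookup(sp$state)
    if (is.null(v) || is.na(v)) stop("missing successor value")
    sp$prob * v
  }, numeric(1)))
}
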