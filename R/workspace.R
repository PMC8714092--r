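# Internal precomputed state-space tables shared by the solver, the rate
# evaluator and the simulators. States are ordered by n_inspected (level),
# then environment, then multiset (lexicographic in size counts); this is the
# same canonical ordering exposed by enumerate_states().

.ws_cache <- new.env(parent = emptyenv())

foraging_workspace <- function(config) {
  stopifnot(inherits(config, "foraging_config"))
  for (ent in as.list(.ws_cache)) {
    if (identical(ent$config, config)) return(ent$ws)
  }
  ws <- build_workspace(config)
  key <- sprintf("c%d", length(ls(.ws_cache)) %% 8L)
  assign(key, list(config = config, ws = ws), envir = .ws_cache)
  ws
}

# Poisson-binomial pmf over the number of successes among independent
# Bernoulli trials with probabilities p (returns length(p)+1 vector).
poisson_binomial <- function(p) {
  d <- 1
  for (pi in p) d <- c(d * (1 - pi), 0) + c(0, d * pi)
  d
}

build_workspace <- function(config) {
  E <- config$n_envs; N <- config$n_objects; K <- config$max_size
  ti <- config$t_inspect; tc <- config$t_consume; tt <- config$t_travel
  k <- config$k

  lev <- vector("list", N + 1L)       # per-level multiset counts
  rank_lookup <- vector("list", N + 1L)
  m_level <- integer(N + 1L)
  for (n in 0:N) {
    M <- multiset_counts(n, K)
    lev[[n + 1L]] <- M
    m_level[n + 1L] <- nrow(M)
    r <- seq_len(nrow(M))
    names(r) <- counts_key(M)
    rank_lookup[[n + 1L]] <- r
  }
  offset <- c(0L, cumsum(E * m_level))[seq_len(N + 1L)]
  n_states <- sum(E * m_level)

  env <- integer(n_states); nvec <- integer(n_states)
  rank <- integer(n_states)
  counts <- matrix(0L, n_states, K + 1L)
  for (n in 0:N) {
    m <- m_level[n + 1L]
    ids <- offset[n + 1L] + seq_len(E * m)
    env[ids] <- rep(1:E, each = m)
    nvec[ids] <- n
    rank[ids] <- rep(seq_len(m), E)
    counts[ids, ] <- lev[[n + 1L]][rep(seq_len(m), E), , drop = FALSE]
  }

  # successor ids for the inspect action (adding size 0..K); NA at level N
  succ <- matrix(NA_integer_, n_states, K + 1L)
  for (n in seq_len(N) - 1L) {
    M <- lev[[n + 1L]]; m <- m_level[n + 1L]
    nxt_rank <- matrix(0L, m, K + 1L)
    for (v in 0:K) {
      M2 <- M
      M2[, v + 1L] <- M2[, v + 1L] + 1L
      nxt_rank[, v + 1L] <- unname(rank_lookup[[n + 2L]][counts_key(M2)])
    }
    m2 <- m_level[n + 2L]
    for (e in 1:E) {
      ids <- offset[n + 1L] + (e - 1L) * m + seq_len(m)
      succ[ids, ] <- offset[n + 2L] + (e - 1L) * m2 + nxt_rank
    }
  }

  # cumulative discounted consumption sums CUM[s, i+1] (i rewards consumed)
  # and elapsed patch time TIME[s, i+1]; NA where i > n_inspected
  CUM <- matrix(NA_real_, n_states, N + 1L)
  TIME <- matrix(NA_real_, n_states, N + 1L)
  dfac <- (1 - k)^(seq_len(N) * tc)
  for (n in 0:N) {
    M <- lev[[n + 1L]]; m <- m_level[n + 1L]
    cb <- matrix(NA_real_, m, N + 1L)
    cb[, 1L] <- 0
    if (n > 0) {
      desc <- matrix(0L, m, n)                    # m x n, descending values
      for (r in seq_len(m)) desc[r, ] <- counts_to_desc(M[r, ])
      cs <- sweep(desc, 2L, dfac[seq_len(n)], `*`)
      if (n > 1L) for (j in 2:n) cs[, j] <- cs[, j - 1L] + cs[, j]
      cb[, 1L + seq_len(n)] <- cs
    }
    cb <- cb * (1 - k)^(n * ti)
    ids <- offset[n + 1L] + seq_len(E * m)
    CUM[ids, ] <- cb[rep(seq_len(m), E), , drop = FALSE]
    TIME[ids, seq_len(n + 1L)] <- rep(n * ti + (0:n) * tc + tt,
                                      each = length(ids))
  }

  # reward probability of the next object to inspect (NA at level N)
  pnext <- rep(NA_real_, n_states)
  ok <- nvec < N
  pnext[ok] <- object_reward_probability(config, env[ok], nvec[ok] + 1L)

  # p(multiset | env, n): Poisson-binomial over which of the first n objects
  # rewarded, times a multinomial size likelihood
  nnz <- nvec - counts[, 1L]
  log_multinom <- lgamma(nnz + 1) -
    rowSums(lgamma(counts[, -1L, drop = FALSE] + 1))
  wprior <- numeric(n_states)
  for (e in 1:E) {
    pb <- vector("list", N + 1L)
    pall <- if (N > 0) object_reward_probability(config, e, 1:N) else numeric(0)
    for (n in 0:N) pb[[n + 1L]] <- poisson_binomial(pall[seq_len(n)])
    sel <- env == e
    sd_e <- config$size_dist[e, ]
    lsize <- counts[sel, -1L, drop = FALSE] %*%
      log(pmax(sd_e, .Machine$double.xmin))
    pbv <- mapply(function(n, j) pb[[n + 1L]][j + 1L], nvec[sel], nnz[sel])
    w <- pbv * exp(log_multinom[sel] + as.vector(lsize))
    if (any(sd_e == 0)) {       # multisets containing an impossible size
      bad <- rowSums(counts[sel, -1L, drop = FALSE][, sd_e == 0,
                                                    drop = FALSE]) > 0
      w[bad] <- 0
    }
    w[pbv == 0] <- 0
    wprior[sel] <- w
  }

  level_ids <- lapply(0:N, function(n) which(nvec == n))

  revealed <- vector("list", n_states)
  for (n in 0:N) {
    M <- lev[[n + 1L]]
    seqs <- lapply(seq_len(nrow(M)), function(r) counts_to_desc(M[r, ]))
    for (e in 1:E) {
      ids <- offset[n + 1L] + (e - 1L) * m_level[n + 1L] +
        seq_len(m_level[n + 1L])
      revealed[ids] <- seqs
    }
  }

  list(config = config, n_states = n_states, env = env, n = nvec,
       rank = rank, counts = counts, revealed = revealed,
       offset = offset, m_level = m_level, rank_lookup = rank_lookup,
       succ = succ, CUM = CUM, TIME = TIME, pnext = pnext,
       wprior = wprior, nnz = nnz, level_ids = level_ids)
}

# id of the state (env, n, counts) in workspace ordering
ws_state_id <- function(ws, env, n, counts_row) {
  r <- ws$rank_lookup[[n + 1L]][paste(counts_row, collapse = ",")]
  ws$offset[n + 1L] + (env - 1L) * ws$m_level[n + 1L] + unname(r)
}
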