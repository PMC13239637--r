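#' Stimulus feature codes
#'
#' The two conditioned stimuli (square vs. diamond) are encoded as two fixed
#' orthogonal 8-bit binary patterns of equal norm. The exact encoding is a
#' configuration constant; any fixed pair of distinct equal-norm codes works.
#'
#' @return 8 x 2 matrix, columns named `CS+` and `CS-`.
#' @export
stimulus_codes <- function() {
  m <- cbind(`CS+` = c(1, 1, 1, 1, 0, 0, 0, 0),
             `CS-` = c(0, 0, 0, 0, 1, 1, 1, 1))
  m
}

#' Hyper-parameters of the replay-trained value model
#'
#' @param b replay batch size.
#' @param lambda recency decay factor of replay priorities, in (0, 1\].
#' @param i number of replayed batches per trial.
#' @param beta inverse temperature of the sleep-replay reactivation softmax.
#' @param rpe if `TRUE`, replay priorities are additionally proportional to
#'   the magnitude of the stored prediction error.
#' @param learning_rate SGD learning rate (fixed training setting).
#' @param sleep_batches,sleep_batch_size the sleep-replay phase performs
#'   exactly `sleep_batches` (100) batch updates of size `sleep_batch_size`
#'   (64).
#' @return object of class `hyper_params`.
#' @export
hyper_params <- function(b = 16L, lambda = 0.8, i = 6L, beta = 3,
                         rpe = FALSE, learning_rate = 0.01,
                         sleep_batches = 100L, sleep_batch_size = 64L) {
  stopifnot(b >= 1L, lambda > 0, lambda <= 1, i >= 0L, beta >= 0,
            is.logical(rpe), learning_rate > 0,
            sleep_batches >= 0L, sleep_batch_size >= 1L)
  structure(list(b = as.integer(b), lambda = lambda, i = as.integer(i),
                 beta = beta, rpe = rpe, learning_rate = learning_rate,
                 sleep_batches = as.integer(sleep_batches),
                 sleep_batch_size = as.integer(sleep_batch_size)),
            class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  cat(sprintf("hyper_params: b=%d lambda=%g i=%d beta=%g RPE=%s\n",
              x$b, x$lambda, x$i, x$beta, if (x$rpe) "Yes" else "No"))
  invisible(x)
}

#' Hyper-parameter grids of the full grid search
#'
#' The full search space: batch size b in \{1, 16, 32, 64, 96, 128\}, decay
#' lambda in \{0.05, 0.4, 0.5, 0.6, 0.7, 0.8, 0.825, 0.85, 0.895, 1\},
#' training repeats i in 1..12, inverse temperature beta in 1..5 and
#' RPE in \{Yes, No\} -- 7200 configurations.
#'
#' @return named list of grid vectors.
#' @export
table1_grid <- function() {
  list(b = c(1L, 16L, 32L, 64L, 96L, 128L),
       lambda = c(0.05, 0.4, 0.5, 0.6, 0.7, 0.8, 0.825, 0.85, 0.895, 1),
       i = 1:12,
       beta = 1:5,
       rpe = c(FALSE, TRUE))
}

#' Desk-scale default grid
#'
#' A subset of the full grid sized for interactive use: b in \{16, 64\},
#' lambda in \{0.5, 0.8, 1\}, i in \{2, 6, 12\}, beta in \{1, 3, 5\},
#' RPE in \{Yes, No\} (108 configurations).
#'
#' @return named list of grid vectors.
#' @export
default_grid <- function() {
  list(b = c(16L, 64L), lambda = c(0.5, 0.8, 1), i = c(2L, 6L, 12L),
       beta = c(1, 3, 5), rpe = c(FALSE, TRUE))
}

#' Prediction error
#'
#' `delta = r - v`: the signed discrepancy between the received reinforcement
#' and the predicted US probability.
#'
#' @param r reinforcement signal in \{0, 1\}.
#' @param v predicted US probability in \[0, 1\].
#' @return delta.
#' @export
prediction_error <- function(r, v) {
  stopifnot(all(r %in% c(0, 1)), all(v >= 0 & v <= 1))
  r - v
}

#' Replay sampling probabilities
#'
#' Priority scores depend on the experiences' recency, `p_k = lambda^tau_k`
#' where `tau_k` is the number of trials since storage; with `rpe = TRUE` the
#' priority is additionally proportional to the magnitude of the stored
#' prediction error, `p_k = |delta_k| * lambda^tau_k`. Probabilities are the
#' priorities normalized to sum 1. If all RPE-weighted priorities are zero,
#' recency-only priorities are used as fallback.
#'
#' @param memory list with numeric vectors `t_stored` and `delta` (as stored).
#' @param t_now current trial index (so `tau = t_now - t_stored >= 0`).
#' @param lambda recency decay in (0, 1\].
#' @param rpe logical.
#' @return probability vector over the stored experiences (sums to 1).
#' @export
replay_probabilities <- function(memory, t_now, lambda, rpe = FALSE) {
  m <- length(memory$t_stored)
  if (m == 0L) stop("memory is empty")
  tau <- t_now - memory$t_stored
  stopifnot(all(tau >= 0), lambda > 0, lambda <= 1)
  p <- lambda^tau
  if (rpe) {
    p_rpe <- abs(memory$delta) * p
    if (sum(p_rpe) > 0) p <- p_rpe
  }
  p / sum(p)
}

#' Sleep-replay reactivation probabilities
#'
#' Softmax over the stored reinforcement signals:
#' `P(e_k) = exp(beta * r_k) / sum_i exp(beta * r_i)`. With `beta = 0` the
#' distribution is uniform; as `beta` grows, reactivation concentrates on the
#' reinforced experiences.
#'
#' @param memory list with numeric vector `r`.
#' @param beta inverse temperature (>= 0).
#' @return probability vector (sums to 1).
#' @export
sleep_probabilities <- function(memory, beta) {
  m <- length(memory$r)
  if (m == 0L) stop("memory is empty")
  stopifnot(beta >= 0)
  w <- exp(beta * memory$r)
  w / sum(w)
}

# ---- value network -------------------------------------------------------
# two hidden fully connected layers with 64 units each (ReLU) and a sigmoid
# output unit representing the probability of the shock; trained with MSE
# loss against the reinforcement signal by plain SGD.

new_agent <- function(seed, n_in = 8L, n_hidden = 64L) {
  a <- new.env(parent = emptyenv())
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  a$W1 <- he(n_hidden, n_in);    a$b1 <- numeric(n_hidden)
  a$W2 <- he(n_hidden, n_hidden); a$b2 <- numeric(n_hidden)
  a$W3 <- he(1L, n_hidden);      a$b3 <- 0
  a$memory <- list(stim = integer(0), r = numeric(0), delta = numeric(0),
                   t_stored = integer(0))
  a$n_sleep_updates <- 0L
  a$codes <- stimulus_codes()
  a
}

.agent_forward <- function(a, X) {
  h1 <- a$W1 %*% X + a$b1
  h1[h1 < 0] <- 0
  h2 <- a$W2 %*% h1 + a$b2
  h2[h2 < 0] <- 0
  z <- drop(a$W3 %*% h2) + a$b3
  list(h1 = h1, h2 = h2, v = 1 / (1 + exp(-z)))
}

#' Predicted US probability for a stimulus
#' @param agent an agent as created inside [run_agent()].
#' @param cs `"CS+"` or `"CS-"` (vectorized).
#' @return predictions in \[0, 1\].
#' @export
agent_predict <- function(agent, cs) {
  X <- agent$codes[, cs, drop = FALSE]
  unname(.agent_forward(agent, X)$v)
}

# one SGD step on MSE loss toward the reinforcement targets, batch X (8 x b)
.agent_update <- function(a, X, r, lr) {
  b <- ncol(X)
  f <- .agent_forward(a, X)
  v <- f$v
  # d(mean (v - r)^2)/dz, sigmoid output
  dz <- (2 / b) * (v - r) * v * (1 - v)        # length b
  dW3 <- matrix(dz, 1L) %*% t(f$h2)
  db3 <- sum(dz)
  dh2 <- t(a$W3) %*% matrix(dz, 1L)            # 64 x b
  dh2[f$h2 <= 0] <- 0
  dW2 <- dh2 %*% t(f$h1)
  db2 <- rowSums(dh2)
  dh1 <- t(a$W2) %*% dh2
  dh1[f$h1 <= 0] <- 0
  dW1 <- dh1 %*% t(X)
  db1 <- rowSums(dh1)
  a$W3 <- a$W3 - lr * dW3; a$b3 <- a$b3 - lr * db3
  a$W2 <- a$W2 - lr * dW2; a$b2 <- a$b2 - lr * db2
  a$W1 <- a$W1 - lr * dW1; a$b1 <- a$b1 - lr * db1
  invisible(a)
}

.sample_batch <- function(memory, prob, size) {
  sample.int(length(prob), size, replace = TRUE, prob = prob)
}

#' Experience one trial: predict, store, replay-train
#'
#' The prediction `v_t` is computed before any update for the trial; the
#' experience tuple `(s_t, r_t, delta_t)` is appended to memory; then `hp$i`
#' batch updates of size `hp$b` are performed on experiences sampled with
#' replacement according to [replay_probabilities()].
#'
#' @param agent agent environment (modified in place).
#' @param cs `"CS+"` or `"CS-"`.
#' @param r reinforcement in \{0, 1\}.
#' @param t_now trial index (for recency).
#' @param hp a [hyper_params()].
#' @return list with `v` and `delta` for the trial.
#' @export
train_on_trial <- function(agent, cs, r, t_now, hp) {
  v <- agent_predict(agent, cs)
  delta <- r - v
  mem <- agent$memory
  mem$stim <- c(mem$stim, match(cs, colnames(agent$codes)))
  mem$r <- c(mem$r, r)
  mem$delta <- c(mem$delta, delta)
  mem$t_stored <- c(mem$t_stored, as.integer(t_now))
  agent$memory <- mem
  if (hp$i > 0L) {
    for (rep in seq_len(hp$i)) {
      prob <- replay_probabilities(mem, t_now, hp$lambda, hp$rpe)
      k <- .sample_batch(mem, prob, hp$b)
      X <- agent$codes[, mem$stim[k], drop = FALSE]
      .agent_update(agent, X, mem$r[k], hp$learning_rate)
    }
  }
  list(v = v, delta = delta)
}

#' Sleep-replay phase
#'
#' Between day 1 and day 2 the agent performs exactly `hp$sleep_batches`
#' (100) batch updates of size `hp$sleep_batch_size` (64), sampling
#' experiences by [sleep_probabilities()] with inverse temperature
#' `hp$beta`. This preferential replay of reinforced experiences re-
#' strengthens the acquired association and is the model's mechanism for
#' spontaneous recovery. The agent's `n_sleep_updates` counter records the
#' number of updates performed.
#'
#' @param agent agent environment (modified in place).
#' @param hp a [hyper_params()].
#' @return the agent, invisibly.
#' @export
sleep_replay <- function(agent, hp) {
  mem <- agent$memory
  if (length(mem$r) == 0L) stop("memory is empty")
  prob <- sleep_probabilities(mem, hp$beta)
  for (u in seq_len(hp$sleep_batches)) {
    k <- .sample_batch(mem, prob, hp$sleep_batch_size)
    X <- agent$codes[, mem$stim[k], drop = FALSE]
    .agent_update(agent, X, mem$r[k], hp$learning_rate)
    agent$n_sleep_updates <- agent$n_sleep_updates + 1L
  }
  invisible(agent)
}

#' Run one agent through the full two-day experiment
#'
#' Habituation, acquisition and extinction trials are experienced in design
#' order (habituation trials are stored with r = 0), followed by the
#' sleep-replay phase, followed by the recall trials. Per-trial predictions
#' `v_t` and prediction errors `delta_t` are recorded.
#'
#' @param design a `fear_design`.
#' @param hp a [hyper_params()].
#' @param seed integer seed (weight initialization and replay sampling).
#' @param sleep if `FALSE`, the sleep-replay phase is skipped (diagnostic:
#'   disables the spontaneous-recovery mechanism).
#' @return object of class `agent_trace`: list with `trace` (data.frame:
#'   trial, phase, cs_type, reinforced, v, delta, memory_size) and `agent`.
#' @export
run_agent <- function(design, hp = hyper_params(), seed = 1L, sleep = TRUE) {
  events <- design$events
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  agent <- new_agent(seed)
  set.seed(derive_seed(seed, 17L))
  n <- nrow(events)
  v <- numeric(n); delta <- numeric(n); msize <- integer(n)
  day2 <- events$phase == "recall"
  slept <- FALSE
  for (k in seq_len(n)) {
    if (day2[k] && !slept) {
      if (sleep) sleep_replay(agent, hp)
      slept <- TRUE
    }
    res <- train_on_trial(agent, events$cs_type[k],
                          as.numeric(events$reinforced[k]), k, hp)
    v[k] <- res$v; delta[k] <- res$delta
    msize[k] <- length(agent$memory$r)
  }
  structure(list(trace = data.frame(trial = seq_len(n), phase = events$phase,
                                    cs_type = events$cs_type,
                                    reinforced = events$reinforced,
                                    v = v, delta = delta,
                                    memory_size = msize,
                                    stringsAsFactors = FALSE),
                 agent = agent, hp = hp, seed = seed, sleep = sleep),
            class = "agent_trace")
}

#' @export
print.agent_trace <- function(x, ...) {
  cat("Agent trace:", nrow(x$trace), "trials;",
      x$agent$n_sleep_updates, "sleep updates\n")
  invisible(x)
}

#' Ensemble of randomly initialized agents
#'
#' Trains `n_agents` (default 25) independently initialized agents on the
#' same design and averages the per-trial US predictions and absolute
#' prediction errors, plus the per-presentation-ordinal averaged curves
#' `V-bar = (v+_1..N, v-_1..N)` used for hyper-parameter fitting.
#'
#' @param design a `fear_design`.
#' @param hp a [hyper_params()].
#' @param n_agents ensemble size (default 25).
#' @param seed master seed; per-agent seeds are derived from it.
#' @param sleep passed to [run_agent()].
#' @return object of class `ensemble_trace`: list with `trace` (per-trial
#'   data.frame: trial, phase, cs_type, reinforced, v, abs_delta), `curve`
#'   (data.frame: cs_type, ordinal, phase, v), `n_agents`, `hp`.
#' @export
run_ensemble <- function(design, hp = hyper_params(), n_agents = 25L,
                         seed = 1L, sleep = TRUE) {
  stopifnot(n_agents >= 1L)
  events <- design$events
  n <- nrow(events)
  V <- matrix(0, n, n_agents)
  D <- matrix(0, n, n_agents)
  for (j in seq_len(n_agents)) {
    at <- run_agent(design, hp, seed = derive_seed(seed, j), sleep = sleep)
    V[, j] <- at$trace$v
    D[, j] <- abs(at$trace$delta)
  }
  vbar <- rowMeans(V)
  trace <- data.frame(trial = seq_len(n), phase = events$phase,
                      cs_type = events$cs_type, reinforced = events$reinforced,
                      v = vbar, abs_delta = rowMeans(D),
                      stringsAsFactors = FALSE)
  ord <- stats::ave(seq_len(n), events$cs_type, FUN = seq_along)
  curve <- data.frame(cs_type = events$cs_type, ordinal = ord,
                      phase = events$phase, v = vbar,
                      stringsAsFactors = FALSE)
  curve <- curve[order(factor(curve$cs_type, levels = c("CS+", "CS-")),
                       curve$ordinal), ]
  rownames(curve) <- NULL
  structure(list(trace = trace, curve = curve, n_agents = n_agents,
                 hp = hp, seed = seed, sleep = sleep),
            class = "ensemble_trace")
}

#' @export
print.ensemble_trace <- function(x, ...) {
  cat("Ensemble of", x$n_agents, "agents over", nrow(x$trace), "trials\n")
  invisible(x)
}
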