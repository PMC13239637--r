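test_that("prediction errors and sampling probabilities match hand cases", {
  expect_equal(prediction_error(1, 1), 0)
  expect_equal(prediction_error(1, 0.25), 0.75)
  expect_equal(prediction_error(0, 1), -1)

  mem <- list(t_stored = c(0, 1, 2), delta = c(0, 0.5, 0.5), r = c(1, 0, 0))
  # tau = (2,1,0), lambda 0.5 -> priorities (0.25, 0.5, 1)
  expect_equal(replay_probabilities(mem, 2, 0.5, FALSE), c(1, 2, 4) / 7)
  expect_equal(replay_probabilities(mem, 5, 1, FALSE), rep(1 / 3, 3))
  # RPE weighting: |delta| = (0, .5, .5), lambda 1
  expect_equal(replay_probabilities(mem, 2, 1, TRUE), c(0, 0.5, 0.5))
  # all-zero RPE priorities fall back to recency
  mem0 <- list(t_stored = c(0, 1), delta = c(0, 0), r = c(0, 0))
  expect_equal(replay_probabilities(mem0, 1, 0.5, TRUE), c(1, 2) / 3)
  expect_error(replay_probabilities(list(t_stored = integer(0),
                                         delta = numeric(0)), 0, 1), "empty")

  expect_equal(sleep_probabilities(mem, 0), rep(1 / 3, 3))
  expect_equal(sleep_probabilities(mem, log(2)), c(0.5, 0.25, 0.25))
  expect_gt(sleep_probabilities(mem, 50)[1], 1 - 1e-12)
})

test_that("probability vectors are proper and recency-monotone", {
  set.seed(7)
  for (k in 1:20) {
    m <- sample(2:40, 1)
    mem <- list(t_stored = sort(sample(0:m, m, replace = TRUE)),
                delta = runif(m, -1, 1), r = rbinom(m, 1, 0.3))
    lam <- runif(1, 0.05, 1)
    p1 <- replay_probabilities(mem, m + 1, lam, FALSE)
    p2 <- replay_probabilities(mem, m + 1, lam, TRUE)
    p3 <- sleep_probabilities(mem, runif(1, 0, 5))
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(sum(p2), 1, tolerance = 1e-12)
    expect_equal(sum(p3), 1, tolerance = 1e-12)
    if (lam < 1) {
      tau <- (m + 1) - mem$t_stored
      o <- order(tau)
      expect_true(all(diff(p1[o]) <= 1e-15))
    }
  }
})

test_that("trial training predicts before updating and i = 0 freezes weights", {
  d <- build_experiment("A", seed = 1)
  hp0 <- hyper_params(i = 0L)
  tr <- run_agent(d, hp0, seed = 3)
  # without updates the prediction for a stimulus never changes
  v_plus <- tr$trace$v[tr$trace$cs_type == "CS+" &
                         tr$trace$phase != "recall"]
  expect_true(all(abs(v_plus - v_plus[1]) < 1e-12))
  expect_equal(tr$trace$memory_size, seq_len(nrow(tr$trace)))
  # delta = r - v throughout
  expect_equal(tr$trace$delta,
               as.numeric(tr$trace$reinforced) - tr$trace$v)
})

test_that("repeated reinforcement drives the CS+ prediction upward", {
  spec <- phase_spec("acquisition", 10, 6, 16)
  d <- build_experiment("A", seed = 1)
  ends <- vapply(1:5, function(s) {
    tr <- run_agent(d, hyper_params(), seed = s)$trace
    acq <- tr[tr$phase == "acquisition", ]
    mean(utils::tail(acq$v[acq$cs_type == "CS+"], 4))
  }, numeric(1))
  # partial (62.5%) reinforcement: late-acquisition CS+ prediction is high
  expect_gt(mean(ends), 0.45)
})

test_that("sleep replay performs exactly 100 batches of 64 and recovers v(CS+)", {
  d <- build_experiment("A", seed = 1)
  hp <- hyper_params()
  expect_equal(hp$sleep_batches, 100L)
  expect_equal(hp$sleep_batch_size, 64L)
  at <- run_agent(d, hp, seed = 5)
  expect_equal(at$agent$n_sleep_updates, 100L)
  at0 <- run_agent(d, hp, seed = 5, sleep = FALSE)
  expect_equal(at0$agent$n_sleep_updates, 0L)
  tr <- run_agent(d, hyper_params(i = 0L), seed = 2)
  expect_true(all(tr$trace$v >= 0 & tr$trace$v <= 1))
})

test_that("an unreinforced design keeps predictions near zero", {
  specs <- list(habituation = phase_spec("habituation", 0, 3, 3),
                acquisition = phase_spec("acquisition", 3, 6, 16),
                extinction = phase_spec("extinction", 0, 16, 16),
                recall = phase_spec("recall", 0, 12, 12))
  d <- build_experiment("A", seed = 1, specs = specs)
  d$events$reinforced <- FALSE  # strip all reinforcement
  tr <- run_agent(d, hyper_params(), seed = 4)$trace
  expect_lt(max(tr$v[tr$phase %in% c("extinction", "recall")]), 0.1)
})

test_that("ensembles average per presentation ordinal and default to 25 agents", {
  expect_equal(eval(formals(run_ensemble)$n_agents), 25L)
  d <- build_experiment("A", seed = 1)
  hp <- hyper_params(i = 1L, b = 4L)
  e1 <- run_ensemble(d, hp, n_agents = 1L, seed = 9)
  a1 <- run_agent(d, hp, seed = fearreplay:::derive_seed(9, 1))
  expect_equal(e1$trace$v, a1$trace$v)
  expect_true(all(e1$curve$v >= 0 & e1$curve$v <= 1))
  expect_equal(nrow(e1$curve), nrow(d$events))
  # deterministic under the master seed
  e2 <- run_ensemble(d, hp, n_agents = 2L, seed = 9)
  e3 <- run_ensemble(d, hp, n_agents = 2L, seed = 9)
  expect_identical(e2$trace$v, e3$trace$v)
})
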