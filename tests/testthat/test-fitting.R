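test_that("averaged curves reproduce hand computations", {
  # single participant: curve equals own normalized log scores
  s1 <- toy_scores(c(0.4, 0.2, 0.1, 0.05))
  c1 <- average_scr_curves(s1, normalize = FALSE)
  expect_equal(c1$ybar, log1p(c(0.4, 0.2, 0.1, 0.05)))
  expect_equal(c1$n, 1L)
  expect_equal(c1$layout$cs_type, c("CS+", "CS+", "CS-", "CS-"))

  # all-zero scores: normalization guarded, curve stays zero
  s0 <- toy_scores(rep(0, 4))
  expect_equal(average_scr_curves(s0)$ybar, rep(0, 4))

  # three participants: per-ordinal mean of log1p, then min-max
  amps <- list(c(0.4, 0.2, 0.1, 0.0), c(0.6, 0.1, 0.2, 0.1),
               c(0.2, 0.3, 0.0, 0.2))
  sc <- do.call(rbind, lapply(seq_along(amps), function(k)
    toy_scores(amps[[k]], participant = k)))
  cc <- average_scr_curves(sc, normalize = FALSE)
  hand <- rowMeans(vapply(amps, log1p, numeric(4)))
  expect_equal(cc$ybar, hand)
  expect_equal(average_scr_curves(sc)$ybar,
               (hand - min(hand)) / diff(range(hand)))

  # mismatched trial counts error
  bad <- rbind(sc, toy_scores(c(0.1, 0.1), participant = 9)[1:2, ])
  expect_error(average_scr_curves(bad), "mismatch")
})

test_that("penalties threshold exactly at the stated boundaries", {
  expect_equal(as.numeric(penalty_saf(0.05)), 0)
  expect_equal(as.numeric(penalty_saf(0.10)), 10)  # boundary penalized
  expect_equal(as.numeric(penalty_saf(0.0999)), 0)
  expect_equal(as.numeric(penalty_ext(0.149)), 0)
  expect_equal(as.numeric(penalty_ext(0.15)), 10)
  expect_equal(as.numeric(penalty_ext(0.20)), 10)
  # from a per-trial trace
  tr <- data.frame(phase = rep(c("acquisition", "extinction"), each = 8),
                   cs_type = rep(c("CS-", "CS+"), 8),
                   v = rep(c(0.3, 0.05), 8))
  expect_equal(as.numeric(penalty_saf(tr)), 10)
  expect_equal(as.numeric(penalty_ext(tr)), 0)
})

test_that("goodness of fit is zero at perfect fit and scales with weights", {
  y <- list(c(0, 0.5, 1), c(1, 0.5, 0))
  expect_equal(goodness_of_fit(y, y, c(3, 5)), 0)
  # toy curves with L1 distance 0.8 and weight 5 -> -4
  a <- c(0.1, 0.2, 0.3); b <- a + c(0.5, 0.2, -0.1)
  expect_equal(goodness_of_fit(list(a), list(b), 5), -4)
  expect_equal(goodness_of_fit(list(a), list(b), 10), -8)
  # penalties subtract
  expect_equal(goodness_of_fit(list(a), list(a), 1, p_saf = 10, p_ext = 10),
               -20)
  expect_error(goodness_of_fit(list(a), list(c(1, 2)), 1), "mismatch")
  # a penalized configuration never outranks an otherwise-equal free one
  expect_lt(goodness_of_fit(y, y, c(3, 5), p_saf = 10),
            goodness_of_fit(y, y, c(3, 5)))
})

test_that("grid search selects and tie-breaks deterministically", {
  designs <- list(A = build_experiment("A", seed = 21),
                  B = build_experiment("B", seed = 22))
  p <- scr_gen_params(group = "verum", recovery_boost = 0)
  coh <- simulate_cohort(2, 2, p, seed = 13, designs = designs)
  sc <- score_cohort(coh)

  one <- list(b = 16L, lambda = 0.8, i = 2L, beta = 3, rpe = FALSE)
  f1 <- fit_replay_model(sc, designs, grid = one, n_agents = 2L, seed = 5)
  expect_s3_class(f1, "replay_fit")
  expect_equal(unname(coef(f1)[c("b", "lambda", "i")]), c(16, 0.8, 2))

  # duplicated configuration: deterministic, picks the (identical) first
  dup <- list(b = c(16L, 16L), lambda = 0.8, i = 2L, beta = 3, rpe = FALSE)
  f2 <- fit_replay_model(sc, designs, grid = dup, n_agents = 2L, seed = 5)
  expect_equal(coef(f2), coef(f1))
  expect_equal(f2$f, f1$f)
  expect_error(fit_replay_model(sc, designs, grid = list(b = integer(0),
                                                         lambda = 0.8, i = 1L,
                                                         beta = 1, rpe = FALSE),
                                n_agents = 1L), "empty")

  # methods behave
  expect_output(print(f1), "Best:")
  expect_output(print(summary(f1)), "Top configurations")
  pr <- predict(f1)
  expect_true(all(pr$v >= 0 & pr$v <= 1))
  expect_equal(length(residuals(f1)), 2L)
  expect_equal(length(fitted(f1)$A), length(f1$targets$A$ybar))
})
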