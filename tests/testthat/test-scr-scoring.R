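test_that("window scoring applies the amplitude and rise-time criteria", {
  fs <- 1000
  sp <- scoring_params()
  score_bump <- function(amp, rise)
    score_window(bump_trace(amp, rise, fs), fs, c(3, 10.5), sp)

  expect_equal(score_window(rep(2, 2000), 100, c(3, 10.5), sp), 0)
  expect_equal(score_bump(0.5, 1.5), 0.5, tolerance = 1e-6)
  expect_equal(score_bump(0.005, 1.5), 0)  # below 0.01 muS
  expect_equal(score_bump(0.5, 0.2), 0)    # rise below 500 ms
  expect_equal(score_bump(0.011, 0.6), 0.011, tolerance = 1e-6)
  expect_error(score_window(rep(2, 100), 100, c(3, 10.5), sp), "outside")
})

test_that("response detection matches a slow reference implementation", {
  set.seed(2024)
  for (rep in 1:12) {
    # random smooth trace with several overlapping responses + mild noise
    fs <- 100
    t <- seq(0, 19.99, by = 1 / fs)
    s <- 2 + 0.05 * cumsum(rnorm(length(t))) / sqrt(fs)
    for (k in 1:4) {
      s <- s + runif(1, 0.02, 0.8) * scr_kernel(t - runif(1, 1, 15),
                                                0.4, 1.5)
    }
    expect_equal(detect_responses(s, 0.01), ref_detect_responses(s, 0.01))
  }
})

test_that("a larger qualifying deflection never decreases the score", {
  fs <- 1000
  sp <- scoring_params()
  base <- bump_trace(0.3, 1.0, fs)
  s0 <- score_window(base, fs, c(3, 10.5), sp)
  # add a second, larger deflection later in the window
  t <- seq(0, 20, by = 1 / fs)
  extra <- base + 0.6 * scr_kernel(t - 9, 0.6, 2.0)
  s1 <- score_window(extra, fs, c(3, 10.5), sp)
  expect_gte(s1, s0)
  expect_equal(s1, 0.6, tolerance = 0.02)
})

test_that("experiment scoring emits CS and UR scores with stimulus classes", {
  d <- build_experiment("A", seed = 6)
  p <- scr_gen_params(noise_sd = 0, amp_noise_sd = 0, nonresponse_prob = 0,
                      group = "sham")
  tr <- simulate_participant(d, p, seed = 2)
  sc <- score_experiment(tr)
  expect_equal(nrow(sc), 2L * nrow(d$events))
  acq <- sc[sc$phase == "acquisition", ]
  expect_equal(nrow(acq), 64L)  # 32 CS-window + 32 UR-window
  expect_setequal(unique(acq$stim_class[acq$window == "UR"]),
                  c("CS+/US", "CS+/no-US", "CS-"))
  # reinforced trials carry an unconditioned response in the UR window
  ur_paired <- acq[acq$window == "UR" & acq$stim_class == "CS+/US", ]
  expect_true(all(ur_paired$amplitude > 0.5))

  # all-zero trace still emits the full, all-zero table
  flat <- tr
  flat$samples <- rep(2, length(tr$samples))
  sc0 <- score_experiment(flat)
  expect_equal(nrow(sc0), 2L * nrow(d$events))
  expect_true(all(sc0$amplitude == 0))
})

test_that("block averaging follows the first/last block scheme and log transform", {
  d <- build_experiment("A", seed = 6)
  p <- scr_gen_params(group = "sham")
  sc <- score_experiment(simulate_participant(d, p, seed = 2))
  b <- block_average(sc)
  expect_equal(sort(unique(b$block)), c("early", "habituation", "late"))
  expect_equal(unique(b$n_trials[b$phase == "habituation"]), 3L)
  expect_equal(unique(b$n_trials[b$phase == "acquisition"]), 8L)
  expect_equal(unique(b$n_trials[b$phase == "recall"]), 6L)

  # early CS+ block = first 8 CS+ trials in presentation order
  cs <- sc[sc$window == "CS" & sc$phase == "acquisition" &
             sc$cs_type == "CS+", ]
  cs <- cs[order(cs$index_in_phase), ]
  expect_equal(b$mean_raw[b$phase == "acquisition" & b$block == "early" &
                            b$cs_type == "CS+"],
               mean(cs$amplitude[1:8]))

  # LN(1 + mean): raw {0.1, 0.3} -> LN(1.2)
  expect_equal(log1p(mean(c(0.1, 0.3))), log(1.2))
  expect_equal(b$mean_log_scr, log1p(b$mean_raw))

  # all-zero amplitudes -> all cells LN(1) = 0
  sc0 <- sc; sc0$amplitude <- 0
  expect_true(all(block_average(sc0)$mean_log_scr == 0))

  # log transform preserves block ranking
  expect_equal(order(b$mean_raw), order(b$mean_log_scr))

  # wrong trial counts error
  expect_error(block_average(sc[-3, ]), "requires")

  # differential SCRs
  dd <- scr_diff(b)
  one <- b[b$phase == "recall" & b$block == "early", ]
  expect_equal(dd$scr_diff[dd$phase == "recall" & dd$block == "early"],
               one$mean_log_scr[one$cs_type == "CS+"] -
                 one$mean_log_scr[one$cs_type == "CS-"])
})
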