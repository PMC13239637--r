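test_that("phase sequences have the required composition and constraints", {
  specs <- canonical_phase_specs()

  acq <- build_phase_sequence(specs$acquisition, seed = 11)
  expect_equal(nrow(acq), 32L)
  expect_true(all(acq$reinforced[c(1, 2, 32)]))
  expect_equal(sum(acq$reinforced), 10L)
  expect_equal(sum(acq$cs_type == "CS+" & !acq$reinforced), 6L)
  expect_equal(sum(acq$cs_type == "CS-"), 16L)
  # 62.5% reinforcement rate of CS+ trials
  expect_equal(sum(acq$reinforced) / sum(acq$cs_type == "CS+"), 0.625)

  hab <- build_phase_sequence(specs$habituation, seed = 11)
  expect_equal(nrow(hab), 6L)
  expect_false(any(hab$reinforced))

  ext <- build_phase_sequence(specs$extinction, seed = 3)
  expect_equal(sum(ext$cs_type[1:16] == "CS+"), 8L)
  expect_equal(sum(ext$cs_type[17:32] == "CS+"), 8L)

  # trial-kind multiset invariant across seeds, only order varies
  ext2 <- build_phase_sequence(specs$extinction, seed = 99)
  expect_equal(sort(ext$cs_type), sort(ext2$cs_type))

  # deterministic for a given seed
  expect_identical(acq, build_phase_sequence(specs$acquisition, seed = 11))

  # infeasible: acquisition with fewer than 3 paired trials
  expect_error(build_phase_sequence(phase_spec("acquisition", 2, 6, 16), 1),
               "at least 3 paired")
})

test_that("trial events carry the stated timings", {
  d <- build_experiment("A", seed = 5)
  e <- d$events
  expect_true(all(e$iti >= 14.3 & e$iti <= 17.9))
  expect_equal(e$us_onset - e$cs_onset, rep(7.9, nrow(e)))
  expect_true(all(e$cs_duration == 8.0))
  expect_true(all(e$cs_type[e$reinforced] == "CS+"))
  # full day-1 timeline strictly increasing on the session clock
  day1 <- e[e$phase != "recall", ]
  expect_true(all(diff(day1$onset_abs) > 0))
})

test_that("counterbalancing yields exactly two recall orderings sharing day 1", {
  a <- build_experiment("A", seed = 7)
  b <- build_experiment("B", seed = 7)
  day1_cols <- c("cs_type", "reinforced")
  expect_identical(a$events[a$events$phase != "recall", day1_cols],
                   b$events[b$events$phase != "recall", day1_cols])
  ra <- a$events[a$events$phase == "recall", ]
  rb <- b$events[b$events$phase == "recall", ]
  expect_equal(nrow(ra), 24L)
  expect_equal(sum(ra$cs_type == "CS+"), 12L)
  expect_equal(ra$cs_type[1], "CS+")
  expect_equal(rb$cs_type[1], "CS-")
  expect_false(identical(ra$cs_type, rb$cs_type))
  # day-1 ordering identical across user seeds (only ITIs vary)
  a2 <- build_experiment("A", seed = 123)
  expect_identical(a$events$cs_type, a2$events$cs_type)
  expect_false(identical(a$events$iti, a2$events$iti))
})

test_that("validate_design passes generator output and flags violations", {
  d <- build_experiment("B", seed = 2)
  v <- validate_design(d)
  expect_true(all(v$pass))

  # constructed violation: last acquisition trial unreinforced
  bad <- d
  acq_rows <- which(bad$events$phase == "acquisition")
  bad$events$reinforced[acq_rows[length(acq_rows)]] <- FALSE
  vb <- validate_design(bad)
  expect_false(vb$pass[vb$check == "last-trial-paired"])

  # constructed violation: unequal halves in acquisition
  bad2 <- d
  k <- bad2$events$phase == "acquisition"
  cs <- bad2$events$cs_type[k]
  cs[cs == "CS-"][1] <- "CS+"  # 9 CS+-ish first half
  bad2$events$cs_type[k] <- cs
  vb2 <- validate_design(bad2)
  expect_false(all(vb2$pass))
})

test_that("designs round-trip through CSV", {
  d <- build_experiment("B", seed = 17)
  path <- tempfile(fileext = ".csv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$counterbalance, "B")
  expect_equal(d$events$cs_onset, d2$events$cs_onset)
  expect_equal(d$events$cs_type, d2$events$cs_type)
  unlink(path)
})
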