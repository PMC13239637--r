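test_that("relative treatment effects match midrank hand computations", {
  # two cells {1,2} and {3,4}: RTEs 0.25 and 0.75
  d <- data.frame(value = c(1, 3, 2, 4), subject = c(1, 1, 2, 2),
                  group = "g", stimulus = rep(c("a", "b"), 2))
  r <- relative_treatment_effects(d, within = "stimulus", n_boot = 0)
  expect_equal(r$rte, c(0.25, 0.75))

  # identical distributions across cells -> all RTEs 0.5
  d2 <- data.frame(value = rep(1:5, 4), subject = rep(1:5, 4),
                   group = "g",
                   stimulus = rep(c("a", "b"), each = 10),
                   block = rep(rep(c("e", "l"), each = 5), 2))
  r2 <- relative_treatment_effects(d2, n_boot = 0)
  expect_true(all(r2$rte == 0.5))

  # weighted mean of cell RTEs is exactly 0.5, unbalanced groups included
  set.seed(5)
  d3 <- null_long_table(0L + 7L)
  d3$group[d3$subject > 10] <- "verum"; d3$group[d3$subject <= 10] <- "sham"
  r3 <- relative_treatment_effects(d3, n_boot = 0)
  expect_equal(sum(r3$rte * r3$n_subjects) / sum(r3$n_subjects), 0.5)

  # invariance under strictly monotone transforms
  set.seed(6)
  d4 <- null_long_table(8L)
  r4a <- relative_treatment_effects(d4, n_boot = 0)
  d4$value <- exp(d4$value)
  r4b <- relative_treatment_effects(d4, n_boot = 0)
  expect_equal(r4a$rte, r4b$rte)

  # bootstrap CIs bracket the point estimate
  set.seed(7)
  d5 <- null_long_table(10L)
  r5 <- relative_treatment_effects(d5, n_boot = 200, seed = 1)
  expect_true(all(r5$lower <= r5$rte + 1e-12 & r5$upper >= r5$rte - 1e-12))
})

test_that("the ATS handles degenerate, null and structured data correctly", {
  set.seed(11)
  d <- null_long_table(10L)
  # constant data: all statistics 0, p = 1
  d0 <- d; d0$value <- 3
  a0 <- ats(d0)
  expect_true(all(a0$statistic == 0))
  expect_true(all(a0$p == 1))

  # monotone-transform invariance (rank statistic)
  a1 <- ats(d)
  d1 <- d; d1$value <- qlogis(pnorm(d$value))
  expect_equal(ats(d1)$statistic, a1$statistic)

  # unbalanced within cells error
  expect_error(ats(d[-1, ]), "unbalanced")

  # injected stimulus effect is detected; absent group effect is not
  set.seed(12)
  reps <- replicate(20, {
    dd <- null_long_table(12L)
    dd$value <- dd$value + ifelse(dd$stimulus == "CS+", 1.2, 0)
    a <- ats(dd)
    c(stim = a$p[a$effect == "stimulus"], grp = a$p[a$effect == "group"])
  })
  expect_true(all(reps["stim", ] < 0.001))
  expect_gt(mean(reps["grp", ] > 0.05), 0.8)
})

test_that("ATS direction agrees with parametric ANOVA on Gaussian data", {
  set.seed(13)
  d <- null_long_table(15L)
  d$value <- d$value + ifelse(d$stimulus == "CS+", 0.9, 0) +
    ifelse(d$block == "early", 0.6, 0)
  a <- ats(d)
  fit <- stats::aov(value ~ stimulus * block * group +
                      Error(factor(subject) / (stimulus * block)), data = d)
  sm <- summary(fit)
  get_p <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "Pr(>F)"]
  }
  p_stim <- get_p("Error: factor(subject):stimulus", "stimulus")
  p_block <- get_p("Error: factor(subject):block", "block")
  expect_lt(a$p[a$effect == "stimulus"], 0.01)
  expect_lt(p_stim, 0.01)
  expect_lt(a$p[a$effect == "block"], 0.01)
  expect_lt(p_block, 0.01)
  expect_gt(a$p[a$effect == "group"], 0.05)
})

test_that("post hoc contrasts are Tukey-Kramer adjusted and sane", {
  set.seed(14)
  d <- null_long_table(10L)
  ph <- posthoc_cellwise(d, effect = c("stimulus", "block"))
  expect_equal(nrow(ph), 6L)  # 4 cells -> 6 pairs
  expect_true(all(ph$p_adj >= ph$p_unadj - 1e-12))
  expect_true(all(ph$p_adj <= 1))

  # identical cells: adjusted p near 1
  d6 <- d; d6$value <- rep(rnorm(20), each = 4)  # no within variation
  ph6 <- posthoc_cellwise(d6, effect = "stimulus")
  expect_gt(ph6$p_adj[1], 0.99)
  expect_error(posthoc_cellwise(d, effect = "nope"), "unknown")
})
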