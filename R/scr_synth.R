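#' Parameters of the synthetic skin-conductance generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: phasic responses whose amplitudes scale with the participant's
#' latent US expectancy, CS+ > CS- differentiation during acquisition, decay
#' across extinction, and an early-recall spontaneous-recovery boost that is
#' present in the sham group and absent under verum stimulation.
#'
#' @param fs sampling rate in Hz (default 100).
#' @param kernel_rise,kernel_decay time constants (s) of the bi-exponential
#'   sudomotor response kernel; `kernel_rise < kernel_decay`.
#' @param gain_expectancy response gain, muS per unit latent expectancy.
#' @param gain_orienting amplitude (muS) of the stimulus-driven orienting
#'   response, decaying multiplicatively by `habituation_rate` per trial.
#' @param habituation_rate per-trial multiplicative decay of the orienting
#'   response, in \[0, 1\].
#' @param ur_gain amplitude (muS) of the unconditioned response to a
#'   delivered US.
#' @param noise_sd additive Gaussian measurement noise on the trace (muS).
#' @param amp_noise_sd scale (muS) of the half-normal trial-to-trial
#'   amplitude jitter.
#' @param nonresponse_prob probability that a trial emits no phasic response.
#' @param baseline tonic conductance level (muS).
#' @param latency response latency (s) from stimulus onset to response onset.
#' @param alpha associative learning rate of the latent-expectancy process.
#' @param recovery_boost extra CS+ expectancy added on the first six recall
#'   CS+ trials, applied only when `group == "sham"`.
#' @param group `"sham"` or `"verum"`.
#' @return object of class `scr_gen_params`.
#' @export
scr_gen_params <- function(fs = 100, kernel_rise = 0.6, kernel_decay = 2.0,
                           gain_expectancy = 0.6, gain_orienting = 0.3,
                           habituation_rate = 0.95, ur_gain = 1.0,
                           noise_sd = 0.02, amp_noise_sd = 0.05,
                           nonresponse_prob = 0.1, baseline = 2.0,
                           latency = 1.5, alpha = 0.2,
                           recovery_boost = 0.35,
                           group = c("sham", "verum")) {
  group <- match.arg(group)
  stopifnot(fs > 0, kernel_rise > 0, kernel_rise < kernel_decay,
            gain_expectancy >= 0, gain_orienting >= 0, ur_gain >= 0,
            noise_sd >= 0, amp_noise_sd >= 0,
            habituation_rate >= 0, habituation_rate <= 1,
            nonresponse_prob >= 0, nonresponse_prob <= 1,
            alpha > 0, alpha < 1, recovery_boost >= 0,
            fs > 2 / kernel_rise)
  structure(as.list(environment()), class = "scr_gen_params")
}

#' Canonical sudomotor response kernel
#'
#' Bi-exponential difference kernel, causal (0 for `t <= 0`), single-peaked
#' and normalized to unit peak; with the default time constants its support is
#' effectively shorter than 10 s.
#'
#' @param t time (s), any real vector.
#' @param rise,decay rise and decay time constants (s), `rise < decay`.
#' @return kernel values, max 1.
#' @export
scr_kernel <- function(t, rise = 0.6, decay = 2.0) {
  if (rise >= decay) stop("kernel rise constant must be smaller than decay constant")
  # analytic peak of exp(-t/decay) - exp(-t/rise)
  t_peak <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / peak
  out
}

#' Latent US-expectancy trajectory of a simulated participant
#'
#' A simple per-stimulus associative (delta-rule) update generates the latent
#' expectancy E_t in \[0, 1\] driving response amplitudes: zero throughout
#' habituation, rising for the CS+ under partial reinforcement in acquisition,
#' decaying across extinction, and -- for the sham group only -- boosted by
#' `recovery_boost` on the first six recall CS+ trials (spontaneous recovery).
#' This process is deliberately not the replay-based value model, so that
#' fitting that model to generated data is a genuine recovery exercise.
#'
#' @param design a `fear_design`.
#' @param params [scr_gen_params()]; `params$group` selects sham/verum.
#' @param seed integer seed (jitters the learning rate across participants).
#' @param expectancy optional externally supplied per-trial expectancy vector
#'   (e.g. model-derived predictions) overriding the associative update; the
#'   recall recovery boost is still applied on top for the sham group.
#' @return numeric vector, one expectancy per design trial, in \[0, 1\].
#' @export
latent_expectancy <- function(design, params = scr_gen_params(), seed = 1L,
                              expectancy = NULL) {
  events <- design$events
  n <- nrow(events)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(expectancy)) {
    alpha <- min(0.9, max(0.02, stats::rnorm(1, params$alpha, 0.03)))
    E <- numeric(n)
    assoc <- c("CS+" = 0, "CS-" = 0)
    for (k in seq_len(n)) {
      if (events$phase[k] == "habituation") { E[k] <- 0; next }
      cs <- events$cs_type[k]
      E[k] <- assoc[cs]
      r <- as.numeric(events$reinforced[k])
      assoc[cs] <- assoc[cs] + alpha * (r - assoc[cs])
    }
  } else {
    stopifnot(length(expectancy) == n)
    E <- pmin(1, pmax(0, expectancy))
  }
  if (params$group == "sham" && params$recovery_boost > 0) {
    rec_plus <- which(events$phase == "recall" & events$cs_type == "CS+")
    boost_idx <- utils::head(rec_plus, 6L)
    E[boost_idx] <- pmin(1, E[boost_idx] + params$recovery_boost)
  }
  pmin(1, pmax(0, E))
}

#' Simulate one participant's skin-conductance trace
#'
#' The trace is baseline plus, for every trial, an event-related response
#' `amplitude * kernel(t - onset - latency)`, plus unconditioned responses on
#' reinforced trials and additive Gaussian noise. Trial amplitudes are
#' `Bernoulli(1 - nonresponse_prob) * (gain_orienting * habituation_rate^(t-1)
#' + gain_expectancy * E_t + half-normal jitter)`.
#'
#' @inheritParams latent_expectancy
#' @return object of class `scr_trace`: list with `fs`, `samples` (muS),
#'   `events` (the design event table), `truth` (per-trial latent expectancy
#'   and emitted amplitudes), `group`, `seed`.
#' @export
simulate_participant <- function(design, params = scr_gen_params(), seed = 1L,
                                 expectancy = NULL) {
  events <- design$events
  n <- nrow(events)
  E <- latent_expectancy(design, params, seed = seed, expectancy = expectancy)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)

  respond <- stats::rbinom(n, 1L, 1 - params$nonresponse_prob)
  jitter <- abs(stats::rnorm(n, 0, params$amp_noise_sd))
  orienting <- params$gain_orienting * params$habituation_rate^(seq_len(n) - 1)
  amp <- respond * (orienting + params$gain_expectancy * E + jitter)
  ur_amp <- ifelse(events$reinforced,
                   params$ur_gain + abs(stats::rnorm(n, 0, params$amp_noise_sd)), 0)

  fs <- params$fs
  t_end <- max(events$onset_abs) + 13
  n_samp <- ceiling(t_end * fs) + 1L
  samples <- rep(params$baseline, n_samp)

  kern_len <- ceiling(20 * fs)
  kern <- scr_kernel(seq_len(kern_len) / fs, params$kernel_rise, params$kernel_decay)
  add_resp <- function(samples, onset, a) {
    if (a <= 0) return(samples)
    i0 <- floor((onset + params$latency) * fs) + 1L
    idx <- i0 + seq_len(kern_len)
    keep <- idx <= n_samp
    samples[idx[keep]] <- samples[idx[keep]] + a * kern[keep]
    samples
  }
  for (k in seq_len(n)) {
    samples <- add_resp(samples, events$onset_abs[k], amp[k])
    if (ur_amp[k] > 0) samples <- add_resp(samples, events$us_onset_abs[k], ur_amp[k])
  }
  if (params$noise_sd > 0)
    samples <- samples + stats::rnorm(n_samp, 0, params$noise_sd)

  structure(list(fs = fs, samples = samples, events = events,
                 truth = data.frame(trial = seq_len(n), phase = events$phase,
                                    cs_type = events$cs_type,
                                    expectancy = E, amplitude = amp,
                                    ur_amplitude = ur_amp),
                 group = params$group, seed = seed),
            class = "scr_trace")
}

#' @export
print.scr_trace <- function(x, ...) {
  cat("Synthetic SCR trace:", length(x$samples), "samples @", x$fs, "Hz,",
      nrow(x$events), "trials, group", x$group, "\n")
  invisible(x)
}

#' Simulate a two-group cohort of skin-conductance traces
#'
#' Per-participant seeds are derived deterministically from the master seed;
#' recall counterbalance alternates within each group so both trial sequences
#' are represented. The study-scale default is 18 sham and 22 verum
#' participants.
#'
#' @param n_sham,n_verum group sizes (>= 1).
#' @param params a [scr_gen_params()]; its `group` field is overridden per
#'   participant.
#' @param seed master seed.
#' @param designs named list of the two counterbalanced designs, defaults to
#'   `build_experiment("A"/"B")` with per-participant ITI seeds.
#' @param expectancy optional named list (by counterbalance label) of
#'   per-trial expectancy vectors driving every participant's responses
#'   (e.g. model-derived prediction curves for parameter-recovery studies)
#'   instead of the internal associative process.
#' @return list of class `scr_cohort`: `traces` (list of `scr_trace`),
#'   `manifest` (data.frame: participant, group, counterbalance, seed).
#' @export
simulate_cohort <- function(n_sham = 18L, n_verum = 22L,
                            params = scr_gen_params(), seed = 1L,
                            designs = NULL, expectancy = NULL) {
  stopifnot(n_sham >= 1L, n_verum >= 1L)
  n <- n_sham + n_verum
  groups <- c(rep("sham", n_sham), rep("verum", n_verum))
  cb <- unlist(lapply(c(n_sham, n_verum),
                      function(m) rep_len(c("A", "B"), m)))
  seeds <- vapply(seq_len(n), function(k) derive_seed(seed, k), integer(1))
  traces <- vector("list", n)
  for (k in seq_len(n)) {
    p <- params; p$group <- groups[k]
    d <- if (!is.null(designs)) designs[[cb[k]]] else
      build_experiment(cb[k], seed = derive_seed(seed, 10000L + k))
    traces[[k]] <- simulate_participant(d, p, seed = seeds[k],
                                        expectancy = expectancy[[cb[k]]])
    traces[[k]]$participant <- k
    traces[[k]]$counterbalance <- cb[k]
  }
  structure(list(traces = traces,
                 manifest = data.frame(participant = seq_len(n),
                                       group = groups, counterbalance = cb,
                                       seed = seeds)),
            class = "scr_cohort")
}

#' @export
print.scr_cohort <- function(x, ...) {
  cat("Synthetic SCR cohort:", nrow(x$manifest), "participants (",
      sum(x$manifest$group == "sham"), "sham /",
      sum(x$manifest$group == "verum"), "verum )\n")
  invisible(x)
}

#' Write an SCR trace as a two-column CSV (time s, conductance muS)
#' @param trace an `scr_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time = (seq_along(trace$samples) - 1) / trace$fs,
                   conductance = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 104729 * as.numeric(k)) %% 2147483629)
}
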