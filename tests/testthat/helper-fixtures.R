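# shared fixtures, built in code at test time

# noise-free single-deflection trace: raised-cosine bump (rise r, fall r)
# on a flat tonic level; returns the raw (unfiltered) sample vector
bump_trace <- function(amp, rise, fs = 1000, onset = 4, len = 20,
                       baseline = 2) {
  t <- seq(0, len, by = 1 / fs)
  x <- rep(baseline, length(t))
  inb <- t >= onset & t <= onset + 2 * rise
  x[inb] <- x[inb] + amp * 0.5 * (1 - cos(pi * (t[inb] - onset) / rise))
  x
}

# slow reference implementation of hysteresis trough/peak detection,
# written as repeated segment scans (independent of the package's
# single-pass state machine)
ref_detect_responses <- function(s, eps) {
  n <- length(s)
  out_t <- integer(0); out_p <- integer(0)
  pos <- 1L
  repeat {
    if (pos > n) break
    seg_min <- Inf; conf <- NA_integer_
    for (ci in pos:n) {
      seg_min <- min(seg_min, s[ci])
      if (s[ci] - seg_min >= eps) { conf <- ci; break }
    }
    if (is.na(conf)) break
    trough <- max(which(s[pos:conf] == seg_min)) + pos - 1L
    seg_max <- -Inf; fall <- NA_integer_
    for (ci in conf:n) {
      seg_max <- max(seg_max, s[ci])
      if (seg_max - s[ci] >= eps) { fall <- ci; break }
    }
    if (is.na(fall)) {
      peak <- min(which(s[conf:n] == seg_max)) + conf - 1L
      out_t <- c(out_t, trough); out_p <- c(out_p, peak)
      break
    }
    peak <- min(which(s[conf:fall] == seg_max)) + conf - 1L
    out_t <- c(out_t, trough); out_p <- c(out_p, peak)
    pos <- fall
  }
  data.frame(trough = out_t, peak = out_p, amplitude = s[out_p] - s[out_t])
}

# balanced null long table: one between group, 2x2 within
null_long_table <- function(n_per_group = 20L) {
  n <- 2L * n_per_group
  data.frame(value = stats::rnorm(4L * n),
             subject = rep(seq_len(n), each = 4L),
             group = rep(c("sham", "verum"), each = 4L * n_per_group),
             stimulus = rep(c("CS+", "CS-"), 2L * n),
             block = rep(rep(c("early", "late"), each = 2L), n))
}

# tiny hand-buildable CS-window score table for fitting tests
toy_scores <- function(amplitudes, participant = 1L, cb = "A") {
  n <- length(amplitudes)
  half <- n / 2
  data.frame(participant = participant,
             phase = "acquisition",
             index_in_phase = seq_len(n),
             cs_type = rep(c("CS+", "CS-"), each = half),
             reinforced = FALSE,
             window = "CS", stim_class = rep(c("CS+", "CS-"), each = half),
             amplitude = amplitudes,
             counterbalance = cb,
             stringsAsFactors = FALSE)
}
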