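#' Scoring parameters for event-related SCR quantification
#'
#' Responses are maximum trough-to-peak deflections meeting a minimum
#' amplitude of 0.01 muS and a minimum rise time of 500 ms, with the response
#' onset (trough) falling 1--8.5 s after CS onset for the CS response window
#' and 8.5--13 s after CS onset for the unconditioned-response window; traces
#' are low-pass filtered at 10 Hz before scoring. Trials with no qualifying
#' response are scored as zero.
#'
#' @param min_amplitude minimum trough-to-peak amplitude (muS).
#' @param min_rise_time minimum trough-to-peak rise time (s).
#' @param cs_window CS response window, seconds after CS onset.
#' @param ur_window unconditioned-response window, seconds after CS onset.
#' @param lowpass_hz low-pass filter cutoff (Hz).
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(min_amplitude = 0.01, min_rise_time = 0.5,
                           cs_window = c(1.0, 8.5), ur_window = c(8.5, 13.0),
                           lowpass_hz = 10) {
  stopifnot(min_amplitude > 0, min_rise_time > 0,
            length(cs_window) == 2L, length(ur_window) == 2L,
            cs_window[1] < cs_window[2], ur_window[1] < ur_window[2],
            cs_window[2] <= ur_window[1], lowpass_hz > 0)
  structure(list(min_amplitude = min_amplitude, min_rise_time = min_rise_time,
                 cs_window = cs_window, ur_window = ur_window,
                 lowpass_hz = lowpass_hz),
            class = "scoring_params")
}

#' Zero-phase low-pass filter for conductance traces
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' replicating in software the study-grade 10 Hz hardware filter. The signal
#' is extended by odd reflection at both ends before filtering (and trimmed
#' afterwards) to suppress the start-up transients of zero initial
#' conditions.
#'
#' @param samples numeric conductance vector.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency; must be below the Nyquist rate.
#' @return filtered samples.
#' @export
scr_lowpass <- function(samples, fs, cutoff_hz = 10) {
  if (cutoff_hz >= fs / 2) stop("low-pass cutoff must be below Nyquist (fs/2)")
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  n <- length(samples)
  np <- min(n - 1L, ceiling(2 * fs / cutoff_hz) * 3L)
  head_pad <- 2 * samples[1] - samples[(np + 1L):2]
  tail_pad <- 2 * samples[n] - samples[(n - 1L):(n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, samples, tail_pad)))
  y[np + seq_len(n)]
}

#' Score the maximum qualifying trough-to-peak amplitude in a window
#'
#' Candidate responses are found by hysteresis extrema detection (see
#' [detect_responses()]): a trough (response onset) and its subsequent peak
#' are confirmed once the signal moves at least the minimum amplitude away
#' from them, so sub-resolution dips never fragment a rise and baseline
#' ripple never spawns spurious onsets. The maximum amplitude
#' (`peak - trough`) over responses with amplitude >= `min_amplitude`, rise
#' time (trough to peak) >= `min_rise_time` and onset inside the window is
#' returned -- the peak may fall up to `peak_horizon` seconds past the
#' window end; 0 if no response qualifies.
#'
#' @param samples conductance vector (already low-pass filtered; see
#'   [score_experiment()] which filters once upstream).
#' @param fs sampling rate (Hz).
#' @param window numeric length-2, window start/end in seconds on the trace
#'   clock (time 0 = first sample).
#' @param params a [scoring_params()].
#' @param peak_horizon seconds past the window end within which the peak must
#'   occur; keeps a trial's score from capturing the next trial's response on
#'   a continuous trace.
#' @return amplitude in muS (>= 0).
#' @export
score_window <- function(samples, fs, window, params = scoring_params(),
                         peak_horizon = 4) {
  n <- length(samples)
  i_lo <- floor(window[1] * fs) + 1L
  i_hi <- ceiling(window[2] * fs) + 1L
  if (i_lo < 1L || i_hi > n || i_lo >= n)
    stop("scoring window falls outside the trace")
  j_max <- min(n, ceiling((window[2] + peak_horizon) * fs) + 1L)
  # scan a segment starting shortly before the window: enough context to
  # establish the detector state without rescanning the whole trace
  i0 <- max(1L, i_lo - as.integer(ceiling(2 * fs)))
  ext <- detect_responses(samples[i0:j_max], params$min_amplitude)
  if (!nrow(ext)) return(0)
  ext$trough <- ext$trough + i0 - 1L
  ext$peak <- ext$peak + i0 - 1L
  ext <- ext[ext$trough >= i_lo & ext$trough <= i_hi, , drop = FALSE]
  if (!nrow(ext)) return(0)
  amp <- ext$amplitude
  rise <- (ext$peak - ext$trough) / fs
  amp <- amp[amp >= params$min_amplitude & rise >= params$min_rise_time - 1e-12]
  if (!length(amp)) 0 else max(amp)
}

#' Detect candidate phasic responses (trough/peak index pairs)
#'
#' Hysteresis (zigzag) extrema detection: scanning the signal, a trough is
#' confirmed at the last sample attaining the running minimum once the signal
#' has risen at least `eps` above it, and the subsequent peak is confirmed at
#' the first sample attaining the running maximum once the signal has fallen
#' at least `eps` below it (a rise still in progress at the end of the
#' segment yields a final truncated response). Excursions smaller than `eps`
#' -- measurement ripple, sub-resolution dips on a rising flank -- neither
#' start nor split a response.
#'
#' @param s numeric signal vector.
#' @param eps hysteresis threshold in the units of `s`; responses smaller
#'   than `eps` are invisible to the detector.
#' @return data.frame with `trough`, `peak` (sample indices) and `amplitude`.
#' @export
detect_responses <- function(s, eps = 0.01) {
  n <- length(s)
  out_t <- integer(0); out_p <- integer(0)
  rising <- FALSE
  min_v <- s[1]; min_i <- 1L
  max_v <- s[1]; max_i <- 1L
  trough_i <- NA_integer_
  for (i in seq_len(n)) {
    x <- s[i]
    if (!rising) {
      if (x <= min_v) { min_v <- x; min_i <- i }          # last sample of minimum
      else if (x - min_v >= eps) {
        trough_i <- min_i
        rising <- TRUE
        max_v <- x; max_i <- i
      }
    } else {
      if (x > max_v) { max_v <- x; max_i <- i }           # first sample at top
      else if (max_v - x >= eps) {
        out_t <- c(out_t, trough_i); out_p <- c(out_p, max_i)
        rising <- FALSE
        min_v <- x; min_i <- i
      }
    }
  }
  if (rising) { out_t <- c(out_t, trough_i); out_p <- c(out_p, max_i) }
  data.frame(trough = out_t, peak = out_p,
             amplitude = s[out_p] - s[out_t])
}

#' Score all trials of an experiment (CS and UR windows)
#'
#' The trace is low-pass filtered once, then every trial receives one
#' CS-window and one UR-window score. UR-window scores are labelled
#' `CS+/US`, `CS+/no-US` or `CS-` according to the trial's reinforcement.
#'
#' @param trace an `scr_trace` (or a list with `samples`, `fs`, `events`).
#' @param design optional `fear_design` overriding `trace$events`.
#' @param params a [scoring_params()].
#' @return data.frame of trial scores: `participant`, `phase`,
#'   `index_in_phase`, `cs_type`, `reinforced`, `window` (`"CS"`/`"UR"`),
#'   `stim_class`, `amplitude`.
#' @export
score_experiment <- function(trace, design = NULL, params = scoring_params()) {
  events <- if (!is.null(design)) design$events else trace$events
  if (is.null(events)) stop("no event table available")
  fs <- trace$fs
  filtered <- scr_lowpass(trace$samples, fs, params$lowpass_hz)
  t_max <- (length(filtered) - 1) / fs
  bad <- which(events$onset_abs + params$ur_window[2] > t_max |
                 events$onset_abs + params$cs_window[1] < 0)
  if (length(bad))
    stop("events outside trace for trial indices: ",
         paste(bad, collapse = ", "))
  n <- nrow(events)
  score1 <- function(win) {
    vapply(seq_len(n), function(k)
      score_window(filtered, fs, events$onset_abs[k] + win, params), numeric(1))
  }
  cs_amp <- score1(params$cs_window)
  ur_amp <- score1(params$ur_window)
  stim_class <- ifelse(events$cs_type == "CS-", "CS-",
                       ifelse(events$reinforced, "CS+/US", "CS+/no-US"))
  pid <- if (!is.null(trace$participant)) trace$participant else 1L
  base <- data.frame(participant = pid, phase = events$phase,
                     index_in_phase = events$index_in_phase,
                     cs_type = events$cs_type, reinforced = events$reinforced,
                     stringsAsFactors = FALSE)
  rbind(cbind(base, window = "CS", stim_class = events$cs_type, amplitude = cs_amp),
        cbind(base, window = "UR", stim_class = stim_class, amplitude = ur_amp))
}

# expected early/late block size per CS for each phase
.block_sizes <- c(habituation = 3L, acquisition = 8L, extinction = 8L,
                  recall = 6L)

#' Average trial scores into early/late blocks with LN(1 + SCR) transform
#'
#' Raw amplitudes are averaged per block first and the block mean is then
#' normalized as `log(1 + mean)`. The three habituation trials of each CS form
#' a single block; acquisition and extinction use the first and last eight
#' trials of each CS, recall the first and last six.
#'
#' @param scores trial-score table from [score_experiment()] (one or several
#'   participants row-bound together); only CS-window rows are used.
#' @param phases phases to include (default all four).
#' @return data.frame: `participant`, `phase`, `block` (`habituation` /
#'   `early` / `late`), `cs_type`, `n_trials`, `mean_raw`, `mean_log_scr`.
#' @export
block_average <- function(scores, phases = names(.block_sizes)) {
  cs <- scores[scores$window == "CS" & scores$phase %in% phases, ]
  out <- list()
  for (pid in unique(cs$participant)) {
    for (ph in intersect(phases, unique(cs$phase))) {
      for (ct in c("CS+", "CS-")) {
        tr <- cs[cs$participant == pid & cs$phase == ph & cs$cs_type == ct, ]
        tr <- tr[order(tr$index_in_phase), ]
        m <- .block_sizes[[ph]]
        if (ph == "habituation") {
          if (nrow(tr) != m)
            stop("habituation requires ", m, " trials per CS, got ", nrow(tr))
          blocks <- list(habituation = tr$amplitude)
        } else {
          if (nrow(tr) != 2L * m)
            stop(ph, " requires ", 2L * m, " trials per CS, got ", nrow(tr))
          blocks <- list(early = tr$amplitude[seq_len(m)],
                         late = tr$amplitude[m + seq_len(m)])
        }
        for (b in names(blocks)) {
          mr <- mean(blocks[[b]])
          out[[length(out) + 1L]] <- data.frame(
            participant = pid, phase = ph, block = b, cs_type = ct,
            n_trials = length(blocks[[b]]), mean_raw = mr,
            mean_log_scr = log1p(mr), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Differential SCRs per block
#'
#' `SCR_diff` = block mean log SCR to CS+ minus block mean log SCR to CS-.
#'
#' @param blocks output of [block_average()].
#' @return data.frame: `participant`, `phase`, `block`, `scr_diff`.
#' @export
scr_diff <- function(blocks) {
  key <- interaction(blocks$participant, blocks$phase, blocks$block, drop = TRUE)
  out <- lapply(split(blocks, key), function(d) {
    if (!all(c("CS+", "CS-") %in% d$cs_type)) return(NULL)
    data.frame(participant = d$participant[1], phase = d$phase[1],
               block = d$block[1],
               scr_diff = d$mean_log_scr[d$cs_type == "CS+"] -
                 d$mean_log_scr[d$cs_type == "CS-"],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a whole cohort
#'
#' @param cohort an `scr_cohort` from [simulate_cohort()].
#' @param params a [scoring_params()].
#' @return trial-score table over all participants with `group` and
#'   `counterbalance` columns attached.
#' @export
score_cohort <- function(cohort, params = scoring_params()) {
  out <- lapply(cohort$traces, function(tr) {
    s <- score_experiment(tr, params = params)
    s$group <- tr$group
    s$counterbalance <- tr$counterbalance
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
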