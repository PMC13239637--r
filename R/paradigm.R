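#' Phase specification for the two-day differential conditioning paradigm
#'
#' A phase is described by how many reinforced CS+ trials (CS+ followed by the
#' aversive US), unreinforced CS+ trials and CS- trials it contains. Only the
#' acquisition phase may contain reinforced trials.
#'
#' @param name one of `"habituation"`, `"acquisition"`, `"extinction"`,
#'   `"recall"`.
#' @param n_paired_csplus number of reinforced (paired CS+/US) trials.
#' @param n_unpaired_csplus number of CS+ only trials.
#' @param n_csminus number of CS- trials.
#' @return an object of class `phase_spec`.
#' @export
phase_spec <- function(name, n_paired_csplus, n_unpaired_csplus, n_csminus) {
  name <- match.arg(name, c("habituation", "acquisition", "extinction", "recall"))
  counts <- c(n_paired_csplus, n_unpaired_csplus, n_csminus)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("trial counts must be non-negative integers")
  if (name != "acquisition" && n_paired_csplus > 0)
    stop("only the acquisition phase may contain reinforced trials")
  structure(list(name = name,
                 n_paired_csplus = as.integer(n_paired_csplus),
                 n_unpaired_csplus = as.integer(n_unpaired_csplus),
                 n_csminus = as.integer(n_csminus)),
            class = "phase_spec")
}

#' Canonical phase specifications of the two-day paradigm
#'
#' Habituation: 3 CS+ only, 3 CS-; acquisition: 10 paired CS+/US, 6 CS+ only,
#' 16 CS- (62.5% reinforcement of CS+); extinction: 16 CS+ only, 16 CS-;
#' recall: 12 CS+ only, 12 CS-.
#'
#' @return named list of `phase_spec` objects.
#' @export
canonical_phase_specs <- function() {
  list(habituation = phase_spec("habituation", 0, 3, 3),
       acquisition = phase_spec("acquisition", 10, 6, 16),
       extinction  = phase_spec("extinction", 0, 16, 16),
       recall      = phase_spec("recall", 0, 12, 12))
}

# trial timing constants (seconds)
.CS_DURATION <- 8.0
.US_DELAY <- 7.9
.ITI_MIN <- 14.3
.ITI_MAX <- 17.9
.INTER_PHASE_GAP <- 60
.PRE_EXTINCTION_FIXATION <- 120
# internal seed fixing the day-1 (and base recall) presentation order so that
# the order is identical for every simulated participant
.CANONICAL_ORDER_SEED <- 183571L

# split per-kind counts between the two phase halves; exact split for even
# counts, |difference| <= 1 for odd counts where the half sizes allow, totals
# matching the half sizes
.split_halves <- function(counts, half1_size) {
  c1 <- counts %/% 2L
  if (half1_size > sum(counts) || half1_size < 0) stop("infeasible half split")
  while (sum(c1) < half1_size) {
    odd <- which(counts %% 2L == 1L & c1 == counts %/% 2L)
    cand <- if (length(odd)) odd else which(c1 < counts)
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    c1[pick] <- c1[pick] + 1L
  }
  while (sum(c1) > half1_size) {
    odd <- which(counts %% 2L == 1L & c1 > counts %/% 2L)
    cand <- if (length(odd)) odd else which(c1 > 0L)
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    c1[pick] <- c1[pick] - 1L
  }
  c1
}

# pseudorandom ordering of trial kinds for one phase.
# kinds: "P" = paired CS+/US, "U" = CS+ only, "M" = CS- only.
# Constraints: each kind split (near-)equally across halves; in acquisition the
# first two and the last trial are paired; optionally the first trial's CS type
# is forced (recall counterbalancing).
.phase_order <- function(spec, first_cs = NULL) {
  counts <- c(P = spec$n_paired_csplus, U = spec$n_unpaired_csplus,
              M = spec$n_csminus)
  n <- sum(counts)
  if (n < 2L) stop("phase must contain at least 2 trials")
  if (spec$name == "acquisition" && counts["P"] < 3L)
    stop("acquisition requires at least 3 paired trials (first two and last)")
  half1_n <- n %/% 2L
  if (spec$name == "acquisition") {
    # paired trials split first so both fixed-position constraints are
    # satisfiable (two at the start of half 1, one at the end of half 2)
    c1 <- counts
    c1["P"] <- max(2L, as.integer(ceiling(counts["P"] / 2)))
    c1[c("U", "M")] <- .split_halves(counts[c("U", "M")],
                                     half1_n - c1[["P"]])
  } else {
    c1 <- .split_halves(counts, half1_n)
  }
  c2 <- counts - c1
  expand <- function(cn) rep(names(counts), times = cn)
  if (spec$name == "acquisition") {
    if (c1["P"] < 2L || c2["P"] < 1L)
      stop("acquisition half split cannot place the fixed paired trials")
    h1 <- c("P", "P", sample(expand(c1 - c(P = 2L, U = 0L, M = 0L))))
    rest2 <- sample(expand(c2 - c(P = 1L, U = 0L, M = 0L)))
    h2 <- c(rest2, "P")
  } else if (!is.null(first_cs)) {
    want <- if (first_cs == "CS+") "U" else "M"
    if (c1[want] < 1L) stop("cannot start phase with requested CS type")
    dec <- c(P = 0L, U = 0L, M = 0L); dec[want] <- 1L
    h1 <- c(want, sample(expand(c1 - dec)))
    h2 <- sample(expand(c2))
  } else {
    h1 <- sample(expand(c1))
    h2 <- sample(expand(c2))
  }
  c(h1, h2)
}

.events_from_order <- function(kinds, phase, itis) {
  n <- length(kinds)
  stopifnot(length(itis) == n)
  cs_type <- ifelse(kinds == "M", "CS-", "CS+")
  reinforced <- kinds == "P"
  # onset accumulates CS duration + preceding ITI; time 0 = first CS onset
  cs_onset <- cumsum(c(0, (.CS_DURATION + itis)[-n]))
  data.frame(phase = phase,
             index_in_phase = seq_len(n),
             cs_type = cs_type,
             reinforced = reinforced,
             cs_onset = cs_onset,
             cs_duration = .CS_DURATION,
             us_onset = cs_onset + .US_DELAY,
             iti = itis,
             stringsAsFactors = FALSE)
}

#' Build a pseudorandomized trial sequence for one phase
#'
#' Ordering constraints: each trial kind is split equally between the first and
#' second half of the phase (to within one trial when a kind has an odd count),
#' and in acquisition the first two and the last trial are reinforced CS+/US
#' trials. Inter-trial intervals are drawn i.i.d. uniform on \[14.3, 17.9\] s;
#' the US (or the no-US marker on unreinforced trials) falls 7.9 s after CS
#' onset.
#'
#' @param spec a [phase_spec()].
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @param first_cs optionally force the CS type of the first trial
#'   (`"CS+"` or `"CS-"`), used for recall counterbalancing.
#' @return data.frame of trial events (one row per trial) with columns
#'   `phase`, `index_in_phase`, `cs_type`, `reinforced`, `cs_onset`,
#'   `cs_duration`, `us_onset`, `iti` (times in seconds from phase start).
#' @export
build_phase_sequence <- function(spec, seed, first_cs = NULL) {
  stopifnot(inherits(spec, "phase_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  kinds <- .phase_order(spec, first_cs = first_cs)
  itis <- stats::runif(length(kinds), .ITI_MIN, .ITI_MAX)
  .events_from_order(kinds, spec$name, itis)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Build the full two-day experiment design
#'
#' Day 1 comprises habituation, acquisition and extinction; day 2 the recall
#' phase. The presentation order of day-1 trials is fixed (identical for all
#' participants) by an internal canonical seed; the user seed affects only the
#' inter-trial-interval draws. The recall phase is counterbalanced: sequence
#' `"A"` opens with a CS+ trial, sequence `"B"` with a CS- trial, and these are
#' the only two distinct recall orderings the generator produces.
#'
#' Phases are laid out on an absolute session clock (`onset_abs`,
#' `us_onset_abs`) with a 60 s gap between phases and an additional 120 s
#' fixation period before extinction; trial indices and phase-relative onsets
#' are unaffected by these offsets.
#'
#' @param counterbalance_id `"A"` (recall opens with CS+) or `"B"` (CS-).
#' @param seed integer seed for the ITI draws.
#' @param specs phase specifications, by default [canonical_phase_specs()].
#' @return object of class `fear_design`: list with `events` (data.frame over
#'   all four phases, incl. absolute onsets), `counterbalance`,
#'   `phase_offsets`.
#' @export
build_experiment <- function(counterbalance_id = c("A", "B"), seed = 1L,
                             specs = canonical_phase_specs()) {
  counterbalance_id <- match.arg(counterbalance_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # canonical, participant-invariant ordering
  set.seed(.CANONICAL_ORDER_SEED)
  orders <- list(
    habituation = .phase_order(specs$habituation),
    acquisition = .phase_order(specs$acquisition),
    extinction  = .phase_order(specs$extinction),
    recall      = .phase_order(specs$recall,
                               first_cs = if (counterbalance_id == "A") "CS+" else "CS-"))

  # participant-specific ITIs
  set.seed(seed)
  phases <- names(orders)
  ev <- lapply(phases, function(ph) {
    itis <- stats::runif(length(orders[[ph]]), .ITI_MIN, .ITI_MAX)
    .events_from_order(orders[[ph]], ph, itis)
  })
  names(ev) <- phases

  offsets <- numeric(length(phases)); names(offsets) <- phases
  t_cursor <- 0
  for (ph in phases) {
    if (ph == "extinction") t_cursor <- t_cursor + .PRE_EXTINCTION_FIXATION
    offsets[ph] <- t_cursor
    last <- ev[[ph]][nrow(ev[[ph]]), ]
    t_cursor <- offsets[ph] + last$cs_onset + .CS_DURATION + last$iti + .INTER_PHASE_GAP
  }

  events <- do.call(rbind, ev)
  events$onset_abs <- events$cs_onset + offsets[events$phase]
  events$us_onset_abs <- events$us_onset + offsets[events$phase]
  rownames(events) <- NULL
  structure(list(events = events,
                 counterbalance = counterbalance_id,
                 phase_offsets = offsets),
            class = "fear_design")
}

#' @export
print.fear_design <- function(x, ...) {
  tab <- table(x$events$phase, x$events$cs_type)
  cat("Two-day differential conditioning design (counterbalance ",
      x$counterbalance, ")\n", sep = "")
  cat(nrow(x$events), "trials;", sum(x$events$reinforced), "reinforced\n")
  print(tab[c("habituation", "acquisition", "extinction", "recall"), ])
  invisible(x)
}

#' Validate a design against the paradigm constraints
#'
#' Report-only checker: each constraint of the paradigm (per-phase trial
#' composition, acquisition first-two/last-trial reinforcement, equal halves,
#' ITI range, US timing, reinforcement restricted to CS+, increasing onsets)
#' is listed with a pass/fail flag.
#'
#' @param design a `fear_design` or a trial-event data.frame.
#' @param specs expected phase composition, default [canonical_phase_specs()].
#' @return data.frame with columns `check`, `phase`, `pass`, `detail`.
#' @export
validate_design <- function(design, specs = canonical_phase_specs()) {
  events <- if (inherits(design, "fear_design")) design$events else design
  out <- list()
  add <- function(check, phase, pass, detail = "") {
    out[[length(out) + 1L]] <<- data.frame(check = check, phase = phase,
                                           pass = pass, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  for (ph in names(specs)) {
    e <- events[events$phase == ph, ]
    sp <- specs[[ph]]
    got <- c(P = sum(e$reinforced),
             U = sum(e$cs_type == "CS+" & !e$reinforced),
             M = sum(e$cs_type == "CS-"))
    want <- c(P = sp$n_paired_csplus, U = sp$n_unpaired_csplus, M = sp$n_csminus)
    add("composition", ph, all(got == want),
        paste0("paired=", got["P"], "/", want["P"],
               " cs+only=", got["U"], "/", want["U"],
               " cs-=", got["M"], "/", want["M"]))
    # equal halves (within one trial for odd per-kind counts)
    n <- nrow(e)
    if (n >= 2L) {
      half1 <- seq_len(n %/% 2L)
      kind <- ifelse(e$reinforced, "P", ifelse(e$cs_type == "CS+", "U", "M"))
      ok <- TRUE
      for (k in c("P", "U", "M")) {
        k1 <- sum(kind[half1] == k); k2 <- sum(kind[-half1] == k)
        tol <- if (sum(kind == k) %% 2L == 0L) 0L else 1L
        if (abs(k1 - k2) > tol) ok <- FALSE
      }
      add("equal-halves", ph, ok, "")
    }
    if (n > 0L) {
      add("iti-range", ph, all(e$iti >= .ITI_MIN & e$iti <= .ITI_MAX), "")
      add("us-timing", ph, all(abs(e$us_onset - e$cs_onset - .US_DELAY) < 1e-9), "")
      add("reinforced-cs+", ph, all(e$cs_type[e$reinforced] == "CS+"), "")
      add("onsets-increasing", ph, all(diff(e$cs_onset) > 0), "")
    }
  }
  acq <- events[events$phase == "acquisition", ]
  if (nrow(acq) >= 3L) {
    add("first-two-paired", "acquisition", all(acq$reinforced[1:2]), "")
    add("last-trial-paired", "acquisition", acq$reinforced[nrow(acq)], "")
  }
  do.call(rbind, out)
}

#' Write / read a design event table as CSV
#'
#' One row per trial event; round-trips through [read_design()].
#' @param design a `fear_design` object.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "fear_design"))
  utils::write.csv(design$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @return for `read_design`, a `fear_design` (counterbalance inferred from
#'   the first recall trial).
#' @export
read_design <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec <- events[events$phase == "recall", ]
  cb <- if (nrow(rec) && rec$cs_type[1] == "CS-") "B" else "A"
  offsets <- tapply(events$onset_abs - events$cs_onset, events$phase, function(x) x[1])
  structure(list(events = events, counterbalance = cb,
                 phase_offsets = offsets),
            class = "fear_design")
}
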