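---
title: "Models and methods behind fearreplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fearreplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearreplay)
```

This vignette is the package's own account of its science: the paradigm it
generates, the synthetic electrodermal data it simulates, the scoring and
statistical conventions it applies, the learning model it fits, and the
design choices made where the underlying methodology left the design open.

## The two-day paradigm

`build_experiment()` produces the constrained trial sequences of a
differential fear-conditioning experiment: habituation (3 CS+ only / 3 CS−),
acquisition (10 paired CS+/US, 6 CS+ only, 16 CS−; a 62.5% partial
reinforcement rate for the CS+), extinction (16/16) on day 1, and recall
(12/12) on day 2. Ordering constraints: the first two and the last
acquisition trials are reinforced, and each trial kind is split equally
between the halves of every phase. Habituation has an odd per-kind count
(3), so an exact split is impossible there; the generator and
`validate_design()` use a within-one-trial tolerance for odd counts and an
exact split everywhere else.

Design choices in this module:

* **Day-1 order is fixed by an internal canonical seed**, making the order
  identical for all simulated participants, as the experimental protocol
  requires; the user seed only draws the inter-trial intervals, which were
  participant-specific.
* **ITIs are i.i.d. uniform on [14.3, 17.9] s** — the protocol states the
  range but not the distribution; uniform is the minimal assumption.
* **Exactly two recall orderings exist** (counterbalance A opens with CS+,
  B with CS−). We take the two sequences to differ only in this
  counterbalance, not in CS-figure assignment, since only ordering enters
  the curve averaging downstream.
* **Time origin** is phase-relative (0 = first CS onset); phases are laid
  out on an absolute session clock with a 60 s inter-phase gap and the
  120 s pre-extinction fixation period recorded as an offset. Trial indices
  never depend on these offsets.

## Synthetic skin-conductance traces

`simulate_participant()` builds a trace as tonic baseline plus one phasic
response per trial, an unconditioned response on reinforced trials, and
Gaussian measurement noise. The phasic shape is a bi-exponential kernel
(`scr_kernel()`, rise 0.6 s / decay 2.0 s time constants, unit peak
amplitude ~1.03 s after response onset, support < 10 s), a standard
sudomotor response approximation. Trial amplitude is

> Bernoulli(1 − nonresponse_prob) × (orienting + expectancy gain × E_t +
> half-normal jitter)

with the orienting component decaying multiplicatively per trial
(habituation). The latent expectancy E_t follows a per-stimulus delta-rule
update (learning rate 0.2, jittered across participants): zero in
habituation, rising under partial reinforcement, decaying across
extinction. In the **sham** group only, a recovery boost (+0.35) raises E
on the first six recall CS+ trials — the spontaneous-recovery signature the
verum (stimulation) group lacks.

Key choices and caveats:

* Default sampling rate is 100 Hz rather than recording-hardware rates
  (kHz); trough-to-peak scoring is rate-independent well below that, and
  the acceptance analyses use 1 kHz where millisecond resolution matters.
* Response latency is fixed at 1.5 s after stimulus onset, inside the CS
  scoring window; physiological latencies vary, but a fixed value keeps
  ground truth exact.
* The generator's expectancy process is deliberately **not** the replay
  model: fitting the model to generated data is therefore a genuine
  recovery exercise, not a self-fit.
* Amplitude gains are calibrated only to directionality (acquisition
  CS+ > CS−, extinction decay, sham-only early-recall differential); no
  claim is made that absolute microsiemens values match human data. Real
  traces additionally contain motion artifacts, slow tonic drift and
  non-stationary noise that the generator does not emulate, so green tests
  here demonstrate pipeline correctness, not robustness to every
  real-world artifact.

## SCR scoring

`score_experiment()` low-pass filters the trace once (4th-order
Butterworth, 10 Hz, zero-phase `filtfilt`, with odd-reflection padding to
suppress edge transients — replicating the hardware filter of typical
recording systems) and scores two windows per trial: the CS response window
(onsets 1–8.5 s after CS onset) and the unconditioned-response window
(8.5–13 s). A response must have trough-to-peak amplitude ≥ 0.01 μS and
rise time ≥ 500 ms; otherwise the trial scores zero but stays in the
analysis.

Candidate responses come from hysteresis (zigzag) extrema detection
(`detect_responses()`): a trough is confirmed at the last sample of a
running minimum once the signal has risen at least the minimum amplitude
above it, and its peak at the first sample of the subsequent running
maximum once the signal has fallen equally far below. This makes the
detector immune to sub-resolution ripple, which would otherwise either
fragment one rise into several or let an arbitrarily early pseudo-trough
defeat the rise-time criterion. The "window" membership applies to the
response onset; the peak may fall later (bounded by a 4 s horizon so a
trial cannot capture the next trial's response).

Averaging follows the stated order of operations — raw amplitudes are
averaged per block first, then LN(1 + mean) transformed — with blocks of 3
(habituation, single block), 8 (acquisition/extinction early/late) and 6
(recall early/late) trials per CS. `scr_diff()` is the per-block CS+ − CS−
difference of the transformed means. Rise time is trough-to-peak with no
upper cap.

## The replay-trained value model

`run_agent()` trains a value network — two fully connected hidden layers of
64 units and a sigmoid output giving the shock probability — across the
whole virtual experiment. Per trial: predict v_t *before* any update,
compute δ_t = r_t − v_t, store the experience tuple, then replay `i`
batches of size `b` sampled with replacement with probabilities
proportional to λ^τ (τ = trials since storage), optionally × |δ| when the
RPE flag is on (falling back to recency if all RPE priorities vanish).
Between the days, `sleep_replay()` performs exactly 100 updates of
batch size 64 with softmax(β·r) reactivation probabilities; with β > 0 this
preferentially replays the reinforced acquisition experiences and restores
the extinguished CS+ prediction — spontaneous recovery. With sleep replay
disabled the prediction carries over unchanged, so no recovery occurs;
`recovery_check()` quantifies both.

Training details the methodology leaves open, fixed here as explicit
configuration: MSE loss toward the reinforcement target, plain SGD with
learning rate 0.01, ReLU hidden activations, He-style Gaussian weight
initialization, seedable per agent. The two stimuli are encoded as fixed
orthogonal equal-norm 8-bit binary patterns (`stimulus_codes()`); any fixed
distinct encoding serves. Habituation trials are experienced and stored
with r = 0. Memory is unbounded (94 experiences at most). Priorities are
recomputed at every sampling call; RPE priorities use the stored δ, since
the tuple is what memory holds. The learning rate was calibrated once so
that the default configuration occupies the penalty-free region defined
below (safety learning and successful extinction); the package's
acceptance checks rely only on that qualitative regime, never on exact
prediction values.

`run_ensemble()` averages 25 (default) independently initialized agents per
trial and per presentation ordinal, yielding the curve
V̄ = (v̄+,1..N, v̄−,1..N) with N = 47 presentations per CS type across the
full experiment.

## Hyper-parameter fitting

`average_scr_curves()` builds the target Ȳ_l per trial sequence l: the
across-participant mean of log-transformed CS-window trial scores per
presentation ordinal, CS+ ordinals first. Trial-level log scores are used
because the LN(1+SCR) scale is the quantity analyzed throughout the SCR
statistics. Ȳ (log-μS) and V̄ (probabilities) live on different scales;
both curves are **min–max normalized to [0, 1]** over their 2N entries
before comparison (with an epsilon guard mapping constant curves to zero).
A per-sequence linear rescaling would be the main alternative; min–max is
simpler, monotone and parameter-free, and is applied identically to both
curves.

The goodness of fit is F̄ = −Σ_l w_l ‖Ȳ_l − V̄_l‖ − P_Saf − P_Ext with the
L1 norm by default (configurable to L2) and penalties P_Saf = 10 when the
mean prediction over the last 4 acquisition CS− presentations is ≥ 0.1,
P_Ext = 10 when the mean over the last 4 extinction CS+ presentations is
≥ 0.15 (boundaries penalized). The penalties are *subtracted*: a
maximization target that added them would reward the failures they are
meant to punish, so the package implements the evident intent rather than
a literal addition. F̄ ≤ 0 always, with 0 at a perfect penalty-free fit.

`fit_replay_model()` evaluates an ensemble per configuration and sequence
over a grid — the full space is b ∈ {1, 16, 32, 64, 96, 128},
λ ∈ {0.05, 0.4, 0.5, 0.6, 0.7, 0.8, 0.825, 0.85, 0.895, 1}, i ∈ 1..12,
β ∈ 1..5, RPE ∈ {Yes, No} (7200 configurations, `table1_grid()`) — and
returns the full surface plus the best configuration, breaking ties
lexicographically on (b, λ, i, β, RPE). The desk-scale default
(`default_grid()`: 108 configurations, 5 agents) keeps an interactive fit
in the minutes range; the package's own recovery analyses use a further
reduced grid (18 configurations over b, λ, i at fixed β and RPE, 3 agents,
cohorts of 8) so that multi-seed recovery runs complete in a few minutes on
one core. At those sizes, data simulated from a known grid point is
recovered to the true or an adjacent configuration within the top 3 of the
surface.

## Parametric-modulation export

`build_modulators()` turns the fitted ensemble's per-trial quantities into
FSL three-column EV regressors per phase: CS events (all CS types grouped)
weighted by the mean prediction, US/no-US events (7.9 s after CS onset)
weighted by the mean absolute prediction error. Event durations are 0 s.
Weights are mean-centered per regressor — the standard convention for
parametric modulators, made explicit here rather than left to downstream
GLM software. `write_fsl_ev3()` uses a fixed 6-decimal format that
round-trips bit-exactly.

## Rank-based statistics

`ats()` implements the midrank ANOVA-type statistic for one
between-subjects factor (group) and one or two within-subjects factors
(stimulus, block): all observations are jointly midranked; cell relative
effects p̂ = (mean cell midrank − 1/2)/N and their subject-level covariance
(estimated per group from the subject rank vectors) enter
F = p̂'Tp̂ / tr(TV̂) per effect, with T the corresponding
centering/averaging projection and numerator degrees of freedom
tr(TV̂)²/tr((TV̂)²). p-values use the F distribution with the
**denominator degrees of freedom set to infinity**, the variant recommended
against type-I inflation for skewed data and small samples. Degenerate
rank-constant data yields statistic 0 and p = 1. A 2000-replication null
simulation (20 subjects per group) in the test suite confirms type-I error
within [0.03, 0.07] at α = 0.05 for every main effect and interaction.

`relative_treatment_effects()` reports the per-cell RTE against the pooled
sample as the reference distribution (the standard convention), whose
sample-size-weighted mean is 0.5 exactly, with subject-level bootstrap
percentile confidence intervals (1000 seeded replicates by default; the
method for the interval is a package choice, as none is canonical).
`posthoc_cellwise()` compares effect cells pairwise on the asymptotic
normal scale of the cell relative effects with Tukey–Kramer
(studentized-range, infinite df) family-wise adjustment. Factor levels are
ordered bytewise (locale-independent) so results are identical across
platforms.

## Numerical and reproducibility choices

* All randomness flows through integer seeds; sub-seeds for participants,
  agents and stages derive deterministically from the master seed (kept
  below 2³¹). Generators save and restore the global RNG state.
* Probability vectors are validated to sum to 1 within 1e-12; min–max
  normalization guards constant curves with a 1e-12 epsilon; demeaned
  modulator sets sum to 0 within 1e-9.
* The scorer's hysteresis threshold equals the minimum amplitude criterion,
  so the detector cannot resolve (and therefore never scores) deflections
  the criteria would reject anyway.
* Ties in the grid search break lexicographically, making the selected
  configuration unique and platform-independent.

## Known limitations

* The ATS with infinite denominator df is mildly liberal for the
  between-subjects effect at small group sizes (observed ≈ 0.06–0.07 at
  n = 20/group); finite-df variants would trade this against power.
* The generator's noise model (white Gaussian plus half-normal amplitude
  jitter) understates the autocorrelated artifacts of real recordings.
* Model fitting targets group-averaged curves, as in the underlying
  methodology; per-participant fitting is out of scope.
* The exported EV files cover the modulator construction only; no GLM,
  HRF convolution or imaging computation is performed.
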