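#' Group-averaged SCR curves for one trial sequence
#'
#' Builds the target curve `Y-bar_l = (y+_1..N, y-_1..N)`: for every
#' presentation ordinal of each CS type (counted over the whole experiment in
#' presentation order), the mean across participants of the log-transformed
#' CS-window trial score `log(1 + amplitude)`. The curve is min-max
#' normalized to \[0, 1\] over all 2N entries (guarded for constant curves)
#' so it is comparable to the model's probability-scale predictions.
#'
#' @param scores CS-window trial scores ([score_experiment()] /
#'   [score_cohort()] output) for the participants of one trial sequence.
#' @param normalize min-max normalize the curve (default `TRUE`).
#' @return list: `ybar` (numeric 2N), `n` (participants contributing),
#'   `layout` (data.frame cs_type, ordinal, phase).
#' @export
average_scr_curves <- function(scores, normalize = TRUE) {
  cs <- scores[scores$window == "CS", ]
  if (!nrow(cs)) stop("no CS-window scores supplied")
  phase_lv <- c("habituation", "acquisition", "extinction", "recall")
  cs <- cs[order(cs$participant,
                 factor(cs$phase, levels = phase_lv), cs$index_in_phase), ]
  pids <- unique(cs$participant)
  per <- split(cs, cs$participant)
  n_trials <- unique(vapply(per, nrow, integer(1)))
  if (length(n_trials) != 1L)
    stop("participants have mismatched trial counts")
  ref <- per[[1]]
  for (p in per) {
    if (!identical(p$cs_type, ref$cs_type) || !identical(p$phase, ref$phase))
      stop("participants have mismatched trial sequences")
  }
  logamp <- vapply(per, function(p) log1p(p$amplitude), numeric(n_trials))
  m <- rowMeans(as.matrix(logamp))
  ord <- stats::ave(seq_len(n_trials), ref$cs_type, FUN = seq_along)
  layout <- data.frame(cs_type = ref$cs_type, ordinal = ord, phase = ref$phase,
                       stringsAsFactors = FALSE)
  o <- order(factor(layout$cs_type, levels = c("CS+", "CS-")), layout$ordinal)
  ybar <- m[o]
  layout <- layout[o, ]; rownames(layout) <- NULL
  if (normalize) ybar <- minmax_normalize(ybar)
  list(ybar = ybar, n = length(pids), layout = layout)
}

#' Min-max normalize a curve to \[0, 1\]
#'
#' Constant curves (range below `eps`) map to all zeros.
#' @param x numeric vector.
#' @param eps guard for constant curves.
#' @return normalized vector.
#' @export
minmax_normalize <- function(x, eps = 1e-12) {
  r <- range(x)
  if (diff(r) < eps) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

# mean model prediction over the last 4 CS- presentations of acquisition
vbar_acq_end <- function(trace) {
  v <- trace$v[trace$phase == "acquisition" & trace$cs_type == "CS-"]
  mean(utils::tail(v, 4L))
}
# mean model prediction over the last 4 CS+ presentations of extinction
vbar_ext_end <- function(trace) {
  v <- trace$v[trace$phase == "extinction" & trace$cs_type == "CS+"]
  mean(utils::tail(v, 4L))
}

#' Safety-learning and extinction penalties
#'
#' `penalty_saf` is 10 when the mean US prediction over the last 4 CS-
#' presentations of acquisition is >= 0.1 (the model failed to learn that
#' CS- is safe), else 0. `penalty_ext` is 10 when the mean prediction over
#' the last 4 CS+ presentations of extinction is >= 0.15 (failure to
#' extinguish), else 0. Boundaries are penalized (inclusive >=).
#'
#' @param x either the scalar end-of-phase mean prediction, or an
#'   `ensemble_trace` / `agent_trace` / per-trial trace data.frame from which
#'   it is computed.
#' @return 0 or 10, with the thresholded value as attribute `"value"`.
#' @export
penalty_saf <- function(x) {
  v <- if (is.numeric(x) && length(x) == 1L) x else
    vbar_acq_end(if (is.data.frame(x)) x else x$trace)
  structure(if (v >= 0.1) 10 else 0, value = v)
}

#' @rdname penalty_saf
#' @export
penalty_ext <- function(x) {
  v <- if (is.numeric(x) && length(x) == 1L) x else
    vbar_ext_end(if (is.data.frame(x)) x else x$trace)
  structure(if (v >= 0.15) 10 else 0, value = v)
}

#' Penalized goodness of fit
#'
#' `F-bar = -sum_l w_l * ||Y-bar_l - V-bar_l|| - P_Saf - P_Ext`, larger is
#' better (0 at a perfect penalty-free fit). The norm is L1 over the 2N curve
#' entries by default, configurable to L2. The penalties reduce the fit.
#'
#' @param ybars list of target curves (numeric vectors), one per sequence.
#' @param vbars list of model curves, matching lengths.
#' @param weights numeric, participants per sequence (`w_l`).
#' @param p_saf,p_ext penalty values (0 or 10).
#' @param norm `"l1"` or `"l2"`.
#' @return scalar F-bar.
#' @export
goodness_of_fit <- function(ybars, vbars, weights, p_saf = 0, p_ext = 0,
                            norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  if (!is.list(ybars)) ybars <- list(ybars)
  if (!is.list(vbars)) vbars <- list(vbars)
  stopifnot(length(ybars) == length(vbars), length(weights) == length(ybars))
  mism <- 0
  for (l in seq_along(ybars)) {
    if (length(ybars[[l]]) != length(vbars[[l]]))
      stop("curve length mismatch for sequence ", l)
    d <- ybars[[l]] - vbars[[l]]
    mism <- mism + weights[l] * switch(norm, l1 = sum(abs(d)),
                                       l2 = sqrt(sum(d^2)))
  }
  -mism - as.numeric(p_saf) - as.numeric(p_ext)
}

#' Fit the replay-trained value model to group-averaged SCR curves
#'
#' The central fitting routine: a grid search over the replay-model
#' hyper-parameters (batch size b, recency decay lambda, replays per trial i,
#' sleep-replay inverse temperature beta, RPE-weighted priorities). For every
#' configuration an ensemble of agents is trained on each trial sequence, the
#' per-ordinal averaged predictions `V-bar_l` are compared to the observed
#' `Y-bar_l` under the penalized goodness of fit [goodness_of_fit()], and the
#' configuration with the best (largest) fit is selected; ties break
#' lexicographically on (b, lambda, i, beta, RPE).
#'
#' @param scores CS-window trial-score table over all participants, with a
#'   `counterbalance` column giving each participant's trial sequence.
#' @param designs named list of `fear_design` objects, one per sequence
#'   label appearing in `scores$counterbalance`.
#' @param grid named list of hyper-parameter grid vectors (`b`, `lambda`,
#'   `i`, `beta`, `rpe`), e.g. [default_grid()] or [table1_grid()].
#' @param n_agents ensemble size per configuration and sequence.
#' @param seed master seed; agent seeds are derived deterministically.
#' @param norm curve norm for the mismatch term, `"l1"` (default) or `"l2"`.
#' @param normalize min-max normalize both curve sets before comparison.
#' @param verbose print progress.
#' @return object of class `replay_fit`.
#' @export
fit_replay_model <- function(scores, designs, grid = default_grid(),
                             n_agents = 5L, seed = 1L,
                             norm = c("l1", "l2"), normalize = TRUE,
                             verbose = FALSE) {
  norm <- match.arg(norm)
  stopifnot(all(c("b", "lambda", "i", "beta", "rpe") %in% names(grid)))
  configs <- expand.grid(b = grid$b, lambda = grid$lambda, i = grid$i,
                         beta = grid$beta, rpe = grid$rpe,
                         KEEP.OUT.ATTRS = FALSE)
  if (!nrow(configs)) stop("empty hyper-parameter grid")
  ls <- sort(unique(scores$counterbalance))
  if (!length(ls)) stop("scores lack a counterbalance column with sequences")
  if (!all(ls %in% names(designs)))
    stop("designs must be supplied for sequences: ", paste(ls, collapse = ", "))
  targets <- lapply(ls, function(l)
    average_scr_curves(scores[scores$counterbalance == l, ],
                       normalize = normalize))
  names(targets) <- ls
  weights <- vapply(targets, `[[`, numeric(1), "n")

  eval_config <- function(hp, keep = FALSE) {
    ens <- lapply(seq_along(ls), function(li)
      run_ensemble(designs[[ls[li]]], hp, n_agents,
                   seed = derive_seed(seed, 100L + li)))
    vbars <- lapply(ens, function(e) {
      v <- e$curve$v
      if (normalize) minmax_normalize(v) else v
    })
    acq_end <- mean(vapply(ens, function(e) vbar_acq_end(e$trace), numeric(1)))
    ext_end <- mean(vapply(ens, function(e) vbar_ext_end(e$trace), numeric(1)))
    ps <- penalty_saf(acq_end); pe <- penalty_ext(ext_end)
    f <- goodness_of_fit(lapply(targets, `[[`, "ybar"), vbars, weights,
                         p_saf = ps, p_ext = pe, norm = norm)
    out <- list(f = f, p_saf = as.numeric(ps), p_ext = as.numeric(pe),
                vbar_acq_end = acq_end, vbar_ext_end = ext_end)
    if (keep) { out$ens <- ens; out$vbars <- vbars }
    out
  }

  surf <- vector("list", nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    hp <- hyper_params(b = configs$b[ci], lambda = configs$lambda[ci],
                       i = configs$i[ci], beta = configs$beta[ci],
                       rpe = configs$rpe[ci])
    r <- eval_config(hp)
    surf[[ci]] <- data.frame(configs[ci, , drop = FALSE],
                             f = r$f, p_saf = r$p_saf, p_ext = r$p_ext,
                             vbar_acq_end = r$vbar_acq_end,
                             vbar_ext_end = r$vbar_ext_end)
    if (verbose)
      message(sprintf("[%d/%d] b=%d lambda=%g i=%d beta=%g RPE=%s F=%.4f",
                      ci, nrow(configs), configs$b[ci], configs$lambda[ci],
                      configs$i[ci], configs$beta[ci],
                      if (configs$rpe[ci]) "Yes" else "No", r$f))
  }
  surface <- do.call(rbind, surf)
  rownames(surface) <- NULL
  # best = argmax F, deterministic lexicographic tie-break
  o <- order(-surface$f, surface$b, surface$lambda, surface$i,
             surface$beta, surface$rpe)
  surface <- surface[o, ]
  rownames(surface) <- NULL
  best_row <- surface[1L, ]
  best_hp <- hyper_params(b = best_row$b, lambda = best_row$lambda,
                          i = best_row$i, beta = best_row$beta,
                          rpe = best_row$rpe)
  best <- eval_config(best_hp, keep = TRUE)
  names(best$ens) <- names(best$vbars) <- ls

  structure(list(surface = surface, best_hp = best_hp, f = best$f,
                 p_saf = best$p_saf, p_ext = best$p_ext,
                 targets = targets, vbars = best$vbars,
                 ensembles = best$ens, weights = weights,
                 sequences = ls, designs = designs[ls],
                 n_agents = n_agents, seed = seed, norm = norm,
                 normalize = normalize, call = match.call()),
            class = "replay_fit")
}

#' @export
print.replay_fit <- function(x, ...) {
  cat("Replay-model fit over", nrow(x$surface), "hyper-parameter configurations\n")
  cat(sprintf("Best: b=%d lambda=%g i=%d beta=%g RPE=%s  (F = %.4f)\n",
              x$best_hp$b, x$best_hp$lambda, x$best_hp$i, x$best_hp$beta,
              if (x$best_hp$rpe) "Yes" else "No", x$f))
  cat(sprintf("Penalties: P_Saf = %g (acq-end v = %.3f), P_Ext = %g (ext-end v = %.3f)\n",
              x$p_saf, x$surface$vbar_acq_end[1L],
              x$p_ext, x$surface$vbar_ext_end[1L]))
  invisible(x)
}

#' @export
summary.replay_fit <- function(object, n_top = 5L, ...) {
  s <- utils::head(object$surface, n_top)
  structure(list(top = s, n_configs = nrow(object$surface),
                 best_hp = object$best_hp, f = object$f,
                 weights = object$weights,
                 penalty_free = sum(object$surface$p_saf +
                                      object$surface$p_ext == 0)),
            class = "summary.replay_fit")
}

#' @export
print.summary.replay_fit <- function(x, ...) {
  cat("Grid search:", x$n_configs, "configurations,",
      x$penalty_free, "in the penalty-free region\n")
  cat("Sequence weights (participants):",
      paste(names(x$weights), x$weights, sep = "=", collapse = ", "), "\n")
  cat("Top configurations by goodness of fit:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.replay_fit <- function(object, ...) {
  c(b = object$best_hp$b, lambda = object$best_hp$lambda,
    i = object$best_hp$i, beta = object$best_hp$beta,
    rpe = as.numeric(object$best_hp$rpe))
}

#' Model predictions from a fitted replay model
#'
#' @param object a `replay_fit`.
#' @param design optional new `fear_design`; if supplied, an ensemble is run
#'   at the selected hyper-parameters on it.
#' @param type `"curve"` for the per-ordinal averaged prediction curves,
#'   `"trial"` for the per-trial ensemble trace (predictions and absolute
#'   prediction errors).
#' @param ... unused.
#' @return a data.frame (with `sequence` column when predicting the fitted
#'   sequences).
#' @export
predict.replay_fit <- function(object, design = NULL,
                               type = c("curve", "trial"), ...) {
  type <- match.arg(type)
  if (!is.null(design)) {
    ens <- run_ensemble(design, object$best_hp, object$n_agents,
                        seed = derive_seed(object$seed, 999L))
    return(if (type == "curve") ens$curve else ens$trace)
  }
  out <- lapply(object$sequences, function(l) {
    e <- object$ensembles[[l]]
    d <- if (type == "curve") e$curve else e$trace
    d$sequence <- l
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
fitted.replay_fit <- function(object, ...) object$vbars

#' @export
residuals.replay_fit <- function(object, ...) {
  out <- lapply(object$sequences, function(l)
    object$targets[[l]]$ybar - object$vbars[[l]])
  names(out) <- object$sequences
  out
}

#' Plot observed vs. fitted learning curves
#'
#' One panel per trial sequence: the normalized group-averaged SCR curve
#' (points) and the best configuration's averaged model predictions (lines),
#' CS+ and CS- over presentation ordinal.
#'
#' @param x a `replay_fit`.
#' @param ... passed to `matplot`.
#' @export
plot.replay_fit <- function(x, ...) {
  ls <- x$sequences
  op <- graphics::par(mfrow = c(1, length(ls)))
  on.exit(graphics::par(op))
  for (l in ls) {
    lay <- x$targets[[l]]$layout
    y <- x$targets[[l]]$ybar
    v <- x$vbars[[l]]
    plus <- lay$cs_type == "CS+"
    graphics::matplot(lay$ordinal[plus], cbind(y[plus], v[plus]),
                      type = c("p", "l"), pch = 1, col = "firebrick",
                      lty = 1, xlab = "presentation ordinal",
                      ylab = "normalized SCR / prediction",
                      main = paste("sequence", l), ylim = c(0, 1), ...)
    graphics::matlines(lay$ordinal[!plus], cbind(y[!plus], v[!plus]),
                       type = c("p", "l"), pch = 2, col = "steelblue", lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = c("CS+ observed/fitted", "CS- observed/fitted"),
                     col = c("firebrick", "steelblue"), lty = c(1, 2))
  }
  invisible(x)
}
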