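#' Configuration for a full synthetic study run
#'
#' A run is a pure function of its configuration: cohort sizes, generator and
#' scoring parameters, the hyper-parameter grid, ensemble size and the master
#' seed fully determine every output.
#'
#' @param n_sham,n_verum cohort sizes (study scale: 18 sham / 22 verum).
#' @param gen_params a [scr_gen_params()].
#' @param scoring a [scoring_params()].
#' @param grid hyper-parameter grid for the fit (`NULL` skips fitting).
#' @param n_agents ensemble size per grid configuration.
#' @param seed master seed.
#' @param out_dir optional output directory for CSV/EV/JSON artifacts.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_sham = 18L, n_verum = 22L,
                         gen_params = scr_gen_params(),
                         scoring = scoring_params(),
                         grid = default_grid(), n_agents = 5L,
                         seed = 1L, out_dir = NULL) {
  structure(list(n_sham = n_sham, n_verum = n_verum,
                 gen_params = gen_params, scoring = scoring, grid = grid,
                 n_agents = n_agents, seed = seed, out_dir = out_dir),
            class = "study_config")
}

#' Run the full synthetic study end-to-end
#'
#' Paradigm generation, cohort simulation, SCR scoring, block averaging,
#' rank-based statistics per phase (with the early-recall post hoc
#' comparison), hyper-parameter fitting (if a grid is configured), the
#' fitted model's spontaneous-recovery check, and parametric-modulator
#' export. Deterministic given the configuration.
#'
#' @param config a [study_config()].
#' @return list of class `study_report`: `designs`, `validation`, `manifest`,
#'   `scores`, `blocks`, `scr_diff`, `ats` (per phase), `rte` (recall),
#'   `early_recall` (ATS + post hoc on the first recall block), `fit`
#'   (a `replay_fit` or `NULL`), `recovery` (spontaneous-recovery check),
#'   `config`.
#' @export
run_study <- function(config = study_config()) {
  designs <- list(A = build_experiment("A", seed = derive_seed(config$seed, 1L)),
                  B = build_experiment("B", seed = derive_seed(config$seed, 2L)))
  validation <- lapply(designs, validate_design)

  cohort <- simulate_cohort(config$n_sham, config$n_verum,
                            params = config$gen_params, seed = config$seed)
  scores <- score_cohort(cohort, params = config$scoring)
  blocks <- block_average(scores)
  grp <- cohort$manifest$group[match(blocks$participant,
                                     cohort$manifest$participant)]
  blocks$group <- grp
  diffs <- scr_diff(blocks)
  diffs$group <- cohort$manifest$group[match(diffs$participant,
                                             cohort$manifest$participant)]

  two_block <- c("acquisition", "extinction", "recall")
  # rank statistics need at least two subjects per group
  enough <- min(table(cohort$manifest$group)) >= 2L
  ats_tables <- NULL; rte_recall <- NULL; early_recall <- NULL
  if (enough) {
    ats_tables <- lapply(stats::setNames(two_block, two_block), function(ph) {
      d <- blocks[blocks$phase == ph, ]
      ats(data.frame(value = d$mean_log_scr, subject = d$participant,
                     group = d$group, stimulus = d$cs_type, block = d$block))
    })

    rec <- blocks[blocks$phase == "recall", ]
    rte_recall <- relative_treatment_effects(
      data.frame(value = rec$mean_log_scr, subject = rec$participant,
                 group = rec$group, stimulus = rec$cs_type, block = rec$block),
      seed = derive_seed(config$seed, 3L))

    early <- rec[rec$block == "early", ]
    early_df <- data.frame(value = early$mean_log_scr,
                           subject = early$participant, group = early$group,
                           stimulus = early$cs_type)
    early_recall <- list(
      ats = ats(early_df, within = "stimulus"),
      posthoc = posthoc_cellwise(early_df, effect = c("stimulus", "group"),
                                 within = "stimulus"))
  }

  fit <- NULL; recovery <- NULL; modulators <- NULL
  if (!is.null(config$grid)) {
    fit <- fit_replay_model(scores, designs, grid = config$grid,
                            n_agents = config$n_agents,
                            seed = derive_seed(config$seed, 4L))
    recovery <- recovery_check(designs$A, fit$best_hp,
                               n_seeds = min(10L, config$n_agents * 2L),
                               seed = derive_seed(config$seed, 5L))
    modulators <- lapply(stats::setNames(two_block, two_block), function(ph)
      build_modulators(fit$ensembles[[fit$sequences[1]]],
                       fit$designs[[fit$sequences[1]]], ph))
  }

  report <- structure(list(designs = designs, validation = validation,
                           manifest = cohort$manifest, scores = scores,
                           blocks = blocks, scr_diff = diffs,
                           ats = ats_tables, rte = rte_recall,
                           early_recall = early_recall, fit = fit,
                           recovery = recovery, modulators = modulators,
                           config = config),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Spontaneous-recovery check for a hyper-parameter configuration
#'
#' Runs paired agents (with and without the sleep-replay phase) over several
#' seeds and compares the CS+ prediction at the first recall presentation to
#' the prediction at the last extinction CS+ presentation. With sleep replay
#' the prediction should rise (spontaneous recovery); without it, it should
#' not.
#'
#' @param design a `fear_design`.
#' @param hp a [hyper_params()].
#' @param n_seeds number of paired runs.
#' @param seed master seed.
#' @return data.frame, one row per seed, with `v_ext_end`, `v_recall_first`
#'   for the sleep and no-sleep runs.
#' @export
recovery_check <- function(design, hp = hyper_params(), n_seeds = 10L,
                           seed = 1L) {
  one <- function(s, sleep) {
    tr <- run_agent(design, hp, seed = s, sleep = sleep)$trace
    ext <- tr$v[tr$phase == "extinction" & tr$cs_type == "CS+"]
    rec <- tr$v[tr$phase == "recall" & tr$cs_type == "CS+"]
    c(ext_end = ext[length(ext)], recall_first = rec[1])
  }
  rows <- lapply(seq_len(n_seeds), function(k) {
    s <- derive_seed(seed, k)
    w <- one(s, TRUE); wo <- one(s, FALSE)
    data.frame(seed = s,
               v_ext_end_sleep = w["ext_end"],
               v_recall_first_sleep = w["recall_first"],
               v_ext_end_nosleep = wo["ext_end"],
               v_recall_first_nosleep = wo["recall_first"])
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$recovery_sleep <- res$v_recall_first_sleep - res$v_ext_end_sleep
  res$recovery_nosleep <- res$v_recall_first_nosleep - res$v_ext_end_nosleep
  res
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic study report:", nrow(x$manifest), "participants\n")
  cat("Design constraints passing:",
      sum(x$validation$A$pass), "/", nrow(x$validation$A), "\n")
  if (!is.null(x$early_recall)) {
    cat("\nEarly-recall ATS (first recall block):\n")
    print(x$early_recall$ats)
  }
  if (!is.null(x$fit)) {
    cat("\n"); print(x$fit)
    cat(sprintf("\nSpontaneous recovery (mean over %d seeds): %+0.3f with sleep, %+0.3f without\n",
                nrow(x$recovery), mean(x$recovery$recovery_sleep),
                mean(x$recovery$recovery_nosleep)))
  }
  invisible(x)
}

#' Write a study report's tables to a directory
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(report$manifest, "manifest.csv")
  w(report$scores, "trial_scores.csv")
  w(report$blocks, "block_means.csv")
  w(report$scr_diff, "scr_diff.csv")
  if (!is.null(report$rte)) w(report$rte, "rte_recall.csv")
  for (ph in names(report$ats)) w(as.data.frame(report$ats[[ph]]),
                                  paste0("ats_", ph, ".csv"))
  if (!is.null(report$early_recall)) {
    w(as.data.frame(report$early_recall$ats), "ats_early_recall.csv")
    w(report$early_recall$posthoc, "posthoc_early_recall.csv")
  }
  if (!is.null(report$fit)) {
    w(report$fit$surface, "fit_surface.csv")
    jsonlite::write_json(as.list(coef(report$fit)),
                         file.path(dir, "best_config.json"),
                         auto_unbox = TRUE, digits = NA)
    w(report$recovery, "recovery_check.csv")
    export_modulators(report$fit, file.path(dir, "ev"))
  }
  for (l in names(report$designs))
    write_design(report$designs[[l]], file.path(dir, paste0("design_", l, ".csv")))
  invisible(dir)
}
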