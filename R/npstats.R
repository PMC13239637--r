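# ---- rank-based nonparametric repeated-measures statistics ---------------
# Midrank ANOVA-type statistic (ATS) for a design with one between-subjects
# factor and one or two within-subjects factors, evaluated with the
# denominator degrees of freedom set to infinity, plus relative treatment
# effects (RTE) and Tukey-Kramer adjusted post hoc cell contrasts.

# validate + normalize a long table; returns list with the subjects x cell
# rank structure
.np_prepare <- function(data, value = "value", subject = "subject",
                        between = "group", within = c("stimulus", "block")) {
  need <- c(value, subject, between, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cfac <- function(x) {   # locale-independent level order
    x <- as.character(x)
    factor(x, levels = sort(unique(x), method = "radix"))
  }
  df <- data.frame(value = as.numeric(data[[value]]),
                   subject = cfac(data[[subject]]),
                   group = cfac(data[[between]]))
  for (k in seq_along(within)) df[[paste0("w", k)]] <- cfac(data[[within[k]]])
  wcols <- paste0("w", seq_along(within))
  cell <- interaction(df[wcols], sep = ":", lex.order = TRUE)
  if (any(table(df$subject, cell) != 1L))
    stop("unbalanced within-subject cells: each subject needs exactly one ",
         "observation per within-factor combination")
  sg <- unique(df[c("subject", "group")])
  if (anyDuplicated(sg$subject))
    stop("each subject must belong to exactly one group")
  d <- nlevels(cell)
  if (any(table(cell) == 0L)) stop("empty within cell")
  # subjects x cells value matrix, cells in lexicographic within order
  df <- df[order(df$subject, cell), ]
  subjects <- levels(df$subject)
  Y <- matrix(df$value, nrow = length(subjects), ncol = d, byrow = TRUE)
  grp <- sg$group[match(subjects, sg$subject)]
  list(Y = Y, group = grp, groups = levels(grp),
       within_levels = lapply(df[wcols], levels),
       within_names = within, d = d,
       cell_labels = levels(cell))
}

# midrank cell means and covariance blocks
.np_rank_stats <- function(prep) {
  Y <- prep$Y
  N <- length(Y)
  R <- matrix(rank(Y, ties.method = "average"), nrow(Y), ncol(Y))
  a <- length(prep$groups)
  d <- prep$d
  p_hat <- numeric(a * d)
  Vblocks <- vector("list", a)
  n_g <- integer(a)
  for (g in seq_len(a)) {
    Rg <- R[prep$group == prep$groups[g], , drop = FALSE]
    n_g[g] <- nrow(Rg)
    p_hat[(g - 1L) * d + seq_len(d)] <- (colMeans(Rg) - 0.5) / N
    if (n_g[g] < 2L)
      stop("each group needs at least 2 subjects for the ATS")
    Vblocks[[g]] <- stats::cov(Rg / N) / n_g[g]
  }
  V <- matrix(0, a * d, a * d)
  for (g in seq_len(a)) {
    ix <- (g - 1L) * d + seq_len(d)
    V[ix, ix] <- Vblocks[[g]]
  }
  list(p_hat = p_hat, V = V, n_g = n_g, N = N, R = R)
}

# projection matrices per factor: centering P for factors in the effect,
# averaging J/n for the others; kronecker in (between, within...) order
.effect_T <- function(effect_factors, all_factors, nlev) {
  mats <- lapply(all_factors, function(f) {
    n <- nlev[[f]]
    if (f %in% effect_factors) diag(n) - matrix(1 / n, n, n)
    else matrix(1 / n, n, n)
  })
  Reduce(kronecker, mats)
}

#' ANOVA-type statistic for rank-based repeated-measures analysis
#'
#' Computes the midrank ANOVA-type statistic (ATS) for a factorial design
#' with one between-subjects factor and one or two within-subjects factors.
#' All observations are jointly midranked; cell relative effects and their
#' subject-level covariance feed an F-type statistic per main effect and
#' interaction, whose p-value uses the F distribution with estimated
#' numerator degrees of freedom and the denominator degrees of freedom set
#' to infinity (the variant recommended to avoid type-I inflation with small
#' samples and skewed data).
#'
#' @param data long-format data.frame.
#' @param value,subject,between,within column names; `within` may name one
#'   or two factors (e.g. stimulus and block).
#' @return object of class `ats_result`: data.frame with `effect`,
#'   `statistic`, `df` (numerator), `p` (denominator df infinite).
#' @export
ats <- function(data, value = "value", subject = "subject",
                between = "group", within = c("stimulus", "block")) {
  prep <- .np_prepare(data, value, subject, between, within)
  rs <- .np_rank_stats(prep)
  factors <- c(between, within)
  nlev <- c(stats::setNames(list(length(prep$groups)), between),
            stats::setNames(lapply(prep$within_levels, length), within))
  nlev <- lapply(nlev, as.integer)
  # all main effects and interactions
  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  out <- lapply(effects, function(ef) {
    Tm <- .effect_T(ef, factors, nlev)
    num <- drop(crossprod(rs$p_hat, Tm %*% rs$p_hat))
    TV <- Tm %*% rs$V
    tr1 <- sum(diag(TV))
    if (tr1 < 1e-14) {
      stat <- 0; f <- NA_real_; p <- 1
    } else {
      stat <- num / tr1
      f <- tr1^2 / sum(TV * t(TV))
      p <- stats::pf(stat, f, Inf, lower.tail = FALSE)
    }
    data.frame(effect = paste(ef, collapse = ":"), statistic = stat,
               df = f, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ats_result", "data.frame")
  attr(res, "n_g") <- rs$n_g
  res
}

#' @export
print.ats_result <- function(x, ...) {
  cat("Rank-based ANOVA-type statistics (denominator df = Inf)\n")
  y <- as.data.frame(x)
  y$statistic <- round(y$statistic, 3)
  y$df <- round(y$df, 2)
  y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Relative treatment effects with bootstrap confidence intervals
#'
#' The RTE of a cell is the probability that a randomly selected observation
#' from the pooled reference distribution is smaller than (plus half the
#' probability of being equal to) a random observation from that cell:
#' computed as `(mean cell midrank - 0.5) / N` over the joint midranks of
#' all observations. The sample-size-weighted mean of all cell RTEs is 0.5
#' exactly. Confidence intervals come from a seeded subject-level bootstrap
#' (resampling subjects within groups).
#'
#' @inheritParams ats
#' @param conf confidence level.
#' @param n_boot bootstrap replicates (0 disables the CI).
#' @param seed bootstrap seed.
#' @return data.frame: one row per (group x within-cell) with `rte`,
#'   `lower`, `upper`, `n_subjects`.
#' @export
relative_treatment_effects <- function(data, value = "value",
                                       subject = "subject",
                                       between = "group",
                                       within = c("stimulus", "block"),
                                       conf = 0.95, n_boot = 1000L,
                                       seed = 1L) {
  prep <- .np_prepare(data, value, subject, between, within)
  rs <- .np_rank_stats(prep)
  a <- length(prep$groups); d <- prep$d
  cells <- expand.grid(cell = prep$cell_labels, group = prep$groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- data.frame(group = cells$group, cell = cells$cell,
                    rte = rs$p_hat,
                    n_subjects = rep(rs$n_g, each = d),
                    stringsAsFactors = FALSE)
  if (n_boot > 0L) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    boot <- matrix(NA_real_, n_boot, a * d)
    gidx <- lapply(seq_len(a), function(g) which(prep$group == prep$groups[g]))
    for (bi in seq_len(n_boot)) {
      rows <- unlist(lapply(gidx, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]))
      Yb <- prep$Y[rows, , drop = FALSE]
      Nb <- length(Yb)
      Rb <- matrix(rank(Yb, ties.method = "average"), nrow(Yb), ncol(Yb))
      grp_b <- rep(seq_len(a), times = vapply(gidx, length, integer(1)))
      for (g in seq_len(a)) {
        Rg <- Rb[grp_b == g, , drop = FALSE]
        boot[bi, (g - 1L) * d + seq_len(d)] <- (colMeans(Rg) - 0.5) / Nb
      }
    }
    alpha <- (1 - conf) / 2
    res$lower <- apply(boot, 2L, stats::quantile, probs = alpha)
    res$upper <- apply(boot, 2L, stats::quantile, probs = 1 - alpha)
  }
  res
}

#' Rank-based post hoc cell contrasts with Tukey-Kramer adjustment
#'
#' Pairwise comparisons between the cells of an effect (collapsing the other
#' factors by averaging), based on the asymptotic normality of the cell
#' relative effects; family-wise adjustment uses the studentized-range
#' (Tukey-Kramer) distribution with infinite degrees of freedom.
#'
#' @inheritParams ats
#' @param effect character vector of factor names defining the cells to
#'   compare (e.g. `c("stimulus")` or `c("stimulus", "group")`).
#' @return data.frame of pairwise comparisons with `estimate` (RTE
#'   difference), `statistic` (z), `p_unadj`, `p_adj`.
#' @export
posthoc_cellwise <- function(data, effect, value = "value",
                             subject = "subject", between = "group",
                             within = c("stimulus", "block")) {
  prep <- .np_prepare(data, value, subject, between, within)
  rs <- .np_rank_stats(prep)
  factors <- c(between, within)
  if (!all(effect %in% factors))
    stop("unknown effect factors: ",
         paste(setdiff(effect, factors), collapse = ", "))
  levs <- c(stats::setNames(list(prep$groups), between),
            stats::setNames(prep$within_levels, within))
  # averaging/selection vectors per factor, kroneckered in factor order
  cell_grid <- expand.grid(rev(levs[intersect(factors, effect)]),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_grid <- cell_grid[, rev(seq_len(ncol(cell_grid))), drop = FALSE]
  names(cell_grid) <- intersect(factors, effect)
  k_cells <- nrow(cell_grid)
  if (k_cells < 2L) stop("effect must define at least 2 cells")
  cvec <- function(row) {
    vs <- lapply(factors, function(f) {
      n <- length(levs[[f]])
      if (f %in% effect) {
        v <- numeric(n); v[match(row[[f]], levs[[f]])] <- 1; v
      } else rep(1 / n, n)
    })
    Reduce(kronecker, vs)
  }
  cs <- lapply(seq_len(k_cells), function(r) cvec(cell_grid[r, , drop = FALSE]))
  lab <- apply(cell_grid, 1L, paste, collapse = ":")
  out <- list()
  for (j in seq_len(k_cells - 1L)) {
    for (k in (j + 1L):k_cells) {
      cc <- cs[[j]] - cs[[k]]
      est <- sum(cc * rs$p_hat)
      se <- sqrt(drop(crossprod(cc, rs$V %*% cc)))
      z <- if (se > 0) est / se else 0
      p_un <- 2 * stats::pnorm(-abs(z))
      p_ad <- stats::ptukey(sqrt(2) * abs(z), k_cells, Inf,
                            lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        cell1 = lab[j], cell2 = lab[k], estimate = est, statistic = z,
        p_unadj = p_un, p_adj = min(1, p_ad), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
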