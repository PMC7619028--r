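# Constant-selection theory and logit-linear estimation. Under constant
# selection coefficient s the resistant frequency follows
#   f_t = 1 / (1 + (1 + s)^(-t) * (1 - f0) / f0),
# so log10(f_t / (1 - f_t)) is linear in t with slope log10(1 + s) and
# intercept -log10((1 - f0) / f0). Fitting that line to an observed
# trajectory recovers s = 10^slope - 1 and the implied f0.

#' Deterministic resistant-frequency trajectory under constant selection
#'
#' Closed form of the infinite-population limit of the Wright-Fisher update:
#' it equals t-fold iteration of `f' = f(1+s) / (f(1+s) + (1-f))`.
#'
#' @param f0 Initial resistant frequency. Values 0 and 1 are degenerate
#'   (absorbing) and are returned unchanged with a warning.
#' @param s Selection coefficient (> -1).
#' @param t Generation number(s), >= 0.
#' @return Frequency at generation `t`.
#' @export
#' @examples
#' deterministic_frequency(0.05, s = 1, t = 0:5)
deterministic_frequency <- function(f0, s, t) {
  if (!is.finite(s) || s <= -1) stop("selection coefficient s must be > -1")
  if (any(t < 0)) stop("generation t must be >= 0")
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  if (f0 == 0 || f0 == 1) {
    warning("degenerate initial frequency ", f0, ": trajectory is constant")
    return(rep(f0, length(t)))
  }
  1 / (1 + (1 + s)^(-t) * (1 - f0) / f0)
}

#' Log10 odds of a frequency
#'
#' `log10(f / (1 - f))`, the response variable of the selection regression.
#' Boundary frequencies 0 and 1 have no finite log-odds and return `NA`
#' (an excluded-point signal the estimator handles explicitly), never a
#' silent +/-Inf.
#'
#' @param f Frequencies in \[0, 1\].
#' @return Log10 odds; `NA` at 0 and 1.
#' @export
log_odds <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("frequency must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(f))
  inside <- f > 0 & f < 1
  out[inside] <- log10(f[inside] / (1 - f[inside]))
  out
}

#' Estimate the selection coefficient from one frequency trajectory
#'
#' Ordinary least squares of `log10(f/(1-f))` on generation number. The slope
#' `g` gives `s = 10^g - 1` and relative fitness `1 + s`; the intercept `c`
#' implies the initial frequency `f0_hat = 1 / (1 + 10^(-c))`.
#'
#' Observed frequencies of exactly 0 or 1 (fixation or loss in the counted
#' sample) have undefined log-odds: such points, and every generation after
#' the first absorbing observation, are excluded from the regression. With
#' `continuity_correction = TRUE` and per-generation count totals supplied,
#' boundary points are instead pulled in by half a count
#' (0 -> 1/(2n), 1 -> 1 - 1/(2n)) and retained.
#'
#' @param freq Numeric vector of resistant frequencies, one per generation.
#' @param generation Generation numbers (default `0, 1, ...`; generation 0 is
#'   the seeded mixture).
#' @param n_counted Optional per-generation totals of counted individuals,
#'   used only by the continuity correction.
#' @param continuity_correction Replace boundary frequencies instead of
#'   excluding them (off by default).
#' @return A `selection_estimate` object: list with `g` (slope), `s`,
#'   `relative_fitness`, `f0_hat`, `n_points`, `slope_se`, `residual_sse`.
#' @export
#' @examples
#' f <- deterministic_frequency(0.05, s = 0.2, t = 0:6)
#' estimate_selection(f)
estimate_selection <- function(freq, generation = seq_along(freq) - 1L,
                               n_counted = NULL,
                               continuity_correction = FALSE) {
  stopifnot(length(freq) == length(generation))
  if (any(freq < 0) || any(freq > 1)) stop("frequencies must lie in [0, 1]")
  ord <- order(generation)
  freq <- freq[ord]
  generation <- generation[ord]
  if (!is.null(n_counted)) n_counted <- n_counted[ord]

  boundary <- freq == 0 | freq == 1
  if (continuity_correction) {
    if (is.null(n_counted)) {
      stop("continuity correction requires per-generation n_counted")
    }
    freq[freq == 0] <- 1 / (2 * n_counted[freq == 0])
    freq[freq == 1] <- 1 - 1 / (2 * n_counted[freq == 1])
    usable <- rep(TRUE, length(freq))
  } else {
    # drop boundary points and everything after the first absorbing observation
    usable <- !boundary
    if (any(boundary)) {
      usable[generation > min(generation[boundary])] <- FALSE
    }
  }
  if (sum(usable) < 2L) {
    stop("not estimable: fewer than 2 usable (interior) frequencies")
  }
  y <- log_odds(freq[usable])
  t_use <- generation[usable]
  fit <- stats::lm(y ~ t_use)
  g <- unname(stats::coef(fit)[2])
  cept <- unname(stats::coef(fit)[1])
  # suppressWarnings: summary.lm warns on noiseless (perfect-fit) trajectories
  slope_se <- if (length(y) > 2L)
    suppressWarnings(summary(fit)$coefficients[2, 2]) else NA_real_
  structure(
    list(
      g = g,
      s = 10^g - 1,
      relative_fitness = 10^g,
      f0_hat = 1 / (1 + 10^(-cept)),
      n_points = length(y),
      slope_se = slope_se,
      residual_sse = sum(stats::resid(fit)^2)
    ),
    class = "selection_estimate"
  )
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat("Logit-linear selection estimate\n")
  cat(sprintf("  slope g            : %.5g (SE %.3g, %d generations)\n",
              x$g, x$slope_se, x$n_points))
  cat(sprintf("  selection coeff s  : %+.5g\n", x$s))
  cat(sprintf("  relative fitness   : %.5g\n", x$relative_fitness))
  cat(sprintf("  implied f0         : %.5g\n", x$f0_hat))
  invisible(x)
}

#' Estimate selection for every replicate line in a trajectory table
#'
#' By default each replicate is fitted separately (and can be summarised as
#' mean +/- SD across lines); `pooled = TRUE` fits one regression per
#' condition over all replicates' points instead.
#'
#' @param trajectories Trajectory table as produced by [wf_simulate()],
#'   [gen_observed_trajectories()] or [read_trajectories()]: columns
#'   `condition`, `replicate`, `generation`, `freq_resistant`, optionally
#'   `n_total`.
#' @param pooled Fit one regression per condition across replicates.
#' @param continuity_correction Passed to [estimate_selection()].
#' @return Data frame with one row per replicate (or per condition when
#'   pooled): condition, replicate, g, s, relative_fitness, f0_hat, n_points,
#'   slope_se, and a `note` column (`"ok"` or the not-estimable reason —
#'   failed lines are reported, never dropped silently).
#' @export
estimate_selection_all <- function(trajectories, pooled = FALSE,
                                   continuity_correction = FALSE) {
  needed <- c("condition", "replicate", "generation", "freq_resistant")
  missing <- setdiff(needed, names(trajectories))
  if (length(missing)) {
    stop("trajectory table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  groups <- if (pooled) {
    split(trajectories, trajectories$condition)
  } else {
    split(trajectories,
          interaction(trajectories$condition, trajectories$replicate,
                      drop = TRUE))
  }
  rows <- lapply(groups, function(gdat) {
    n_counted <- if ("n_total" %in% names(gdat)) gdat$n_total else NULL
    est <- tryCatch(
      estimate_selection(gdat$freq_resistant, gdat$generation,
                         n_counted = n_counted,
                         continuity_correction = continuity_correction),
      error = function(e) conditionMessage(e)
    )
    base <- data.frame(
      condition = gdat$condition[1],
      replicate = if (pooled) NA else gdat$replicate[1],
      g = NA_real_, s = NA_real_, relative_fitness = NA_real_,
      f0_hat = NA_real_, n_points = NA_integer_, slope_se = NA_real_,
      note = "ok"
    )
    if (is.character(est)) {
      base$note <- est
    } else {
      base[c("g", "s", "relative_fitness", "f0_hat", "slope_se")] <-
        est[c("g", "s", "relative_fitness", "f0_hat", "slope_se")]
      base$n_points <- est$n_points
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare in-vivo (trajectory-derived) and in-silico relative fitness
#'
#' The in-silico relative fitness of a condition is the direct ratio
#' `w_R / w_S` of the genotype fitnesses; the in-vivo value is `1 + s` from
#' the per-replicate logit-linear estimates, summarised as mean +/- SD across
#' replicate lines. Conditions present on only one side are flagged, not
#' dropped.
#'
#' @param in_vivo Trajectory table (observed or simulated) with replicate
#'   lines per condition.
#' @param in_silico Named list: condition label -> list of
#'   [genotype_params()] (as from [condition_fitness()]) with `R` and `S`
#'   entries, or a list with `w_R`, `w_S`.
#' @param pooled,continuity_correction Passed to [estimate_selection_all()].
#' @return Data frame with columns condition, rf_insilico, rf_invivo_mean,
#'   rf_invivo_sd, n_lines_used, n_lines_total, note.
#' @export
compare_relative_fitness <- function(in_vivo, in_silico, pooled = FALSE,
                                     continuity_correction = FALSE) {
  est <- estimate_selection_all(in_vivo, pooled = pooled,
                                continuity_correction = continuity_correction)
  vivo_conds <- unique(as.character(est$condition))
  silico_conds <- names(in_silico)
  conds <- union(silico_conds, vivo_conds)
  rows <- lapply(conds, function(cond) {
    rf_sil <- NA_real_
    if (cond %in% silico_conds) {
      gp <- in_silico[[cond]]
      w_R <- if (!is.null(gp$w_R)) gp$w_R else gp$R$w
      w_S <- if (!is.null(gp$w_S)) gp$w_S else gp$S$w
      rf_sil <- relative_fitness(w_R, w_S)$ratio
    }
    note <- if (!cond %in% silico_conds) {
      "missing in-silico parameters"
    } else if (!cond %in% vivo_conds) {
      "missing in-vivo trajectories"
    } else "ok"
    sub <- est[est$condition == cond, , drop = FALSE]
    usable <- sub$note == "ok"
    if (cond %in% vivo_conds && !any(usable)) note <- "not estimable in vivo"
    data.frame(
      condition = cond,
      rf_insilico = rf_sil,
      rf_invivo_mean = if (any(usable)) mean(sub$relative_fitness[usable])
                       else NA_real_,
      rf_invivo_sd = if (sum(usable) > 1)
        stats::sd(sub$relative_fitness[usable]) else NA_real_,
      n_lines_used = sum(usable),
      n_lines_total = nrow(sub),
      note = note
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
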