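# Inverse-sigmoid dose-survival model on a log2-concentration axis:
#   survival(c) = 1 / (1 + exp(a * (log2(c) - b)))
# a > 0 is the slope, b the midpoint; EC50 = 2^b in assay units.

#' Normalise plate-assay survival to the control mean
#'
#' Each compound well's survival is the number of mature adults divided by the
#' mean adult count of the zero-compound control wells, so a well that outgrows
#' the control can legitimately exceed 1 (values are not clamped). Replicate
#' wells at the same concentration are averaged.
#'
#' @param records Data frame with columns `concentration`, `n_seeded`,
#'   `n_adults`, `replicate`, `is_control`. Control rows must have
#'   `concentration == 0`.
#' @param per_well If `TRUE`, return one row per well instead of
#'   per-concentration means.
#' @return Data frame with columns `concentration` and `survival`
#'   (mean normalised survival per concentration unless `per_well`).
#' @export
#' @examples
#' rec <- data.frame(
#'   concentration = c(0, 0, 10, 10), n_seeded = 100,
#'   n_adults = c(90, 110, 60, 40), replicate = c(1, 2, 1, 2),
#'   is_control = c(TRUE, TRUE, FALSE, FALSE)
#' )
#' normalize_survival(rec)
normalize_survival <- function(records, per_well = FALSE) {
  validate_dose_survival(records)
  ctrl <- records[records$is_control, , drop = FALSE]
  if (nrow(ctrl) == 0L) {
    stop("normalization error: no control records (is_control == TRUE)")
  }
  ctrl_mean <- mean(ctrl$n_adults)
  if (ctrl_mean <= 0) {
    stop("normalization error: control mean adult count is zero")
  }
  wells <- records[!records$is_control, , drop = FALSE]
  wells$survival <- wells$n_adults / ctrl_mean
  if (per_well) {
    return(data.frame(
      concentration = wells$concentration,
      replicate = wells$replicate,
      survival = wells$survival
    ))
  }
  agg <- stats::aggregate(survival ~ concentration, data = wells, FUN = mean)
  agg <- agg[order(agg$concentration), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

validate_dose_survival <- function(records) {
  needed <- c("concentration", "n_seeded", "n_adults", "is_control")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("dose-survival table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"replicate" %in% names(records)) records$replicate <- seq_len(nrow(records))
  if (any(records$concentration < 0)) stop("concentrations must be >= 0")
  if (any(records$n_seeded <= 0)) stop("n_seeded must be positive")
  if (any(records$n_adults < 0)) stop("n_adults must be non-negative")
  if (any(records$is_control & records$concentration != 0)) {
    stop("control records must have concentration 0")
  }
  invisible(records)
}

#' Predicted survival under the inverse-sigmoid dose-survival curve
#'
#' Evaluates `1 / (1 + exp(a * (log2(concentration) - b)))`. Survival at the
#' midpoint concentration `2^b` is exactly 0.5, and the curve is strictly
#' decreasing for `a > 0`. Concentration 0 lies off the log2 axis; by
#' convention the no-compound control has survival 1 (see
#' [condition_fitness()]), so a non-positive concentration is an error here.
#'
#' @param fit A `dose_response_fit` object, or any list with elements `a`, `b`.
#' @param concentration Positive concentration(s) in assay units.
#' @return Predicted survival proportion(s) in (0, 1).
#' @export
predict_survival <- function(fit, concentration) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration must be finite and > 0; survival at concentration 0 ",
         "is 1 by the control convention")
  }
  x <- log2(concentration)
  1 / (1 + exp(fit$a * (x - fit$b)))
}

#' Fit the inverse-sigmoid dose-survival curve by least squares
#'
#' Finds the slope `a` and log2-axis midpoint `b` minimising the total squared
#' error between predicted and observed survival, using [stats::nls()]
#' (`"port"` algorithm, constrained to `a > 0` so the curve is decreasing).
#' Starting values are `a = 1` and `b` at the log2 of the tested concentration
#' whose mean survival is closest to 0.5, which keeps the search away from the
#' flat tails of the sigmoid.
#'
#' By default the fit uses per-concentration replicate means (the survival
#' values a plate assay is summarised by); set `per_well = TRUE` to fit every
#' well individually.
#'
#' @param records Raw dose-survival records (see [normalize_survival()]), or a
#'   data frame already holding `concentration` and `survival` columns.
#' @param per_well Fit raw wells instead of per-concentration means.
#' @return An object of class `dose_response_fit`: list with `a`, `b`,
#'   `residual_sse`, `n_points`, `concentration_unit`.
#' @param concentration_unit Label stored with the fit (e.g. `"ug/ml"`).
#' @export
#' @examples
#' truth <- list(a = 1.5, b = 4)
#' doses <- 2^seq(0, 8, length.out = 11)
#' dat <- data.frame(concentration = doses,
#'                   survival = predict_survival(truth, doses))
#' fit <- fit_dose_response(dat)
#' c(fit$a, fit$b, ec50(fit))
fit_dose_response <- function(records, per_well = FALSE,
                              concentration_unit = "assay units") {
  if ("survival" %in% names(records)) {
    dat <- records[records$concentration > 0,
                   c("concentration", "survival"), drop = FALSE]
  } else {
    dat <- normalize_survival(records, per_well = per_well)
  }
  if (length(unique(dat$concentration)) < 3L) {
    stop("insufficient data: need >= 3 distinct positive concentrations")
  }
  if (anyNA(dat$survival)) stop("survival values contain NA")

  dat$x <- log2(dat$concentration)
  # start b at the dose whose mean survival is nearest 0.5
  mean_by_conc <- stats::aggregate(survival ~ x, data = dat, FUN = mean)
  b0 <- mean_by_conc$x[which.min(abs(mean_by_conc$survival - 0.5))]

  sse <- function(par) {
    sum((dat$survival - 1 / (1 + exp(par[1] * (dat$x - par[2]))))^2)
  }
  # nls (port, bounded) first; on its occasional false-convergence failures
  # fall back to L-BFGS-B on the identical SSE objective
  est <- tryCatch({
    fit <- stats::nls(
      survival ~ 1 / (1 + exp(a * (x - b))),
      data = dat,
      start = list(a = 1, b = b0),
      algorithm = "port",
      lower = c(a = 1e-8, b = -Inf),
      control = stats::nls.control(maxiter = 1000, tol = 1e-8,
                                   minFactor = 1e-12, warnOnly = FALSE)
    )
    stats::coef(fit)
  },
  error = function(e) {
    opt <- stats::optim(c(a = 1, b = b0), sse, method = "L-BFGS-B",
                        lower = c(1e-8, -Inf),
                        control = list(maxit = 10000, factr = 1e4))
    if (opt$convergence != 0) {
      stop("dose-response fit did not converge (flat or degenerate response?): ",
           conditionMessage(e), call. = FALSE)
    }
    opt$par
  })
  if (est["a"] <= 1e-4) {
    stop("dose-response fit did not converge: slope is unidentifiable ",
         "(flat response)", call. = FALSE)
  }
  structure(
    list(
      a = unname(est["a"]),
      b = unname(est["b"]),
      residual_sse = sse(est),
      n_points = nrow(dat),
      concentration_unit = concentration_unit
    ),
    class = "dose_response_fit"
  )
}

#' Half-maximal effect concentration of a fitted dose-survival curve
#'
#' The concentration at which predicted survival is 50% of control,
#' `2^b` on the fit's log2 axis.
#'
#' @param fit A `dose_response_fit` object (or list with element `b`).
#' @return EC50 in assay units.
#' @export
ec50 <- function(fit) {
  2^fit$b
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Inverse-sigmoid dose-survival fit\n")
  cat(sprintf("  slope a       : %.4f per log2 unit\n", x$a))
  cat(sprintf("  midpoint b    : %.4f (log2 %s)\n", x$b, x$concentration_unit))
  cat(sprintf("  EC50          : %.4g %s\n", ec50(x), x$concentration_unit))
  cat(sprintf("  residual SSE  : %.4g over %d points\n", x$residual_sse,
              x$n_points))
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, records = NULL, ...) {
  if (!is.null(records)) {
    pts <- if ("survival" %in% names(records)) records else
      normalize_survival(records)
    pts <- pts[pts$concentration > 0, ]
    plot(pts$concentration, pts$survival, log = "x",
         xlab = paste0("concentration (", x$concentration_unit, ")"),
         ylab = "normalised survival", ...)
    grid_c <- 2^seq(min(log2(pts$concentration)) - 1,
                    max(log2(pts$concentration)) + 1, length.out = 200)
  } else {
    grid_c <- 2^seq(x$b - 6, x$b + 6, length.out = 200)
    plot(NA, xlim = range(grid_c), ylim = c(0, 1), log = "x",
         xlab = paste0("concentration (", x$concentration_unit, ")"),
         ylab = "normalised survival", ...)
  }
  graphics::lines(grid_c, predict_survival(x, grid_c))
  graphics::abline(v = ec50(x), lty = 2)
  invisible(x)
}
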