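# Genotype fitness under a compound condition: w = m * v, where m is baseline
# fecundity normalised to the susceptible strain and v is survival under the
# condition. The study system is a selfing hermaphrodite, so only homozygous
# resistant (R) and susceptible (S) genotypes segregate.

#' Relative baseline fecundity of the resistant genotype
#'
#' Normalises the resistant strain's mean per-worm egg count to the
#' susceptible strain's, which is set to 1 by definition.
#'
#' @param mean_eggs_resistant,mean_eggs_susceptible Mean eggs laid per worm
#'   over the assay window; both must be positive.
#' @return Relative fecundity `m` of the resistant genotype.
#' @export
normalize_fecundity <- function(mean_eggs_resistant, mean_eggs_susceptible) {
  if (!is.finite(mean_eggs_resistant) || mean_eggs_resistant <= 0 ||
      !is.finite(mean_eggs_susceptible) || mean_eggs_susceptible <= 0) {
    stop("fecundity means must be positive")
  }
  mean_eggs_resistant / mean_eggs_susceptible
}

#' Genotype fitness as fecundity times survival
#'
#' @param m Relative baseline fecundity (> 0; susceptible genotype has m = 1).
#' @param v Survival proportion under the condition, in \[0, 1\].
#' @return Fitness `w = m * v`.
#' @export
genotype_fitness <- function(m, v) {
  if (!is.finite(m) || m <= 0) stop("relative fecundity m must be > 0")
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("survival v must lie in [0, 1]")
  }
  m * v
}

#' Bundle one genotype's fitness components
#'
#' @param label Genotype identifier, conventionally `"R"` or `"S"`.
#' @param m Relative baseline fecundity.
#' @param v Survival proportion under the condition.
#' @return A `genotype_params` object with fields `label`, `m`, `v`,
#'   and `w = m * v`.
#' @export
genotype_params <- function(label, m, v) {
  w <- genotype_fitness(m, v)
  structure(list(label = label, m = m, v = v, w = w),
            class = "genotype_params")
}

#' @export
print.genotype_params <- function(x, ...) {
  cat(sprintf("genotype %s: fecundity m = %.4g, survival v = %.4g, fitness w = %.4g\n",
              x$label, x$m, x$v, x$w))
  invisible(x)
}

#' Per-genotype fitness under a compound condition
#'
#' Survival is evaluated from each genotype's fitted dose-survival curve at
#' the condition's concentration; at concentration 0 (vehicle control) the
#' survival of every genotype is 1 by construction, because assay survival is
#' normalised to that control.
#'
#' @param genotypes Named list, one entry per genotype label, each a list with
#'   `m` (relative fecundity) and `fit` (a [fit_dose_response()] result; may be
#'   omitted when only the control condition is evaluated).
#' @param concentration Compound concentration (>= 0; 0 means vehicle control).
#' @return Named list of [genotype_params()] objects.
#' @export
#' @examples
#' fitS <- list(a = 3, b = log2(24.4))
#' fitR <- list(a = 3, b = log2(93.3))
#' gp <- condition_fitness(
#'   list(R = list(m = 1.2, fit = fitR), S = list(m = 1, fit = fitS)),
#'   concentration = 24
#' )
#' relative_fitness(gp$R$w, gp$S$w)
condition_fitness <- function(genotypes, concentration) {
  if (!is.finite(concentration) || concentration < 0) {
    stop("concentration must be >= 0")
  }
  out <- lapply(names(genotypes), function(lab) {
    g <- genotypes[[lab]]
    if (concentration == 0) {
      v <- 1
    } else {
      if (is.null(g$fit)) {
        stop("genotype ", lab, " has no dose-survival fit but concentration > 0")
      }
      v <- predict_survival(g$fit, concentration)
    }
    genotype_params(lab, g$m, v)
  })
  names(out) <- names(genotypes)
  out
}

#' Relative fitness and selection coefficient of resistant over susceptible
#'
#' Relative fitness is `w_R / w_S` and the selection coefficient is
#' `s = w_R / w_S - 1`, so `relative fitness = 1 + s` identically.
#'
#' @param w_R,w_S Genotype fitness values; `w_S` must be positive.
#' @return A `relative_fitness` object: list with `ratio` and `s`.
#' @export
relative_fitness <- function(w_R, w_S) {
  if (!is.finite(w_S) || w_S <= 0) {
    stop("relative fitness undefined: susceptible fitness must be > 0")
  }
  if (!is.finite(w_R) || w_R < 0) stop("resistant fitness must be >= 0")
  ratio <- w_R / w_S
  structure(list(ratio = ratio, s = ratio - 1), class = "relative_fitness")
}

#' @export
print.relative_fitness <- function(x, ...) {
  cat(sprintf("relative fitness w_R/w_S = %.4g (selection coefficient s = %+.4g)\n",
              x$ratio, x$s))
  invisible(x)
}
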