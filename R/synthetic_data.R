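# Synthetic data with the statistical structure of the laboratory assays:
# binomially noised plate-survival counts around an inverse-sigmoid truth,
# overdispersed (negative-binomial) per-worm fecundity counts, and
# binomially observed Wright-Fisher frequency trajectories. Every generator
# takes an explicit seed and restores the caller's RNG state.

# evaluate code under a local set.seed without disturbing the session RNG
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dose-survival plate assay
#'
#' Emulates a plate assay in which a fixed number of eggs is seeded per well
#' and mature adults are counted after incubation. Control wells draw
#' `Binomial(eggs, control_viability)` adults; compound wells draw
#' `Binomial(eggs, control_viability * survival(a, b, dose))`, with survival
#' the inverse sigmoid on the log2 dose axis. Normalisation to the control
#' mean (see [normalize_survival()]) cancels the control viability in
#' expectation, so its exact value is immaterial downstream. With
#' `noise = FALSE`, counts are the rounded expectations.
#'
#' @param a,b True sigmoid slope and log2-axis midpoint.
#' @param doses Positive, distinct compound concentrations (assay units).
#' @param eggs Eggs seeded per well (default 100).
#' @param wells Replicate wells per concentration, controls included
#'   (default 4).
#' @param control_viability Proportion of eggs reaching adulthood with no
#'   compound (default 0.9).
#' @param noise Draw binomial counts (`TRUE`) or use rounded expectations.
#' @param seed RNG seed.
#' @return Dose-survival record table: columns `concentration`, `n_seeded`,
#'   `n_adults`, `replicate`, `is_control`.
#' @export
#' @examples
#' tab <- gen_dose_survival(a = 3, b = log2(24.4), doses = 2^(-2:8), seed = 1)
#' fit_dose_response(tab)
gen_dose_survival <- function(a, b, doses, eggs = 100, wells = 4,
                              control_viability = 0.9, noise = TRUE,
                              seed = 1) {
  if (length(doses) == 0) stop("config error: dose list is empty")
  if (any(doses <= 0) || anyDuplicated(doses)) {
    stop("doses must be positive and distinct")
  }
  stopifnot(eggs > 0, wells >= 1, control_viability > 0, control_viability <= 1)
  conc <- c(rep(0, wells), rep(doses, each = wells))
  p <- ifelse(conc == 0, control_viability,
              control_viability *
                predict_survival(list(a = a, b = b), pmax(conc, .Machine$double.xmin)))
  n_adults <- if (noise) {
    with_local_seed(seed, stats::rbinom(length(conc), size = eggs, prob = p))
  } else {
    round(eggs * p)
  }
  data.frame(
    concentration = conc,
    n_seeded = eggs,
    n_adults = n_adults,
    replicate = rep(seq_len(wells), times = length(doses) + 1L),
    is_control = conc == 0
  )
}

#' Generate synthetic per-worm fecundity counts
#'
#' Per-worm egg counts are drawn from a negative binomial with the given mean
#' and dispersion (size) parameter; `dispersion = Inf` gives the Poisson
#' limit. The variance is `mean + mean^2 / dispersion`.
#'
#' @param mean_R,mean_S True mean eggs per worm for the resistant and
#'   susceptible strains.
#' @param n_worms Worms assayed per strain (default 12).
#' @param dispersion Negative-binomial size parameter (> 0; `Inf` = Poisson).
#' @param seed RNG seed.
#' @return Data frame with columns `strain` (`"R"`/`"S"`), `worm`, `eggs`.
#' @export
gen_fecundity <- function(mean_R, mean_S, n_worms = 12, dispersion = 30,
                          seed = 1) {
  if (mean_R <= 0 || mean_S <= 0) stop("fecundity means must be positive")
  if (n_worms < 1) stop("need at least one worm per strain")
  if (is.na(dispersion) || dispersion <= 0) {
    stop("dispersion must be positive (Inf for Poisson)")
  }
  draw <- function(mu) {
    if (is.infinite(dispersion)) stats::rpois(n_worms, mu)
    else stats::rnbinom(n_worms, size = dispersion, mu = mu)
  }
  with_local_seed(seed, {
    data.frame(
      strain = rep(c("R", "S"), each = n_worms),
      worm = rep(seq_len(n_worms), 2),
      eggs = c(draw(mean_R), draw(mean_S))
    )
  })
}

#' Generate observation-sampled Wright-Fisher trajectories
#'
#' The latent truth is a [wf_simulate()] ensemble; each generation's observed
#' frequency is `k / n_counted` with `k ~ Binomial(n_counted, latent f_t)`,
#' emulating scoring a finite sample of individuals (fluorescent susceptible
#' versus non-fluorescent resistant) under the microscope. `n_counted = Inf`
#' switches observation noise off, so observed equals latent.
#'
#' @param conditions Named list, one entry per condition: a list with `f0`,
#'   `generations`, `w_R`, `w_S`, optional `N` and `n_reps`.
#' @param N Population size (default 7500) for conditions not overriding it.
#' @param n_reps Replicate lines per condition (default 6).
#' @param n_counted Individuals scored per frequency measurement
#'   (default 200; `Inf` = exact observation).
#' @param seed Master RNG seed.
#' @return Trajectory table: columns `condition`, `replicate`, `generation`,
#'   `freq_resistant` (observed), `n_resistant`, `n_total`, `latent_freq`,
#'   `source` (`"observed"`).
#' @export
gen_observed_trajectories <- function(conditions, N = 7500, n_reps = 6,
                                      n_counted = 200, seed = 1) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  if (!is.infinite(n_counted) && (n_counted < 1 || n_counted != round(n_counted))) {
    stop("n_counted must be a positive integer or Inf")
  }
  out <- lapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    cfg <- sim_config(
      N = if (is.null(cond$N)) N else cond$N,
      f0 = cond$f0, generations = cond$generations,
      n_reps = if (is.null(cond$n_reps)) n_reps else cond$n_reps,
      seed = seed + i, w_R = cond$w_R, w_S = cond$w_S,
      condition = names(conditions)[i]
    )
    latent <- wf_simulate(cfg)
    latent$latent_freq <- latent$freq_resistant
    if (is.infinite(n_counted)) {
      latent$n_resistant <- NA_integer_
      latent$n_total <- NA_integer_
    } else {
      k <- with_local_seed(seed + i + 10000L,
        stats::rbinom(nrow(latent), size = n_counted,
                      prob = latent$latent_freq))
      latent$n_resistant <- k
      latent$n_total <- n_counted
      latent$freq_resistant <- k / n_counted
    }
    latent$source <- "observed"
    latent
  })
  do.call(rbind, out)
}

#' Default truth parameters of the synthetic study
#'
#' The five-condition competitive-microevolution design the generator
#' emulates: spirotetramat (susceptible EC50 24.4, resistant 93.3 assay
#' units; resistant fecundity advantage m = 1.2; resistance seeded at 5%;
#' conditions control / 20 / 24 units; 7 generations) and ivermectin
#' (susceptible EC50 1.07, resistant 50.1 units; resistant fecundity cost
#' m = 0.5; resistance seeded at 50%; conditions control / 1.4 units;
#' 4 generations), with N = 7500 and 6 replicate lines per condition.
#' Sigmoid slopes are set so susceptible survival at the selection doses is
#' roughly 52% (spirotetramat 24 units) and 10% (ivermectin 1.4 units).
#'
#' @return Nested list of true parameters, assay designs and evolution
#'   designs; the `assumed` element lists values that are generator
#'   assumptions rather than measured quantities.
#' @export
synthetic_study_truth <- function() {
  list(
    spirotetramat = list(
      unit = "ug/ml",
      S = list(a = 3, b = log2(24.4), mean_eggs = 192),
      R = list(a = 3, b = log2(93.3), mean_eggs = 230.4),
      doses = 256 / 2^(0:10),          # 0.25 .. 256, 2-fold series
      f0 = 0.05, generations = 7,
      concentrations = c(control = 0, sel_low = 20, sel_high = 24)
    ),
    ivermectin = list(
      unit = "ng/ml",
      S = list(a = 5.7, b = log2(1.07), mean_eggs = 200),
      R = list(a = 3, b = log2(50.1), mean_eggs = 100),
      doses_S = 3.125 * 0.8^(0:9),     # 0.419 .. 3.125, x0.8 series
      doses_R = 2^(-1:9),              # 0.5 .. 512, 2-fold series
      f0 = 0.5, generations = 4,
      concentrations = c(control = 0, sel = 1.4)
    ),
    design = list(N = 7500, n_reps = 6, eggs_per_well = 100, wells = 4,
                  n_worms = 12, dispersion = 30, control_viability = 0.9,
                  n_counted = 200),
    assumed = c("sigmoid slopes a", "mean fecundities", "dispersion",
                "control_viability", "n_counted")
  )
}

# true fitness pair for one condition from the truth list
truth_fitness <- function(truth_cmpd, concentration) {
  m_R <- truth_cmpd$R$mean_eggs / truth_cmpd$S$mean_eggs
  gp <- condition_fitness(
    list(R = list(m = m_R, fit = list(a = truth_cmpd$R$a, b = truth_cmpd$R$b)),
         S = list(m = 1, fit = list(a = truth_cmpd$S$a, b = truth_cmpd$S$b))),
    concentration
  )
  list(w_R = gp$R$w, w_S = gp$S$w)
}

#' Generate the full synthetic study bundle
#'
#' Packages every table the pipeline consumes: one dose-survival assay per
#' strain and compound, one fecundity assay per compound, and
#' observation-sampled trajectory ensembles for all five evolution
#' conditions, together with a manifest of the generating truth (including
#' each condition's true fitness pair and relative fitness). Re-running with
#' the same seed reproduces the bundle exactly.
#'
#' @param seed Master RNG seed.
#' @param dir Optional directory; when given, all tables are written as CSV
#'   and the manifest as JSON.
#' @param truth Study truth parameters (default [synthetic_study_truth()]).
#' @return List with `dose_survival` (named list of record tables),
#'   `fecundity` (named list), `trajectories` (one table), `manifest`.
#' @export
#' @examples
#' study <- gen_full_study(seed = 7)
#' names(study$dose_survival)
#' subset(study$manifest$conditions, select = c(condition, rf_true))
gen_full_study <- function(seed = 1, dir = NULL,
                           truth = synthetic_study_truth()) {
  d <- truth$design
  dose_survival <- list(
    spirotetramat_S = gen_dose_survival(
      truth$spirotetramat$S$a, truth$spirotetramat$S$b,
      truth$spirotetramat$doses, eggs = d$eggs_per_well, wells = d$wells,
      control_viability = d$control_viability, seed = seed + 101L),
    spirotetramat_R = gen_dose_survival(
      truth$spirotetramat$R$a, truth$spirotetramat$R$b,
      truth$spirotetramat$doses, eggs = d$eggs_per_well, wells = d$wells,
      control_viability = d$control_viability, seed = seed + 102L),
    ivermectin_S = gen_dose_survival(
      truth$ivermectin$S$a, truth$ivermectin$S$b,
      truth$ivermectin$doses_S, eggs = d$eggs_per_well, wells = d$wells,
      control_viability = d$control_viability, seed = seed + 103L),
    ivermectin_R = gen_dose_survival(
      truth$ivermectin$R$a, truth$ivermectin$R$b,
      truth$ivermectin$doses_R, eggs = d$eggs_per_well, wells = d$wells,
      control_viability = d$control_viability, seed = seed + 104L)
  )
  fecundity <- list(
    spirotetramat = gen_fecundity(
      truth$spirotetramat$R$mean_eggs, truth$spirotetramat$S$mean_eggs,
      n_worms = d$n_worms, dispersion = d$dispersion, seed = seed + 201L),
    ivermectin = gen_fecundity(
      truth$ivermectin$R$mean_eggs, truth$ivermectin$S$mean_eggs,
      n_worms = d$n_worms, dispersion = d$dispersion, seed = seed + 202L)
  )

  cond_rows <- list()
  conditions <- list()
  for (cmpd in c("spirotetramat", "ivermectin")) {
    tr <- truth[[cmpd]]
    for (j in seq_along(tr$concentrations)) {
      conc <- tr$concentrations[[j]]
      label <- paste0(cmpd, "_", names(tr$concentrations)[j])
      wpair <- truth_fitness(tr, conc)
      conditions[[label]] <- list(f0 = tr$f0, generations = tr$generations,
                                  w_R = wpair$w_R, w_S = wpair$w_S)
      cond_rows[[label]] <- data.frame(
        condition = label, compound = cmpd, concentration = conc,
        unit = tr$unit, f0 = tr$f0, generations = tr$generations,
        w_R_true = wpair$w_R, w_S_true = wpair$w_S,
        rf_true = wpair$w_R / wpair$w_S
      )
    }
  }
  trajectories <- gen_observed_trajectories(
    conditions, N = d$N, n_reps = d$n_reps, n_counted = d$n_counted,
    seed = seed + 300L
  )
  manifest <- list(
    seed = seed,
    design = d,
    truth = truth[c("spirotetramat", "ivermectin")],
    assumed = truth$assumed,
    conditions = do.call(rbind, unname(cond_rows))
  )
  study <- list(dose_survival = dose_survival, fecundity = fecundity,
                trajectories = trajectories, manifest = manifest)
  if (!is.null(dir)) write_study(study, dir)
  study
}

write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$dose_survival)) {
    utils::write.csv(study$dose_survival[[nm]],
                     file.path(dir, paste0("dose_survival_", nm, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(study$fecundity)) {
    utils::write.csv(study$fecundity[[nm]],
                     file.path(dir, paste0("fecundity_", nm, ".csv")),
                     row.names = FALSE)
  }
  write_trajectories(study$trajectories, file.path(dir, "trajectories.csv"))
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
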