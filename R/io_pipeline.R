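# Table schemas and the pipeline orchestration.
#
# Trajectory CSV schema: condition, replicate, generation, freq_resistant
# (and/or n_resistant + n_total). Comma-separated, header row mandatory,
# generations 0-based with generation 0 = seeded mixture; frequencies are
# written at full precision.

#' Write a trajectory table to CSV
#'
#' @param trajectories Trajectory table (see [read_trajectories()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trajectory table
#'
#' Requires columns `condition`, `replicate`, `generation` and either
#' `freq_resistant` or both `n_resistant` and `n_total`. When counts are
#' present the frequency is derived from them (and checked for consistency
#' against any frequency column, tolerance 1e-8). Frequencies outside
#' \[0, 1\] and gaps in a replicate's generation sequence are schema errors
#' that name the offending row.
#'
#' @param path CSV file path.
#' @return Validated trajectory data frame.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("condition", "replicate", "generation")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("trajectory file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  has_counts <- all(c("n_resistant", "n_total") %in% names(tab)) &&
    !all(is.na(tab$n_resistant))
  if (!has_counts && !"freq_resistant" %in% names(tab)) {
    stop("trajectory file needs freq_resistant or n_resistant + n_total")
  }
  if (has_counts) {
    ok <- !is.na(tab$n_resistant) & !is.na(tab$n_total)
    bad <- which(ok & (tab$n_total <= 0 | tab$n_resistant < 0 |
                         tab$n_resistant > tab$n_total))
    if (length(bad)) {
      stop("schema error in row ", bad[1], ": counts invalid (",
           tab$n_resistant[bad[1]], "/", tab$n_total[bad[1]], ")")
    }
    derived <- tab$n_resistant / tab$n_total
    if ("freq_resistant" %in% names(tab)) {
      off <- which(ok & abs(derived - tab$freq_resistant) > 1e-8)
      if (length(off)) {
        stop("schema error in row ", off[1],
             ": freq_resistant inconsistent with counts")
      }
    }
    tab$freq_resistant[ok] <- derived[ok]
  }
  bad_f <- which(is.na(tab$freq_resistant) | tab$freq_resistant < 0 |
                   tab$freq_resistant > 1)
  if (length(bad_f)) {
    stop("schema error in row ", bad_f[1], ": freq_resistant = ",
         tab$freq_resistant[bad_f[1]], " outside [0, 1]")
  }
  # generations must be contiguous from their minimum within each line
  for (key in split(seq_len(nrow(tab)),
                    interaction(tab$condition, tab$replicate, drop = TRUE))) {
    gens <- sort(tab$generation[key])
    if (length(gens) > 1L && any(diff(gens) != 1)) {
      stop("schema error: non-contiguous generations for condition ",
           tab$condition[key[1]], " replicate ", tab$replicate[key[1]],
           " (first such row ", key[1], ")")
    }
  }
  tab
}

#' Read and validate a dose-survival record table
#'
#' @param path CSV with columns `concentration`, `n_seeded`, `n_adults`,
#'   `replicate`, `is_control`.
#' @return Validated record data frame.
#' @export
read_dose_survival <- function(path) {
  if (!file.exists(path)) stop("dose-survival file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(tab$is_control)) {
    tab$is_control <- toupper(tab$is_control) %in% c("TRUE", "T", "1", "YES")
  }
  validate_dose_survival(tab)
  tab
}

#' Run the full prediction pipeline on a study bundle
#'
#' Orchestrates the complete workflow: fit a dose-survival curve per strain
#' and compound, normalise fecundity, derive each condition's genotype
#' fitness, simulate a Wright-Fisher ensemble per condition
#' (`n_sim_reps` stochastic predictions), estimate selection from the
#' observed ("in-vivo") trajectories per replicate line, and tabulate the
#' in-vivo versus in-silico relative fitness. Conditions whose trajectories
#' cannot be estimated are flagged in the comparison table, never dropped.
#'
#' @param study Either a directory written by [gen_full_study()] (containing
#'   the dose-survival / fecundity / trajectory CSVs and `manifest.json`) or
#'   the in-memory bundle list itself.
#' @param n_sim_reps Stochastic simulation replicates per condition
#'   (default 100).
#' @param seed Master seed for the simulation ensembles.
#' @param pooled Pool replicate lines in the selection regression.
#' @param verbose Log each stage with [message()].
#' @return List with `fits`, `fecundity_m`, `condition_params` (per-condition
#'   fitted w_R, w_S), `simulated` (ensemble trajectory table), `estimates`
#'   (per-line selection estimates), `comparison` (in-vivo vs in-silico
#'   relative fitness).
#' @export
#' @examples
#' study <- gen_full_study(seed = 7)
#' res <- run_pipeline(study, n_sim_reps = 20, seed = 7)
#' res$comparison
run_pipeline <- function(study, n_sim_reps = 100, seed = 1, pooled = FALSE,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[resevo] ", ...)
  if (is.character(study)) {
    say("loading study bundle from ", study)
    study <- read_study(study)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  conds <- study$manifest$conditions

  say("fitting dose-survival curves (seed ", seed, ")")
  fits <- stage("dose-response fit", lapply(study$dose_survival, fit_dose_response))

  say("normalising fecundity")
  fecundity_m <- stage("fecundity normalisation", {
    sapply(study$fecundity, function(tab) {
      normalize_fecundity(mean(tab$eggs[tab$strain == "R"]),
                          mean(tab$eggs[tab$strain == "S"]))
    })
  })

  say("deriving per-condition genotype fitness")
  condition_params <- stage("condition fitness", {
    rows <- lapply(seq_len(nrow(conds)), function(i) {
      cmpd <- conds$compound[i]
      gp <- condition_fitness(
        list(R = list(m = fecundity_m[[cmpd]],
                      fit = fits[[paste0(cmpd, "_R")]]),
             S = list(m = 1, fit = fits[[paste0(cmpd, "_S")]])),
        conds$concentration[i]
      )
      data.frame(condition = conds$condition[i], compound = cmpd,
                 concentration = conds$concentration[i],
                 w_R = gp$R$w, w_S = gp$S$w,
                 rf_insilico = gp$R$w / gp$S$w)
    })
    do.call(rbind, rows)
  })

  say("simulating ", n_sim_reps, " stochastic predictions per condition")
  simulated <- stage("Wright-Fisher simulation", {
    ens <- lapply(seq_len(nrow(condition_params)), function(i) {
      wf_simulate(sim_config(
        N = study$manifest$design$N,
        f0 = conds$f0[i], generations = conds$generations[i],
        n_reps = n_sim_reps, seed = seed + i,
        w_R = condition_params$w_R[i], w_S = condition_params$w_S[i],
        condition = condition_params$condition[i]
      ))
    })
    do.call(rbind, ens)
  })

  say("estimating selection from observed trajectories")
  estimates <- stage("selection estimation",
                     estimate_selection_all(study$trajectories, pooled = pooled))

  say("comparing in-vivo and in-silico relative fitness")
  in_silico <- split(condition_params[c("w_R", "w_S")],
                     condition_params$condition)
  in_silico <- lapply(in_silico, as.list)
  comparison <- stage("comparison",
                      compare_relative_fitness(study$trajectories, in_silico,
                                               pooled = pooled))

  list(fits = fits, fecundity_m = fecundity_m,
       condition_params = condition_params, simulated = simulated,
       estimates = estimates, comparison = comparison, seed = seed)
}

#' Read a study bundle directory written by [gen_full_study()]
#'
#' Pre-flight checks that every referenced file exists before reading any of
#' them.
#'
#' @param dir Bundle directory.
#' @return Study bundle list (same shape as [gen_full_study()] output).
#' @export
read_study <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  traj_path <- file.path(dir, "trajectories.csv")
  ds_files <- list.files(dir, pattern = "^dose_survival_.*\\.csv$")
  fec_files <- list.files(dir, pattern = "^fecundity_.*\\.csv$")
  missing <- c(manifest_path, traj_path)[!file.exists(c(manifest_path, traj_path))]
  if (length(missing) || length(ds_files) == 0 || length(fec_files) == 0) {
    stop("study bundle incomplete in ", dir,
         if (length(missing)) paste0(": missing ", paste(missing, collapse = ", "))
         else ": missing dose-survival or fecundity CSVs")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dose_survival <- lapply(ds_files, function(f) read_dose_survival(file.path(dir, f)))
  names(dose_survival) <- sub("^dose_survival_(.*)\\.csv$", "\\1", ds_files)
  fecundity <- lapply(fec_files, function(f)
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE))
  names(fecundity) <- sub("^fecundity_(.*)\\.csv$", "\\1", fec_files)
  list(dose_survival = dose_survival, fecundity = fecundity,
       trajectories = read_trajectories(traj_path), manifest = manifest)
}
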