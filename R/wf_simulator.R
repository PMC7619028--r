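# Wright-Fisher forward simulation of a two-genotype selfing population.
# Each generation, N offspring are sampled with replacement with parental
# contribution proportional to genotype fitness. With only two genotypes the
# multinomial offspring draw reduces to a single binomial draw on the
# resistant count; frequencies are stored as counts/N, the exact rationals of
# the sampling.

#' Fitness-weighted probability that an offspring is resistant
#'
#' @param f Current resistant-genotype frequency in \[0, 1\].
#' @param w_R,w_S Genotype fitness values (>= 0); the mean fitness
#'   `f * w_R + (1 - f) * w_S` must be positive.
#' @return `f * w_R / (f * w_R + (1 - f) * w_S)`.
#' @export
selection_probability <- function(f, w_R, w_S) {
  if (any(f < 0) || any(f > 1)) stop("frequency f must lie in [0, 1]")
  if (any(w_R < 0) || any(w_S < 0)) stop("fitness must be >= 0")
  total <- f * w_R + (1 - f) * w_S
  if (any(total <= 0)) {
    stop("mean fitness is zero: selection probability undefined")
  }
  f * w_R / total
}

#' One Wright-Fisher generation
#'
#' Draws the next generation's resistant count `k ~ Binomial(N, p)` with
#' `p = selection_probability(f, w_R, w_S)` and returns `k / N`. Frequencies
#' 0 and 1 are absorbing. Uses the session RNG stream.
#'
#' @inheritParams selection_probability
#' @param N Population size per generation.
#' @return Next-generation resistant frequency (a multiple of 1/N).
#' @export
wf_step <- function(f, w_R, w_S, N) {
  p <- selection_probability(f, w_R, w_S)
  stats::rbinom(length(p), size = N, prob = p) / N
}

#' Simulation run configuration
#'
#' @param N Constant population size per generation (study default 7500).
#' @param f0 Initial resistant frequency in \[0, 1\].
#' @param generations Number of discrete generations to simulate.
#' @param n_reps Number of stochastic replicate trajectories (study default
#'   100).
#' @param seed Master RNG seed; each replicate runs on its own independent
#'   substream, so increasing `n_reps` never perturbs earlier replicates.
#' @param w_R,w_S Genotype fitness values.
#' @param condition Label carried through to the output table.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(N = 7500, f0, generations, n_reps = 100, seed = 1,
                       w_R, w_S, condition = "sim") {
  stopifnot(is.numeric(N), length(N) == 1, N >= 1, N == round(N))
  if (!is.numeric(f0) || f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  stopifnot(generations >= 1, n_reps >= 1)
  if (w_R < 0 || w_S < 0) stop("fitness must be >= 0")
  structure(list(N = as.integer(N), f0 = f0,
                 generations = as.integer(generations),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 w_R = w_R, w_S = w_S, condition = condition),
            class = "sim_config")
}

# Run code with the L'Ecuyer-CMRG substreams of a master seed; restores the
# caller's RNG kind and state afterwards. fn(streams) receives the list of
# .Random.seed vectors, one per replicate.
with_rng_substreams <- function(seed, n, fn) {
  # restore the caller's generator kind first (RNGkind reseeds as a side
  # effect), then reinstate the saved state vector on top of it
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old_seed <- get(".Random.seed", globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  streams <- vector("list", n)
  s <- get(".Random.seed", globalenv())
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  fn(streams)
}

#' Simulate replicate Wright-Fisher trajectories
#'
#' Iterates [wf_step()] for `generations` steps from `f0`, independently for
#' each of `n_reps` replicates. Simulation continues to the final generation
#' even after fixation or loss (the boundaries are absorbing), so every
#' trajectory has the same length. Generation 0 is the seeded mixture at `f0`.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `condition`, `replicate`, `generation`
#'   (0-based), `freq_resistant`, `n_resistant`, `n_total`, `source`
#'   (`"simulated"`).
#' @export
#' @examples
#' cfg <- sim_config(N = 7500, f0 = 0.05, generations = 5, n_reps = 10,
#'                   seed = 42, w_R = 1.5, w_S = 1)
#' traj <- wf_simulate(cfg)
#' aggregate(freq_resistant ~ generation, traj, mean)
wf_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng_substreams(config$seed, config$n_reps, function(streams) {
    reps <- lapply(seq_len(config$n_reps), function(r) {
      assign(".Random.seed", streams[[r]], globalenv())
      f <- numeric(config$generations + 1L)
      f[1] <- config$f0
      for (t in seq_len(config$generations)) {
        f[t + 1] <- wf_step(f[t], config$w_R, config$w_S, config$N)
      }
      data.frame(
        condition = config$condition,
        replicate = r,
        generation = 0:config$generations,
        freq_resistant = f,
        n_resistant = round(f * config$N),
        n_total = config$N,
        source = "simulated"
      )
    })
    do.call(rbind, reps)
  })
}

#' Replicate spread of drift across population sizes
#'
#' Re-runs [wf_simulate()] at each population size and reports the standard
#' deviation of the resistant frequency across replicates at every
#' generation. Under neutrality the one-generation SD is
#' `sqrt(f0 * (1 - f0) / N)`, so halving N by a factor k inflates the SD by
#' `sqrt(k)` — the mechanism by which small effective populations produce
#' noisy trajectories.
#'
#' @param N_values Vector of population sizes to sweep.
#' @param config A [sim_config()]; its `N` is replaced by each swept value.
#' @return Data frame with columns `N`, `generation`, `sd_freq`.
#' @export
variance_sweep <- function(N_values, config) {
  stopifnot(inherits(config, "sim_config"), all(N_values >= 1))
  out <- lapply(N_values, function(N) {
    cfg <- config
    cfg$N <- as.integer(N)
    traj <- wf_simulate(cfg)
    sds <- stats::aggregate(freq_resistant ~ generation, data = traj,
                            FUN = stats::sd)
    data.frame(N = N, generation = sds$generation, sd_freq = sds$freq_resistant)
  })
  do.call(rbind, out)
}
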