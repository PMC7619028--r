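# one-step deterministic selection update; independent oracle for Eq-style
# closed form
step_update <- function(f, s) f * (1 + s) / (f * (1 + s) + (1 - f))

test_that("closed-form frequency matches direct evaluation and the neutral case", {
  expect_equal(deterministic_frequency(0.3, 0, 0:10), rep(0.3, 11))
  expect_equal(deterministic_frequency(0.05, 1, 0), 0.05)
  expect_equal(deterministic_frequency(0.5, 1, 1), 2 / 3)
  expect_equal(deterministic_frequency(0.05, 1, 5), 1 / (1 + 2^-5 * 19))
  expect_warning(out <- deterministic_frequency(0, 0.5, 3), "degenerate")
  expect_equal(out, rep(0, 1))
  expect_error(deterministic_frequency(0.5, -1, 1), "> -1")
})

test_that("closed form equals t-fold iteration of the one-step update", {
  worst <- 0
  for (f0 in c(0.01, 0.1, 0.5, 0.9, 0.99)) {
    for (s in c(-0.5, -0.1, 0, 0.2, 1, 4)) {
      f_iter <- f0
      for (t in 1:20) {
        f_iter <- step_update(f_iter, s)
        gap <- abs(deterministic_frequency(f0, s, t) - f_iter)
        worst <- max(worst, gap)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("log-odds is log10(f/(1-f)) with boundary points signalled as NA", {
  expect_equal(log_odds(0.5), 0)
  expect_equal(log_odds(0.9), log10(9))
  expect_true(is.na(log_odds(1)))
  expect_true(is.na(log_odds(0)))
  expect_error(log_odds(1.1), "\\[0, 1\\]")
  # antisymmetry around 0.5
  f <- c(0.1, 0.25, 0.4)
  expect_equal(log_odds(f), -log_odds(1 - f))
})

test_that("estimator is exact on noiseless constant-selection trajectories", {
  est0 <- estimate_selection(rep(0.5, 5))
  expect_equal(est0$s, 0)
  expect_equal(est0$f0_hat, 0.5)

  f <- deterministic_frequency(0.05, 0.2, 0:6)
  est <- estimate_selection(f)
  expect_equal(est$s, 0.2, tolerance = 1e-10)
  expect_equal(est$f0_hat, 0.05, tolerance = 1e-10)
  expect_equal(est$relative_fitness, 1 + est$s)
  expect_equal(est$g, log10(1.2), tolerance = 1e-12)
  expect_lt(est$residual_sse, 1e-20)
  expect_equal(est$n_points, 7L)

  # exactness holds across the (f0, s) plane
  for (f0 in c(0.02, 0.5, 0.9)) {
    for (s in c(-0.4, 0.15, 3)) {
      est <- estimate_selection(deterministic_frequency(f0, s, 0:5))
      expect_equal(est$s, s, tolerance = 1e-10)
      expect_equal(est$f0_hat, f0, tolerance = 1e-10)
    }
  }
})

test_that("boundary observations are excluded along with later generations", {
  f <- c(0.5, 0.8, 1, 0.9, 1)      # fixation observed at generation 2
  est <- estimate_selection(f)
  expect_equal(est$n_points, 2L)   # only generations 0 and 1 survive

  expect_error(estimate_selection(c(0.5, 1, 1, 1)), "not estimable")
  expect_error(estimate_selection(c(1, 0)), "not estimable")
})

test_that("continuity correction retains boundary points using count totals", {
  f <- c(0.5, 0.9, 1)
  n <- c(200, 200, 200)
  est <- estimate_selection(f, n_counted = n, continuity_correction = TRUE)
  expect_equal(est$n_points, 3L)
  # corrected final point is 1 - 1/400
  expect_gt(est$s, 0)
  expect_error(estimate_selection(f, continuity_correction = TRUE),
               "n_counted")
})

test_that("estimator is unbiased on Wright-Fisher ensembles at study scale", {
  true_ratio <- 1.5
  traj <- wf_simulate(sim_config(N = 7500, f0 = 0.05, generations = 6,
                                 n_reps = 100, seed = 77,
                                 w_R = true_ratio, w_S = 1))
  est <- estimate_selection_all(traj)
  expect_true(all(est$note == "ok"))
  expect_equal(mean(est$s), 0.5, tolerance = 0.05)
  expect_equal(mean(est$f0_hat), 0.05, tolerance = 0.05)
})

test_that("per-line table flags not-estimable lines instead of dropping them", {
  traj <- data.frame(
    condition = rep(c("ok", "fixed"), each = 4),
    replicate = 1,
    generation = rep(0:3, 2),
    freq_resistant = c(0.5, 0.6, 0.7, 0.8, 0.5, 1, 1, 1)
  )
  est <- estimate_selection_all(traj)
  expect_equal(nrow(est), 2)
  expect_equal(est$note[est$condition == "ok"], "ok")
  expect_match(est$note[est$condition == "fixed"], "not estimable")
})

test_that("pooled fitting returns one estimate per condition", {
  f <- deterministic_frequency(0.1, 0.3, 0:5)
  traj <- rbind(
    data.frame(condition = "c1", replicate = 1, generation = 0:5,
               freq_resistant = f),
    data.frame(condition = "c1", replicate = 2, generation = 0:5,
               freq_resistant = f)
  )
  est <- estimate_selection_all(traj, pooled = TRUE)
  expect_equal(nrow(est), 1)
  expect_equal(est$s, 0.3, tolerance = 1e-10)
})

test_that("in-vivo and in-silico relative fitness agree in a self-consistency loop", {
  w_R <- 1.8; w_S <- 1
  traj <- wf_simulate(sim_config(N = 7500, f0 = 0.05, generations = 6,
                                 n_reps = 6, seed = 123, w_R = w_R, w_S = w_S,
                                 condition = "loop"))
  cmp <- compare_relative_fitness(traj, list(loop = list(w_R = w_R, w_S = w_S)))
  expect_equal(cmp$note, "ok")
  expect_equal(cmp$rf_insilico, 1.8)
  expect_lt(abs(cmp$rf_invivo_mean - 1.8), 2 * cmp$rf_invivo_sd + 1e-9)

  # neutral condition: both sides sit at 1
  neut <- wf_simulate(sim_config(N = 7500, f0 = 0.5, generations = 5,
                                 n_reps = 6, seed = 9, w_R = 1, w_S = 1,
                                 condition = "neutral"))
  cmp_n <- compare_relative_fitness(neut, list(neutral = list(w_R = 1, w_S = 1)))
  expect_equal(cmp_n$rf_insilico, 1)
  expect_equal(cmp_n$rf_invivo_mean, 1, tolerance = 0.05)
})

test_that("comparison flags one-sided and non-estimable conditions", {
  traj <- data.frame(condition = "fixed", replicate = rep(1:2, each = 3),
                     generation = rep(0:2, 2),
                     freq_resistant = rep(c(0.5, 1, 1), 2))
  cmp <- compare_relative_fitness(
    traj, list(fixed = list(w_R = 5, w_S = 1), ghost = list(w_R = 1, w_S = 1)))
  expect_match(cmp$note[cmp$condition == "fixed"], "not estimable")
  expect_match(cmp$note[cmp$condition == "ghost"], "missing in-vivo")
})
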