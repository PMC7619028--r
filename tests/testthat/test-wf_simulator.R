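test_that("selection probability is the fitness-weighted frequency", {
  expect_equal(selection_probability(0.5, 1.3, 1.3), 0.5)
  expect_equal(selection_probability(0, 2, 1), 0)
  expect_equal(selection_probability(1, 2, 1), 1)
  expect_equal(selection_probability(0.05, 2, 1), 0.1 / 1.05)
  expect_error(selection_probability(0.5, 0, 0), "mean fitness")
  expect_error(selection_probability(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("wf_step respects absorbing boundaries and binomial support", {
  set.seed(1)
  expect_true(all(replicate(20, wf_step(0, 2, 1, 50)) == 0))
  expect_true(all(replicate(20, wf_step(1, 2, 1, 50)) == 1))
  draws <- replicate(200, wf_step(0.5, 1, 1, 10))
  expect_true(all(draws %in% ((0:10) / 10)))
})

test_that("one-step outcome distribution matches the enumerated binomial pmf", {
  # N = 2, f = 0.5, w_R/w_S = 2 -> p = 2/3; P(0, .5, 1) = (1/9, 4/9, 4/9)
  n_draws <- 50000
  set.seed(42)
  draws <- wf_step(rep(0.5, n_draws), 2, 1, 2)
  counts <- table(factor(draws, levels = c(0, 0.5, 1)))
  p_expected <- dbinom(0:2, 2, 2 / 3)
  gof <- chisq.test(counts, p = p_expected)
  expect_gt(gof$p.value, 0.001)

  # N = 3 against the exact pmf as well
  set.seed(43)
  draws3 <- wf_step(rep(0.4, n_draws), 1.5, 1, 3)
  p3 <- selection_probability(0.4, 1.5, 1)
  gof3 <- chisq.test(table(factor(draws3, levels = (0:3) / 3)),
                     p = dbinom(0:3, 3, p3))
  expect_gt(gof3$p.value, 0.001)
})

test_that("simulation is reproducible and replicates are seed-stable", {
  cfg <- sim_config(N = 500, f0 = 0.2, generations = 5, n_reps = 8,
                    seed = 99, w_R = 1.4, w_S = 1)
  t1 <- wf_simulate(cfg)
  t2 <- wf_simulate(cfg)
  expect_identical(t1, t2)

  # growing the ensemble never perturbs existing replicates
  cfg_big <- cfg
  cfg_big$n_reps <- 16L
  t_big <- wf_simulate(cfg_big)
  expect_identical(t1, t_big[t_big$replicate <= 8, ])

  # trajectories start at f0, have uniform length, store counts/N exactly
  expect_true(all(t1$freq_resistant[t1$generation == 0] == 0.2))
  expect_true(all(table(t1$replicate) == 6))
  expect_identical(t1$freq_resistant, t1$n_resistant / t1$n_total)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- .Random.seed
  wf_simulate(sim_config(N = 100, f0 = 0.5, generations = 3, n_reps = 4,
                         seed = 1, w_R = 1, w_S = 1))
  expect_identical(.Random.seed, before)
  expect_identical(RNGkind()[1], "Mersenne-Twister")
})

test_that("fixation and loss are absorbing for the rest of the trajectory", {
  cfg <- sim_config(N = 20, f0 = 0.5, generations = 15, n_reps = 40,
                    seed = 5, w_R = 1, w_S = 1)
  traj <- wf_simulate(cfg)
  for (r in split(traj, traj$replicate)) {
    f <- r$freq_resistant[order(r$generation)]
    hit <- which(f %in% c(0, 1))
    if (length(hit)) {
      expect_true(all(f[hit[1]:length(f)] == f[hit[1]]))
    }
  }
  # N = 1 fixes to 0 or 1 after a single step in every replicate
  one <- wf_simulate(sim_config(N = 1, f0 = 0.5, generations = 1, n_reps = 50,
                                seed = 2, w_R = 1, w_S = 1))
  expect_true(all(one$freq_resistant[one$generation == 1] %in% c(0, 1)))
})

test_that("one-generation mean and variance follow the neutral drift law", {
  n_reps <- 10000
  cfg <- sim_config(N = 7500, f0 = 0.5, generations = 1, n_reps = n_reps,
                    seed = 11, w_R = 1, w_S = 1)
  f1 <- wf_simulate(cfg)
  f1 <- f1$freq_resistant[f1$generation == 1]
  se <- sqrt(0.25 / 7500 / n_reps)
  expect_lt(abs(mean(f1) - 0.5), 4 * se)
  expect_equal(var(f1), 0.25 / 7500, tolerance = 0.05)
})

test_that("one-step conditional mean tracks the selection probability", {
  n_reps <- 20000
  for (case in list(c(f = 0.05, wr = 2), c(f = 0.3, wr = 1.2))) {
    p <- selection_probability(case[["f"]], case[["wr"]], 1)
    cfg <- sim_config(N = 1000, f0 = case[["f"]], generations = 1,
                      n_reps = n_reps, seed = 13, w_R = case[["wr"]], w_S = 1)
    traj <- wf_simulate(cfg)
    f1 <- traj$freq_resistant[traj$generation == 1]
    se <- sqrt(p * (1 - p) / 1000 / n_reps)
    expect_lt(abs(mean(f1) - p), 4 * se)
  }
})

test_that("large populations converge to the deterministic trajectory", {
  cfg <- sim_config(N = 1e6, f0 = 0.05, generations = 6, n_reps = 1,
                    seed = 21, w_R = 2, w_S = 1)
  traj <- wf_simulate(cfg)
  expected <- deterministic_frequency(0.05, 1, 0:6)
  expect_lt(max(abs(traj$freq_resistant - expected)), 0.005)
})

test_that("mean final frequency is monotone in the fitness ratio", {
  ratios <- c(0.8, 1, 1.3, 1.8, 2.5)
  means <- sapply(ratios, function(r) {
    traj <- wf_simulate(sim_config(N = 2000, f0 = 0.2, generations = 4,
                                   n_reps = 300, seed = 31, w_R = r, w_S = 1))
    mean(traj$freq_resistant[traj$generation == 4])
  })
  expect_true(all(diff(means) > 0))
})

test_that("replicate SD scales as 1/sqrt(N) in the variance sweep", {
  cfg <- sim_config(N = 7500, f0 = 0.5, generations = 1, n_reps = 10000,
                    seed = 41, w_R = 1, w_S = 1)
  sweep <- variance_sweep(c(100, 7500), cfg)
  sd100 <- sweep$sd_freq[sweep$N == 100 & sweep$generation == 1]
  sd7500 <- sweep$sd_freq[sweep$N == 7500 & sweep$generation == 1]
  expect_equal(sd100 / sd7500, sqrt(75), tolerance = 0.1)
  expect_equal(sd100, sqrt(0.25 / 100), tolerance = 0.05)
  # SD at generation 0 is zero (seeded mixture is deterministic)
  expect_true(all(sweep$sd_freq[sweep$generation == 0] == 0))
})

test_that("invalid configurations fail before any sampling", {
  expect_error(sim_config(N = 0, f0 = 0.5, generations = 1, w_R = 1, w_S = 1))
  expect_error(sim_config(N = 10, f0 = 1.5, generations = 1, w_R = 1, w_S = 1),
               "f0")
  expect_error(sim_config(N = 10, f0 = 0.5, generations = 0, w_R = 1, w_S = 1))
  expect_error(sim_config(N = 10, f0 = 0.5, generations = 2, w_R = -1, w_S = 1))
})
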