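test_that("stimulus currents follow the coherence split and the time window", {
  s <- stimulus_spec(coherence = 0, mu = 40, t_on = 0.5, t_off = 1.5)
  cur <- stimulus_current(0.7, s)
  expect_equal(c(cur$I1, cur$I2), c(0.0208, 0.0208), tolerance = 1e-12)
  s100 <- stimulus_spec(coherence = 100, mu = 40, t_on = 0.5, t_off = 1.5)
  cur <- stimulus_current(1.0, s100)
  expect_equal(cur$I1, 0)
  expect_equal(cur$I2, 2 * 5.2e-4 * 40)
  # off outside the window (off boundary is exclusive)
  for (t in c(0, 0.49, 1.5, 2)) {
    cur <- stimulus_current(t, s)
    expect_equal(c(cur$I1, cur$I2), c(0, 0))
  }
})

test_that("a noiseless trial started at the low fixed point stays there", {
  p <- circuit_params(noise_sd = 0)
  fp <- find_fixed_points(p)
  low <- fp[fp$stability == "attractor" & abs(fp$S1 - fp$S2) < 1e-8, ]
  expect_equal(nrow(low), 1)
  traj <- simulate_trial(p, stim = stimulus_spec(0, mu = 0, t_on = 0.5, t_off = 1.5),
                         init = c(low$S1, low$S2))
  expect_lt(max(abs(traj$S1 - low$S1)), 1e-6)
  expect_lt(max(abs(traj$S2 - low$S2)), 1e-6)
})

test_that("a clear stimulus drives at least 15 Hz of rate separation on valid trials", {
  p <- circuit_params()
  ses <- run_session(p, coherences = 20, n_per_coherence = 60, seed = 4)
  v <- ses$trials[ses$trials$valid, ]
  expect_gt(nrow(v), 40)
  # validity requires the separation, and the favoured population must win
  expect_true(all(v$choice == 2L))
})

test_that("neutral stimuli split choices evenly within binomial error", {
  p <- circuit_params()
  ses <- run_session(p, coherences = 0, n_per_coherence = 300, seed = 8)
  ch <- ses$trials$choice[ses$trials$valid]
  n <- length(ch)
  expect_gt(n, 150)
  p2 <- mean(ch == 2L)
  expect_lt(abs(p2 - 0.5), 3 * sqrt(0.25 / n))
})

test_that("trajectories are seed-deterministic and mirror-equivariant at c = 0", {
  p <- circuit_params()
  t1 <- simulate_trial(p, coherence = 0, seed = 11)
  t2 <- simulate_trial(p, coherence = 0, seed = 11)
  expect_identical(t1$S1, t2$S1)
  expect_identical(t1$Ieta2, t2$Ieta2)
  # swapping the per-population noise streams mirrors the trajectory exactly
  s <- stimulus_spec(coherence = 0, t_on = 0.5, t_off = 1.5)
  a <- inhibmotifs:::mf_integrate(p, s, n = 1, seed = 11, mirror = FALSE)
  b <- inhibmotifs:::mf_integrate(p, s, n = 1, seed = 11, mirror = TRUE)
  expect_identical(a$S1, b$S2)
  expect_identical(a$S2, b$S1)
  expect_identical(a$rE1, b$rE2)
  expect_identical(a$Ieta1, b$Ieta2)
})

test_that("activations remain inside the unit interval along stochastic trials", {
  p <- circuit_params()
  for (seed in 1:5) {
    tr <- simulate_trial(p, coherence = sample(c(0, 20, 60), 1), seed = seed)
    expect_true(all(tr$S1 >= 0 & tr$S1 <= 1))
    expect_true(all(tr$S2 >= 0 & tr$S2 <= 1))
    expect_true(all(tr$rE1 >= 0 & tr$rE2 >= 0 & tr$rI1 >= 0 & tr$rI2 >= 0))
  }
})
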