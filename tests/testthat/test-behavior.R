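test_that("trial evaluation applies both validity criteria to constructed trajectories", {
  # 6 Hz pre-stimulus separation -> premature separation
  tr <- make_fixture("step_trajectory", pre_sep = 6, cross_at = 0.2)
  out <- evaluate_trial(tr)
  expect_false(out$valid)
  expect_equal(out$invalid_reason, "premature_separation")
  # separation never reaching 15 Hz -> no threshold crossing
  tr <- make_fixture("step_trajectory", pre_sep = 0, cross_at = 0.2, level = 14.9)
  out <- evaluate_trial(tr)
  expect_false(out$valid)
  expect_equal(out$invalid_reason, "no_threshold_crossing")
  # clean crossing at 0.2 s with population 1 ahead
  tr <- make_fixture("step_trajectory", pre_sep = 0, cross_at = 0.2, level = 20)
  out <- evaluate_trial(tr)
  expect_true(out$valid)
  expect_equal(out$choice, 1L)
  expect_equal(out$decision_time, 0.2, tolerance = 1e-9)
  expect_true(out$maintained_after_delay)
  # boundary: exactly 5 Hz pre-stimulus separation is premature (criterion is < 5)
  tr <- make_fixture("step_trajectory", pre_sep = 5, cross_at = 0.2)
  expect_false(evaluate_trial(tr)$valid)
  # exactly 15 Hz crossing qualifies (criterion is >= threshold)
  tr <- make_fixture("step_trajectory", pre_sep = 0, cross_at = 0.2, level = 15)
  expect_true(evaluate_trial(tr)$valid)
})

test_that("the strict AND reading requires separation past stimulus offset", {
  sched <- trial_schedule()
  # crosses during the stimulus but collapses before offset
  tr <- make_fixture("step_trajectory", cross_at = 0.2, level = 20)
  tr$rE1[tr$time > sched$t_off - 0.3] <- tr$rE2[tr$time > sched$t_off - 0.3]
  expect_true(evaluate_trial(tr, rule = "or")$valid)
  expect_false(evaluate_trial(tr, rule = "and")$valid)
})

test_that("easy stimuli saturate accuracy", {
  ses <- run_session(circuit_params(), coherences = 100,
                     n_per_coherence = 150, seed = 21)
  s <- ses$summary
  expect_gt(s$completion, 0.9)
  expect_gt(s$accuracy, 1 - 3 * sqrt(0.25 / s$n_valid))
})

test_that("psychometric and chronometric curves are monotone within 2 sem", {
  ses <- run_session(circuit_params(), coherences = c(0, 5, 10, 20, 40),
                     n_per_coherence = 150, seed = 31)
  s <- ses$summary
  acc <- c(0.5, s$accuracy[-1]) # c = 0 has no correct side
  sem_acc <- sqrt(acc * (1 - acc) / s$n_valid)
  for (i in seq_len(nrow(s) - 1)) {
    expect_gte(acc[i + 1] - acc[i],
               -2 * sqrt(sem_acc[i]^2 + sem_acc[i + 1]^2))
    expect_lte(s$mean_decision_time[i + 1] - s$mean_decision_time[i],
               2 * sqrt(s$sem_decision_time[i]^2 + s$sem_decision_time[i + 1]^2))
  }
})

test_that("contraspecific circuits decide faster than ipsispecific ones", {
  sc <- run_session(circuit_params(gamma_IE = -0.15), coherences = 0,
                    n_per_coherence = 150, seed = 41)
  si <- run_session(circuit_params(gamma_IE = 0.15), coherences = 0,
                    n_per_coherence = 150, seed = 41)
  expect_lt(sc$summary$mean_decision_time, si$summary$mean_decision_time)
})

test_that("strongly contraspecific circuits fail by premature separation", {
  # the competitive instability of the pre-stimulus state expresses on the
  # slow NMDA time scale, so probe it with a long pre-stimulus epoch
  sched <- trial_schedule(t_pre = 2, t_stim = 1, t_post = 0.5)
  p <- circuit_params(gamma_IE = -0.8)
  ses <- run_session(p, coherences = c(0, 20), n_per_coherence = 100,
                     seed = 51, schedule = sched)
  prem <- with(ses$trials, tapply(invalid_reason == "premature_separation",
                                  coherence, mean))
  expect_true(all(prem > 0.5))
  # the premature floor is stimulus-independent (pre-stimulus dynamics)
  expect_lt(abs(prem[1] - prem[2]), 0.15)
  # a nonspecific circuit shows no such floor under the same protocol
  ses0 <- run_session(circuit_params(), coherences = c(0, 20),
                      n_per_coherence = 100, seed = 51, schedule = sched)
  prem0 <- mean(ses0$trials$invalid_reason == "premature_separation")
  expect_lt(prem0, 0.1)
})

test_that("nonspecific circuits maintain the choice across a one-second delay", {
  wm <- working_memory_probability(circuit_params(), delay = 1, n = 120,
                                   seed = 61)
  expect_gt(wm$probability, 0.95)
})

test_that("past the working-memory merge the choice read-out collapses", {
  # gamma_IE above the unstimulated merge point: no working-memory attractors
  wm <- working_memory_probability(circuit_params(gamma_IE = 0.14),
                                   delay = 1, n = 120, seed = 62)
  expect_lt(wm$probability, 0.2)
})

test_that("a noiseless trial ending at a choice attractor is maintained forever", {
  p <- circuit_params(noise_sd = 0)
  u <- find_fixed_points(p)
  wm_attr <- u[u$stability == "attractor" & u$S1 > u$S2, ]
  sched <- trial_schedule(t_pre = 0, t_stim = 0.1, t_post = 3)
  stim <- stimulus_spec(0, t_on = 0, t_off = 0.1)
  r <- inhibmotifs:::mf_integrate(p, stim, schedule = sched,
                                  init = c(wm_attr$S1, wm_attr$S2))
  sep <- abs(r$rE1[1, ] - r$rE2[1, ])
  expect_true(all(sep[r$times > 0.2] >= 15))
})

test_that("zero perturbation gives exactly zero deltas under common random numbers", {
  pe <- perturbation_experiment(circuit_params(), baseline_nu = 11.5,
                                deltas = c(-0.25, 0, 0.25),
                                coherences = c(0, 10), n = 40, seed = 71)
  z <- pe[pe$delta_nu == 0, ]
  expect_identical(z$d_completion, 0)
  expect_identical(z$d_decision_time, 0)
  expect_identical(z$d_accuracy, 0)
})
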