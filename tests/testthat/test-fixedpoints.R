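test_that("the reference circuit has five unstimulated and three stimulated fixed points", {
  p <- circuit_params()
  u <- find_fixed_points(p)
  s <- find_fixed_points(p, stim = 0)
  expect_equal(nrow(u), 5)
  expect_equal(table(u$stability)[["attractor"]], 3)
  expect_equal(table(u$stability)[["saddle"]], 2)
  expect_equal(nrow(s), 3)
  expect_equal(table(s$stability)[["attractor"]], 2)
  expect_equal(table(s$stability)[["saddle"]], 1)
  expect_true(all(u$residual <= 1e-6))
  expect_true(all(s$residual <= 1e-6))
})

test_that("fixed-point sets are closed under population relabeling at c = 0", {
  p <- circuit_params(gamma_IE = -0.1)
  for (stim in list(NULL, 0)) {
    fp <- find_fixed_points(p, stim = stim)
    for (i in seq_len(nrow(fp))) {
      d <- sqrt((fp$S1 - fp$S2[i])^2 + (fp$S2 - fp$S1[i])^2)
      expect_lt(min(d), 1e-5)
    }
  }
})

test_that("Newton and Levenberg-Marquardt multistarts find the same roots", {
  p <- circuit_params()
  a <- find_fixed_points(p, method = "newton")
  b <- find_fixed_points(p, method = "lm", grid_n = 9)
  expect_equal(nrow(a), nrow(b))
  oa <- order(a$S1); ob <- order(b$S1)
  expect_equal(a$S1[oa], b$S1[ob], tolerance = 1e-6)
  expect_equal(a$S2[oa], b$S2[ob], tolerance = 1e-6)
  expect_equal(a$stability[oa], b$stability[ob])
})

test_that("analytic Jacobian matches central finite differences", {
  p <- circuit_params()
  cpl <- derive_couplings(p)
  set.seed(3)
  pts <- matrix(stats::runif(200), ncol = 2)
  h <- 1e-6
  for (i in seq_len(nrow(pts))) {
    s1 <- pts[i, 1]; s2 <- pts[i, 2]
    J <- inhibmotifs:::mf_jacobian_entries(s1, s2, cpl, p)
    f <- function(a, b) unlist(inhibmotifs:::mf_field(a, b, cpl, p)[c("f1", "f2")])
    fd <- cbind((f(s1 + h, s2) - f(s1 - h, s2)) / (2 * h),
                (f(s1, s2 + h) - f(s1, s2 - h)) / (2 * h))
    expect_equal(c(J$J11, J$J21, J$J12, J$J22), as.numeric(fd),
                 tolerance = 1e-5)
  }
})

test_that("linearize classifies the stimulated saddle with a competition eigenvector", {
  p <- circuit_params()
  s <- find_fixed_points(p, stim = 0)
  sad <- s[s$stability == "saddle", ]
  lin <- linearize(p, c(sad$S1, sad$S2), stim = 0)
  expect_equal(lin$stability, "saddle")
  re <- Re(lin$eigenvalues)
  expect_equal(sum(re > 0), 1)
  vec <- lin$eigenvectors[, which.max(re)]
  expect_lt(Re(vec[1]) * Re(vec[2]), 0) # components of opposite sign
  expect_equal(lin$tau_slow, sad$tau_slow, tolerance = 1e-8)
  # attractors have strictly negative real parts
  low <- s[s$stability == "attractor", ][1, ]
  lin2 <- linearize(p, c(low$S1, low$S2), stim = 0)
  expect_true(all(Re(lin2$eigenvalues) < 0))
  # a non-fixed point is rejected
  expect_error(linearize(p, c(0.3, 0.9), stim = 0), "not a fixed point")
})

test_that("stability classification agrees with noiseless simulation", {
  # attractors re-converge and saddles diverge along the unstable direction
  set.seed(5)
  cfgs <- expand.grid(gEE = c(0.28, 0.32, 0.36), gIE = c(-0.1, 0, 0.1))
  for (i in seq_len(nrow(cfgs))) {
    p <- circuit_params(gamma_EE = cfgs$gEE[i], gamma_IE = cfgs$gIE[i],
                        noise_sd = 0)
    fp <- find_fixed_points(p, stim = 0)
    if (nrow(fp) == 0) next
    sched <- trial_schedule(t_pre = 0, t_stim = 3, t_post = 0)
    stim <- stimulus_spec(0, t_on = 0, t_off = 3)
    for (j in seq_len(nrow(fp))) {
      if (fp$stability[j] == "attractor") {
        # a perturbed start must stay in a small ball around the attractor
        r <- inhibmotifs:::mf_integrate(
          p, stim, schedule = sched,
          init = c(fp$S1[j] + 1e-3, fp$S2[j] + 1e-3))
        endd <- sqrt((r$S1[1, ncol(r$S1)] - fp$S1[j])^2 +
                       (r$S2[1, ncol(r$S2)] - fp$S2[j])^2)
        expect_lt(endd, 0.02)
      } else if (fp$stability[j] == "saddle") {
        # a nudge along the unstable eigenvector must leave that ball
        lin <- linearize(p, c(fp$S1[j], fp$S2[j]), stim = 0)
        tau <- lin$tau_slow
        sched_j <- trial_schedule(t_pre = 0, t_stim = min(8, 8 * tau),
                                  t_post = 0)
        stim_j <- stimulus_spec(0, t_on = 0, t_off = sched_j$t_stim)
        v <- Re(lin$eigenvectors[, which.max(Re(lin$eigenvalues))])
        r <- inhibmotifs:::mf_integrate(
          p, stim_j, schedule = sched_j,
          init = pmin(pmax(c(fp$S1[j], fp$S2[j]) + 1e-3 * v, 0), 1))
        endd <- sqrt((r$S1[1, ncol(r$S1)] - fp$S1[j])^2 +
                       (r$S2[1, ncol(r$S2)] - fp$S2[j])^2)
        # the displacement must have grown several-fold (some saddles sit
        # within a hundredth of a neighbouring attractor, capping the escape)
        expect_gt(endd, 3 * sqrt(2) * 1e-3)
      }
    }
  }
})

test_that("tau_slow matches the e-folding of separation near the saddle", {
  p <- circuit_params(noise_sd = 0)
  s <- find_fixed_points(p, stim = 0)
  sad <- s[s$stability == "saddle", ]
  lin <- linearize(p, c(sad$S1, sad$S2), stim = 0)
  v <- Re(lin$eigenvectors[, which.max(Re(lin$eigenvalues))])
  v <- v / sqrt(sum(v^2))
  sched <- trial_schedule(t_pre = 0, t_stim = 0.6, t_post = 0)
  stim <- stimulus_spec(0, t_on = 0, t_off = 0.6)
  r <- inhibmotifs:::mf_integrate(p, stim, schedule = sched,
                                  init = c(sad$S1, sad$S2) + 1e-4 * v)
  sep <- abs(r$S1[1, ] - r$S2[1, ])
  # fit the growth rate over the early exponential phase
  k <- which(sep > 1e-4 & sep < 5e-3)
  fit <- stats::lm(log(sep[k]) ~ r$times[k])
  tau_meas <- 1 / stats::coef(fit)[2]
  expect_equal(as.numeric(tau_meas), sad$tau_slow, tolerance = 0.1)
})
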