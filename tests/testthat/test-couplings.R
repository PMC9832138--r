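test_that("kappa matches independent arithmetic over the table constants", {
  dc <- derive_couplings(circuit_params())
  # independent evaluation: kappa = 1 + (c_I/g_I2) N_I J_GABA_I tau_GABA,
  # with J_GABA_I = -g_I_rec_GABA (E_I - V_I)
  J_GABA_I <- -0.0084 * (-70 - (-52.1))
  kappa_expected <- 1 + (615 / 2) * 400 * J_GABA_I * 0.005
  expect_equal(dc$kappa, kappa_expected, tolerance = 1e-12)
  expect_gt(dc$kappa, 1)
})

test_that("direct excitatory drive is conserved across gamma_EE", {
  a0 <- derive_couplings(circuit_params(gamma_EE = 0))
  for (g in c(0.1, 0.32, 0.7, 1)) {
    dc <- derive_couplings(circuit_params(gamma_EE = g))
    s <- dc$alpha1_components[["a"]] + dc$alpha2_components[["a"]]
    s0 <- a0$alpha1_components[["a"]] + a0$alpha2_components[["a"]]
    expect_equal(s, s0, tolerance = 1e-12)
  }
})

test_that("inhibitory loop drive is conserved across gamma_EI and gamma_IE", {
  ref <- derive_couplings(circuit_params(gamma_EI = 0, gamma_IE = 0))
  loop_sum <- function(dc) {
    sum(dc$alpha1_components[c("b", "c")]) + sum(dc$alpha2_components[c("b", "c")])
  }
  for (gEI in c(0, 0.25, 0.8)) {
    for (gIE in c(-0.7, 0, 0.4)) {
      dc <- derive_couplings(circuit_params(gamma_EI = gEI, gamma_IE = gIE))
      expect_equal(loop_sum(dc), loop_sum(ref), tolerance = 1e-12)
    }
  }
})

test_that("at gamma_IE = 0 the selective loop legs are insensitive to gamma_EI", {
  # with gamma_IE = 0 both legs share one w_IE, so b + c is proportional to
  # w_EI_plus + w_EI_minus, which the mapping conserves: the sum is constant
  # in gamma_EI (equivalently, symmetric under flipping its sign)
  f <- function(gEI) {
    dc <- derive_couplings(circuit_params(gamma_EI = gEI, gamma_IE = 0))
    sum(dc$alpha1_components[c("b", "c")])
  }
  expect_equal(f(0.25), f(0), tolerance = 1e-12)
  expect_equal(f(0.9), f(0.1), tolerance = 1e-12)
})

test_that("background inputs are population-symmetric and motif-independent", {
  for (gIE in c(-0.5, 0, 0.5)) {
    dc <- derive_couplings(circuit_params(gamma_IE = gIE))
    expect_identical(dc$I0_1, dc$I0_2)
  }
  i0 <- vapply(c(-0.5, 0, 0.5), function(g) {
    derive_couplings(circuit_params(gamma_IE = g))$I0_1
  }, numeric(1))
  expect_equal(max(i0) - min(i0), 0, tolerance = 1e-12)
})

test_that("inhibitory rates are affine, symmetric under relabeling, and floored", {
  dc <- derive_couplings(circuit_params(gamma_EI = 0.25))
  r <- inhibitory_rates(0.6, 0.2, dc)
  r_swapped <- inhibitory_rates(0.2, 0.6, dc)
  expect_equal(r$rI1, r_swapped$rI2)
  expect_equal(r$rI2, r_swapped$rI1)
  # selective inhibition: the population matched to the more active side fires more
  expect_gt(r$rI1, r$rI2)
  # gamma_EI = 0 removes inhibitory choice selectivity
  dc0 <- derive_couplings(circuit_params(gamma_EI = 0))
  r0 <- inhibitory_rates(0.6, 0.2, dc0)
  expect_equal(r0$rI1, r0$rI2)
  expect_true(all(unlist(inhibitory_rates(0, 0, dc)) >= 0))
})
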