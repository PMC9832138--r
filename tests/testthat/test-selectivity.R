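test_that("rank-based AUC agrees with trapezoidal ROC integration", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (k in 1:5) {
    act <- stats::rnorm(60)
    ch <- sample(c(1L, 2L), 60, replace = TRUE)
    a1 <- inhibmotifs:::auc_rank(act, ch)
    a2 <- as.numeric(pROC::auc(pROC::roc(ch, act, levels = c(1, 2),
                                         direction = "<", quiet = TRUE)))
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("synthetic shifted-normal activity matches the closed-form AUC", {
  fx <- make_fixture("unit_activity", n = 4000, shift = 1, sd = 1, seed = 2)
  a <- inhibmotifs:::auc_rank(fx$activity, fx$choice)
  expect_equal(a, attr(fx, "expected_auc"), tolerance = 0.02)
})

test_that("selectivity classification separates informative from uninformative units", {
  # hand-built selectivity computation on synthetic activity
  set.seed(5)
  n <- 120
  choice <- rep(c(1L, 2L), each = n / 2)
  flat <- stats::rnorm(n)                     # choice-independent
  sharp <- ifelse(choice == 2L, 1, 0) + stats::rnorm(n, sd = 1e-3) # separator
  test_unit <- function(a) {
    auc <- inhibmotifs:::auc_rank(a, choice)
    null <- replicate(150, inhibmotifs:::auc_rank(a, sample(choice)))
    c(auc = auc,
      sig = unname(auc < stats::quantile(null, 0.025) |
                     auc > stats::quantile(null, 0.975)))
  }
  u1 <- test_unit(flat)
  expect_lt(abs(u1[["auc"]] - 0.5), 0.12)
  expect_false(as.logical(u1[["sig"]]))
  u2 <- test_unit(sharp)
  expect_equal(abs(u2[["auc"]] - 0.5), 0.5, tolerance = 1e-9)
  expect_true(as.logical(u2[["sig"]]))
})

test_that("planted block weights give exact specificity estimates", {
  p <- rnn_params()
  w <- make_fixture("planted_weights", params = p,
                    gamma = c(EE = 1 / 3, EI = 0.5, IE = -0.25, II = 0),
                    base = 0.1)
  sel <- selectivity_from_prefs(attr(w, "pref_E"), attr(w, "pref_I"))
  g <- estimate_gamma_rnn(w, sel, p)
  expect_equal(g$gamma_hat[g$class == "EE"], 1 / 3, tolerance = 1e-12)
  expect_equal(g$gamma_hat[g$class == "EI"], 0.5, tolerance = 1e-12)
  expect_equal(g$gamma_hat[g$class == "IE"], -0.25, tolerance = 1e-12)
  expect_equal(g$gamma_hat[g$class == "II"], 0, tolerance = 1e-12)
  # same/opposite weights 2 and 1 give gamma = 1/3 by the defining formula
  w2 <- make_fixture("planted_weights", params = p,
                     gamma = c(EE = 1 / 3, EI = 1 / 3, IE = 1 / 3, II = 1 / 3),
                     base = 1.5)
  expect_equal(max(w2$W_EI), 2)
  expect_equal(min(w2$W_EI), 1)
  g2 <- estimate_gamma_rnn(w2, sel, p)
  expect_equal(g2$gamma_hat, rep(1 / 3, 4), tolerance = 1e-12)
})

test_that("specificity estimates are scale-invariant and robust to jitter", {
  p <- rnn_params()
  sel <- selectivity_from_prefs(rep(c(1L, 2L), length.out = p$N_E),
                                rep(c(1L, 2L), length.out = p$N_I))
  w <- make_fixture("planted_weights", params = p,
                    gamma = c(EE = 0.4, EI = 0.4, IE = 0.4, II = 0.4),
                    base = 0.2, noise = 0.05, seed = 8)
  g <- estimate_gamma_rnn(w, sel, p)
  w_scaled <- w
  w_scaled$W_EE <- 7 * w$W_EE
  g_scaled <- estimate_gamma_rnn(w_scaled, sel, p)
  expect_equal(g_scaled$gamma_hat[g_scaled$class == "EE"],
               g$gamma_hat[g$class == "EE"], tolerance = 1e-12)
  # jittered planted structure is recovered within sampling tolerance
  expect_equal(g$gamma_hat, rep(0.4, 4), tolerance = 0.05)
})

test_that("classes lacking significant units of a preference are reported absent", {
  p <- rnn_params()
  w <- make_fixture("planted_weights", params = p)
  sel <- selectivity_from_prefs(rep(1L, p$N_E), # all E prefer choice 1
                                rep(c(1L, 2L), length.out = p$N_I))
  g <- estimate_gamma_rnn(w, sel, p)
  expect_true(is.na(g$gamma_hat[g$class == "EE"]))
  expect_false(is.na(g$gamma_hat[g$class == "IE"]))
})
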