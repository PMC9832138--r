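test_that("tau_slow grows monotonically toward the stabilising bifurcation", {
  p <- circuit_params()
  bs <- bifurcation_sweep(p, "gamma_IE", from = -0.2, to = 0.19, n = 14,
                          stim = 0)
  sad <- bs$points[bs$points$stability == "saddle" &
                     abs(bs$points$rE1 - bs$points$rE2) < 0.1, ]
  sad <- sad[order(sad$param_value), ]
  expect_gt(nrow(sad), 10)
  expect_true(all(diff(sad$tau_slow) > 0))
})

test_that("the stimulated saddle becomes an attractor at high ipsispecificity", {
  p <- circuit_params()
  bs <- bifurcation_sweep(p, "gamma_IE", from = 0.1, to = 0.3, n = 9, stim = 0)
  expect_gt(nrow(bs$events), 0)
  # before the event the symmetric point is a saddle, after it none remains
  ev <- bs$events[1, ]
  expect_lt(ev$upper - ev$lower, 1e-3)
  expect_true(grepl("saddle", ev$signature_before))
  before <- bs$points[bs$points$param_value < ev$lower, ]
  after <- bs$points[bs$points$param_value > ev$upper, ]
  sym_saddle <- function(x) any(x$stability == "saddle" &
                                  abs(x$rE1 - x$rE2) < 0.1)
  expect_true(sym_saddle(before))
  expect_false(sym_saddle(after))
})

test_that("working-memory attractors merge with saddles and vanish", {
  p <- circuit_params()
  bu <- bifurcation_sweep(p, "gamma_IE", from = 0, to = 0.2, n = 11,
                          stim = NULL)
  expect_gt(nrow(bu$events), 0)
  ev <- bu$events[1, ]
  before <- bu$points[bu$points$param_value < ev$lower, ]
  after <- bu$points[bu$points$param_value > ev$upper, ]
  wm <- function(x) sum(x$stability == "attractor" & abs(x$rE1 - x$rE2) > 1)
  n_before <- wm(before[before$param_value == max(before$param_value), ])
  n_after <- wm(after[after$param_value == min(after$param_value), ])
  expect_equal(n_before, 2)
  expect_equal(n_after, 0)
  # the asymmetric saddles disappear together with the attractors (merge)
  expect_true(grepl("saddlesaddle", ev$signature_before))
  expect_false(grepl("saddle", ev$signature_after))
})

test_that("tau_slow is U-shaped along the inhibitory baseline", {
  p <- circuit_params()
  bn <- bifurcation_sweep(p, "nu0_I", from = 11, to = 14.4, n = 18, stim = 0)
  sad <- bn$points[bn$points$stability == "saddle" &
                     abs(bn$points$rE1 - bn$points$rE2) < 0.1, ]
  sad <- sad[order(sad$param_value), ]
  expect_gt(nrow(sad), 12)
  k <- which.min(sad$tau_slow)
  expect_gt(k, 2)
  expect_lt(k, nrow(sad) - 2)
  expect_true(all(diff(sad$tau_slow[1:k]) < 0))
  expect_true(all(diff(sad$tau_slow[k:nrow(sad)]) > 0))
  # the two perturbation baselines sit on opposite branches
  expect_lt(sad$param_value[k], 14)
  expect_gt(sad$param_value[k], 11.5)
})

test_that("specificity scans attach the inhibitory index and stream to disk", {
  tmp <- tempfile(fileext = ".csv")
  sc <- scan_specificity(circuit_params(),
                         gamma_EE = c(0.28, 0.32, 0.36),
                         gamma_EI = c(0, 0.25),
                         gamma_IE = c(-0.2, 0, 0.2),
                         out_file = tmp)
  expect_equal(nrow(sc), 18)
  expect_equal(sc$spec_index, sc$gamma_EI * sc$gamma_IE)
  onfile <- utils::read.csv(tmp)
  expect_equal(nrow(onfile), 18)
  expect_equal(onfile$is_good_decision_circuit, sc$is_good_decision_circuit)
  # the reference point is a good circuit; degenerate corners are not flagged
  expect_true(sc$is_good_decision_circuit[sc$gamma_EE == 0.32 &
                                            sc$gamma_EI == 0.25 &
                                            sc$gamma_IE == 0])
})
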