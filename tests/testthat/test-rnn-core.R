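test_that("weight initialisation satisfies the structural invariants", {
  p <- rnn_params()
  expect_equal(p$theta, 4) # 100 * 1 / (25 * 1)
  w <- init_rnn(p, seed = 3)
  for (nm in names(w)) expect_true(all(w[[nm]] >= 0))
  expect_true(all(diag(w$W_EE) == 0))
  expect_true(all(diag(w$W_II) == 0))
  # each input stream's and output unit's weights sum to one
  expect_equal(colSums(w$W_in), c(1, 1), tolerance = 1e-12)
  expect_equal(rowSums(w$W_out), c(1, 1), tolerance = 1e-12)
  # deterministic from seed
  expect_identical(init_rnn(p, seed = 3)$W_EE, w$W_EE)
  # inhibitory-source weights are theta-fold stronger in expectation
  expect_gt(mean(w$W_IE) / mean(w$W_EE[w$W_EE > 0 | TRUE]), 2.5)
})

test_that("training batches respect catch fraction, balance and stimulus design", {
  p <- rnn_params()
  b <- make_batch(p, n = 200, seed = 5)
  expect_equal(mean(b$meta$catch), 0.5, tolerance = 3 * sqrt(0.25 / 200) + 0.01)
  go <- b$meta[!b$meta$catch, ]
  expect_lt(abs(mean(go$coherence > 0) - 0.5), 0.1)
  # stimulus period is exactly 21 steps with the margins respected
  expect_true(all(go$t_off - go$t_on + 1 == 21))
  expect_true(all(go$t_on >= 11 & go$t_off <= 60 - 10))
  # catch trials: flat targets, full mask
  ct <- which(b$meta$catch)[1]
  expect_true(all(b$target[, ct, ] == 0.2))
  expect_true(all(b$mask[ct, ] == 1))
  # non-catch trials: mask zero exactly during the stimulus
  i <- which(!b$meta$catch)[1]
  expect_true(all(b$mask[i, b$meta$t_on[i]:b$meta$t_off[i]] == 0))
  expect_true(all(b$mask[i, -(b$meta$t_on[i]:b$meta$t_off[i])] == 1))
})

test_that("stimulus offsets the two streams by 2 mu c / 100 before noise", {
  p <- rnn_params(sigma0_in = 0) # remove input noise to expose the mean
  b <- make_batch(p, n = 10, seed = 5, coherences = 20)
  i <- 1
  w <- b$meta$t_on[i]:b$meta$t_off[i]
  gap <- mean(b$u[1, i, w]) - mean(b$u[2, i, w])
  expect_equal(gap, 2 * 3.2 * 20 / 100, tolerance = 1e-12)
})

test_that("forward dynamics follow the leaky closed form when weights vanish", {
  p <- tiny_rnn_params(sigma0_r = 0, sigma0_in = 0)
  w <- init_rnn(p, seed = 1)
  for (nm in c("W_EE", "W_EI", "W_IE", "W_II", "W_out")) w[[nm]][] <- 0
  b <- make_batch(p, n = 3, seed = 2, coherences = 0)
  fwd <- rnn_forward(w, p, b, seed = 3)
  # x_in converges geometrically to u with rate (1 - alpha_in):
  # since u == u0 at baseline and x_in starts at u0, it stays at u0
  pre <- seq_len(min(b$meta$t_on) - 1)
  expect_equal(as.numeric(fwd$x_in[, 1, pre]),
               rep(p$u0, 2 * length(pre)), tolerance = 1e-12)
  # with W_in kept, xE integrates the input; rates stay nonnegative
  expect_true(all(fwd$rE >= 0) && all(fwd$rI >= 0))
  expect_true(all(fwd$z == 0))
})

test_that("input filtering is geometric with rate (1 - alpha_in)", {
  p <- tiny_rnn_params(sigma0_in = 0)
  b <- make_batch(p, n = 2, seed = 2, coherences = 10)
  w <- init_rnn(p, seed = 1)
  fwd <- rnn_forward(w, p, b, seed = 3)
  i <- 1; ton <- b$meta$t_on[i]
  u_stim <- b$u[1, i, ton] # constant during stimulus (no noise)
  # deviation from the stimulus level decays by (1 - alpha_in) each step
  dev <- u_stim - fwd$x_in[1, i, ton:(ton + 5)]
  expect_equal(dev[-1] / dev[-length(dev)], rep(1 - p$alpha_in, 5),
               tolerance = 1e-10)
})

test_that("outputs depend on excitatory rates only", {
  p <- tiny_rnn_params()
  w <- init_rnn(p, seed = 4)
  b <- make_batch(p, n = 4, seed = 5)
  f1 <- rnn_forward(w, p, b, seed = 6)
  # scaling all inhibitory outgoing weights changes rates but z = W_out rE only
  # sees E rates; directly check z == W_out %*% rE at each step
  for (t in c(1, 10, p$N_time)) {
    expect_equal(matrix(f1$z[, , t], p$N_out),
                 w$W_out %*% matrix(f1$rE[, , t], p$N_E), tolerance = 1e-12)
  }
})

test_that("the loss vanishes for perfect outputs and scales linearly in lambda_w", {
  p <- tiny_rnn_params()
  w <- init_rnn(p, seed = 1)
  b <- make_batch(p, n = 3, seed = 2)
  fwd <- rnn_forward(w, p, b, seed = 3)
  # construct a perfect, silent, weightless configuration
  fwd0 <- fwd
  fwd0$z <- b$target
  fwd0$xE[] <- 0; fwd0$xI[] <- 0
  w0 <- w; for (nm in names(w0)) w0[[nm]][] <- 0
  expect_equal(as.numeric(rnn_loss(fwd0, w0, p, b)), 0)
  # doubling lambda_w doubles the weight penalty exactly
  l1 <- rnn_loss(fwd, w, p, b)
  p2 <- p; p2$lambda_w <- 2 * p$lambda_w
  l2 <- rnn_loss(fwd, w, p2, b)
  expect_equal(attr(l2, "parts")[["weight"]], 2 * attr(l1, "parts")[["weight"]])
  expect_equal(attr(l2, "parts")[["error"]], attr(l1, "parts")[["error"]])
})

test_that("target mismatches during masked stimulus steps do not contribute", {
  p <- tiny_rnn_params()
  w <- init_rnn(p, seed = 1)
  b <- make_batch(p, n = 4, seed = 2)
  fwd <- rnn_forward(w, p, b, seed = 3)
  i <- which(!b$meta$catch)[1]
  b2 <- b
  # corrupt the targets only where the mask is zero
  b2$target[, i, b$meta$t_on[i]:b$meta$t_off[i]] <- 99
  expect_equal(as.numeric(rnn_loss(fwd, w, p, b)),
               as.numeric(rnn_loss(fwd, w, p, b2)))
})

test_that("analytic BPTT gradients match finite differences", {
  p <- tiny_rnn_params()
  w <- init_rnn(p, seed = 2)
  # move weights away from zero so the L1 kink does not bias the check
  for (nm in c("W_EE", "W_EI", "W_IE", "W_II")) w[[nm]] <- w[[nm]] + 0.05
  diag(w$W_EE) <- 0; diag(w$W_II) <- 0
  b <- make_batch(p, n = 4, seed = 3)
  loss_of <- function(w) {
    as.numeric(rnn_loss(rnn_forward(w, p, b, seed = 42), w, p, b))
  }
  fwd <- rnn_forward(w, p, b, seed = 42)
  g <- rnn_gradients(fwd, w, p, b)
  set.seed(9)
  h <- 1e-6
  for (nm in names(w)) {
    for (k in 1:5) {
      i <- sample(length(w[[nm]]), 1)
      if (w[[nm]][i] == 0) next # skip structural zeros (diagonals)
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (loss_of(wp) - loss_of(wm)) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("constructed output traces violating the pre-stimulus rule are invalid", {
  p <- tiny_rnn_params()
  w <- init_rnn(p, seed = 1)
  b <- make_batch(p, n = 2, seed = 2, coherences = c(10, 10))
  fwd <- rnn_forward(w, p, b, seed = 3, keep_state = FALSE)
  # synthetic validation: outputs separated throughout the pre-stimulus epoch
  fake <- fwd
  fake$z[1, , ] <- 1; fake$z[2, , ] <- 0
  # inject via the internal path: rebuild a validation on doctored outputs
  thr <- p$decision_threshold
  i <- 1
  don <- b$meta$t_on[i]
  dz <- fake$z[1, i, ] - fake$z[2, i, ]
  above <- abs(dz) > thr
  valid <- mean(!above[seq_len(don - 1)]) >= 0.75
  expect_false(valid)
})
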