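#' Parameters of the excitatory-inhibitory recurrent network
#'
#' Architecture, task and training constants of the Dale-constrained
#' rate RNN trained on the two-alternative evidence-comparison task. Defaults
#' are the standard configuration (100 excitatory and 25 inhibitory units,
#' 60-step trials with a 21-step stimulus).
#'
#' @param N_E,N_I Numbers of excitatory and inhibitory units.
#' @param s_E,s_I Rectifier slopes (excitability) of E and I units.
#' @param N_time Trial length in steps.
#' @param seed_stim_len Stimulus duration in steps.
#' @param min_pre,min_post Minimum pre- and post-stimulus steps when sampling
#'   the per-trial stimulus onset (uniform over the feasible range).
#' @param ... Overrides for any other field (see the returned list).
#' @return An object of class `rnn_params`.
#' @export
rnn_params <- function(N_E = 100, N_I = 25, s_E = 1, s_I = 1, N_time = 60,
                       seed_stim_len = 21, min_pre = 10, min_post = 10, ...) {
  p <- list(
    N_E = N_E, N_I = N_I, N_in = 2, N_out = 2, N_time = N_time,
    alpha_r = 0.2, alpha_in = 0.2,
    s_E = s_E, s_I = s_I,
    u0 = 0.2, mu = 3.2,
    sigma0_r = 0.35, sigma0_in = 0.05,
    stim_len = seed_stim_len, min_pre = min_pre, min_post = min_post,
    # training
    N_trial = 200, f_catch = 0.5,
    lambda_x = 0.1, lambda_w = 1.0,
    w_mu = 0.0375, w_sigma = 0.5,
    learning_rate = 0.01, grad_clip = 1,
    decision_threshold = 0.25, stop_performance = 0.85,
    train_coherences = setdiff(seq(-20, 20, by = 2), 0),
    difficulty_sampling = "levels",
    valid_coherences = seq(-20, 20, by = 2)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  abort_if(length(unknown) > 0,
           paste0("rnn_params(): unknown parameter(s): ",
                  paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  p$theta <- p$N_E * p$s_E / (p$N_I * p$s_I)
  abort_if(p$alpha_r <= 0 || p$alpha_r > 1 || p$alpha_in <= 0 || p$alpha_in > 1,
           "alpha_r and alpha_in must lie in (0, 1]")
  abort_if(p$f_catch < 0 || p$f_catch > 1, "f_catch must lie in [0, 1]")
  abort_if(p$N_time < p$stim_len + p$min_pre + p$min_post,
           "N_time too short for the stimulus plus pre/post margins")
  structure(p, class = "rnn_params")
}

#' Initialise RNN weights
#'
#' Recurrent weights are drawn from Gamma distributions: shape `w_mu` and
#' scale `w_sigma` for excitatory-source matrices (`W_EE`, `W_EI`), shape
#' `theta * w_mu` for inhibitory-source matrices (`W_IE`, `W_II`), where
#' `theta = N_E s_E / (N_I s_I)` offsets the count and excitability imbalance
#' between the populations. Input and output weights are uniform, normalised
#' so the weights of each input stream and each output unit sum to one.
#' Self-connections are removed and all matrices are nonnegative (weights
#' carry no sign; inhibition enters the dynamics with an explicit minus).
#'
#' @param params An [rnn_params()] object.
#' @param seed Integer seed.
#' @return An `rnn_weights` list: `W_EE` (`N_E x N_E`), `W_EI` (`N_I x N_E`),
#'   `W_IE` (`N_E x N_I`), `W_II` (`N_I x N_I`), `W_in` (`N_E x N_in`),
#'   `W_out` (`N_out x N_E`).
#' @export
init_rnn <- function(params, seed = 1) {
  stopifnot(inherits(params, "rnn_params"))
  set.seed(seed)
  NE <- params$N_E; NI <- params$N_I
  g <- function(nr, nc, shape) {
    matrix(stats::rgamma(nr * nc, shape = shape, scale = params$w_sigma), nr, nc)
  }
  W_EE <- g(NE, NE, params$w_mu); diag(W_EE) <- 0
  W_EI <- g(NI, NE, params$w_mu)
  W_IE <- g(NE, NI, params$theta * params$w_mu)
  W_II <- g(NI, NI, params$theta * params$w_mu); diag(W_II) <- 0
  W_in <- matrix(stats::runif(NE * params$N_in), NE, params$N_in)
  W_in <- sweep(W_in, 2, colSums(W_in), "/")
  W_out <- matrix(stats::runif(params$N_out * NE), params$N_out, NE)
  W_out <- sweep(W_out, 1, rowSums(W_out), "/")
  structure(list(W_EE = W_EE, W_EI = W_EI, W_IE = W_IE, W_II = W_II,
                 W_in = W_in, W_out = W_out),
            class = "rnn_weights")
}

#' Build a batch of task trials
#'
#' Generates input streams, targets and the loss mask for `n` trials. When
#' `coherences` is `NULL` a training batch is built: a fraction `f_catch` of
#' catch trials (no stimulus, targets stay at baseline, mask all ones) and the
#' remainder split equally between choices with difficulty sampled uniformly
#' from the training coherence levels. Otherwise the given coherences are
#' recycled across trials (validation-style batch, no catch trials).
#'
#' The stimulus lasts `stim_len` steps with a per-trial onset drawn uniformly
#' so that at least `min_pre` pre-stimulus and `min_post` post-stimulus steps
#' remain. Positive coherence raises input stream 1, so choice 1 is correct
#' for `c > 0`. Targets are `u0` at baseline and 1 for the correct output from
#' stimulus onset to the end of the trial; the mask zeroes the error term
#' during the stimulus steps of non-catch trials.
#'
#' @param params An [rnn_params()] object.
#' @param n Number of trials.
#' @param seed Integer seed (inputs include the realised input noise).
#' @param coherences Optional coherence vector for a validation-style batch.
#' @return An `rnn_batch` list: `u` (`N_in x n x N_time`), `target`
#'   (`N_out x n x N_time`), `mask` (`n x N_time`), `stim_on` (`n x N_time`
#'   logical), and `meta` (tibble: trial, catch, coherence, t_on, t_off,
#'   correct).
#' @export
make_batch <- function(params, n = params$N_trial, seed = 1, coherences = NULL) {
  stopifnot(inherits(params, "rnn_params"))
  abort_if(n < 1, "make_batch(): n must be >= 1")
  set.seed(seed)
  TT <- params$N_time
  on_lo <- params$min_pre + 1
  on_hi <- TT - params$stim_len - params$min_post + 1
  abort_if(on_hi < on_lo, "make_batch(): infeasible stimulus onset window")

  if (is.null(coherences)) {
    n_catch <- round(n * params$f_catch)
    n_go <- n - n_catch
    half <- floor(n_go / 2)
    ch <- c(rep(1L, half), rep(2L, n_go - half))
    mag <- if (identical(params$difficulty_sampling, "uniform")) {
      stats::runif(n_go, 0, max(abs(params$train_coherences)))
    } else {
      sample(abs(params$train_coherences), n_go, replace = TRUE)
    }
    co <- ifelse(ch == 1L, mag, -mag)
    catch <- c(rep(TRUE, n_catch), rep(FALSE, n_go))
    co <- c(rep(0, n_catch), co)
    ord <- sample.int(n)
    catch <- catch[ord]; co <- co[ord]
  } else {
    catch <- rep(FALSE, n)
    co <- rep_len(coherences, n)
  }
  t_on <- sample(seq.int(on_lo, on_hi), n, replace = TRUE)
  t_off <- t_on + params$stim_len - 1L

  u <- array(params$u0, c(params$N_in, n, TT))
  target <- array(params$u0, c(params$N_out, n, TT))
  mask <- matrix(1, n, TT)
  stim_on <- matrix(FALSE, n, TT)
  correct <- ifelse(catch | co == 0, NA_integer_, ifelse(co > 0, 1L, 2L))

  for (i in seq_len(n)) {
    if (!catch[i]) {
      w <- t_on[i]:t_off[i]
      stim_on[i, w] <- TRUE
      u[1, i, w] <- u[1, i, w] + (1 + params$mu * co[i] / 100)
      u[2, i, w] <- u[2, i, w] + (1 - params$mu * co[i] / 100)
      mask[i, w] <- 0
      if (!is.na(correct[i])) target[correct[i], i, t_on[i]:TT] <- 1
    }
  }
  # input noise enters the streams at every step
  u <- u + sqrt(2 / params$alpha_in) * params$sigma0_in *
    array(stats::rnorm(length(u)), dim(u))

  structure(list(
    u = u, target = target, mask = mask, stim_on = stim_on,
    meta = tibble::tibble(trial = seq_len(n), catch = catch, coherence = co,
                          t_on = t_on, t_off = t_off, correct = correct)
  ), class = "rnn_batch")
}

#' Run the network forward over a batch
#'
#' Leaky discrete-time dynamics: excitatory activations receive recurrent
#' excitation, recurrent inhibition (explicit minus; weights are nonnegative),
#' the filtered input streams and private Gaussian noise; inhibitory
#' activations receive recurrent input and noise but no stimulus. Rates are
#' slope-scaled rectifications and the two outputs are weighted sums of
#' excitatory rates only.
#'
#' @param weights An [init_rnn()] weight set.
#' @param params An [rnn_params()] object.
#' @param batch An [make_batch()] batch.
#' @param seed Seed for the recurrent noise draws.
#' @param delta_I Constant perturbation added to the inhibitory drive during
#'   each trial's stimulus steps (inhibitory perturbation experiments).
#' @param keep_state Keep the activation/rate history needed for
#'   backpropagation (set `FALSE` to save memory when only outputs matter).
#' @return An `rnn_forward` list with `z` (`N_out x n x N_time`) and, when
#'   `keep_state`, arrays `xE`, `xI`, `rE`, `rI`, `x_in`.
#' @export
rnn_forward <- function(weights, params, batch, seed = 1, delta_I = 0,
                        keep_state = TRUE) {
  stopifnot(inherits(weights, "rnn_weights"), inherits(batch, "rnn_batch"))
  set.seed(seed)
  NE <- params$N_E; NI <- params$N_I
  n <- dim(batch$u)[2]; TT <- params$N_time
  ar <- params$alpha_r; ain <- params$alpha_in
  sdr <- sqrt(2 * ar) * params$sigma0_r

  xE <- matrix(0, NE, n); xI <- matrix(0, NI, n)
  rE <- xE; rI <- xI
  x_in <- matrix(params$u0, params$N_in, n)

  z <- array(NA_real_, c(params$N_out, n, TT))
  if (keep_state) {
    AxE <- array(NA_real_, c(NE, n, TT)); AxI <- array(NA_real_, c(NI, n, TT))
    ArE <- AxE; ArI <- AxI
    Axin <- array(NA_real_, c(params$N_in, n, TT))
  }
  stim_t <- t(batch$stim_on) # TT x n; row t gives per-trial stimulus flag

  for (t in seq_len(TT)) {
    x_in <- (1 - ain) * x_in + ain * matrix(batch$u[, , t], params$N_in, n)
    noiseE <- matrix(stats::rnorm(NE * n, sd = sdr), NE, n)
    noiseI <- matrix(stats::rnorm(NI * n, sd = sdr), NI, n)
    driveI <- weights$W_EI %*% rE - weights$W_II %*% rI + noiseI
    if (delta_I != 0) {
      driveI <- driveI + delta_I * matrix(stim_t[t, ], NI, n, byrow = TRUE)
    }
    xE <- (1 - ar) * xE +
      ar * (weights$W_EE %*% rE - weights$W_IE %*% rI +
              weights$W_in %*% x_in + noiseE)
    xI <- (1 - ar) * xI + ar * driveI
    abort_if(any(!is.finite(xE)) || any(!is.finite(xI)),
             "rnn_forward(): non-finite activations (network diverged)")
    rE <- params$s_E * pmax(xE, 0)
    rI <- params$s_I * pmax(xI, 0)
    z[, , t] <- weights$W_out %*% rE
    if (keep_state) {
      AxE[, , t] <- xE; AxI[, , t] <- xI
      ArE[, , t] <- rE; ArI[, , t] <- rI
      Axin[, , t] <- x_in
    }
  }
  out <- list(z = z)
  if (keep_state) {
    out <- c(out, list(xE = AxE, xI = AxI, rE = ArE, rI = ArI, x_in = Axin))
  }
  structure(out, class = "rnn_forward")
}

#' Training loss
#'
#' Masked mean squared output error plus L2 activation regularisation
#' (strength `lambda_x`) and L1 weight regularisation over the four recurrent
#' matrices (strength `lambda_w`). The mask removes the stimulus steps of
#' non-catch trials from the error term only.
#'
#' @param fwd An [rnn_forward()] result (with state kept).
#' @param weights,params,batch As in [rnn_forward()].
#' @return Scalar loss, with components in attribute `parts`.
#' @export
rnn_loss <- function(fwd, weights, params, batch) {
  n <- dim(fwd$z)[2]; TT <- params$N_time
  NU <- params$N_E + params$N_I
  msk <- aperm(array(batch$mask, c(n, TT, params$N_out)), c(3, 1, 2))
  err <- sum(msk * (batch$target - fwd$z)^2) / (n * TT * params$N_out)
  act <- params$lambda_x * (sum(fwd$xE^2) + sum(fwd$xI^2)) / (NU * n * TT)
  wt <- params$lambda_w * (sum(abs(weights$W_EE)) + sum(abs(weights$W_EI)) +
                             sum(abs(weights$W_IE)) + sum(abs(weights$W_II))) /
    NU^2
  structure(err + act + wt, parts = c(error = err, activation = act,
                                      weight = wt))
}

# Backpropagation through time: returns gradients for all six matrices.
rnn_gradients <- function(fwd, weights, params, batch) {
  NE <- params$N_E; NI <- params$N_I; NU <- NE + NI
  n <- dim(fwd$z)[2]; TT <- params$N_time
  ar <- params$alpha_r
  cz <- 2 / (n * TT * params$N_out)
  cx <- 2 * params$lambda_x / (NU * n * TT)

  gE <- matrix(0, NE, n); gI <- matrix(0, NI, n)
  dWEE <- matrix(0, NE, NE); dWIE <- matrix(0, NE, NI)
  dWEI <- matrix(0, NI, NE); dWII <- matrix(0, NI, NI)
  dWin <- matrix(0, NE, params$N_in); dWout <- matrix(0, params$N_out, NE)

  tWout <- t(weights$W_out); tWEE <- t(weights$W_EE); tWEI <- t(weights$W_EI)
  tWIE <- t(weights$W_IE); tWII <- t(weights$W_II)

  for (t in TT:1) {
    mrow <- matrix(batch$mask[, t], params$N_out, n, byrow = TRUE)
    zt <- matrix(fwd$z[, , t], params$N_out, n)
    tt <- matrix(batch$target[, , t], params$N_out, n)
    xEt <- matrix(fwd$xE[, , t], NE, n)
    xIt <- matrix(fwd$xI[, , t], NI, n)
    dz <- cz * mrow * (zt - tt)
    drE <- tWout %*% dz + ar * (tWEE %*% gE + tWEI %*% gI)
    drI <- ar * (-tWIE %*% gE - tWII %*% gI)
    gE <- (1 - ar) * gE + drE * (params$s_E * (xEt > 0)) + cx * xEt
    gI <- (1 - ar) * gI + drI * (params$s_I * (xIt > 0)) + cx * xIt
    rEprev <- if (t > 1) matrix(fwd$rE[, , t - 1], NE, n) else matrix(0, NE, n)
    rIprev <- if (t > 1) matrix(fwd$rI[, , t - 1], NI, n) else matrix(0, NI, n)
    dWEE <- dWEE + gE %*% t(rEprev)
    dWIE <- dWIE - gE %*% t(rIprev)
    dWEI <- dWEI + gI %*% t(rEprev)
    dWII <- dWII - gI %*% t(rIprev)
    dWin <- dWin + gE %*% t(matrix(fwd$x_in[, , t], params$N_in, n))
    dWout <- dWout + dz %*% t(matrix(fwd$rE[, , t], NE, n))
  }
  cw <- params$lambda_w / NU^2
  list(
    W_EE = ar * dWEE + cw * sign(weights$W_EE),
    W_EI = ar * dWEI + cw * sign(weights$W_EI),
    W_IE = ar * dWIE + cw * sign(weights$W_IE),
    W_II = ar * dWII + cw * sign(weights$W_II),
    W_in = ar * dWin,
    W_out = dWout
  )
}

project_dale <- function(weights) {
  for (nm in names(weights)) weights[[nm]][weights[[nm]] < 0] <- 0
  diag(weights$W_EE) <- 0
  diag(weights$W_II) <- 0
  weights
}

#' Evaluate task behaviour of a network
#'
#' Runs a validation-style batch and applies the decision rules: a decision is
#' registered at the first step at/after stimulus onset where the output
#' difference exceeds the threshold; a trial is valid when at least 75% of the
#' pre-stimulus steps are below threshold and at least 50% of the post-stimulus
#' steps are above. Overall performance is the fraction of correct choices
#' among all trials excluding the ambiguous zero-coherence level.
#'
#' @param weights An `rnn_weights` set.
#' @param params An [rnn_params()] object.
#' @param seed Seed for batch construction and forward noise.
#' @param n Number of validation trials.
#' @param delta_I Inhibitory perturbation during the stimulus (see
#'   [rnn_forward()]).
#' @param batch Optional pre-built batch (overrides `n`/coherence defaults;
#'   used for common-random-number comparisons).
#' @return An `rnn_validation` list: `performance`, `trials` (per-trial
#'   tibble: coherence, valid, choice, correct, decision_time in steps) and
#'   `by_coherence` summary.
#' @export
validate_rnn <- function(weights, params, seed = 1, n = 100, delta_I = 0,
                         batch = NULL) {
  if (is.null(batch)) {
    batch <- make_batch(params, n = n, seed = derive_seed(seed, 1),
                        coherences = params$valid_coherences)
  }
  fwd <- rnn_forward(weights, params, batch, seed = derive_seed(seed, 2),
                     delta_I = delta_I, keep_state = FALSE)
  thr <- params$decision_threshold
  n <- dim(fwd$z)[2]; TT <- params$N_time
  dzm <- matrix(fwd$z[1, , ] - fwd$z[2, , ], n, TT)
  meta <- batch$meta

  res <- purrr::map_dfr(seq_len(n), function(i) {
    don <- meta$t_on[i]; doff <- meta$t_off[i]
    above <- abs(dzm[i, ]) > thr
    pre <- seq_len(don - 1)
    post <- seq.int(doff + 1, TT)
    cross <- which(above & seq_len(TT) >= don)
    has <- length(cross) > 0
    valid <- mean(!above[pre]) >= 0.75 && mean(above[post]) >= 0.5 && has
    choice <- if (valid) ifelse(dzm[i, cross[1]] > 0, 1L, 2L) else NA_integer_
    tibble::tibble(
      coherence = meta$coherence[i],
      valid = valid,
      choice = choice,
      correct = if (!is.na(meta$correct[i]) && valid)
        choice == meta$correct[i] else NA,
      decision_time = if (valid) cross[1] - don else NA_integer_
    )
  })
  nz <- res$coherence != 0
  perf <- sum(res$correct[nz], na.rm = TRUE) / sum(nz)
  by_coh <- res |>
    dplyr::group_by(.data$coherence) |>
    dplyr::summarise(
      n = dplyr::n(),
      completion = mean(.data$valid),
      accuracy = mean(.data$correct[.data$valid]),
      mean_decision_time = mean(.data$decision_time[.data$valid]),
      .groups = "drop"
    )
  structure(list(performance = perf, trials = res, by_coherence = by_coh),
            class = "rnn_validation")
}

#' Train an excitatory-inhibitory RNN to criterion
#'
#' Epochs of freshly generated trial batches, backpropagation through time,
#' adaptive-moment (Adam) updates at the configured learning rate with global
#' gradient-norm clipping, and after every update a projection restoring
#' nonnegativity of all six weight matrices and zero self-connections.
#' Validation performance is measured after every epoch; training stops when
#' it reaches `stop_performance`.
#'
#' @param params An [rnn_params()] object.
#' @param seed Master seed; epoch batches, noise draws and validation batches
#'   all use seeds derived from it, so training is exactly reproducible.
#' @param max_epochs Trial budget expressed in epochs; if the criterion is not
#'   reached the fit is returned with `converged = FALSE`.
#' @param init Optional initial weights (defaults to [init_rnn()]).
#' @param quiet Suppress progress messages.
#' @return An `rnn_fit` list: `weights`, `history` (tibble: epoch, loss,
#'   performance, trials_seen), `converged`, `params`, `seed`.
#' @export
train_rnn <- function(params = rnn_params(), seed = 1, max_epochs = 1500,
                      init = NULL, quiet = TRUE) {
  stopifnot(inherits(params, "rnn_params"))
  weights <- init %||% init_rnn(params, seed = derive_seed(seed, 0))
  adam <- list(m = lapply(weights, function(w) w * 0),
               v = lapply(weights, function(w) w * 0), t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- vector("list", max_epochs)
  converged <- FALSE

  for (epoch in seq_len(max_epochs)) {
    batch <- make_batch(params, n = params$N_trial,
                        seed = derive_seed(seed, epoch))
    fwd <- rnn_forward(weights, params, batch,
                       seed = derive_seed(seed, 100000 + epoch))
    loss <- rnn_loss(fwd, weights, params, batch)
    grads <- rnn_gradients(fwd, weights, params, batch)

    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm > params$grad_clip) {
      grads <- lapply(grads, function(g) g * params$grad_clip / gnorm)
    }
    adam$t <- adam$t + 1
    for (nm in names(weights)) {
      adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * grads[[nm]]
      adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- adam$m[[nm]] / (1 - b1^adam$t)
      vhat <- adam$v[[nm]] / (1 - b2^adam$t)
      weights[[nm]] <- weights[[nm]] -
        params$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    weights <- project_dale(weights)

    val <- validate_rnn(weights, params, seed = derive_seed(seed, 200000 + epoch))
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = as.numeric(loss),
      performance = val$performance,
      trials_seen = epoch * params$N_trial
    )
    if (!quiet && epoch %% 25 == 0) {
      message(sprintf("epoch %d: loss %.4f, performance %.3f",
                      epoch, loss, val$performance))
    }
    if (val$performance >= params$stop_performance) {
      converged <- TRUE
      break
    }
  }
  structure(list(weights = weights, history = dplyr::bind_rows(history),
                 converged = converged, params = params, seed = seed),
            class = "rnn_fit")
}

#' @export
print.rnn_fit <- function(x, ...) {
  h <- x$history
  cat("<rnn_fit>", x$params$N_E, "E /", x$params$N_I, "I units;",
      nrow(h), "epochs;",
      if (x$converged) "reached" else "did NOT reach", "criterion\n")
  if (nrow(h) > 0) {
    cat(sprintf("  final loss %.4f, performance %.3f, %d trials\n",
                h$loss[nrow(h)], h$performance[nrow(h)],
                h$trials_seen[nrow(h)]))
  }
  invisible(x)
}
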