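#' Parameters of the four-variable model
#'
#' The four-variable model represents the two choice-selective excitatory
#' populations by their NMDA activations (as in the two-variable model) and
#' the two choice-selective inhibitory populations explicitly by GABA
#' activations, allowing inhibitory-inhibitory connection specificity
#' `gamma_II` to be studied. Synaptic strengths and background currents are
#' fixed constants of the model (obtained upstream by calibrating the
#' four-variable excitatory dynamics against the two-variable model; they are
#' used here as data, not re-fitted).
#'
#' @param gamma_EE,gamma_EI,gamma_IE Connection specificities as in
#'   [circuit_params()].
#' @param gamma_II Inhibitory-to-inhibitory specificity in `[-1, 1]`.
#' @param noise_sd White-noise amplitude (nA) of the input noise, applied to
#'   all four populations.
#' @param dt Integration time step (s).
#' @param ... Overrides for the synaptic constants (`J_NMDA_E`, `J_NMDA_I`,
#'   `J_GABA_E`, `J_GABA_I`, `I0_E`, `I0_I`), gains (`gain_E`, `gain_I`), time
#'   constants, or `J_AMPA_ext`/`mu`.
#' @return An object of class `fourvar_params`.
#' @export
fourvar_params <- function(gamma_EE = 0.32, gamma_EI = 0.25, gamma_IE = 0,
                           gamma_II = 0, noise_sd = 0.2, dt = 0.002, ...) {
  p <- list(
    gamma_EE = gamma_EE, gamma_EI = gamma_EI, gamma_IE = gamma_IE,
    gamma_II = gamma_II,
    # synaptic constants (nA): NMDA positive, GABA negative
    J_NMDA_E = 0.4235, J_NMDA_I = 0.5743,
    J_GABA_E = -0.4699, J_GABA_I = -0.6421,
    # background currents (nA)
    I0_E = 0.7707, I0_I = 1.0267,
    # transfer gains: excitatory and inhibitory populations
    gain_E = c(a = 310, b = 125, d = 0.16),
    gain_I = c(a = 615, b = 177, d = 0.087),
    tau_NMDA = 0.1, tau_GABA = 0.005, gamma_kinetic = 0.641,
    tau_AMPA = 0.002,
    J_AMPA_ext = 5.2e-4, mu = 40,
    noise_sd = noise_sd,
    noise_convention = "amplitude",
    dt = dt,
    N_s = 2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  abort_if(length(unknown) > 0,
           paste0("fourvar_params(): unknown parameter(s): ",
                  paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  abort_if(p$gamma_EE < 0 || p$gamma_EE > 1, "gamma_EE must lie in [0, 1]")
  abort_if(p$gamma_EI < 0 || p$gamma_EI > 1, "gamma_EI must lie in [0, 1]")
  abort_if(abs(p$gamma_IE) > 1 || abs(p$gamma_II) > 1,
           "gamma_IE and gamma_II must lie in [-1, 1]")
  abort_if(p$J_NMDA_E <= 0 || p$J_NMDA_I <= 0,
           "NMDA synaptic constants must be positive")
  abort_if(p$J_GABA_E >= 0 || p$J_GABA_I >= 0,
           "GABA synaptic constants must be negative")
  structure(p, class = "fourvar_params")
}

#' Adjacency matrix of the four-variable model
#'
#' Assembles the 4x4 coupling matrix of the state vector
#' `(S_E1, S_E2, S_I1, S_I2)`: excitatory columns carry `J_NMDA` weights and
#' inhibitory columns `J_GABA` weights, each split into same/opposite
#' preference by the corresponding specificity parameter through
#' [specificity_to_weights()]. Because the weight mapping conserves
#' `w_plus + w_minus`, every row-sum over a column class is independent of the
#' class's specificity.
#'
#' @param params A [fourvar_params()] object.
#' @return A 4x4 numeric matrix.
#' @export
fourvar_adjacency <- function(params) {
  stopifnot(inherits(params, "fourvar_params"))
  w_EE <- specificity_to_weights(params$gamma_EE, params$N_s)
  w_EI <- specificity_to_weights(params$gamma_EI, params$N_s)
  w_IE <- specificity_to_weights(params$gamma_IE, params$N_s)
  w_II <- specificity_to_weights(params$gamma_II, params$N_s)
  jE <- params$J_NMDA_E; jI <- params$J_NMDA_I
  gE <- params$J_GABA_E; gI <- params$J_GABA_I
  matrix(c(
    w_EE$w_plus * jE, w_EE$w_minus * jE, w_IE$w_plus * gE, w_IE$w_minus * gE,
    w_EE$w_minus * jE, w_EE$w_plus * jE, w_IE$w_minus * gE, w_IE$w_plus * gE,
    w_EI$w_plus * jI, w_EI$w_minus * jI, w_II$w_plus * gI, w_II$w_minus * gI,
    w_EI$w_minus * jI, w_EI$w_plus * jI, w_II$w_minus * gI, w_II$w_plus * gI
  ), nrow = 4, byrow = TRUE)
}

# Vector field of the noiseless four-variable system. S is a length-4 vector
# or an n x 4 matrix; returns same shape. Rows 1-2 (excitatory) follow NMDA
# gating kinetics; rows 3-4 (inhibitory) follow GABA kinetics S' = -S/tau + Phi.
fourvar_field <- function(S, A, params, Ist = c(0, 0)) {
  S <- rbind(S)
  x <- S %*% t(A)
  x[, 1] <- x[, 1] + params$I0_E + Ist[1]
  x[, 2] <- x[, 2] + params$I0_E + Ist[2]
  x[, 3] <- x[, 3] + params$I0_I
  x[, 4] <- x[, 4] + params$I0_I
  rE1 <- transfer_rate(x[, 1], params$gain_E)
  rE2 <- transfer_rate(x[, 2], params$gain_E)
  rI1 <- transfer_rate(x[, 3], params$gain_I)
  rI2 <- transfer_rate(x[, 4], params$gain_I)
  gk <- params$gamma_kinetic
  cbind(
    -S[, 1] / params$tau_NMDA + (1 - S[, 1]) * gk * rE1,
    -S[, 2] / params$tau_NMDA + (1 - S[, 2]) * gk * rE2,
    -S[, 3] / params$tau_GABA + rI1,
    -S[, 4] / params$tau_GABA + rI2
  )
}

fourvar_jacobian <- function(S, A, params, Ist = c(0, 0)) {
  x <- as.numeric(A %*% S)
  x[1:2] <- x[1:2] + params$I0_E + Ist
  x[3:4] <- x[3:4] + params$I0_I
  r <- c(transfer_rate(x[1:2], params$gain_E),
         transfer_rate(x[3:4], params$gain_I))
  dr <- c(transfer_rate_deriv(x[1:2], params$gain_E),
          transfer_rate_deriv(x[3:4], params$gain_I))
  gk <- params$gamma_kinetic
  J <- matrix(0, 4, 4)
  for (i in 1:2) {
    J[i, ] <- (1 - S[i]) * gk * dr[i] * A[i, ]
    J[i, i] <- J[i, i] - 1 / params$tau_NMDA - gk * r[i]
  }
  for (i in 3:4) {
    J[i, ] <- dr[i] * A[i, ]
    J[i, i] <- J[i, i] - 1 / params$tau_GABA
  }
  J
}

#' Simulate one stochastic trial of the four-variable model
#'
#' Euler integration of the four coupled activation equations. Only the
#' excitatory populations receive the evidence stimulus; AMPA-filtered
#' Gaussian noise (amplitude `noise_sd`) enters the inputs of all four
#' populations. Excitatory activations are confined to `[0, 1]`; inhibitory
#' activations are nonnegative (their scale is `tau_GABA` times the
#' inhibitory rate).
#'
#' @param params A [fourvar_params()] object.
#' @param coherence Signed stimulus coherence (percent).
#' @param schedule A [trial_schedule()].
#' @param seed Integer seed.
#' @param init Initial state `c(S_E1, S_E2, S_I1, S_I2)`; `NA` inhibitory
#'   entries are replaced by their fast steady state given the excitatory
#'   state (the GABA activations equilibrate within `tau_GABA`, so starting
#'   them off their slow manifold only injects an artificial transient).
#' @param n Number of trials (vectorised); the returned tibble contains trial
#'   1, with all-trial matrices in attribute `matrices` when `n > 1`.
#' @return A tibble of class `fourvar_trajectory` with columns `time`, `S_E1`,
#'   `S_E2`, `S_I1`, `S_I2`, `rE1`, `rE2`, `rI1`, `rI2`.
#' @export
simulate_fourvar <- function(params, coherence = 0,
                             schedule = trial_schedule(), seed = NULL,
                             init = c(0.1, 0.1, NA, NA), n = 1) {
  stopifnot(inherits(params, "fourvar_params"))
  if (anyNA(init[3:4])) {
    si <- fourvar_settle_inhibition(params, init[1:2])
    init[3:4][is.na(init[3:4])] <- si[is.na(init[3:4])]
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  n_steps <- as.integer(round(schedule$t_total / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1)
  A <- fourvar_adjacency(params)
  base <- params$J_AMPA_ext * params$mu
  Ist_on <- c(base * (1 - coherence / 100), base * (1 + coherence / 100))

  S <- matrix(rep(init, each = n), n, 4)
  Ieta <- matrix(0, n, 4)
  store <- array(NA_real_, c(n, n_steps + 1, 8))
  gk <- params$gamma_kinetic

  rates_of <- function(S, Ist) {
    x <- S %*% t(A)
    x[, 1] <- x[, 1] + params$I0_E + Ist[1]
    x[, 2] <- x[, 2] + params$I0_E + Ist[2]
    x[, 3] <- x[, 3] + params$I0_I
    x[, 4] <- x[, 4] + params$I0_I
    cbind(transfer_rate(x[, 1], params$gain_E),
          transfer_rate(x[, 2], params$gain_E),
          transfer_rate(x[, 3], params$gain_I),
          transfer_rate(x[, 4], params$gain_I))
  }

  r <- rates_of(S, c(0, 0))
  store[, 1, ] <- cbind(S, r)
  for (k in seq_len(n_steps)) {
    t_k <- times[k + 1]
    on <- t_k >= schedule$t_on && t_k < schedule$t_off
    Ist <- if (on) Ist_on else c(0, 0)
    if (params$noise_sd > 0) {
      # population order of draws: E1, E2, I1, I2 at each step
      z <- matrix(stats::rnorm(4 * n), n, 4)
      Ieta <- step_noise(Ieta, dt, params$noise_sd, params$tau_AMPA, z,
                         params$noise_convention)
    }
    x <- S %*% t(A) + Ieta
    x[, 1] <- x[, 1] + params$I0_E + Ist[1]
    x[, 2] <- x[, 2] + params$I0_E + Ist[2]
    x[, 3] <- x[, 3] + params$I0_I
    x[, 4] <- x[, 4] + params$I0_I
    rE1 <- transfer_rate(x[, 1], params$gain_E)
    rE2 <- transfer_rate(x[, 2], params$gain_E)
    rI1 <- transfer_rate(x[, 3], params$gain_I)
    rI2 <- transfer_rate(x[, 4], params$gain_I)
    S[, 1] <- S[, 1] + dt * (-S[, 1] / params$tau_NMDA + (1 - S[, 1]) * gk * rE1)
    S[, 2] <- S[, 2] + dt * (-S[, 2] / params$tau_NMDA + (1 - S[, 2]) * gk * rE2)
    S[, 3] <- S[, 3] + dt * (-S[, 3] / params$tau_GABA + rI1)
    S[, 4] <- S[, 4] + dt * (-S[, 4] / params$tau_GABA + rI2)
    eps <- 1e-6
    abort_if(any(S[, 1:2] < -eps | S[, 1:2] > 1 + eps),
             "simulate_fourvar(): excitatory activation left [0, 1]")
    S[, 1:2] <- pmin(pmax(S[, 1:2], 0), 1)
    S[, 3:4] <- pmax(S[, 3:4], 0)
    store[, k + 1, ] <- cbind(S, rates_of(S, Ist))
  }

  out <- tibble::tibble(
    time = times,
    S_E1 = store[1, , 1], S_E2 = store[1, , 2],
    S_I1 = store[1, , 3], S_I2 = store[1, , 4],
    rE1 = store[1, , 5], rE2 = store[1, , 6],
    rI1 = store[1, , 7], rI2 = store[1, , 8]
  )
  attr(out, "schedule") <- schedule
  attr(out, "coherence") <- coherence
  attr(out, "seed") <- seed
  if (n > 1) attr(out, "matrices") <- store
  class(out) <- c("fourvar_trajectory", class(out))
  out
}

#' Steady-state inhibitory activations given a frozen excitatory state
#'
#' Solves `S_I = tau_GABA * Phi_I(x_I)` for the two inhibitory populations by
#' fixed-point iteration with the excitatory activations held fixed. Used to
#' start simulations on the fast (GABA) manifold.
#'
#' @param params A [fourvar_params()] object.
#' @param S_E Excitatory activation pair.
#' @return Inhibitory activation pair.
#' @export
fourvar_settle_inhibition <- function(params, S_E) {
  A <- fourvar_adjacency(params)
  AII <- A[3:4, 3:4]
  si <- c(0.5, 0.5)
  for (i in 1:100) {
    x <- as.numeric(A %*% c(S_E, si))[3:4] + params$I0_I
    g <- params$tau_GABA * transfer_rate(x, params$gain_I) - si
    if (max(abs(g)) < 1e-12) break
    dphi <- transfer_rate_deriv(x, params$gain_I)
    J <- params$tau_GABA * (dphi * AII) - diag(2)
    step <- tryCatch(solve(J, -g), error = function(e) -g)
    nrm <- sqrt(sum(step^2))
    if (nrm > 0.2) step <- step * 0.2 / nrm
    si <- pmax(si + step, 0)
  }
  si
}

#' Fixed points and classification of the four-variable model
#'
#' Multistart Newton root finding in the four-dimensional state space,
#' deduplication, stability classification from the analytic Jacobian, and
#' decision-circuit labeling by projecting onto the excitatory coordinates
#' (same taxonomy as [label_fixed_points()]).
#'
#' @param params A [fourvar_params()] object.
#' @param stim `NULL` for the unstimulated system or a coherence (percent).
#' @param grid_e Number of grid levels per excitatory coordinate.
#' @param grid_i Number of grid levels per inhibitory coordinate.
#' @param tol Residual tolerance (`max |dS/dt|`).
#' @param dedup Deduplication radius.
#' @return A tibble of class `fourvar_fixedpoints` with the state, excitatory
#'   rates, `residual`, `stability` and `tau_slow`.
#' @export
find_fixed_points_fourvar <- function(params, stim = NULL, grid_e = 9,
                                      grid_i = 4, tol = 1e-6, dedup = 1e-4) {
  stopifnot(inherits(params, "fourvar_params"))
  A <- fourvar_adjacency(params)
  Ist <- if (is.null(stim) || (length(stim) == 1 && is.na(stim))) c(0, 0) else {
    base <- params$J_AMPA_ext * params$mu
    c(base * (1 - stim / 100), base * (1 + stim / 100))
  }
  # inhibitory activations live on [0, tau_GABA * max rate]; 0.6 is generous
  ge <- seq(0, 1, length.out = grid_e)
  gi <- seq(0, 0.6, length.out = grid_i)
  starts <- as.matrix(expand.grid(ge, ge, gi, gi))

  roots <- list()
  for (i in seq_len(nrow(starts))) {
    s <- starts[i, ]
    ok <- FALSE
    for (it in 1:100) {
      f <- as.numeric(fourvar_field(s, A, params, Ist))
      if (max(abs(f)) < 1e-10) { ok <- TRUE; break }
      J <- fourvar_jacobian(s, A, params, Ist)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      nrm <- sqrt(sum(step^2))
      if (nrm > 0.25) step <- step * 0.25 / nrm
      s <- s + step
      if (any(!is.finite(s)) || any(abs(s) > 3)) break
    }
    if (ok && all(s[1:2] > -1e-9 & s[1:2] < 1 + 1e-9) && all(s[3:4] > -1e-9)) {
      roots[[length(roots) + 1]] <- s
    }
  }
  if (length(roots) == 0) {
    out <- tibble::tibble(S_E1 = numeric(), S_E2 = numeric(), S_I1 = numeric(),
                          S_I2 = numeric(), rE1 = numeric(), rE2 = numeric(),
                          residual = numeric(), stability = character(),
                          tau_slow = numeric())
    class(out) <- c("fourvar_fixedpoints", class(out))
    return(out)
  }
  R <- do.call(rbind, roots)
  keep <- rep(TRUE, nrow(R))
  for (i in seq_len(nrow(R))) {
    if (!keep[i] || i == nrow(R)) next
    j <- (i + 1):nrow(R)
    d <- sqrt(rowSums((R[j, , drop = FALSE] -
                         matrix(R[i, ], length(j), 4, byrow = TRUE))^2))
    keep[j][d < dedup] <- FALSE
  }
  R <- R[keep, , drop = FALSE]

  rows <- lapply(seq_len(nrow(R)), function(i) {
    s <- R[i, ]
    f <- as.numeric(fourvar_field(s, A, params, Ist))
    J <- fourvar_jacobian(s, A, params, Ist)
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    stab <- if (all(re < 0)) "attractor"
    else if (sum(re > 0) == 1 && abs(Im(ev[which.max(re)])) < 1e-9) "saddle"
    else "repeller"
    x <- as.numeric(A %*% s)
    tibble::tibble(
      S_E1 = s[1], S_E2 = s[2], S_I1 = s[3], S_I2 = s[4],
      rE1 = transfer_rate(x[1] + params$I0_E + Ist[1], params$gain_E),
      rE2 = transfer_rate(x[2] + params$I0_E + Ist[2], params$gain_E),
      residual = max(abs(f)),
      stability = stab,
      tau_slow = if (stab == "saddle") 1 / max(re) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$residual <= tol, ]
  out <- out[order(out$S_E1 + out$S_E2, out$S_E1), ]
  class(out) <- c("fourvar_fixedpoints", class(out))
  out
}

#' Classify a four-variable circuit
#'
#' Labels the unstimulated and neutrally stimulated fixed-point sets of the
#' four-variable model via their excitatory projection, using the same
#' taxonomy as the two-variable classifier.
#'
#' @inheritParams find_fixed_points_fourvar
#' @param ... Passed to [find_fixed_points_fourvar()].
#' @return The one-row classification tibble of [label_fixed_points()].
#' @export
classify_fourvar <- function(params, ...) {
  as_two <- function(fp) {
    out <- fp
    names(out)[names(out) == "S_E1"] <- "S1"
    names(out)[names(out) == "S_E2"] <- "S2"
    out
  }
  label_fixed_points(as_two(find_fixed_points_fourvar(params, stim = NULL, ...)),
                     as_two(find_fixed_points_fourvar(params, stim = 0, ...)))
}

#' Scan inhibitory-inhibitory specificity in the four-variable model
#'
#' Classifies circuits over a grid of the four specificity parameters.
#'
#' @param params Template [fourvar_params()].
#' @param gamma_EE,gamma_EI,gamma_IE,gamma_II Numeric grids.
#' @param ... Passed to [find_fixed_points_fourvar()].
#' @return A tibble with one row per grid point (specificities, `spec_index`,
#'   classification flags).
#' @export
scan_fourvar <- function(params = fourvar_params(),
                         gamma_EE = c(0.25, 0.32, 0.4),
                         gamma_EI = c(0, 0.25, 0.5),
                         gamma_IE = seq(-0.6, 0.6, by = 0.3),
                         gamma_II = c(-0.5, 0, 0.5), ...) {
  pts <- expand.grid(gamma_EE = gamma_EE, gamma_EI = gamma_EI,
                     gamma_IE = gamma_IE, gamma_II = gamma_II,
                     KEEP.OUT.ATTRS = FALSE)
  purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    p <- fourvar_params(gamma_EE = pts$gamma_EE[i], gamma_EI = pts$gamma_EI[i],
                        gamma_IE = pts$gamma_IE[i], gamma_II = pts$gamma_II[i])
    dplyr::bind_cols(
      tibble::tibble(gamma_EE = pts$gamma_EE[i], gamma_EI = pts$gamma_EI[i],
                     gamma_IE = pts$gamma_IE[i], gamma_II = pts$gamma_II[i],
                     spec_index = pts$gamma_EI[i] * pts$gamma_IE[i]),
      classify_fourvar(p, ...)
    )
  })
}
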