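#' One update of the filtered synaptic noise current
#'
#' The noise current is an Ornstein-Uhlenbeck process: white Gaussian noise
#' filtered through the fast AMPA time constant. The Euler-Maruyama update is
#' `I <- I * (1 - dt/tau_AMPA) + sqrt(dt) * (sd_eff / sqrt(tau_AMPA)) * z`
#' with standard-normal `z`. Under the `"amplitude"` convention
#' `sd_eff = noise_sd` and the stationary standard deviation of `I` is
#' `noise_sd / sqrt(2 - dt/tau_AMPA)`; the `"stationary"` convention rescales
#' `sd_eff` so the stationary s.d. equals `noise_sd` itself.
#'
#' @param I_eta Current noise state (nA), vectorised.
#' @param dt Time step (s).
#' @param noise_sd Noise amplitude (nA).
#' @param tau_AMPA Filter time constant (s).
#' @param z Standard-normal draws (defaults to fresh draws from the session
#'   RNG, one per element of `I_eta`).
#' @param convention `"amplitude"` or `"stationary"` (see above).
#' @return Updated noise current, same shape as `I_eta`.
#' @export
step_noise <- function(I_eta, dt, noise_sd, tau_AMPA,
                       z = stats::rnorm(length(I_eta)),
                       convention = c("amplitude", "stationary")) {
  convention <- match.arg(convention)
  abort_if(dt <= 0, "step_noise(): dt must be positive")
  sd_eff <- if (convention == "stationary") {
    noise_sd * sqrt(2 - dt / tau_AMPA)
  } else {
    noise_sd
  }
  I_eta * (1 - dt / tau_AMPA) + sqrt(dt) * (sd_eff / sqrt(tau_AMPA)) * z
}

#' Stationary standard deviation implied by the noise discretisation
#'
#' Closed form of the stationary s.d. of the discretised noise process, used
#' as the oracle for the noise-variance tests.
#'
#' @inheritParams step_noise
#' @return Stationary s.d. (nA).
#' @export
noise_stationary_sd <- function(noise_sd, dt, tau_AMPA,
                                convention = c("amplitude", "stationary")) {
  convention <- match.arg(convention)
  if (convention == "stationary") return(noise_sd)
  a <- 1 - dt / tau_AMPA
  sqrt(dt * noise_sd^2 / tau_AMPA / (1 - a^2))
}

# Core Euler integrator, vectorised over trials. Returns recorded matrices
# (trials x time points, including the t = 0 state). `delta_nu` shifts nu0_I
# during the stimulus window only (inhibitory perturbation experiments).
# `mirror = TRUE` swaps the two per-population noise streams (used by the
# equivariance tests). Population-1 noise is drawn before population-2 noise
# at every step, from a single generator seeded once per call.
mf_integrate <- function(params, stim, n = 1, seed = NULL,
                         schedule = trial_schedule(),
                         init = c(0.1, 0.1), delta_nu = 0,
                         record = c("full", "rates"), mirror = FALSE) {
  record <- match.arg(record)
  stopifnot(inherits(params, "circuit_params"), inherits(stim, "stimulus_spec"))
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  n_steps <- as.integer(round(schedule$t_total / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1)

  cpl <- derive_couplings(params)
  cpl_stim <- if (delta_nu != 0) {
    p2 <- params; p2$nu0_I <- p2$nu0_I + delta_nu
    derive_couplings(validate_circuit_params(p2))
  } else cpl

  base_stim <- params$J_AMPA_ext * stim$mu
  Ist1_on <- base_stim * (1 - stim$coherence / 100)
  Ist2_on <- base_stim * (1 + stim$coherence / 100)

  S1 <- rep(init[1], n); S2 <- rep(init[2], n)
  Ieta1 <- numeric(n); Ieta2 <- numeric(n)

  full <- record == "full"
  if (full) {
    m <- function() matrix(NA_real_, n, n_steps + 1)
    R <- list(S1 = m(), S2 = m(), rE1 = m(), rE2 = m(),
              rI1 = m(), rI2 = m(), Ieta1 = m(), Ieta2 = m())
  } else {
    rE1m <- matrix(NA_real_, n, n_steps + 1)
    rE2m <- matrix(NA_real_, n, n_steps + 1)
  }

  # Reported population rates are the read-out of the slow NMDA state
  # (transfer function of the state-driven input, noise current excluded);
  # the noise current shapes the dynamics and is recorded separately.
  record_state <- function(k, cc) {
    x1 <- cc$alpha1 * S1 + cc$alpha2 * S2 + cc$I0_1 + Ist1_k
    x2 <- cc$alpha1 * S2 + cc$alpha2 * S1 + cc$I0_2 + Ist2_k
    r1 <- transfer_rate(x1, params$gain_E)
    r2 <- transfer_rate(x2, params$gain_E)
    if (full) {
      R$S1[, k] <<- S1; R$S2[, k] <<- S2
      R$rE1[, k] <<- r1; R$rE2[, k] <<- r2
      rI <- inhibitory_rates(pmin(pmax(S1, 0), 1), pmin(pmax(S2, 0), 1), cc)
      R$rI1[, k] <<- rI$rI1; R$rI2[, k] <<- rI$rI2
      R$Ieta1[, k] <<- Ieta1; R$Ieta2[, k] <<- Ieta2
    } else {
      rE1m[, k] <<- r1; rE2m[, k] <<- r2
    }
    list(r1 = r1, r2 = r2)
  }

  Ist1_k <- 0; Ist2_k <- 0
  rr <- record_state(1, cpl)
  tau_inv <- 1 / params$tau_NMDA
  gk <- params$gamma_kinetic
  for (k in seq_len(n_steps)) {
    t_k <- times[k + 1]
    on <- t_k >= stim$t_on && t_k < stim$t_off
    cc <- if (on) cpl_stim else cpl
    Ist1_k <- if (on) Ist1_on else 0
    Ist2_k <- if (on) Ist2_on else 0
    if (params$noise_sd > 0) {
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      if (mirror) { tmp <- z1; z1 <- z2; z2 <- tmp }
      Ieta1 <- step_noise(Ieta1, dt, params$noise_sd, params$tau_AMPA, z1,
                          params$noise_convention)
      Ieta2 <- step_noise(Ieta2, dt, params$noise_sd, params$tau_AMPA, z2,
                          params$noise_convention)
    } else {
      Ieta1 <- Ieta1 * (1 - dt / params$tau_AMPA)
      Ieta2 <- Ieta2 * (1 - dt / params$tau_AMPA)
    }
    x1 <- cc$alpha1 * S1 + cc$alpha2 * S2 + cc$I0_1 + Ist1_k + Ieta1
    x2 <- cc$alpha1 * S2 + cc$alpha2 * S1 + cc$I0_2 + Ist2_k + Ieta2
    r1 <- transfer_rate(x1, params$gain_E)
    r2 <- transfer_rate(x2, params$gain_E)
    S1 <- S1 + dt * (-S1 * tau_inv + (1 - S1) * gk * r1)
    S2 <- S2 + dt * (-S2 * tau_inv + (1 - S2) * gk * r2)
    eps <- 1e-6
    abort_if(any(S1 < -eps | S1 > 1 + eps | S2 < -eps | S2 > 1 + eps),
             "mf_integrate(): NMDA activation left [0, 1]; integration is unstable")
    S1 <- pmin(pmax(S1, 0), 1); S2 <- pmin(pmax(S2, 0), 1)
    record_state(k + 1, cc)
  }

  out <- list(times = times, schedule = schedule, stim = stim,
              seed = seed, n = n)
  if (full) c(out, R) else c(out, list(rE1 = rE1m, rE2 = rE2m))
}

#' Simulate one stochastic trial of the two-variable model
#'
#' Integrates the two NMDA activations with the Euler method at `dt` (2 ms by
#' default), with evidence input during the stimulus epoch and
#' AMPA-filtered Gaussian noise throughout. Excitatory rates are the
#' transfer-function output; inhibitory rates are affine read-outs of the
#' activations (floored at zero when reported).
#'
#' @param params A [circuit_params()] object.
#' @param stim A [stimulus_spec()]; if `NULL`, one is built from `coherence`
#'   and the schedule.
#' @param coherence Signed coherence in percent (used when `stim` is `NULL`).
#' @param schedule A [trial_schedule()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   trajectories.
#' @param init Initial activations `c(S1, S2)` (noise currents start at 0).
#' @param delta_nu Perturbation of `nu0_I` (Hz) applied during the stimulus
#'   window only.
#' @return A tibble of class `mf_trajectory` with columns `time`, `S1`, `S2`,
#'   `rE1`, `rE2`, `rI1`, `rI2`, `Ieta1`, `Ieta2` and the trial metadata in
#'   attributes `stim`, `schedule`, `seed`, `params_hash`.
#' @examples
#' p <- circuit_params()
#' traj <- simulate_trial(p, coherence = 20, seed = 1)
#' @export
simulate_trial <- function(params, stim = NULL, coherence = 0,
                           schedule = trial_schedule(), seed = NULL,
                           init = c(0.1, 0.1), delta_nu = 0) {
  if (is.null(stim)) {
    stim <- stimulus_spec(coherence = coherence, t_on = schedule$t_on,
                          t_off = schedule$t_off)
  }
  r <- mf_integrate(params, stim, n = 1, seed = seed, schedule = schedule,
                    init = init, delta_nu = delta_nu, record = "full")
  out <- tibble::tibble(
    time = r$times,
    S1 = r$S1[1, ], S2 = r$S2[1, ],
    rE1 = r$rE1[1, ], rE2 = r$rE2[1, ],
    rI1 = r$rI1[1, ], rI2 = r$rI2[1, ],
    Ieta1 = r$Ieta1[1, ], Ieta2 = r$Ieta2[1, ]
  )
  attr(out, "stim") <- stim
  attr(out, "schedule") <- schedule
  attr(out, "seed") <- seed
  attr(out, "params_hash") <- hash_of(unclass(params))
  class(out) <- c("mf_trajectory", class(out))
  out
}
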