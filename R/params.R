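#' Parameters of the two-variable decision-circuit model
#'
#' Builds the full parameter set of the reduced two-variable mean-field model:
#' physiological constants of the underlying six-population circuit, the three
#' connection-specificity parameters, the baseline drive to inhibitory
#' neurons, and numerical settings for stochastic trial integration.
#'
#' Two effective GABA couplings onto excitatory cells are package-level
#' calibration constants rather than raw physiological conductances:
#' `g_E_rec_GABA_loop` (the strength of the disynaptic
#' excitation-inhibition-excitation loop between selective populations) and
#' `g_E_rec_GABA_bg` (the strength with which baseline inhibitory activity
#' suppresses the excitatory background current). They are fixed once so that
#' at the reference circuit (`gamma_EE = 0.32`, `gamma_EI = 0.25`,
#' `gamma_IE = 0`) the effective couplings match the canonical two-variable
#' reduction that the `lambda_1`, `lambda_2` scalings presuppose, and
#' so that the range of `nu0_I` that supports decision-making spans its stated
#' operating range `[9, 16]` Hz. See the methods vignette for the calibration.
#'
#' @param gamma_EE Excitatory-to-excitatory connection specificity in `[0, 1]`.
#' @param gamma_EI Excitatory-to-inhibitory specificity in `[0, 1]`; controls
#'   how choice-selective the inhibitory populations are.
#' @param gamma_IE Inhibitory-to-excitatory specificity in `[-1, 1]`; negative
#'   values define a contraspecific motif, positive an ipsispecific motif,
#'   zero a nonspecific motif.
#' @param nu0_I Baseline drive to inhibitory neurons (Hz), in `[9, 16]`.
#' @param f Fraction of neurons in each choice-selective population,
#'   in `[0.13, 0.2]`.
#' @param noise_sd White-noise amplitude of the synaptic noise current (nA).
#' @param noise_convention `"amplitude"` (default) treats `noise_sd` as the
#'   white-noise amplitude, giving a stationary noise s.d. of
#'   `noise_sd / sqrt(2)`; `"stationary"` rescales so the stationary s.d. of
#'   the filtered noise current equals `noise_sd`.
#' @param dt Integration time step (s).
#' @param ... Overrides for any physiological constant (use the field names of
#'   the returned object, e.g. `tau_NMDA`, `g_E_rec_NMDA`, `nu_ext`).
#' @return An object of class `circuit_params` (a named list).
#' @seealso [derive_couplings()], [simulate_trial()], [find_fixed_points()]
#' @examples
#' p <- circuit_params()
#' p$gamma_EE
#' @export
circuit_params <- function(gamma_EE = 0.32, gamma_EI = 0.25, gamma_IE = 0,
                           nu0_I = 11.5, f = 0.15,
                           noise_sd = 0.02,
                           noise_convention = c("amplitude", "stationary"),
                           dt = 0.002, ...) {
  noise_convention <- match.arg(noise_convention)
  p <- list(
    gamma_EE = gamma_EE, gamma_EI = gamma_EI, gamma_IE = gamma_IE,
    nu0_I = nu0_I, f = f,
    # population sizes
    N_E = 1600, N_I = 400, N_ext = 800, N_s = 2,
    # synaptic time constants (s)
    tau_NMDA = 0.1, tau_AMPA = 0.002, tau_GABA = 0.005,
    # rate-to-NMDA-activation kinetic factor
    gamma_kinetic = 0.641,
    # linearised inhibitory f-I curve
    I_mI = 177, c_I = 615, g_I2 = 2,
    # background input rates (Hz)
    nu_ext = 3, nu_3_in = 2,
    # potentials (mV)
    V_E = -53.4, V_I = -52.1, E_E = 0, E_I = -70,
    # conductances (uS)
    g_E_rec_NMDA = 1.95e-4, g_I_rec_NMDA = 1.02e-4,
    g_I_rec_GABA = 0.0084,
    # calibrated effective GABA-onto-E couplings (uS); see vignette
    g_E_rec_GABA_loop = 0.477852 / 16.6,
    g_E_rec_GABA_bg = 0.216731 / 16.6,
    g_E_ext_AMPA = 2.1e-3, g_I_ext_AMPA = 1.62e-3,
    # external stimulus current per input event (nA/Hz)
    J_AMPA_ext = 5.2e-4,
    # scaling factors of the reduction
    lambda_1 = 1.6719, lambda_2 = 1.8844, lambda_I = 0.9229,
    # excitatory transfer-function gain triple (1/nC, Hz, s)
    gain_E = c(a = 270, b = 108, d = 0.154),
    # integration settings
    noise_sd = noise_sd, noise_convention = noise_convention, dt = dt
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  abort_if(length(unknown) > 0,
           paste0("circuit_params(): unknown parameter(s): ",
                  paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  validate_circuit_params(structure(p, class = "circuit_params"))
}

validate_circuit_params <- function(p) {
  abort_if(p$gamma_EE < 0 || p$gamma_EE > 1, "gamma_EE must lie in [0, 1]")
  abort_if(p$gamma_EI < 0 || p$gamma_EI > 1, "gamma_EI must lie in [0, 1]")
  abort_if(abs(p$gamma_IE) > 1, "gamma_IE must lie in [-1, 1]")
  abort_if(1 - p$N_s * p$f <= 0, "nonselective pool must be nonempty: N_s * f < 1")
  abort_if(p$f <= 0 || p$f >= 0.5, "f must lie in (0, 0.5)")
  pos <- c("N_E", "N_I", "N_ext", "N_s", "tau_NMDA", "tau_AMPA", "tau_GABA", "dt")
  for (nm in pos) abort_if(p[[nm]] <= 0, paste0(nm, " must be positive"))
  abort_if(p$noise_sd < 0, "noise_sd must be nonnegative")
  p
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  specificity: gamma_EE = %.3g, gamma_EI = %.3g, gamma_IE = %.3g\n",
              x$gamma_EE, x$gamma_EI, x$gamma_IE))
  cat(sprintf("  baseline inhibitory drive nu0_I = %.3g Hz; f = %.3g\n",
              x$nu0_I, x$f))
  cat(sprintf("  noise_sd = %.3g nA (%s convention); dt = %.3g s\n",
              x$noise_sd, x$noise_convention, x$dt))
  invisible(x)
}

#' Trial epoch schedule
#'
#' Timing of a simulated behavioural trial: a pre-stimulus epoch, a stimulus
#' epoch and a post-stimulus delay. Defaults follow the package's standard
#' protocol (0.5 s / 1 s / 1 s).
#'
#' @param t_pre Pre-stimulus duration (s).
#' @param t_stim Stimulus duration (s).
#' @param t_post Post-stimulus delay duration (s).
#' @return A `trial_schedule` list with onset/offset times.
#' @export
trial_schedule <- function(t_pre = 0.5, t_stim = 1.0, t_post = 1.0) {
  abort_if(any(c(t_pre, t_stim, t_post) < 0), "epoch durations must be >= 0")
  abort_if(t_stim <= 0, "stimulus epoch must have positive duration")
  structure(
    list(t_pre = t_pre, t_stim = t_stim, t_post = t_post,
         t_on = t_pre, t_off = t_pre + t_stim,
         t_total = t_pre + t_stim + t_post),
    class = "trial_schedule"
  )
}
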