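#' Effective couplings of the two-variable reduction
#'
#' Collapses the six-population circuit (two choice-selective excitatory, one
#' nonselective excitatory, two choice-selective inhibitory, one nonselective
#' inhibitory population) into the three constants that drive the two-variable
#' dynamics: `alpha1` (how a population's NMDA activation feeds back onto its
#' own input current, directly and through the inhibitory populations),
#' `alpha2` (how it reaches the opposite population), and the background
#' current `I0` (identical for both populations). Also returns the affine
#' coefficients used to report inhibitory population rates.
#'
#' Each `alpha` is a scaled sum of four components: (a) the direct excitatory
#' coupling and the disynaptic loops through (b) the same-preference
#' inhibitory population, (c) the opposite-preference inhibitory population
#' and (d) the nonselective inhibitory population. Inhibitory loop components
#' enter with a negative sign; the `J_GABA` constants are magnitudes. Because
#' the specificity mapping conserves `w_plus + w_minus`, the summed direct
#' components are independent of `gamma_EE` and the summed loop components
#' independent of `gamma_EI` and `gamma_IE`.
#'
#' @param params A [circuit_params()] object.
#' @return A `derived_couplings` list with elements `alpha1`, `alpha2`, `I0_1`,
#'   `I0_2` (nA), their unscaled components, the derived synaptic constants
#'   (`kappa`, effective `J` currents, `psi_3in`) and the inhibitory-rate
#'   coefficients `alpha1_I`, `alpha2_I`, `I0_II` (Hz).
#' @examples
#' dc <- derive_couplings(circuit_params())
#' c(dc$alpha1, dc$alpha2, dc$I0_1)
#' @export
derive_couplings <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  p <- params

  # effective synaptic currents (nA); GABA constants are magnitudes
  J_GABA_E_loop <- -p$g_E_rec_GABA_loop * (p$E_I - p$V_E)
  J_GABA_E_bg   <- -p$g_E_rec_GABA_bg * (p$E_I - p$V_E)
  J_GABA_I      <- -p$g_I_rec_GABA * (p$E_I - p$V_I)
  J_AMPA_ext_E  <- p$g_E_ext_AMPA * (p$E_E - p$V_E)
  J_AMPA_ext_I  <- p$g_I_ext_AMPA * (p$E_E - p$V_I)
  J_NMDAeff_E <- p$g_E_rec_NMDA * (p$E_E - p$V_E) / (1 + exp(-0.062 * p$V_E) / 3.57)
  J_NMDAeff_I <- p$g_I_rec_NMDA * (p$E_E - p$V_I) / (1 + exp(-0.062 * p$V_I) / 3.57)

  kappa <- 1 + (p$c_I / p$g_I2) * p$N_I * J_GABA_I * p$tau_GABA
  psi_3in <- p$gamma_kinetic * p$tau_NMDA * p$nu_3_in /
    (1 + p$gamma_kinetic * p$tau_NMDA * p$nu_3_in)

  w_EE <- specificity_to_weights(p$gamma_EE, p$N_s)
  w_EI <- specificity_to_weights(p$gamma_EI, p$N_s)
  w_IE <- specificity_to_weights(p$gamma_IE, p$N_s)

  # disynaptic E -> I -> E loop gain per unit product of (E->I) x (I->E) weights
  loop <- (p$c_I * p$f * p$N_E * J_NMDAeff_I) *
    (p$f * p$N_I * J_GABA_E_loop * p$tau_GABA) / (kappa * p$g_I2)

  alpha1_components <- c(
    a = p$f * p$N_E * w_EE$w_plus * J_NMDAeff_E,
    b = -loop * w_EI$w_plus * w_IE$w_plus,
    c = -loop * w_EI$w_minus * w_IE$w_minus,
    d = -loop
  )
  alpha2_components <- c(
    a = p$f * p$N_E * w_EE$w_minus * J_NMDAeff_E,
    b = -loop * w_EI$w_minus * w_IE$w_plus,
    c = -loop * w_EI$w_plus * w_IE$w_minus,
    d = -loop
  )

  # background inputs: nonselective excitation, external drive, and the
  # baseline inhibitory rate fed back through GABA synapses
  I_AMPA_ext_E <- J_AMPA_ext_E * p$tau_AMPA * p$N_ext * p$nu_ext
  I_AMPA_ext_I <- J_AMPA_ext_I * p$tau_AMPA * p$N_ext * p$nu_ext
  I0_I <- I_AMPA_ext_I + J_NMDAeff_I * (1 - p$N_s * p$f) * p$N_E * psi_3in
  r_I0 <- p$nu0_I + (p$c_I * I0_I - p$I_mI) / p$g_I2
  r_I0_k <- r_I0 / kappa

  I0_components <- c(
    a = (1 - p$N_s * p$f) * p$N_E * J_NMDAeff_E * psi_3in,
    b = I_AMPA_ext_E -
      (1 - p$N_s * p$f) * p$N_I * J_GABA_E_bg * p$tau_GABA * r_I0_k,
    c = -p$f * w_IE$w_plus * p$N_I * J_GABA_E_bg * p$tau_GABA * r_I0_k,
    d = -p$f * w_IE$w_minus * p$N_I * J_GABA_E_bg * p$tau_GABA * r_I0_k
  )
  I0 <- p$lambda_I * sum(I0_components)

  structure(list(
    alpha1 = p$lambda_1 * sum(alpha1_components),
    alpha2 = p$lambda_2 * sum(alpha2_components),
    alpha1_components = alpha1_components,
    alpha2_components = alpha2_components,
    I0_1 = I0, I0_2 = I0, I0_components = I0_components,
    kappa = kappa, psi_3in = psi_3in,
    J_GABA_E_loop = J_GABA_E_loop, J_GABA_E_bg = J_GABA_E_bg,
    J_GABA_I = J_GABA_I,
    J_AMPA_ext_E = J_AMPA_ext_E, J_AMPA_ext_I = J_AMPA_ext_I,
    J_NMDAeff_E = J_NMDAeff_E, J_NMDAeff_I = J_NMDAeff_I,
    I0_I = I0_I,
    # affine coefficients of the reported inhibitory population rates
    alpha1_I = p$c_I * p$f * p$N_E * w_EI$w_plus * J_NMDAeff_I / p$g_I2,
    alpha2_I = p$c_I * p$f * p$N_E * w_EI$w_minus * J_NMDAeff_I / p$g_I2,
    I0_II = p$nu0_I + (p$c_I * I0_I - p$I_mI) / p$g_I2
  ), class = "derived_couplings")
}

#' Inhibitory population firing rates
#'
#' The reduced model does not integrate inhibitory state variables; inhibitory
#' rates are affine read-outs of the two excitatory NMDA activations,
#' `Phi_I1 = alpha1_I S1 + alpha2_I S2 + I0_II` (and symmetrically for the
#' second population). Reported rates are floored at 0 Hz; the flooring never
#' enters the excitatory dynamics, which depend on S only.
#'
#' @param S1,S2 NMDA activations in `[0, 1]` (vectorised).
#' @param couplings A [derive_couplings()] object.
#' @return A list with vectors `rI1`, `rI2` (Hz).
#' @export
inhibitory_rates <- function(S1, S2, couplings) {
  stopifnot(inherits(couplings, "derived_couplings"))
  abort_if(any(S1 < -1e-9 | S1 > 1 + 1e-9 | S2 < -1e-9 | S2 > 1 + 1e-9),
           "inhibitory_rates(): S must lie in [0, 1]")
  list(
    rI1 = pmax(couplings$alpha1_I * S1 + couplings$alpha2_I * S2 + couplings$I0_II, 0),
    rI2 = pmax(couplings$alpha1_I * S2 + couplings$alpha2_I * S1 + couplings$I0_II, 0)
  )
}
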