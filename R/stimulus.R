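#' Stimulus specification
#'
#' An evidence stimulus is an increase of rate `mu` in the external excitatory
#' input, split between the two populations by the signed coherence `c` (in
#' percent): population 1 receives `J_AMPA_ext * mu * (1 - c/100)` and
#' population 2 `J_AMPA_ext * mu * (1 + c/100)` while the stimulus is on.
#' Positive coherence therefore favours population 2.
#'
#' @param coherence Signed coherence in percent, in `[-100, 100]`.
#' @param mu Stimulus input rate (Hz).
#' @param t_on,t_off Stimulus onset/offset times (s).
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(coherence = 0, mu = 40, t_on = 0.5, t_off = 1.5) {
  abort_if(abs(coherence) > 100, "coherence must lie in [-100, 100]")
  abort_if(mu < 0, "mu must be >= 0")
  abort_if(t_on >= t_off, "t_on must be < t_off")
  structure(list(coherence = coherence, mu = mu, t_on = t_on, t_off = t_off),
            class = "stimulus_spec")
}

#' Stimulus currents at a given time
#'
#' @param t Time (s), vectorised.
#' @param stim A [stimulus_spec()].
#' @param J_AMPA_ext External current per input event (nA/Hz).
#' @return A list with vectors `I1`, `I2` (nA); zero outside `[t_on, t_off)`.
#' @export
stimulus_current <- function(t, stim, J_AMPA_ext = 5.2e-4) {
  stopifnot(inherits(stim, "stimulus_spec"))
  on <- as.numeric(t >= stim$t_on & t < stim$t_off)
  base <- J_AMPA_ext * stim$mu
  list(I1 = on * base * (1 - stim$coherence / 100),
       I2 = on * base * (1 + stim$coherence / 100))
}
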