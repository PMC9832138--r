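#' Current-to-rate transfer function
#'
#' The standard smoothed threshold-linear transfer function of reduced
#' attractor models, `Phi(x) = (a x - b) / (1 - exp(-d (a x - b)))`, mapping an
#' input current (nA) to a population firing rate (Hz). The function is
#' continuous through the removable singularity at `a x = b`, where its value
#' is `1/d`, and decays to zero for strongly hyperpolarising inputs.
#'
#' @param x Input current in nA (vectorised).
#' @param gain Gain triple `c(a, b, d)`: slope (1/nC), threshold (Hz) and
#'   curvature (s). Defaults to the excitatory-population values of the
#'   two-variable model.
#' @return Firing rate in Hz, same length as `x`.
#' @examples
#' transfer_rate(0.4)            # at the singular point: 1/0.154
#' transfer_rate(1.0)            # near-linear regime: ~ 270 - 108 = 162 Hz
#' @export
transfer_rate <- function(x, gain = c(a = 270, b = 108, d = 0.154)) {
  abort_if(any(!is.finite(x)), "transfer_rate(): input current must be finite")
  a <- gain[[1]]; b <- gain[[2]]; d <- gain[[3]]
  u <- a * x - b
  du <- d * u
  out <- numeric(length(u))
  sml <- abs(du) < 1e-9
  neg <- du < -500
  ok <- !sml & !neg
  # series expansion around the removable singularity: 1/d + u/2 + d u^2/12
  out[sml] <- 1 / d + u[sml] / 2 + d * u[sml]^2 / 12
  # for very negative currents 1 - exp(-du) overflows; use u * exp(du) -> 0
  out[neg] <- -u[neg] * exp(du[neg])
  out[ok] <- u[ok] / (1 - exp(-du[ok]))
  out
}

#' Derivative of the transfer function with respect to input current
#'
#' Closed-form `dPhi/dx`, used when assembling analytic Jacobians for the
#' fixed-point and stability analysis.
#'
#' @inheritParams transfer_rate
#' @return Derivative in Hz/nA, same length as `x`.
#' @export
transfer_rate_deriv <- function(x, gain = c(a = 270, b = 108, d = 0.154)) {
  abort_if(any(!is.finite(x)), "transfer_rate_deriv(): input current must be finite")
  a <- gain[[1]]; b <- gain[[2]]; d <- gain[[3]]
  u <- a * x - b
  du <- d * u
  out <- numeric(length(u))
  sml <- abs(du) < 1e-6
  neg <- du < -500
  ok <- !sml & !neg
  out[sml] <- a * (1 / 2 + d * u[sml] / 6)
  out[neg] <- a * exp(du[neg]) * (1 + du[neg]) * -1 # ~0; keep continuity
  e <- exp(-du[ok])
  out[ok] <- a * ((1 - e) - du[ok] * e) / (1 - e)^2
  out
}
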