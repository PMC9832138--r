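# Noiseless vector field of the two-variable model and its analytic Jacobian.
# `Ist` is the pair of stimulus currents (0 when the stimulus is off).
mf_field <- function(S1, S2, cpl, params, Ist = c(0, 0)) {
  x1 <- cpl$alpha1 * S1 + cpl$alpha2 * S2 + cpl$I0_1 + Ist[1]
  x2 <- cpl$alpha1 * S2 + cpl$alpha2 * S1 + cpl$I0_2 + Ist[2]
  r1 <- transfer_rate(x1, params$gain_E)
  r2 <- transfer_rate(x2, params$gain_E)
  gk <- params$gamma_kinetic
  list(
    f1 = -S1 / params$tau_NMDA + (1 - S1) * gk * r1,
    f2 = -S2 / params$tau_NMDA + (1 - S2) * gk * r2,
    x1 = x1, x2 = x2, r1 = r1, r2 = r2
  )
}

mf_jacobian_entries <- function(S1, S2, cpl, params, Ist = c(0, 0)) {
  fld <- mf_field(S1, S2, cpl, params, Ist)
  gk <- params$gamma_kinetic
  d1 <- transfer_rate_deriv(fld$x1, params$gain_E)
  d2 <- transfer_rate_deriv(fld$x2, params$gain_E)
  list(
    J11 = -1 / params$tau_NMDA - gk * fld$r1 + (1 - S1) * gk * d1 * cpl$alpha1,
    J12 = (1 - S1) * gk * d1 * cpl$alpha2,
    J21 = (1 - S2) * gk * d2 * cpl$alpha2,
    J22 = -1 / params$tau_NMDA - gk * fld$r2 + (1 - S2) * gk * d2 * cpl$alpha1,
    f1 = fld$f1, f2 = fld$f2
  )
}

stim_currents_for <- function(params, stim) {
  if (is.null(stim) || (length(stim) == 1 && is.na(stim))) return(c(0, 0))
  base <- params$J_AMPA_ext * 40
  c(base * (1 - stim / 100), base * (1 + stim / 100))
}

# multistart grid: uniform grid over [0,1]^2 plus canonical seeds
multistart_grid <- function(grid_n = 21) {
  g <- seq(0, 1, length.out = grid_n)
  pts <- as.matrix(expand.grid(S1 = g, S2 = g))
  seeds <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5),
                 c(0.5, 0), c(0, 0.5), c(1, 0.5), c(0.5, 1))
  unique(rbind(pts, seeds))
}

#' Fixed points of the noiseless two-variable dynamics
#'
#' Finds the equilibria of the deterministic system by damped root finding
#' from a multistart grid over the unit square, deduplicates the roots and
#' classifies each by the eigenvalues of the analytic Jacobian. For saddle
#' points, `tau_slow` (the inverse of the positive eigenvalue) sets the time
#' scale of escape along the unstable manifold and hence the pace of
#' decisions.
#'
#' @param params A [circuit_params()] object.
#' @param stim Stimulus strength: `NULL` (or `NA`) for the unstimulated plane,
#'   otherwise the signed coherence in percent with the stimulus on
#'   (`mu = 40` Hz); `stim = 0` is the neutral stimulated plane.
#' @param delta_nu Shift of `nu0_I` (Hz), e.g. for perturbation analyses.
#' @param grid_n Multistart grid resolution per axis (plus 9 canonical seeds).
#' @param tol Residual tolerance `max |dS/dt|` for an accepted root.
#' @param dedup Clustering radius for collapsing duplicate roots (S-space).
#' @param method `"newton"` (vectorised damped Newton with the analytic
#'   Jacobian; fast, used everywhere by default) or `"lm"`
#'   (Levenberg-Marquardt via \pkg{minpack.lm}, one solve per start).
#' @return A tibble of class `mf_fixedpoints`: columns `S1`, `S2`, `rE1`,
#'   `rE2`, `residual`, `eig1`, `eig2` (complex), `stability`
#'   (`attractor`/`saddle`/`repeller`) and `tau_slow` (s; `NA` unless saddle),
#'   ordered by `S1 + S2`. Zero rows if no root is found.
#' @examples
#' p <- circuit_params()
#' find_fixed_points(p)            # unstimulated plane: 5 fixed points
#' find_fixed_points(p, stim = 0)  # stimulated plane: 3 fixed points
#' @export
find_fixed_points <- function(params, stim = NULL, delta_nu = 0, grid_n = 21,
                              tol = 1e-6, dedup = 1e-4,
                              method = c("newton", "lm")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "circuit_params"))
  p2 <- params
  if (delta_nu != 0) {
    p2$nu0_I <- p2$nu0_I + delta_nu
    p2 <- validate_circuit_params(p2)
  }
  cpl <- derive_couplings(p2)
  Ist <- stim_currents_for(params, stim)
  starts <- multistart_grid(grid_n)

  roots <- if (method == "newton") {
    newton_multistart(starts, cpl, params, Ist)
  } else {
    lm_multistart(starts, cpl, params, Ist)
  }

  if (nrow(roots) == 0) return(empty_fixedpoints(stim))
  # deduplicate by clustering radius
  keep <- rep(TRUE, nrow(roots))
  for (i in seq_len(nrow(roots))) {
    if (!keep[i]) next
    if (i < nrow(roots)) {
      j <- (i + 1):nrow(roots)
      d <- sqrt((roots$S1[j] - roots$S1[i])^2 + (roots$S2[j] - roots$S2[i])^2)
      keep[j][d < dedup] <- FALSE
    }
  }
  roots <- roots[keep, , drop = FALSE]
  roots <- roots[roots$residual <= tol, , drop = FALSE]
  if (nrow(roots) == 0) return(empty_fixedpoints(stim))

  out <- classify_points(roots$S1, roots$S2, cpl, params, Ist)
  out <- out[order(out$S1 + out$S2, out$S1), ]
  attr(out, "stim") <- stim
  class(out) <- c("mf_fixedpoints", class(out))
  out
}

empty_fixedpoints <- function(stim) {
  out <- tibble::tibble(S1 = numeric(), S2 = numeric(), rE1 = numeric(),
                        rE2 = numeric(), residual = numeric(),
                        eig1 = complex(), eig2 = complex(),
                        stability = character(), tau_slow = numeric())
  attr(out, "stim") <- stim
  class(out) <- c("mf_fixedpoints", class(out))
  out
}

newton_multistart <- function(starts, cpl, params, Ist,
                              max_iter = 80, res_tol = 1e-10) {
  S1 <- starts[, 1]; S2 <- starts[, 2]
  active <- rep(TRUE, length(S1))
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    J <- mf_jacobian_entries(S1[active], S2[active], cpl, params, Ist)
    det <- J$J11 * J$J22 - J$J12 * J$J21
    det[abs(det) < 1e-14] <- 1e-14
    d1 <- -(J$J22 * J$f1 - J$J12 * J$f2) / det
    d2 <- -(-J$J21 * J$f1 + J$J11 * J$f2) / det
    # damp long steps to stay in the basin of the nearest root
    nrm <- pmax(sqrt(d1^2 + d2^2), 1e-300)
    sc <- pmin(1, 0.2 / nrm)
    S1[active] <- pmin(pmax(S1[active] + sc * d1, -0.2), 1.2)
    S2[active] <- pmin(pmax(S2[active] + sc * d2, -0.2), 1.2)
    f <- mf_field(S1[active], S2[active], cpl, params, Ist)
    conv <- pmax(abs(f$f1), abs(f$f2)) < res_tol
    idx <- which(active)
    active[idx[conv]] <- FALSE
  }
  f <- mf_field(S1, S2, cpl, params, Ist)
  res <- pmax(abs(f$f1), abs(f$f2))
  ok <- res < 1e-8 & S1 > -1e-9 & S1 < 1 + 1e-9 & S2 > -1e-9 & S2 < 1 + 1e-9
  tibble::tibble(S1 = pmin(pmax(S1[ok], 0), 1),
                 S2 = pmin(pmax(S2[ok], 0), 1),
                 residual = res[ok])
}

lm_multistart <- function(starts, cpl, params, Ist) {
  res_fn <- function(s) {
    f <- mf_field(s[1], s[2], cpl, params, Ist)
    c(f$f1, f$f2)
  }
  sols <- apply(starts, 1, function(s0) {
    fit <- minpack.lm::nls.lm(par = s0, fn = res_fn,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-15, ptol = 1e-15, maxiter = 200))
    c(fit$par, max(abs(res_fn(fit$par))))
  })
  S1 <- sols[1, ]; S2 <- sols[2, ]; res <- sols[3, ]
  ok <- res < 1e-8 & S1 > -1e-9 & S1 < 1 + 1e-9 & S2 > -1e-9 & S2 < 1 + 1e-9
  tibble::tibble(S1 = pmin(pmax(S1[ok], 0), 1),
                 S2 = pmin(pmax(S2[ok], 0), 1),
                 residual = res[ok])
}

classify_points <- function(S1, S2, cpl, params, Ist) {
  J <- mf_jacobian_entries(S1, S2, cpl, params, Ist)
  tr <- J$J11 + J$J22
  det <- J$J11 * J$J22 - J$J12 * J$J21
  disc <- as.complex(tr^2 - 4 * det)
  eig1 <- (tr + sqrt(disc)) / 2
  eig2 <- (tr - sqrt(disc)) / 2
  stability <- ifelse(Re(eig1) < 0 & Re(eig2) < 0, "attractor",
                      ifelse((Re(eig1) > 0) + (Re(eig2) > 0) == 1 &
                               abs(Im(eig1)) < 1e-12, "saddle", "repeller"))
  tau_slow <- ifelse(stability == "saddle", 1 / pmax(Re(eig1), Re(eig2)), NA_real_)
  fld <- mf_field(S1, S2, cpl, params, Ist)
  tibble::tibble(
    S1 = S1, S2 = S2, rE1 = fld$r1, rE2 = fld$r2,
    residual = pmax(abs(fld$f1), abs(fld$f2)),
    eig1 = eig1, eig2 = eig2, stability = stability, tau_slow = tau_slow
  )
}

#' Linearise the dynamics at a fixed point
#'
#' Assembles the analytic 2x2 Jacobian of the noiseless dynamics (chain rule
#' through the transfer function and input currents) at a candidate fixed
#' point, and classifies its stability.
#'
#' @inheritParams find_fixed_points
#' @param S Activation pair `c(S1, S2)`; must satisfy the residual tolerance.
#' @param tol Residual tolerance for accepting `S` as a fixed point.
#' @return A list with `jacobian` (2x2 matrix), `eigenvalues` (complex pair),
#'   `stability` and `tau_slow` (s, `NA` unless saddle).
#' @export
linearize <- function(params, S, stim = NULL, delta_nu = 0, tol = 1e-6) {
  stopifnot(inherits(params, "circuit_params"), length(S) == 2)
  p2 <- params
  if (delta_nu != 0) {
    p2$nu0_I <- p2$nu0_I + delta_nu
    p2 <- validate_circuit_params(p2)
  }
  cpl <- derive_couplings(p2)
  Ist <- stim_currents_for(params, stim)
  f <- mf_field(S[1], S[2], cpl, params, Ist)
  abort_if(max(abs(f$f1), abs(f$f2)) > tol,
           "linearize(): point is not a fixed point at the requested tolerance")
  J <- mf_jacobian_entries(S[1], S[2], cpl, params, Ist)
  jac <- matrix(c(J$J11, J$J21, J$J12, J$J22), 2, 2)
  ev <- eigen(jac, only.values = FALSE)
  re <- Re(ev$values)
  stability <- if (all(re < 0)) "attractor"
  else if (sum(re > 0) == 1 && all(abs(Im(ev$values)) < 1e-12)) "saddle"
  else "repeller"
  list(
    jacobian = jac,
    eigenvalues = ev$values,
    eigenvectors = ev$vectors,
    stability = stability,
    tau_slow = if (stability == "saddle") 1 / max(re) else NA_real_
  )
}

#' Label fixed-point sets and test for a decision-competent circuit
#'
#' Applies the decision-circuit taxonomy to the fixed points of the
#' unstimulated and the neutrally stimulated (`c = 0`) planes. A circuit
#' supports decision-making when eight fixed points are present: in the
#' unstimulated plane a symmetric low-rate attractor, a mirror pair of
#' working-memory attractors and a mirror pair of saddles; in the stimulated
#' plane a mirror pair of choice attractors and one symmetric saddle.
#'
#' @param unstim,stim Fixed-point tibbles from [find_fixed_points()] for the
#'   unstimulated and stimulated (`stim = 0`) planes.
#' @param rate_threshold Rate ceiling (Hz) for the low-state attractor.
#' @param sym_tol Rate symmetry tolerance (Hz) for calling a point symmetric.
#' @param pair_tol S-space tolerance for mirror pairing.
#' @return A one-row tibble with logical flags `low_state_attractor`,
#'   `wm_attractor_pair`, `unstim_saddle_pair`, `choice_attractor_pair`,
#'   `stim_saddle`, `is_good_decision_circuit`, `indeterminate`, plus the
#'   attractor/saddle counts of both planes.
#' @export
label_fixed_points <- function(unstim, stim, rate_threshold = 15,
                               sym_tol = 0.1, pair_tol = 1e-3) {
  sym <- function(fp) abs(fp$rE1 - fp$rE2) < sym_tol
  mirror_paired <- function(fp, idx) {
    # every listed point must have its reflection in the same subset
    if (length(idx) == 0) return(FALSE)
    ok <- vapply(idx, function(i) {
      any(abs(fp$S1[idx] - fp$S2[i]) < pair_tol &
            abs(fp$S2[idx] - fp$S1[i]) < pair_tol)
    }, logical(1))
    all(ok)
  }

  u_attr <- which(unstim$stability == "attractor")
  u_sadd <- which(unstim$stability == "saddle")
  s_attr <- which(stim$stability == "attractor")
  s_sadd <- which(stim$stability == "saddle")

  u_sym_attr <- u_attr[sym(unstim)[u_attr]]
  indeterminate <- length(u_sym_attr) > 1 ||
    length(s_attr[sym(stim)[s_attr]]) > 1

  low_state <- length(u_sym_attr) == 1 &&
    all(unstim$rE1[u_sym_attr] < rate_threshold,
        unstim$rE2[u_sym_attr] < rate_threshold)

  u_asym_attr <- setdiff(u_attr, u_sym_attr)
  wm_pair <- length(u_asym_attr) == 2 && mirror_paired(unstim, u_asym_attr)

  u_asym_sadd <- u_sadd[!sym(unstim)[u_sadd]]
  unstim_saddle_pair <- length(u_asym_sadd) == 2 &&
    mirror_paired(unstim, u_asym_sadd)

  s_sym_sadd <- s_sadd[sym(stim)[s_sadd]]
  stim_saddle <- length(s_sym_sadd) == 1
  s_asym_attr <- s_attr[!sym(stim)[s_attr]]
  choice_pair <- length(s_asym_attr) == 2 && mirror_paired(stim, s_asym_attr)

  counts_ok <- length(u_attr) == 3 && length(u_sadd) == 2 &&
    length(s_attr) == 2 && length(s_sadd) == 1

  tibble::tibble(
    low_state_attractor = low_state,
    wm_attractor_pair = wm_pair,
    unstim_saddle_pair = unstim_saddle_pair,
    choice_attractor_pair = choice_pair,
    stim_saddle = stim_saddle,
    is_good_decision_circuit = !indeterminate && counts_ok && low_state &&
      wm_pair && unstim_saddle_pair && choice_pair && stim_saddle,
    indeterminate = indeterminate,
    n_unstim_attractors = length(u_attr),
    n_unstim_saddles = length(u_sadd),
    n_stim_attractors = length(s_attr),
    n_stim_saddles = length(s_sadd)
  )
}

#' Classify one circuit configuration
#'
#' Convenience wrapper: finds the fixed points of both phase planes and labels
#' them with [label_fixed_points()].
#'
#' @inheritParams find_fixed_points
#' @param ... Passed to [find_fixed_points()].
#' @return The one-row classification tibble of [label_fixed_points()].
#' @export
classify_circuit <- function(params, ...) {
  label_fixed_points(
    find_fixed_points(params, stim = NULL, ...),
    find_fixed_points(params, stim = 0, ...)
  )
}
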