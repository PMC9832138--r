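#' Construct test fixtures with known ground truth
#'
#' Builds synthetic inputs whose correct analysis outcome is known by
#' construction, for use in tests and demonstrations:
#'
#' * `step_trajectory`: an `mf_trajectory` whose rate difference follows a
#'   prescribed step profile (e.g. a known threshold-crossing time, or a
#'   prescribed pre-stimulus separation).
#' * `planted_weights`: an `rnn_weights` set whose same-preference and
#'   opposite-preference blocks have prescribed mean strengths, so every
#'   class's specificity is known exactly.
#' * `unit_activity`: two-group activity draws from shifted normal
#'   distributions with a closed-form expected ROC area.
#'
#' @param kind Fixture kind.
#' @param ... Kind-specific arguments, see Details.
#' @param seed Seed for stochastic fixtures.
#'
#' @details
#' `step_trajectory(pre_sep = 0, cross_at = NULL, level = 20, schedule)`:
#' rate difference is `pre_sep` before stimulus onset and jumps to `level` Hz
#' from `cross_at` seconds after onset (never crosses when `cross_at` is
#' `NULL`).
#'
#' `planted_weights(params, gamma = c(EE=, EI=, IE=, II=), base = 0.1,
#' noise = 0)`: half of each population prefers each choice; same-preference
#' entries get `base * (1 + gamma)`, opposite `base * (1 - gamma)`, plus
#' optional uniform jitter.
#'
#' `unit_activity(n = 100, shift = 1, sd = 1)`: `n` trials per choice;
#' choice-2 activity is shifted by `shift`; expected AUC is
#' `pnorm(shift / sqrt(2 * sd^2))`.
#'
#' @return The fixture object; planted parameters are attached as attributes.
#' @export
make_fixture <- function(kind = c("step_trajectory", "planted_weights",
                                  "unit_activity"), ..., seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
         step_trajectory = fixture_step_trajectory(...),
         planted_weights = fixture_planted_weights(..., seed = seed),
         unit_activity = fixture_unit_activity(..., seed = seed))
}

fixture_step_trajectory <- function(pre_sep = 0, cross_at = NULL, level = 20,
                                    schedule = trial_schedule(), dt = 0.002) {
  times <- seq(0, schedule$t_total, by = dt)
  base <- 5
  d <- rep(pre_sep, length(times))
  after_on <- times >= schedule$t_on
  d[after_on] <- 0
  if (!is.null(cross_at)) {
    abort_if(cross_at < 0 || schedule$t_on + cross_at > schedule$t_total,
             "step_trajectory: cross_at outside the trial")
    d[times >= schedule$t_on + cross_at] <- level
  }
  out <- tibble::tibble(
    time = times,
    S1 = 0.1, S2 = 0.1,
    rE1 = base + d, rE2 = base,
    rI1 = 10, rI2 = 10, Ieta1 = 0, Ieta2 = 0
  )
  attr(out, "schedule") <- schedule
  attr(out, "stim") <- stimulus_spec(t_on = schedule$t_on, t_off = schedule$t_off)
  class(out) <- c("mf_trajectory", class(out))
  out
}

fixture_planted_weights <- function(params = rnn_params(),
                                    gamma = c(EE = 0.5, EI = 0.5, IE = 0.5,
                                              II = 0.5),
                                    base = 0.1, noise = 0, seed = 1) {
  set.seed(seed)
  NE <- params$N_E; NI <- params$N_I
  prefE <- rep(c(1L, 2L), length.out = NE)
  prefI <- rep(c(1L, 2L), length.out = NI)
  block <- function(post_pref, pre_pref, g) {
    same <- outer(post_pref, pre_pref, "==")
    w <- ifelse(same, base * (1 + g), base * (1 - g))
    if (noise > 0) w <- pmax(w + matrix(stats::runif(length(w), -noise, noise),
                                        nrow(w)), 0)
    w
  }
  W_EE <- block(prefE, prefE, gamma[["EE"]]); diag(W_EE) <- 0
  W_EI <- block(prefI, prefE, gamma[["EI"]])
  W_IE <- block(prefE, prefI, gamma[["IE"]])
  W_II <- block(prefI, prefI, gamma[["II"]]); diag(W_II) <- 0
  w <- structure(list(W_EE = W_EE, W_EI = W_EI, W_IE = W_IE, W_II = W_II,
                      W_in = matrix(1 / NE, NE, params$N_in),
                      W_out = matrix(1 / NE, params$N_out, NE)),
                 class = "rnn_weights")
  attr(w, "pref_E") <- prefE
  attr(w, "pref_I") <- prefI
  attr(w, "gamma") <- gamma
  w
}

fixture_unit_activity <- function(n = 100, shift = 1, sd = 1, seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(
    choice = rep(c(1L, 2L), each = n),
    activity = c(stats::rnorm(n, 0, sd), stats::rnorm(n, shift, sd))
  )
  attr(out, "expected_auc") <- stats::pnorm(shift / sqrt(2 * sd^2))
  out
}

#' Build a selectivity report from known unit preferences
#'
#' Constructs an `rnn_selectivity`-shaped report in which the given units are
#' significantly selective with the given preferred choices. Used to exercise
#' [estimate_gamma_rnn()] against planted weight matrices.
#'
#' @param pref_E,pref_I Preferred choice (1/2) per unit; `NA` marks a
#'   non-significant unit.
#' @return An `rnn_selectivity` object.
#' @export
selectivity_from_prefs <- function(pref_E, pref_I) {
  units <- tibble::tibble(
    unit = seq_len(length(pref_E) + length(pref_I)),
    type = rep(c("E", "I"), c(length(pref_E), length(pref_I))),
    auc = 0.5,
    index = 0,
    significant = !is.na(c(pref_E, pref_I)),
    preferred = c(pref_E, pref_I)
  )
  structure(list(units = units, summary = NULL, trials_used = NA_integer_),
            class = "rnn_selectivity")
}
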