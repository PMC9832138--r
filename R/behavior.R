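# Vectorised trial evaluation on rate matrices (trials x time points).
# Validity: (i) |rE1 - rE2| < pre_threshold at every pre-stimulus step;
# (ii) |rE1 - rE2| >= decision_threshold at >= 1 step in the stimulus window,
# which includes the first post-offset time point ("or" rule) or at a step in
# both the window and the first post-offset point ("and" rule).
eval_rate_matrices <- function(rE1, rE2, times, schedule,
                               pre_threshold = 5, decision_threshold = 15,
                               rule = c("or", "and")) {
  rule <- match.arg(rule)
  D <- rE1 - rE2
  pre_idx <- which(times < schedule$t_on)
  win_idx <- which(times >= schedule$t_on & times <= schedule$t_off)
  post_idx <- win_idx[length(win_idx)] # first post-offset time point
  stim_idx <- setdiff(win_idx, post_idx)

  absD <- abs(D)
  pre_ok <- apply(absD[, pre_idx, drop = FALSE], 1, max) < pre_threshold
  crossed <- absD[, win_idx, drop = FALSE] >= decision_threshold
  if (rule == "or") {
    cross_ok <- rowSums(crossed) > 0
  } else {
    cross_ok <- rowSums(absD[, stim_idx, drop = FALSE] >= decision_threshold) > 0 &
      absD[, post_idx] >= decision_threshold
  }
  valid <- pre_ok & cross_ok

  first <- max.col(crossed, ties.method = "first")
  any_cross <- rowSums(crossed) > 0
  t_cross <- ifelse(any_cross, times[win_idx][first], NA_real_)
  choice_sign <- D[cbind(seq_len(nrow(D)),
                         ifelse(any_cross, win_idx[first], 1L))]
  choice <- ifelse(valid, ifelse(choice_sign > 0, 1L, 2L), NA_integer_)
  decision_time <- ifelse(valid, t_cross - schedule$t_on, NA_real_)
  maintained <- ifelse(valid, absD[, ncol(D)] >= decision_threshold, NA)

  tibble::tibble(
    valid = valid,
    invalid_reason = ifelse(valid, "none",
                            ifelse(!pre_ok, "premature_separation",
                                   "no_threshold_crossing")),
    choice = choice,
    decision_time = decision_time,
    maintained_after_delay = maintained
  )
}

#' Evaluate a trial trajectory into a behavioural outcome
#'
#' A trial is valid when (i) the absolute excitatory rate difference stays
#' below `pre_threshold` (5 Hz) throughout the pre-stimulus epoch and (ii) it
#' reaches `decision_threshold` (15 Hz) at one or more time steps during the
#' stimulus window or at the time point following stimulus offset. The choice
#' is the population with the higher rate at the first qualifying crossing and
#' the decision time is that crossing time minus stimulus onset (resolution:
#' one integration step). Invalid trials keep their failure reason and are
#' never assigned a choice.
#'
#' @param traj An `mf_trajectory` from [simulate_trial()].
#' @param pre_threshold Pre-stimulus quiescence threshold (Hz).
#' @param decision_threshold Decision threshold (Hz).
#' @param rule `"or"` (default): the first post-offset point counts as part of
#'   the qualifying window; `"and"`: the separation must exceed threshold both
#'   during the stimulus and at the first post-offset point.
#' @return A one-row tibble: `valid`, `invalid_reason`
#'   (`premature_separation`, `no_threshold_crossing` or `none`), `choice`
#'   (1, 2 or `NA`), `decision_time` (s from stimulus onset) and
#'   `maintained_after_delay` (separation still above threshold at the end of
#'   the post-stimulus delay).
#' @export
evaluate_trial <- function(traj, pre_threshold = 5, decision_threshold = 15,
                           rule = c("or", "and")) {
  stopifnot(inherits(traj, "mf_trajectory"))
  schedule <- attr(traj, "schedule")
  abort_if(is.null(schedule), "evaluate_trial(): trajectory lacks a schedule attribute")
  abort_if(max(traj$time) < schedule$t_off,
           "evaluate_trial(): trajectory does not cover all trial epochs")
  eval_rate_matrices(matrix(traj$rE1, 1), matrix(traj$rE2, 1), traj$time,
                     schedule, pre_threshold, decision_threshold,
                     match.arg(rule))
}

#' Simulate a behavioural session
#'
#' Runs `n_per_coherence` stochastic trials at each requested coherence and
#' aggregates them into psychometric (accuracy), chronometric (mean decision
#' time) and trial-completion curves. Accuracy and decision times are computed
#' over valid trials only; the completion fraction counts valid trials out of
#' all presented. At `coherence = 0` there is no correct answer and accuracy
#' is reported as `NA`.
#'
#' @param params A [circuit_params()] object.
#' @param coherences Numeric vector of signed coherences (percent).
#' @param n_per_coherence Trials per coherence.
#' @param seed Master seed; each coherence uses a derived child seed, so the
#'   same trials are reproduced independently of which other coherences are
#'   requested.
#' @param schedule A [trial_schedule()].
#' @param delta_nu Perturbation of `nu0_I` during the stimulus window (Hz).
#' @param pre_threshold,decision_threshold,rule Passed to trial evaluation.
#' @return An `mf_session` list with `trials` (one row per trial) and
#'   `summary` (one row per coherence: `n`, `n_valid`, `completion`,
#'   `accuracy`, `p_choice2`, `mean_decision_time`, `sem_decision_time`).
#' @export
run_session <- function(params, coherences = c(0, 5, 10, 20, 40),
                        n_per_coherence = 100, seed = 1,
                        schedule = trial_schedule(), delta_nu = 0,
                        pre_threshold = 5, decision_threshold = 15,
                        rule = c("or", "and")) {
  rule <- match.arg(rule)
  abort_if(n_per_coherence < 1, "run_session(): n_per_coherence must be >= 1")
  trials <- purrr::map2_dfr(coherences, seq_along(coherences), function(co, i) {
    stim <- stimulus_spec(coherence = co, t_on = schedule$t_on,
                          t_off = schedule$t_off)
    r <- mf_integrate(params, stim, n = n_per_coherence,
                      seed = derive_seed(seed, i), schedule = schedule,
                      delta_nu = delta_nu, record = "rates")
    out <- eval_rate_matrices(r$rE1, r$rE2, r$times, schedule,
                              pre_threshold, decision_threshold, rule)
    out$coherence <- co
    out$trial <- seq_len(n_per_coherence)
    out
  })
  trials$correct <- dplyr::case_when(
    !trials$valid | trials$coherence == 0 ~ NA,
    trials$coherence > 0 ~ trials$choice == 2L,
    TRUE ~ trials$choice == 1L
  )
  summary <- trials |>
    dplyr::group_by(.data$coherence) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_valid = sum(.data$valid),
      completion = mean(.data$valid),
      accuracy = if (all(is.na(.data$correct))) NA_real_ else
        mean(.data$correct, na.rm = TRUE),
      p_choice2 = if (sum(.data$valid) == 0) NA_real_ else
        mean(.data$choice[.data$valid] == 2L),
      mean_decision_time = if (sum(.data$valid) == 0) NA_real_ else
        mean(.data$decision_time[.data$valid]),
      sem_decision_time = if (sum(.data$valid) < 2) NA_real_ else
        stats::sd(.data$decision_time[.data$valid]) / sqrt(sum(.data$valid)),
      .groups = "drop"
    )
  structure(list(trials = trials, summary = summary, params = params,
                 schedule = schedule, seed = seed, delta_nu = delta_nu,
                 thresholds = c(pre = pre_threshold,
                                decision = decision_threshold)),
            class = "mf_session")
}

#' @export
print.mf_session <- function(x, ...) {
  cat("<mf_session>", sum(x$summary$n), "trials,",
      nrow(x$summary), "coherence levels\n")
  print(x$summary)
  invisible(x)
}

#' Probability of maintaining a choice across a memory delay
#'
#' Among trials with a valid decision, the fraction whose excitatory rate
#' separation is still at or above the decision threshold at the end of the
#' post-offset delay window. Circuits whose unstimulated phase plane lacks
#' working-memory attractors lose the choice read-out during the delay.
#'
#' @inheritParams run_session
#' @param delay Delay duration after stimulus offset (s).
#' @param n Number of trials.
#' @param coherence Stimulus coherence (percent).
#' @return A one-row tibble with `probability` (`NA` when no trial is valid),
#'   `n_valid` and `n`.
#' @export
working_memory_probability <- function(params, delay = 1, n = 200, seed = 1,
                                       coherence = 0,
                                       schedule = NULL,
                                       decision_threshold = 15) {
  if (is.null(schedule)) schedule <- trial_schedule(t_post = delay)
  ses <- run_session(params, coherences = coherence, n_per_coherence = n,
                     seed = seed, schedule = schedule,
                     decision_threshold = decision_threshold)
  v <- ses$trials$valid
  tibble::tibble(
    probability = if (sum(v) == 0) NA_real_ else
      mean(ses$trials$maintained_after_delay[v]),
    n_valid = sum(v), n = n
  )
}

#' Inhibitory perturbation experiment
#'
#' Perturbs the baseline drive to inhibitory neurons by `delta_nu` during the
#' stimulus window only and measures the change in completion fraction,
#' accuracy and mean decision time relative to the unperturbed condition.
#' All perturbation levels reuse the same per-condition random streams
#' (common random numbers), so the reported deltas are paired differences and
#' their standard errors come from the paired per-trial differences.
#'
#' @inheritParams run_session
#' @param baseline_nu Baseline `nu0_I` (Hz); overrides `params$nu0_I`.
#' @param deltas Perturbations of `nu0_I` (Hz), each in `[-0.5, 0.5]`.
#' @param coherences Coherence set used for the deltas; accuracy excludes the
#'   `coherence = 0` trials (no correct answer there).
#' @param n Trials per coherence and perturbation level.
#' @param crn Common random numbers: reuse the same noise streams across
#'   perturbation levels (paired deltas, minimal Monte-Carlo variance). With
#'   `crn = FALSE` each level draws independent streams; deltas are then
#'   unpaired differences with the corresponding standard errors (needed for
#'   honest uncertainty on accuracy, which under common random numbers almost
#'   never changes on a paired trial).
#' @return A tibble with one row per `delta`: raw `completion`, `accuracy`,
#'   `mean_decision_time` plus deltas (`d_completion`, `d_accuracy`,
#'   `d_decision_time`) and their standard errors relative to `delta = 0`.
#' @export
perturbation_experiment <- function(params, baseline_nu = 11.5,
                                    deltas = c(-0.5, 0, 0.5),
                                    coherences = c(0, 5, 10), n = 200,
                                    seed = 1, schedule = trial_schedule(),
                                    crn = TRUE) {
  abort_if(any(abs(deltas) > 0.5 + 1e-12),
           "perturbation_experiment(): |delta_nu| must be <= 0.5 Hz")
  p <- params; p$nu0_I <- baseline_nu
  p <- validate_circuit_params(p)
  if (!0 %in% deltas) deltas <- sort(c(0, deltas))

  sessions <- lapply(seq_along(deltas), function(i) {
    s <- if (crn) seed else derive_seed(seed, 5000 + i)
    run_session(p, coherences = coherences, n_per_coherence = n, seed = s,
                schedule = schedule, delta_nu = deltas[i])$trials
  })
  names(sessions) <- as.character(deltas)
  ref <- sessions[[as.character(0)]]

  purrr::map_dfr(seq_along(deltas), function(i) {
    tr <- sessions[[i]]
    if (crn) {
      # paired per-trial comparisons against the unperturbed condition
      d_comp <- tr$valid - ref$valid
      both <- sum(tr$valid & ref$valid)
      idx <- tr$valid & ref$valid
      d_dt <- tr$decision_time[idx] - ref$decision_time[idx]
      acc_ok <- idx & tr$coherence != 0
      d_acc <- as.numeric(tr$correct[acc_ok]) - as.numeric(ref$correct[acc_ok])
    } else {
      both <- sum(tr$valid)
      d_comp <- tr$valid - mean(ref$valid)
      d_dt <- tr$decision_time[tr$valid] -
        mean(ref$decision_time[ref$valid])
      nz <- tr$valid & tr$coherence != 0
      d_acc <- as.numeric(tr$correct[nz]) -
        mean(ref$correct[ref$valid & ref$coherence != 0])
    }
    sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
    tibble::tibble(
      delta_nu = deltas[i],
      completion = mean(tr$valid),
      accuracy = mean(tr$correct[tr$valid & tr$coherence != 0]),
      mean_decision_time = mean(tr$decision_time[tr$valid]),
      d_completion = mean(d_comp),
      sem_completion = sem(d_comp),
      d_accuracy = mean(d_acc),
      sem_accuracy = sem(d_acc),
      d_decision_time = mean(d_dt),
      sem_decision_time = sem(d_dt),
      n_pairs_dt = both
    )
  })
}
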