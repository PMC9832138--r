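# Rank-based AUC: probability that a draw from group 2 (choice 2) exceeds a
# draw from group 1, with ties counted half. Equivalent to the Mann-Whitney
# statistic; cross-checked against trapezoidal ROC integration in the tests.
auc_rank <- function(activity, choice) {
  n1 <- sum(choice == 1L); n2 <- sum(choice == 2L)
  r <- rank(activity)
  (sum(r[choice == 2L]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' ROC choice selectivity of RNN units
#'
#' Quantifies how well each unit's activity at the time step immediately
#' following stimulus offset decodes the network's choice, using the area
#' under the ROC curve over valid evaluation trials. The selectivity index is
#' `|AUC - 0.5|` (0 = uninformative, 0.5 = perfect). Significance is assessed
#' by a permutation test: the unit is selective when its AUC falls outside the
#' central 95% of the AUC distribution obtained by shuffling choice labels.
#'
#' @param fit An `rnn_fit` (or a list with elements `weights` and `params`).
#' @param n_eval Number of evaluation trials (fresh batch spanning the
#'   validation coherences; valid trials only are analysed).
#' @param seed Seed for the evaluation batch, forward noise and shuffles.
#' @param n_shuffle Number of label permutations.
#' @return An `rnn_selectivity` list: `units` (tibble: unit, type, auc, index,
#'   significant, preferred), `summary` (per-type mean index and fraction
#'   significant) and `trials_used`.
#' @export
roc_selectivity <- function(fit, n_eval = 200, seed = 1, n_shuffle = 150) {
  params <- fit$params
  weights <- fit$weights
  batch <- make_batch(params, n = n_eval, seed = derive_seed(seed, 11),
                      coherences = params$valid_coherences)
  fwd <- rnn_forward(weights, params, batch, seed = derive_seed(seed, 12),
                     keep_state = TRUE)
  val <- validate_rnn(weights, params, batch = batch,
                      seed = derive_seed(seed, 12))
  # recompute outputs deterministically is not needed; reuse choice labels
  keep <- which(val$trials$valid)
  abort_if(length(unique(val$trials$choice[keep])) < 2 ||
             min(table(val$trials$choice[keep])) < 2,
           "roc_selectivity(): need >= 2 valid trials of each choice")
  choice <- val$trials$choice[keep]

  # unit activity at the step following stimulus offset, per trial
  NE <- params$N_E; NI <- params$N_I
  act <- matrix(NA_real_, length(keep), NE + NI)
  for (k in seq_along(keep)) {
    i <- keep[k]
    t1 <- batch$meta$t_off[i] + 1L
    act[k, ] <- c(fwd$rE[, i, t1], fwd$rI[, i, t1])
  }

  set.seed(derive_seed(seed, 13))
  shuffles <- replicate(n_shuffle, sample(choice))
  units <- purrr::map_dfr(seq_len(NE + NI), function(u) {
    a <- act[, u]
    auc <- auc_rank(a, choice)
    null <- apply(shuffles, 2, function(ch) auc_rank(a, ch))
    lo <- stats::quantile(null, 0.025, names = FALSE)
    hi <- stats::quantile(null, 0.975, names = FALSE)
    tibble::tibble(
      unit = u,
      type = if (u <= NE) "E" else "I",
      auc = auc,
      index = abs(auc - 0.5),
      significant = auc < lo | auc > hi,
      preferred = ifelse(auc >= 0.5, 2L, 1L)
    )
  })
  summary <- units |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_index = mean(.data$index),
      fraction_significant = mean(.data$significant),
      .groups = "drop"
    )
  structure(list(units = units, summary = summary,
                 trials_used = length(keep), n_shuffle = n_shuffle),
            class = "rnn_selectivity")
}

#' @export
print.rnn_selectivity <- function(x, ...) {
  cat("<rnn_selectivity>", x$trials_used, "valid trials\n")
  print(x$summary)
  invisible(x)
}

#' Estimate connection specificity from trained weights
#'
#' For each directed connection class (EE, EI, IE, II) the specificity is the
#' normalised difference between the mean weight linking significantly
#' selective units of the same choice preference and the mean weight linking
#' units of opposite preference, `(w_plus - w_minus)/(w_plus + w_minus)` —
#' the same definition used for the mean-field circuit. Self-connections are
#' excluded; classes missing a preference group on either side are reported
#' as `NA`.
#'
#' @param weights An `rnn_weights` set.
#' @param selectivity An [roc_selectivity()] report for the same network.
#' @param params The network's [rnn_params()].
#' @return A tibble with one row per class: `class`, `gamma_hat`, `w_plus`,
#'   `w_minus`, `n_same`, `n_opp`.
#' @export
estimate_gamma_rnn <- function(weights, selectivity, params) {
  u <- selectivity$units
  NE <- params$N_E
  sigE <- u$unit[u$significant & u$type == "E"]
  sigI <- u$unit[u$significant & u$type == "I"] - NE
  prefE <- u$preferred[u$significant & u$type == "E"]
  prefI <- u$preferred[u$significant & u$type == "I"]

  class_gamma <- function(W, pre_idx, pre_pref, post_idx, post_pref,
                          exclude_diag = FALSE) {
    if (length(pre_idx) == 0 || length(post_idx) == 0) {
      return(tibble::tibble(gamma_hat = NA_real_, w_plus = NA_real_,
                            w_minus = NA_real_, n_same = 0L, n_opp = 0L))
    }
    same <- outer(post_pref, pre_pref, "==")
    sub <- W[post_idx, pre_idx, drop = FALSE]
    if (exclude_diag) {
      dup <- outer(post_idx, pre_idx, "==")
      same[dup] <- NA
    }
    w_plus <- mean(sub[which(same)], na.rm = TRUE)
    w_minus <- mean(sub[which(!same)], na.rm = TRUE)
    n_same <- sum(same, na.rm = TRUE); n_opp <- sum(!same, na.rm = TRUE)
    if (n_same == 0 || n_opp == 0) {
      return(tibble::tibble(gamma_hat = NA_real_, w_plus = NA_real_,
                            w_minus = NA_real_, n_same = n_same, n_opp = n_opp))
    }
    tibble::tibble(gamma_hat = (w_plus - w_minus) / (w_plus + w_minus),
                   w_plus = w_plus, w_minus = w_minus,
                   n_same = n_same, n_opp = n_opp)
  }

  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(class = "EE"),
                     class_gamma(weights$W_EE, sigE, prefE, sigE, prefE, TRUE)),
    dplyr::bind_cols(tibble::tibble(class = "EI"),
                     class_gamma(weights$W_EI, sigE, prefE, sigI, prefI)),
    dplyr::bind_cols(tibble::tibble(class = "IE"),
                     class_gamma(weights$W_IE, sigI, prefI, sigE, prefE)),
    dplyr::bind_cols(tibble::tibble(class = "II"),
                     class_gamma(weights$W_II, sigI, prefI, sigI, prefI, TRUE))
  )
}

#' Inhibitory perturbation experiment on a trained network
#'
#' Adds a constant input to all inhibitory units during each trial's stimulus
#' steps and measures changes in decision time, completion and accuracy
#' relative to the unperturbed network. By default all perturbation levels
#' share the same trials and noise (common random numbers); set `crn = FALSE`
#' for independent streams (needed for honest standard errors on accuracy,
#' which under common random numbers almost never changes on a paired trial).
#'
#' @param fit An `rnn_fit`.
#' @param deltas Perturbation levels, each in `[-1, 1]`.
#' @param n Trials per level.
#' @param seed Master seed.
#' @param crn Use common random numbers across levels.
#' @return A tibble with one row per `delta_I`: raw metrics, deltas relative
#'   to `delta_I = 0`, and standard errors.
#' @export
perturb_rnn <- function(fit, deltas = c(-0.5, 0, 0.5), n = 200, seed = 1,
                        crn = TRUE) {
  abort_if(any(abs(deltas) > 1), "perturb_rnn(): |delta_I| must be <= 1")
  params <- fit$params
  if (!0 %in% deltas) deltas <- sort(c(0, deltas))
  runs <- lapply(seq_along(deltas), function(i) {
    s <- if (crn) seed else derive_seed(seed, 7000 + i)
    batch <- make_batch(params, n = n, seed = derive_seed(s, 21),
                        coherences = params$valid_coherences)
    validate_rnn(fit$weights, params, batch = batch,
                 seed = derive_seed(s, 22), delta_I = deltas[i])$trials
  })
  ref <- runs[[which(deltas == 0)]]
  sem <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  purrr::map_dfr(seq_along(deltas), function(i) {
    tr <- runs[[i]]
    if (crn) {
      d_comp <- tr$valid - ref$valid
      both <- tr$valid & ref$valid
      d_dt <- tr$decision_time[both] - ref$decision_time[both]
      acc_ok <- both & tr$coherence != 0
      d_acc <- as.numeric(tr$correct[acc_ok]) - as.numeric(ref$correct[acc_ok])
    } else {
      d_comp <- tr$valid - mean(ref$valid)
      d_dt <- tr$decision_time[tr$valid] - mean(ref$decision_time[ref$valid])
      nz <- tr$valid & tr$coherence != 0
      d_acc <- as.numeric(tr$correct[nz]) -
        mean(ref$correct[ref$valid & ref$coherence != 0])
    }
    tibble::tibble(
      delta_I = deltas[i],
      completion = mean(tr$valid),
      accuracy = mean(tr$correct[tr$valid & tr$coherence != 0]),
      mean_decision_time = mean(tr$decision_time[tr$valid]),
      d_completion = mean(d_comp), sem_completion = sem(d_comp),
      d_accuracy = mean(d_acc), sem_accuracy = sem(d_acc),
      d_decision_time = mean(d_dt), sem_decision_time = sem(d_dt)
    )
  })
}
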