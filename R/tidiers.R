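#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a behavioural session
#'
#' @param x An `mf_session`.
#' @param ... Unused.
#' @return The per-coherence summary tibble.
#' @export
tidy.mf_session <- function(x, ...) x$summary

#' One-row summary of a behavioural session
#'
#' @param x An `mf_session`.
#' @param ... Unused.
#' @return A one-row tibble: trial counts, overall completion, accuracy over
#'   non-neutral valid trials, and mean decision time.
#' @export
glance.mf_session <- function(x, ...) {
  tr <- x$trials
  tibble::tibble(
    n_trials = nrow(tr),
    n_coherences = length(unique(tr$coherence)),
    completion = mean(tr$valid),
    accuracy = mean(tr$correct[tr$valid & tr$coherence != 0]),
    mean_decision_time = mean(tr$decision_time[tr$valid]),
    seed = x$seed
  )
}

#' Tidy a fixed-point set
#'
#' @param x An `mf_fixedpoints` tibble.
#' @param ... Unused.
#' @return The tibble itself (already one row per fixed point).
#' @export
tidy.mf_fixedpoints <- function(x, ...) tibble::as_tibble(x)

#' Tidy an RNN training history
#'
#' @param x An `rnn_fit`.
#' @param ... Unused.
#' @return The epoch-level history tibble.
#' @export
tidy.rnn_fit <- function(x, ...) x$history

#' One-row summary of an RNN fit
#'
#' @param x An `rnn_fit`.
#' @param ... Unused.
#' @return A one-row tibble with convergence, epochs, trials seen and final
#'   loss/performance.
#' @export
glance.rnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    converged = x$converged,
    epochs = nrow(h),
    trials_seen = if (nrow(h)) max(h$trials_seen) else 0L,
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_performance = if (nrow(h)) h$performance[nrow(h)] else NA_real_,
    seed = x$seed
  )
}

#' Tidy a selectivity report
#'
#' @param x An `rnn_selectivity`.
#' @param ... Unused.
#' @return The per-unit tibble.
#' @export
tidy.rnn_selectivity <- function(x, ...) x$units

#' Plot a trial trajectory
#'
#' Excitatory population rates over the trial, with the stimulus epoch shaded.
#'
#' @param object An `mf_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mf_trajectory <- function(object, ...) {
  sched <- attr(object, "schedule")
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", "rE1", "rE2")],
    c("rE1", "rE2"), names_to = "population", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rate,
                                   colour = .data$population)) +
    ggplot2::annotate("rect", xmin = sched$t_on, xmax = sched$t_off,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "population rate (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot psychometric, chronometric and completion curves
#'
#' @param object An `mf_session`.
#' @param ... Unused.
#' @return A ggplot object (three stacked panels).
#' @export
autoplot.mf_session <- function(object, ...) {
  s <- object$summary
  df <- tidyr::pivot_longer(
    s[, c("coherence", "completion", "accuracy", "mean_decision_time")],
    -"coherence", names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coherence, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "coherence (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Fixed-point positions (as `S1`) against the swept parameter, solid for
#' attractors and dashed for saddles.
#'
#' @param object An `mf_bifurcation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mf_bifurcation <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$param_value, y = .data$S1,
                                    group = .data$branch,
                                    linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(attractor = "solid",
                                              saddle = "dashed",
                                              repeller = "dotted")) +
    ggplot2::labs(x = object$param, y = "S1 at fixed point",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of choice-selectivity indices
#'
#' @param object An `rnn_selectivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rnn_selectivity <- function(object, ...) {
  ggplot2::ggplot(object$units,
                  ggplot2::aes(x = .data$index, fill = .data$type)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 25) +
    ggplot2::labs(x = "choice-selectivity index |AUC - 0.5|", y = "units",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
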