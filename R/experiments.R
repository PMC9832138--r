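#' Run a named figure-level experiment
#'
#' Drivers that chain the package's modules into the standard experiments:
#'
#' * `"specificity_scan"`: classification of a specificity grid plus the
#'   correlation between `gamma_EE` and the inhibitory specificity index over
#'   decision-competent circuits.
#' * `"motif_behavior"`: psychometric/chronometric/completion sessions for
#'   contra-, non- and ipsispecific circuits at matched `gamma_EE`, `gamma_EI`.
#' * `"working_memory"`: choice-maintenance probability across a `gamma_IE`
#'   sweep.
#' * `"perturbation"`: inhibitory perturbation experiments at the low and
#'   high inhibitory baselines.
#' * `"rnn_replication"`: trains networks to criterion and reports
#'   selectivity fractions, indices and per-class specificity estimates.
#'
#' @param experiment Experiment name.
#' @param seed Master seed.
#' @param config Optional list of overrides passed to the relevant parameter
#'   constructor.
#' @param ... Experiment-specific options (e.g. `n_networks`, `n_trials`,
#'   grids); see the driver sources.
#' @param out_dir Optional directory; when given, result tables are written as
#'   CSV together with a JSON run manifest.
#' @return A list of result tibbles (class `circuit_experiment`), with the
#'   manifest in attribute `manifest`.
#' @export
run_experiment <- function(experiment = c("specificity_scan", "motif_behavior",
                                           "working_memory", "perturbation",
                                           "rnn_replication"),
                           seed = 1, config = list(), ..., out_dir = NULL) {
  experiment <- match.arg(experiment)
  t0 <- Sys.time()
  res <- switch(experiment,
    specificity_scan = exp_specificity_scan(seed, config, ...),
    motif_behavior = exp_motif_behavior(seed, config, ...),
    working_memory = exp_working_memory(seed, config, ...),
    perturbation = exp_perturbation(seed, config, ...),
    rnn_replication = exp_rnn_replication(seed, config, ...)
  )
  manifest <- list(
    experiment = experiment, seed = seed, config = config,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    tables = lapply(res, function(x) {
      if (is.data.frame(x)) list(rows = nrow(x), hash = hash_of(x)) else NULL
    })
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      if (is.data.frame(res[[nm]])) {
        utils::write.csv(as.data.frame(res[[nm]]),
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(res, manifest = manifest, class = c("circuit_experiment", "list"))
}

exp_specificity_scan <- function(seed, config,
                                 gamma_EE = seq(0.2, 0.5, length.out = 8),
                                 gamma_EI = seq(0, 1, length.out = 5),
                                 gamma_IE = seq(-1, 1, length.out = 9),
                                 grid_n = 21) {
  params <- do.call(circuit_params, config)
  scan <- scan_specificity(params, gamma_EE, gamma_EI, gamma_IE,
                           grid_n = grid_n)
  good <- scan[scan$is_good_decision_circuit, ]
  corr <- if (nrow(good) > 2) {
    stats::cor(good$gamma_EE, good$spec_index)
  } else NA_real_
  list(scan = scan,
       stats = tibble::tibble(n_good = nrow(good),
                              cor_gammaEE_spec_index = corr))
}

exp_motif_behavior <- function(seed, config, gamma_IEs = c(-0.15, 0, 0.15),
                               coherences = c(0, 5, 10, 20, 40), n = 200) {
  purrr::map_dfr(gamma_IEs, function(g) {
    cfg <- config; cfg$gamma_IE <- g
    params <- do.call(circuit_params, cfg)
    ses <- run_session(params, coherences = coherences, n_per_coherence = n,
                       seed = seed)
    out <- ses$summary
    out$gamma_IE <- g
    out$motif <- if (g < 0) "contraspecific" else
      if (g > 0) "ipsispecific" else "nonspecific"
    out
  }) |> (\(x) list(behavior = x))()
}

exp_working_memory <- function(seed, config,
                               gamma_IEs = seq(-0.1, 0.15, by = 0.05),
                               delay = 1, n = 200) {
  wm <- purrr::map_dfr(gamma_IEs, function(g) {
    cfg <- config; cfg$gamma_IE <- g
    params <- do.call(circuit_params, cfg)
    out <- working_memory_probability(params, delay = delay, n = n, seed = seed)
    out$gamma_IE <- g
    out$spec_index <- params$gamma_EI * g
    out
  })
  list(working_memory = wm)
}

exp_perturbation <- function(seed, config, baselines = c(11.5, 14),
                             deltas = c(-0.5, 0, 0.5),
                             coherences = c(0, 5, 10), n = 200) {
  params <- do.call(circuit_params, config)
  tab <- purrr::map_dfr(baselines, function(b) {
    out <- perturbation_experiment(params, baseline_nu = b, deltas = deltas,
                                   coherences = coherences, n = n, seed = seed)
    out$baseline_nu = b
    out
  })
  signs <- tab[tab$delta_nu > 0, c("baseline_nu", "d_completion",
                                   "d_accuracy", "d_decision_time")]
  list(perturbation = tab, sign_summary = signs)
}

exp_rnn_replication <- function(seed, config, n_networks = 3,
                                max_epochs = 1500, n_eval = 200) {
  params <- do.call(rnn_params, config)
  nets <- purrr::map_dfr(seq_len(n_networks), function(k) {
    fit <- train_rnn(params, seed = derive_seed(seed, k), max_epochs = max_epochs)
    sel <- roc_selectivity(fit, n_eval = n_eval, seed = derive_seed(seed, 500 + k))
    g <- estimate_gamma_rnn(fit$weights, sel, params)
    sm <- sel$summary
    tibble::tibble(
      network = k, converged = fit$converged,
      epochs = nrow(fit$history),
      trials_to_criterion = max(fit$history$trials_seen),
      frac_sig_E = sm$fraction_significant[sm$type == "E"],
      frac_sig_I = sm$fraction_significant[sm$type == "I"],
      mean_index_E = sm$mean_index[sm$type == "E"],
      mean_index_I = sm$mean_index[sm$type == "I"],
      gamma_EE = g$gamma_hat[g$class == "EE"],
      gamma_EI = g$gamma_hat[g$class == "EI"],
      gamma_IE = g$gamma_hat[g$class == "IE"],
      gamma_II = g$gamma_hat[g$class == "II"]
    )
  })
  summary <- tibble::tibble(
    n_networks = nrow(nets),
    all_converged = all(nets$converged),
    mean_frac_sig_E = mean(nets$frac_sig_E),
    mean_frac_sig_I = mean(nets$frac_sig_I),
    mean_index_I = mean(nets$mean_index_I),
    mean_gamma_EE = mean(nets$gamma_EE),
    mean_gamma_IE = mean(nets$gamma_IE),
    cor_gammaEE_spec_index = if (nrow(nets) > 2) {
      stats::cor(nets$gamma_EE, nets$gamma_EI * nets$gamma_IE)
    } else NA_real_
  )
  list(networks = nets, summary = summary)
}
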