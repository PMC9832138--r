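#' Scan the connection-specificity space for decision-competent circuits
#'
#' Classifies every point of a grid over `(gamma_EE, gamma_EI, gamma_IE)` by
#' the presence of the eight decision fixed points. The inhibitory specificity
#' index `gamma_EI * gamma_IE` (negative for contraspecific, positive for
#' ipsispecific motifs) is attached to every row.
#'
#' @param params Template [circuit_params()]; its specificity entries are
#'   overridden at each grid point.
#' @param gamma_EE,gamma_EI,gamma_IE Numeric grids for the three specificity
#'   parameters.
#' @param grid_n Multistart resolution passed to [find_fixed_points()].
#' @param out_file Optional CSV path; when given, rows are appended as they
#'   are computed (the full tibble is still returned).
#' @param progress Print a progress line every `progress` points (0 = quiet).
#' @return A tibble with one row per grid point: the three specificities,
#'   `spec_index`, and the classification flags of [label_fixed_points()].
#' @export
scan_specificity <- function(params = circuit_params(),
                             gamma_EE = seq(0.2, 0.5, length.out = 15),
                             gamma_EI = seq(0, 1, length.out = 9),
                             gamma_IE = seq(-1, 1, length.out = 17),
                             grid_n = 21, out_file = NULL, progress = 0) {
  abort_if(length(gamma_EE) == 0 || length(gamma_EI) == 0 || length(gamma_IE) == 0,
           "scan_specificity(): empty grid")
  pts <- expand.grid(gamma_EE = gamma_EE, gamma_EI = gamma_EI,
                     gamma_IE = gamma_IE, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- params
    p$gamma_EE <- pts$gamma_EE[i]
    p$gamma_EI <- pts$gamma_EI[i]
    p$gamma_IE <- pts$gamma_IE[i]
    p <- validate_circuit_params(p)
    cls <- classify_circuit(p, grid_n = grid_n)
    row <- dplyr::bind_cols(
      tibble::tibble(gamma_EE = pts$gamma_EE[i], gamma_EI = pts$gamma_EI[i],
                     gamma_IE = pts$gamma_IE[i],
                     spec_index = pts$gamma_EI[i] * pts$gamma_IE[i]),
      cls
    )
    rows[[i]] <- row
    if (!is.null(out_file)) {
      utils::write.table(row, out_file, sep = ",", row.names = FALSE,
                         col.names = i == 1, append = i > 1)
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("scan_specificity: %d / %d", i, nrow(pts)))
    }
  }
  dplyr::bind_rows(rows)
}

set_sweep_param <- function(params, param, value) {
  p <- params
  if (param == "gamma_IE") {
    p$gamma_IE <- value
  } else if (param == "spec_index") {
    # sweep the index at fixed gamma_EI by moving gamma_IE
    abort_if(p$gamma_EI == 0, "spec_index sweep needs gamma_EI != 0")
    p$gamma_IE <- value / p$gamma_EI
  } else if (param == "nu0_I") {
    p$nu0_I <- value
  } else {
    stop("unknown sweep parameter: ", param, call. = FALSE)
  }
  validate_circuit_params(p)
}

fp_signature <- function(fp) {
  paste(sort(fp$stability), collapse = "")
}

#' Bifurcation sweep of the fixed-point structure
#'
#' Tracks the fixed points, their stability and the saddle time constant
#' `tau_slow` along a monotone path of one model parameter, links points into
#' branches by nearest-neighbour continuation, and localises bifurcation
#' events (changes of the fixed-point signature: branch birth/death or
#' stability change) by bisection.
#'
#' @param params Template [circuit_params()].
#' @param param One of `"gamma_IE"`, `"spec_index"` (`gamma_EI * gamma_IE`
#'   varied through `gamma_IE` at fixed `gamma_EI`), or `"nu0_I"`.
#' @param from,to,n Sweep range and number of points.
#' @param stim `NULL` for the unstimulated plane or a coherence (percent) with
#'   the stimulus on (`stim = 0` for the neutral stimulus).
#' @param event_tol Parameter bracket width for bisection of events.
#' @param grid_n Multistart resolution for [find_fixed_points()].
#' @return An `mf_bifurcation` list: `points` (one row per parameter value and
#'   fixed point, with `branch` ids) and `events` (bracketed bifurcations with
#'   the signatures on both sides).
#' @export
bifurcation_sweep <- function(params, param = c("gamma_IE", "spec_index", "nu0_I"),
                              from, to, n = 41, stim = NULL,
                              event_tol = 1e-4, grid_n = 21) {
  param <- match.arg(param)
  values <- seq(from, to, length.out = n)
  fps <- lapply(values, function(v) {
    find_fixed_points(set_sweep_param(params, param, v),
                      stim = stim, grid_n = grid_n)
  })

  # nearest-neighbour branch continuation in S-space
  next_branch <- 0L
  prev <- NULL
  points <- vector("list", length(values))
  for (i in seq_along(values)) {
    fp <- fps[[i]]
    if (nrow(fp) == 0) {
      points[[i]] <- NULL
      prev <- NULL
      next
    }
    branch <- integer(nrow(fp))
    if (!is.null(prev) && nrow(prev) > 0) {
      used <- logical(nrow(prev))
      for (j in order(fp$S1 + fp$S2)) {
        d <- sqrt((prev$S1 - fp$S1[j])^2 + (prev$S2 - fp$S2[j])^2)
        d[used] <- Inf
        k <- which.min(d)
        if (length(k) == 1 && is.finite(d[k]) && d[k] < 0.2) {
          branch[j] <- prev$branch[k]
          used[k] <- TRUE
        } else {
          next_branch <- next_branch + 1L
          branch[j] <- next_branch
        }
      }
    } else {
      branch <- next_branch + seq_len(nrow(fp))
      next_branch <- next_branch + nrow(fp)
    }
    out <- fp
    out$branch <- branch
    out$value <- values[i]
    points[[i]] <- out
    prev <- out
  }
  points <- dplyr::bind_rows(points)
  if (nrow(points) > 0) {
    names(points)[names(points) == "value"] <- "param_value"
    points$param <- param
  }

  # localise signature changes by bisection
  sigs <- vapply(fps, fp_signature, character(1))
  events <- list()
  for (i in seq_len(length(values) - 1)) {
    if (sigs[i] == sigs[i + 1]) next
    lo <- values[i]; hi <- values[i + 1]
    sig_lo <- sigs[i]
    while (hi - lo > event_tol) {
      mid <- (lo + hi) / 2
      sig_mid <- fp_signature(
        find_fixed_points(set_sweep_param(params, param, mid),
                          stim = stim, grid_n = grid_n))
      if (sig_mid == sig_lo) lo <- mid else hi <- mid
    }
    events[[length(events) + 1]] <- tibble::tibble(
      param = param, lower = lo, upper = hi,
      signature_before = sigs[i], signature_after = sigs[i + 1]
    )
  }
  structure(list(points = points,
                 events = dplyr::bind_rows(events),
                 param = param, stim = stim),
            class = "mf_bifurcation")
}

#' @export
print.mf_bifurcation <- function(x, ...) {
  cat("<mf_bifurcation> parameter:", x$param,
      if (is.null(x$stim)) "(unstimulated)" else sprintf("(stim = %g)", x$stim), "\n")
  cat(" ", nrow(x$points), "fixed-point records,",
      nrow(x$events), "bifurcation event(s)\n")
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}
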