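#' Map a connection-specificity parameter to same/opposite-preference weights
#'
#' Each directed connection class between choice-selective populations is
#' parameterised by a specificity `gamma` in `[-1, 1]`. The mapping keeps the
#' total input weight to every population constant: an intermediate weight
#' `w_hat = N_s w / (N_s + gamma (2 - N_s))` is split into a same-preference
#' weight `w_plus = w_hat (1 + gamma)` and an opposite-preference weight
#' `w_minus = w_hat (1 - gamma)`. With `N_s = 2` competing populations,
#' `w_hat = w` and `w_plus + w_minus = 2 w` for every `gamma`.
#'
#' @param gamma Specificity in `[-1, 1]` (vectorised).
#' @param n_s Number of competing choice-selective populations (default 2).
#' @param w_base Baseline weight (default 1).
#' @return A tibble with columns `gamma`, `w_plus`, `w_minus`.
#' @examples
#' specificity_to_weights(0.32)   # w_plus = 1.32, w_minus = 0.68
#' @export
specificity_to_weights <- function(gamma, n_s = 2, w_base = 1) {
  abort_if(any(abs(gamma) > 1), "specificity_to_weights(): |gamma| must be <= 1")
  abort_if(n_s < 2, "specificity_to_weights(): n_s must be >= 2")
  w_hat <- n_s * w_base / (n_s + gamma * (2 - n_s))
  tibble::tibble(
    gamma = gamma,
    w_plus = w_hat * (1 + gamma),
    w_minus = w_hat * (1 - gamma)
  )
}

#' Recover a specificity parameter from a weight pair
#'
#' Inverse of [specificity_to_weights()]:
#' `gamma = (w_plus - w_minus) / (w_plus + w_minus)`. The same normalised
#' difference is used to estimate connection specificity from trained
#' recurrent-network weights (see [estimate_gamma_rnn()]).
#'
#' @param w_plus,w_minus Mean same- and opposite-preference weights.
#' @return Specificity estimate (vectorised).
#' @export
weights_to_specificity <- function(w_plus, w_minus) {
  (w_plus - w_minus) / (w_plus + w_minus)
}
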