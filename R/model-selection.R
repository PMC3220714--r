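#' Small-sample Akaike information criterion
#'
#' AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1).
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Effective sample size; must exceed K + 1.
#' @return The AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (any(n <= K + 1))
    stop("AICc undefined: effective sample size n must exceed K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' AICc differences and Akaike weights
#'
#' Given AICc values, computes the differences Delta_i from the smallest
#' value and the normalized Akaike weights
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)`, and returns the rows
#' sorted by AICc. Weights are invariant to adding a constant to all AICc
#' values and sum to one.
#'
#' @param aicc_values Numeric vector of finite AICc values.
#' @param model Optional model labels (default positional).
#' @return Data frame with columns model, AICc, delta, weight, sorted
#'   ascending by AICc.
#' @export
akaike_weights <- function(aicc_values, model = NULL) {
  stopifnot(length(aicc_values) >= 1, all(is.finite(aicc_values)))
  if (is.null(model)) model <- paste0("M", seq_along(aicc_values))
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = as.character(model), AICc = aicc_values,
                    delta = delta, weight = w, stringsAsFactors = FALSE)
  out[order(out$AICc), , drop = FALSE]
}

#' Model-averaged estimate with unconditional standard error
#'
#' Averages per-model estimates with Akaike weights and reports the
#' unconditional standard error
#' `SE = sum_i w_i * sqrt(var_i + (theta_i - theta_bar)^2)`, which absorbs
#' between-model spread on top of within-model sampling variance.
#'
#' @param estimates Per-model point estimates.
#' @param variances Per-model sampling variances (same length).
#' @param weights Model weights summing to one.
#' @return A list with `estimate` and `se`.
#' @export
model_average <- function(estimates, variances, weights) {
  n <- length(estimates)
  if (length(variances) != n || length(weights) != n)
    stop("estimates, variances and weights must have equal lengths")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1")
  est <- sum(weights * estimates)
  se <- sum(weights * sqrt(variances + (estimates - est)^2))
  list(estimate = est, se = se)
}
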