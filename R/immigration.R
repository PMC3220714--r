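#' Estimated number of immigrants over one interval
#'
#' Subtracts the expected number of survivors from the preceding session
#' from the adult population size of the next session:
#' `I = N_adult(t+1) - phi * N(t)`, where `N(t)` is the total population
#' size (complete histories) and `N_adult(t+1)` the population size of
#' adults only (young animals recruited in situ excluded). The estimator is
#' deterministic given its inputs and can go negative; negative values are
#' kept by default (truncation would bias means upward) and flagged.
#'
#' @param N_t Estimated total population size at time t (>= 0).
#' @param phi_t Apparent survival over the interval, in `[0, 1]`.
#' @param N_adult_t1 Estimated adult population size at time t + 1 (>= 0).
#' @param floor_zero Truncate negative estimates at zero.
#' @return Numeric vector of immigrant numbers, with attribute `negative`
#'   flagging entries that were negative before any truncation.
#' @export
estimate_immigrants <- function(N_t, phi_t, N_adult_t1, floor_zero = FALSE) {
  stopifnot(all(N_t >= 0), all(phi_t >= 0), all(phi_t <= 1),
            all(N_adult_t1 >= 0))
  I <- N_adult_t1 - phi_t * N_t
  neg <- I < 0
  if (floor_zero) I <- pmax(I, 0)
  attr(I, "negative") <- neg
  I
}

#' Immigrant numbers per patch and interval from two averaged analyses
#'
#' Combines the model-averaged output of the complete-history analysis
#' (total N per patch-session and per-patch phi) with the model-averaged
#' adult population sizes from the adult-reduced analysis
#' ([reduce_to_adults()]) into one immigrant estimate per patch and
#' interval, for intervals 1 .. T-1 (i.e. arrivals counted in sessions
#' 2 .. T).
#'
#' @param avg_full Output of [rd_model_average()] on the complete dataset.
#' @param avg_adult Output of [rd_model_average()] on the adult-reduced
#'   dataset.
#' @param design The [rd_design()] (supplies landscape labels).
#' @param floor_zero Passed to [estimate_immigrants()].
#' @return Data frame with one row per patch x interval: patch_id,
#'   landscape, interval, I, N_t, phi_t, N_adult_t1, negative.
#' @export
immigration_series <- function(avg_full, avg_adult, design,
                               floor_zero = FALSE) {
  T_ <- design$n_primary
  out <- list()
  for (g in seq_len(nrow(design$patches))) {
    pid <- design$patches$patch_id[g]
    phi <- avg_full$phi_lambda$phi[avg_full$phi_lambda$patch_id == pid]
    Nf <- avg_full$abundance[avg_full$abundance$patch_id == pid, ]
    Na <- avg_adult$abundance[avg_adult$abundance$patch_id == pid, ]
    if (!nrow(Na)) {
      warning("no adult-reduced estimates for patch ", pid, "; skipped")
      next
    }
    for (t in seq_len(T_ - 1L)) {
      N_t <- Nf$N[Nf$session == t]
      N_a <- Na$N[Na$session == t + 1L]
      I <- estimate_immigrants(N_t, phi, N_a, floor_zero = floor_zero)
      out[[length(out) + 1L]] <- data.frame(
        patch_id = pid, landscape = design$patches$landscape[g],
        interval = t, I = as.numeric(I), N_t = N_t, phi_t = phi,
        N_adult_t1 = N_a, negative = attr(I, "negative"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Exact permutation comparison of immigration between two landscapes
#'
#' Test statistic: difference between landscape means of the patch-level
#' mean immigrant numbers (first landscape class in decreasing order minus
#' the second). The null distribution is built by reassigning patches to
#' landscapes: exhaustively over all arrangements when their number is at
#' most `max_exact` (with 3 + 3 patches there are choose(6,3) = 20, so the
#' smallest attainable two-sided p is 0.1), otherwise by Monte Carlo
#' sampling. The two-sided p-value is the proportion of arrangements whose
#' absolute statistic is at least the observed one.
#'
#' @param estimates Data frame from [immigration_series()] (needs columns
#'   patch_id, landscape, I).
#' @param max_exact Arrangement count up to which enumeration is exact.
#' @param n_mc Monte Carlo samples used beyond `max_exact`.
#' @param seed Seed for the Monte Carlo fallback.
#' @return List with `observed` (mean difference), `p_value`,
#'   `n_arrangements` and `method` (`"exact"` or `"monte_carlo"`).
#' @export
compare_landscapes <- function(estimates, max_exact = 1e4, n_mc = 1e4,
                               seed = NULL) {
  pm <- stats::aggregate(I ~ patch_id + landscape, data = estimates, mean)
  ls <- sort(unique(pm$landscape), decreasing = TRUE)
  if (length(ls) != 2)
    stop("exactly two landscape classes with patches are required")
  if (any(table(pm$landscape) < 2))
    stop("at least two patches per landscape are required")
  x <- pm$I
  n <- length(x)
  n1 <- sum(pm$landscape == ls[1])
  stat <- function(idx1) mean(x[idx1]) - mean(x[-idx1])
  observed <- stat(which(pm$landscape == ls[1]))
  n_arr <- choose(n, n1)
  if (n_arr <= max_exact) {
    perms <- utils::combn(n, n1)
    stats_null <- apply(perms, 2, stat)
    method <- "exact"
    n_used <- n_arr
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_null <- replicate(n_mc, stat(sample.int(n, n1)))
    method <- "monte_carlo"
    n_used <- n_mc
  }
  p <- mean(abs(stats_null) >= abs(observed) - 1e-12)
  list(observed = observed, p_value = p, n_arrangements = n_used,
       method = method, landscape_order = ls)
}
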