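#' The eight-model candidate set for density vs patch area
#'
#' Each candidate combines per-landscape component functions of density:
#' `constant_nb` (no area effect; counts negative-binomial, 2 parameters:
#' log mean and dispersion) or `linear_pois` (counts Poisson with log mean
#' linear in log10 patch area, 2 parameters: intercept and slope). The set
#' spans: no structure at all (D1), a global area effect (D2), landscape
#' structure without (D3) and with (D4) area effects everywhere, and area
#' effects restricted to particular landscapes (D5-D8). Components never
#' share parameters; the model log-likelihood is the sum over components.
#'
#' @return Named list of model specifications, each a list with
#'   `model_id`, `components` (list of `list(kind, scope)`), and `K`.
#' @export
density_candidates <- function() {
  comp <- function(kind, scope) list(kind = kind, scope = scope)
  per_ls <- function(kinds) {
    # one component per landscape in the order 50, 30, 10
    mapply(comp, kinds, list(50, 30, 10), SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  specs <- list(
    D1 = list(comp("constant_nb", c(50, 30, 10))),
    D2 = list(comp("linear_pois", c(50, 30, 10))),
    D3 = per_ls(c("constant_nb", "constant_nb", "constant_nb")),
    D4 = per_ls(c("linear_pois", "linear_pois", "linear_pois")),
    D5 = per_ls(c("linear_pois", "constant_nb", "constant_nb")),
    D6 = per_ls(c("constant_nb", "linear_pois", "linear_pois")),
    D7 = per_ls(c("linear_pois", "linear_pois", "constant_nb")),
    D8 = per_ls(c("constant_nb", "linear_pois", "constant_nb")))
  out <- lapply(names(specs), function(id) {
    list(model_id = id, components = specs[[id]],
         K = 2L * length(specs[[id]]))
  })
  names(out) <- names(specs)
  out
}

#' Fit a log-linear Poisson density component
#'
#' Maximum-likelihood fit of `count ~ Poisson(exp(intercept + slope *
#' log10(area_ha)))` via [stats::glm()]. The log-likelihood includes the
#' full Poisson mass (factorial term included).
#'
#' @param counts Non-negative integer counts.
#' @param areas_ha Patch areas in hectares (at least two distinct values).
#' @return List with intercept, slope, loglik, K = 2, fitted means, and a
#'   `boundary` flag (TRUE when all counts are zero and the intercept
#'   diverges to -Inf).
#' @export
fit_linear_poisson <- function(counts, areas_ha) {
  stopifnot(length(counts) == length(areas_ha), all(counts >= 0),
            all(counts == round(counts)), all(areas_ha > 0))
  lx <- log10(areas_ha)
  if (length(unique(lx)) < 2)
    stop("at least two distinct areas are required")
  if (all(counts == 0)) {
    return(list(intercept = -Inf, slope = 0, loglik = 0, K = 2L,
                fitted = rep(0, length(counts)), boundary = TRUE))
  }
  fit <- stats::glm(counts ~ lx, family = stats::poisson())
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       loglik = as.numeric(stats::logLik(fit)),
       K = 2L, fitted = unname(stats::fitted(fit)), boundary = FALSE)
}

#' Fit a constant negative-binomial density component
#'
#' The mean MLE equals the sample mean; the dispersion `k` (negative
#' binomial size, variance = mean + mean^2/k) is found by one-dimensional
#' likelihood maximization on the log scale, capped at 1e6. Underdispersed
#' or degenerate data hit the cap and are flagged as boundary fits.
#'
#' @param counts Non-negative integer counts, length >= 2.
#' @param k_max Upper cap for the dispersion parameter.
#' @return List with mean, log_mean, k, loglik, K = 2 and `boundary` flag.
#' @export
fit_constant_nb <- function(counts, k_max = 1e6) {
  stopifnot(length(counts) >= 2, all(counts >= 0),
            all(counts == round(counts)))
  m <- mean(counts)
  if (m == 0) {
    return(list(mean = 0, log_mean = -Inf, k = k_max, loglik = 0, K = 2L,
                boundary = TRUE))
  }
  nll <- function(logk)
    -sum(stats::dnbinom(counts, mu = m, size = exp(logk), log = TRUE))
  opt <- stats::optimize(nll, interval = c(log(1e-4), log(k_max)),
                         tol = 1e-10)
  k <- exp(opt$minimum)
  boundary <- k >= k_max * 0.99
  if (boundary) k <- k_max
  list(mean = m, log_mean = log(m), k = k,
       loglik = -nll(log(k)), K = 2L, boundary = boundary)
}

#' Fit one density model
#'
#' Fits every component of the specification independently on its
#' landscape subset and sums component log-likelihoods (components share
#' no parameters, so independent fitting is exact joint maximization).
#'
#' @param data A [density_records()] data frame.
#' @param spec One element of [density_candidates()].
#' @return A list of class `density_fit` with model_id, K, loglik and the
#'   per-component fits.
#' @export
fit_density_model <- function(data, spec) {
  fits <- lapply(spec$components, function(cm) {
    sub <- data[data$landscape %in% cm$scope, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("model ", spec$model_id, ": no data in landscape scope ",
           paste(cm$scope, collapse = "/"))
    f <- if (cm$kind == "linear_pois")
      fit_linear_poisson(sub$count, sub$area_ha)
    else
      fit_constant_nb(sub$count)
    c(list(kind = cm$kind, scope = cm$scope, n = nrow(sub)), f)
  })
  structure(list(model_id = spec$model_id, K = spec$K,
                 loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")),
                 components = fits),
            class = "density_fit")
}

#' Fit and rank the full density candidate set
#'
#' Fits all eight candidates, computes AICc (effective sample size = number
#' of patches), Delta and Akaike weights, and returns the ranked table.
#' Models whose parameter count leaves no room for the AICc correction
#' (n <= K + 1) are excluded with a warning.
#'
#' @param data A [density_records()] data frame.
#' @param models Candidate list, default [density_candidates()].
#' @return A list with `table` (data frame: model, K, loglik, AICc, delta,
#'   weight) and `fits` (named list of `density_fit`).
#' @export
select_density_models <- function(data, models = density_candidates()) {
  n <- nrow(data)
  fits <- list()
  for (spec in models) {
    if (n <= spec$K + 1) {
      warning("model ", spec$model_id, " excluded: n <= K + 1")
      next
    }
    fits[[spec$model_id]] <- fit_density_model(data, spec)
  }
  if (!length(fits)) stop("no fittable density model")
  K <- vapply(fits, `[[`, integer(1), "K")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  tab <- akaike_weights(aicc(ll, K, n), model = names(fits))
  tab$K <- K[tab$model]
  tab$loglik <- ll[tab$model]
  tab <- tab[c("model", "K", "loglik", "AICc", "delta", "weight")]
  rownames(tab) <- NULL
  list(table = tab, fits = fits, n = n)
}
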