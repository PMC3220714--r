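#' Run the density analysis end to end
#'
#' Either reads density records from CSV or simulates them from a
#' [density_truth()], fits and ranks the eight-model candidate set, and
#' reports the set of equally plausible models (Delta <= 2).
#'
#' @param data A [density_records()] data frame, or `NULL` to simulate.
#' @param truth A [density_truth()] used when `data` is `NULL`.
#' @param seed Seed for simulation (mandatory when simulating).
#' @param out_dir Optional directory; when given, writes the ranked table
#'   (`density_models.csv`) and coefficients (`density_coefficients.json`),
#'   each stamped with the seed.
#' @return A list with `table`, `fits`, `plausible` (model ids with
#'   Delta <= 2) and `data`.
#' @export
run_density_analysis <- function(data = NULL, truth = density_truth(),
                                 seed = NULL, out_dir = NULL) {
  if (is.null(data)) {
    if (is.null(seed)) stop("a seed is mandatory when simulating data")
    data <- simulate_density(truth, seed = seed)
  }
  sel <- select_density_models(data)
  plausible <- sel$table$model[sel$table$delta <= 2]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- sel$table
    tab$weight <- round(tab$weight, 3)
    utils::write.csv(cbind(tab, seed = if (is.null(seed)) NA else seed),
                     file.path(out_dir, "density_models.csv"),
                     row.names = FALSE)
    coefs <- lapply(sel$fits, function(f) f$components)
    jsonlite::write_json(list(seed = seed, models = coefs),
                         file.path(out_dir, "density_coefficients.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = sel$table, fits = sel$fits, plausible = plausible,
       data = data)
}

#' Run the demographic analysis end to end
#'
#' Simulates (or takes) a robust-design dataset, fits the nine candidate
#' structures on the complete and on the adult-reduced histories, model
#' averages abundance, survival and population rate of change, derives
#' the immigrant-number series, and compares landscapes with the exact
#' permutation test.
#'
#' @param data An [rd_data()] object, or `NULL` to simulate.
#' @param truth An [rd_truth()] used when `data` is `NULL`.
#' @param seed Seed for simulation and optimizer restarts (mandatory when
#'   simulating).
#' @param structures Candidate structures, default [rd_structures()].
#' @param n_random_starts Extra optimizer starts per fit.
#' @param drop_ever_young Use the stricter adult-reduction rule.
#' @param floor_zero Truncate negative immigrant estimates at zero.
#' @param out_dir Optional output directory for CSV/JSON results.
#' @return A list with `selection` (9-structure table), `averages`,
#'   `adult_averages`, `immigration`, `comparison`, and both fit sets.
#' @export
run_demography_analysis <- function(data = NULL, truth = rd_truth(),
                                    seed = NULL,
                                    structures = rd_structures(),
                                    n_random_starts = 2,
                                    drop_ever_young = FALSE,
                                    floor_zero = FALSE, out_dir = NULL) {
  if (is.null(data)) {
    if (is.null(seed)) stop("a seed is mandatory when simulating data")
    data <- simulate_rd(truth, seed = seed)
  }
  full <- fit_rd_set(data, structures, n_random_starts = n_random_starts,
                     seed = seed)
  adult_data <- reduce_to_adults(data, drop_ever_young = drop_ever_young)
  adult <- fit_rd_set(adult_data, structures,
                      n_random_starts = n_random_starts, seed = seed)
  avg_full <- rd_model_average(full)
  avg_adult <- rd_model_average(adult)
  imm <- immigration_series(avg_full, avg_adult, data$design,
                            floor_zero = floor_zero)
  cmp <- compare_landscapes(imm, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- full$table; tab$weight <- round(tab$weight, 3)
    utils::write.csv(cbind(tab, seed = if (is.null(seed)) NA else seed),
                     file.path(out_dir, "rd_models.csv"), row.names = FALSE)
    utils::write.csv(avg_full$abundance,
                     file.path(out_dir, "abundance.csv"), row.names = FALSE)
    utils::write.csv(avg_full$phi_lambda,
                     file.path(out_dir, "phi_lambda.csv"), row.names = FALSE)
    utils::write.csv(imm, file.path(out_dir, "immigration.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, observed_difference = cmp$observed,
           p_value = cmp$p_value, n_arrangements = cmp$n_arrangements,
           method = cmp$method),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  }
  list(selection = full$table, averages = avg_full,
       adult_averages = avg_adult, immigration = imm, comparison = cmp,
       full_fits = full, adult_fits = adult, data = data)
}

#' Run an analysis from a YAML configuration file
#'
#' The configuration selects an analysis (`density` or `demography`),
#' carries a mandatory `seed` when data are simulated, optional input
#' paths (`density_csv`, or `capture_csv` / `inp` with a design block),
#' and options (`drop_ever_young`, `floor_zero`, `n_random_starts`,
#' `out_dir`).
#'
#' @param path Path to a YAML configuration file.
#' @return The corresponding `run_*` result.
#' @export
run_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$analysis) ||
      !cfg$analysis %in% c("density", "demography"))
    stop("config must set analysis: density or demography")
  if (cfg$analysis == "density") {
    data <- if (!is.null(cfg$density_csv)) {
      if (!file.exists(cfg$density_csv))
        stop("missing input file: ", cfg$density_csv)
      read_density_csv(cfg$density_csv)
    } else NULL
    return(run_density_analysis(data = data, seed = cfg$seed,
                                out_dir = cfg$out_dir))
  }
  design <- if (!is.null(cfg$design)) {
    rd_design(cfg$design$n_primary, cfg$design$n_secondary,
              as.data.frame(cfg$design$patches))
  } else default_design()
  data <- NULL
  if (!is.null(cfg$capture_csv)) {
    if (!file.exists(cfg$capture_csv))
      stop("missing input file: ", cfg$capture_csv)
    data <- read_capture_csv(cfg$capture_csv, design)
  } else if (!is.null(cfg$inp)) {
    if (!file.exists(cfg$inp)) stop("missing input file: ", cfg$inp)
    data <- read_inp(cfg$inp, design)
  }
  run_demography_analysis(
    data = data, seed = cfg$seed,
    n_random_starts = if (is.null(cfg$n_random_starts)) 2
                      else cfg$n_random_starts,
    drop_ever_young = isTRUE(cfg$drop_ever_young),
    floor_zero = isTRUE(cfg$floor_zero),
    out_dir = cfg$out_dir)
}
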