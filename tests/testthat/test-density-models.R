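test_that("the candidate set spans the eight component layouts", {
  cand <- density_candidates()
  expect_named(cand, paste0("D", 1:8))
  expect_equal(vapply(cand, `[[`, integer(1), "K"),
               c(D1 = 2L, D2 = 2L, D3 = 6L, D4 = 6L, D5 = 6L, D6 = 6L,
                 D7 = 6L, D8 = 6L))
  kinds <- function(m) vapply(m$components, `[[`, character(1), "kind")
  scope_of <- function(m, kind)
    sort(unlist(lapply(m$components,
                       function(cm) if (cm$kind == kind) cm$scope)))
  # D8: area effect only at intermediate cover
  expect_equal(scope_of(cand$D8, "linear_pois"), 30)
  expect_equal(scope_of(cand$D8, "constant_nb"), c(10, 50))
  # D6: area effect in the two most deforested landscapes
  expect_equal(scope_of(cand$D6, "linear_pois"), c(10, 30))
  # D1/D2 are global single components
  expect_length(cand$D1$components, 1)
  expect_equal(kinds(cand$D2), "linear_pois")
})

test_that("linear Poisson fits satisfy closed forms and a grid oracle", {
  # constant counts: slope 0, intercept log(mean), exactly
  f0 <- fit_linear_poisson(rep(7L, 5), c(1, 10, 50, 100, 500))
  expect_equal(f0$slope, 0, tolerance = 1e-8)
  expect_equal(f0$intercept, log(7), tolerance = 1e-8)

  # brute-force grid oracle on a small dataset: the Poisson loglik at
  # log10 areas (0, 1, 2) and counts (2, 4, 8) reduces to
  # 14a + 20b - e^a (1 + e^b + e^(2b)) + const, evaluated on a fine grid
  counts <- c(2L, 4L, 8L); areas <- 10^c(0, 1, 2)
  fit <- fit_linear_poisson(counts, areas)
  a_grid <- seq(0.2, 1.2, 2e-4)
  b_grid <- seq(0.2, 1.2, 2e-4)
  ll <- outer(14 * a_grid, 20 * b_grid, `+`) -
    outer(exp(a_grid), 1 + exp(b_grid) + exp(2 * b_grid))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  expect_equal(fit$intercept, a_grid[best[1]], tolerance = 1e-3)
  expect_equal(fit$slope, b_grid[best[2]], tolerance = 1e-3)
  expect_equal(fit$loglik,
               sum(dpois(counts,
                         exp(fit$intercept + fit$slope * log10(areas)),
                         log = TRUE)))

  # all-zero data yields a flagged boundary fit, not an error
  fz <- fit_linear_poisson(c(0L, 0L, 0L), c(1, 10, 100))
  expect_true(fz$boundary)
  expect_equal(fz$loglik, 0)
})

test_that("slope recovery is calibrated over replicates", {
  set.seed(60)
  ok <- replicate(100, {
    la <- runif(200, 0, 2)
    y <- rpois(200, exp(0.5 + 1.0 * la))
    f <- suppressWarnings(stats::glm(y ~ la, family = stats::poisson()))
    se <- summary(f)$coefficients["la", "Std. Error"]
    abs(stats::coef(f)["la"] - 1.0) <= 2 * se
  })
  expect_gte(mean(ok), 0.9)
})

test_that("constant NB fits: exact mean, grid oracle for dispersion", {
  counts <- c(1L, 2L, 3L, 10L, 20L)
  fit <- fit_constant_nb(counts)
  expect_equal(fit$mean, 7.2)
  ks <- exp(seq(log(0.01), log(100), length.out = 40001))
  lls <- vapply(ks, function(k)
    sum(dnbinom(counts, mu = 7.2, size = k, log = TRUE)), numeric(1))
  expect_equal(fit$k, ks[which.max(lls)], tolerance = 1e-3)
  expect_equal(fit$loglik, max(lls), tolerance = 1e-8)

  # degenerate data hit boundaries with the mean kept exact
  fz <- fit_constant_nb(c(0L, 0L, 0L, 0L))
  expect_true(fz$boundary)
  expect_equal(fz$mean, 0)
  fe <- fit_constant_nb(c(4L, 4L, 4L, 4L))
  expect_true(fe$boundary)
  expect_equal(fe$mean, 4)
})

test_that("Poisson-simulated counts drive the NB dispersion to its cap", {
  set.seed(61)
  at_cap <- replicate(100, fit_constant_nb(rpois(40, 9))$boundary)
  expect_gt(mean(at_cap), 0.5)
})

test_that("model loglik is the exact sum of independent component fits", {
  d <- simulate_density(density_truth(), seed = 70)
  cand <- density_candidates()
  f3 <- fit_density_model(d, cand$D3)
  separate <- sum(vapply(c(50, 30, 10), function(ls)
    fit_constant_nb(d$count[d$landscape == ls])$loglik, numeric(1)))
  expect_equal(f3$loglik, separate)

  # nested Poisson components: the larger model never fits worse
  f2 <- fit_density_model(d, cand$D2)
  f4 <- fit_density_model(d, cand$D4)
  expect_gte(f4$loglik, f2$loglik - 1e-8)
})

test_that("the selection table is ranked, normalized and complete", {
  d <- simulate_density(density_truth(), seed = 71)
  sel <- select_density_models(d)
  expect_equal(nrow(sel$table), 8)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_equal(sel$table$delta[1], 0)
  expect_true(all(diff(sel$table$delta) >= 0))
  expect_true(all(diff(sel$table$AICc) >= 0))
  # AICc consistency on every row
  expect_equal(sel$table$AICc,
               aicc(sel$table$loglik, sel$table$K, nrow(d)))
})

test_that("structureless truth favors the two-parameter models", {
  flat <- density_truth(list(
    list(landscape = 50, kind = "constant", mean = 9, k = 2,
         area_range = c(3, 145), n_patches = 15L),
    list(landscape = 30, kind = "constant", mean = 9, k = 2,
         area_range = c(2, 374), n_patches = 20L),
    list(landscape = 10, kind = "constant", mean = 9, k = 2,
         area_range = c(6, 106), n_patches = 15L)))
  top2 <- vapply(1:20, function(r) {
    sel <- select_density_models(simulate_density(flat, seed = 500 + r))
    sel$table$K[1] == 2
  }, logical(1))
  expect_gt(mean(top2), 0.5)
})

test_that("models with too many parameters for n are excluded with a warning", {
  d <- simulate_density(density_truth(), seed = 72)
  tiny <- d[c(1:3, 16:18, 36), ]  # 7 patches: n <= K + 1 for K = 6
  tiny <- density_records(tiny$patch_id, tiny$landscape, tiny$area_ha,
                          tiny$count)
  w <- capture_warnings(sel <- select_density_models(tiny))
  expect_length(w, 6)  # every 6-parameter model is excluded
  expect_true(all(grepl("excluded", w)))
  expect_true(all(sel$table$K == 2))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
})
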