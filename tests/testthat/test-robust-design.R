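test_that("parameter counts follow the factor contribution rule", {
  expect_equal(count_parameters(rd_structure("constant", "constant"), 6, 5), 22L)
  expect_equal(count_parameters(rd_structure("landscape", "landscape"),
                                6, 5, n_landscapes = 2), 24L)
  expect_equal(count_parameters(rd_structure("patch", "patch"), 6, 5), 32L)
  # constant-detection variant used in reduced analyses
  expect_equal(count_parameters(rd_structure("constant", "constant",
                                             detection = "constant"),
                                6, 5), 4L)
})

test_that("pstar follows its closed form and monotonicity", {
  expect_equal(pstar(c(0.5, 0.5)), 0.75)
  expect_equal(pstar(rep(0, 4)), 0)
  expect_equal(pstar(rep(0.2, 5)), 1 - 0.8^5)
  set.seed(100)
  p <- runif(5)
  p2 <- p; p2[3] <- min(p2[3] + 0.1, 1)
  expect_gte(pstar(p2), pstar(p))
})

test_that("Huggins conditional probabilities sum to one over all histories", {
  hs <- nonzero_histories(5)
  tot <- sum(vapply(seq_len(nrow(hs)), function(i)
    exp(huggins_session_loglik(hs[i, , drop = FALSE], 0.3, 0.6)),
    numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)

  # single occasion: conditioning saturates, every history contributes 0
  expect_equal(huggins_session_loglik(matrix(1, 3, 1), 0.4, 0.5), 0)
})

test_that("with p = c the Huggins likelihood equals the classical M0 form", {
  hs <- nonzero_histories(4)
  p <- 0.37
  ps <- 1 - (1 - p)^4
  for (i in seq_len(nrow(hs))) {
    x <- sum(hs[i, ])
    m0 <- x * log(p) + (4 - x) * log(1 - p) - log(ps)
    expect_equal(huggins_session_loglik(hs[i, , drop = FALSE], p, p), m0)
  }
})

test_that("Huggins abundance follows N = M / p* with a lognormal interval", {
  ab <- huggins_abundance(3, 0.75)
  expect_equal(ab$N, 4)
  expect_gte(ab$lcl, 3)
  expect_lte(ab$lcl, ab$N)
  expect_gte(ab$ucl, ab$N)
  # perfect detection collapses the interval onto M
  ab1 <- huggins_abundance(7, 1)
  expect_equal(ab1$N, 7)
  expect_equal(ab1$lcl, 7)
  expect_equal(ab1$ucl, 7)
})

test_that("the entry distribution matches its closed forms", {
  # growth exactly balancing survival leaves no recruitment
  ed <- entry_distribution(0.7, 0.7, 5)
  expect_equal(ed$beta, c(1, 0, 0, 0, 0))
  expect_false(ed$floored)
  ed2 <- entry_distribution(0.5, 1.0, 3)
  expect_equal(ed2$beta, c(0.5, 0.25, 0.25))
  expect_equal(ed2$penalty, 0)
  # lambda below phi floors the raw entries and reports a penalty
  ed3 <- entry_distribution(0.8, 0.5, 4)
  expect_true(ed3$floored)
  expect_gt(ed3$penalty, 0)
  expect_equal(sum(ed3$beta), 1)
})

test_that("open-process conditional probabilities sum to one", {
  hs <- nonzero_histories(4)
  ps <- rep(0.4, 4)
  tot <- sum(vapply(seq_len(nrow(hs)), function(i)
    exp(open_history_loglik(hs[i, , drop = FALSE], 0.6, 1.1, ps)),
    numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("phi = 1, lambda = 1 degenerates to a closed Bernoulli model", {
  hs <- nonzero_histories(3)
  ps <- c(0.3, 0.5, 0.7)
  denom <- 1 - prod(1 - ps)
  for (i in seq_len(nrow(hs))) {
    h <- hs[i, ]
    bern <- sum(h * log(ps) + (1 - h) * log(1 - ps)) - log(denom)
    expect_equal(open_history_loglik(hs[i, , drop = FALSE], 1, 1, ps),
                 bern, tolerance = 1e-12)
  }
})

test_that("joint fits recover sensible estimates and respect link ranges", {
  tr <- uniform_truth()
  d <- simulate_rd(tr, seed = 120)
  f <- fit_robust_design(d, rd_structure("constant", "constant"),
                         n_random_starts = 0)
  expect_true(f$converged)
  expect_equal(f$K, 22L)
  expect_true(all(f$real$phi > 0 & f$real$phi < 1))
  expect_true(all(f$real$lambda > 0))
  expect_lt(abs(f$real$phi[1] - 0.6), 3 * f$real$phi_se[1])
  expect_lt(abs(f$real$lambda[1] - 1.0), 3 * f$real$lambda_se[1])
  # abundance estimates never fall below the observed counts
  expect_true(all(f$abundance$N >= f$abundance$M - 1e-8))
  expect_true(all(f$abundance$lcl >= f$abundance$M - 1e-8))
  expect_true(all(f$abundance$lcl <= f$abundance$N + 1e-8))
  expect_true(all(f$abundance$ucl >= f$abundance$N - 1e-8))
})

test_that("adding factor levels never decreases the maximized loglik", {
  tr <- rd_truth()
  d <- simulate_rd(tr, seed = 121)
  lls <- vapply(list(rd_structure("constant", "constant"),
                     rd_structure("landscape", "constant"),
                     rd_structure("patch", "constant"),
                     rd_structure("patch", "patch")),
                function(s) fit_robust_design(d, s, n_random_starts = 1,
                                              seed = 1)$loglik,
                numeric(1))
  expect_true(all(diff(lls) >= -1e-4))
})

test_that("the nine-structure table reproduces K and normalizes weights", {
  tr <- rd_truth()
  d <- simulate_rd(tr, seed = 122)
  fs <- fit_rd_set(d, n_random_starts = 0)
  expect_equal(nrow(fs$table), 9)
  expect_equal(sum(fs$table$weight), 1, tolerance = 1e-12)
  K <- vapply(fs$fits, `[[`, integer(1), "K")
  expect_equal(K[paste0("I", 1:9)],
               c(I1 = 22L, I2 = 24L, I3 = 23L, I4 = 23L, I5 = 28L,
                 I6 = 28L, I7 = 27L, I8 = 27L, I9 = 32L))
  avg <- rd_model_average(fs)
  # averaged abundance lies within the per-model spread
  for (i in seq_len(nrow(avg$abundance))) {
    Ns <- vapply(fs$fits, function(f) f$abundance$N[i], numeric(1))
    expect_gte(avg$abundance$N[i], min(Ns) - 1e-8)
    expect_lte(avg$abundance$N[i], max(Ns) + 1e-8)
  }
  expect_true(all(avg$phi_lambda$phi >= 0 & avg$phi_lambda$phi <= 1))
})

test_that("estimation bias shrinks with more individuals per patch", {
  fit_bias <- function(N1) {
    tr <- uniform_truth(n_patches = 4, N1 = N1, phi = 0.6,
                        imm_rate = 0.4 * N1, p = 0.5, c = 0.5)
    d <- simulate_rd(tr, seed = 123)
    f <- fit_robust_design(d, rd_structure("constant", "constant"),
                           n_random_starts = 0)
    abs(f$real$phi[1] - 0.6)
  }
  expect_lt(fit_bias(400), 0.05)
})
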