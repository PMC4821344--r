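test_that("corrected AIC follows its closed form", {
  expect_equal(aicc(50, 100, 5), 100 * log(0.5) + 10 + 60 / 94,
               tolerance = 1e-12)
  expect_equal(aicc(100, 100, 0), 0)
  # equal chi2: extra parameters can only penalize
  expect_gt(aicc(50, 100, 7) - aicc(50, 100, 5), 4)
  expect_error(aicc(50, 6, 5), "n_points")
})

test_that("AICc differences, not levels, survive a common sigma
          rescaling", {
  d0 <- aicc(50, 100, 5) - aicc(80, 100, 7)
  # rescaling all sigma by c scales every chi2 by 1/c^2
  d1 <- aicc(50 / 4, 100, 5) - aicc(80 / 4, 100, 7)
  expect_equal(d0, d1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(aicc(50, 100, 5), aicc(50 / 4, 100, 5))))
})

test_that("the nested F-test matches the distribution-function oracle", {
  eq <- f_test(list(chi2 = 100, dof = 97), list(chi2 = 100, dof = 95))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  ex <- f_test(list(chi2 = 120, dof = 97), list(chi2 = 100, dof = 95))
  expect_equal(ex$F, 9.5)
  expect_equal(ex$p, pf(9.5, 2, 95, lower.tail = FALSE))
  worse <- f_test(list(chi2 = 90, dof = 97), list(chi2 = 100, dof = 95))
  expect_equal(worse$F, 0)
  expect_equal(worse$p, 1)
  expect_error(f_test(list(chi2 = 1, dof = 95),
                      list(chi2 = 1, dof = 97)), "nested")
})

test_that("the dispersion screen computes per-parameter CVs and flags
          wild scatter", {
  reps <- list(c(tau3 = 0.050), c(tau3 = 0.150), c(tau3 = 0.400))
  sc <- screen_dispersion(reps)
  expect_equal(sc$max_cv, sd(c(50, 150, 400)) / 200, tolerance = 1e-9)
  expect_false(sc$unstable)
  # the sample CV of 3 replicates is bounded by sqrt(3) < 2, so a
  # >200% flag needs more replicates
  near <- screen_dispersion(list(c(tau3 = 0.001), c(tau3 = 0.010),
                                 c(tau3 = 0.600)))
  expect_equal(near$max_cv, sd(c(1, 10, 600)) / mean(c(1, 10, 600)),
               tolerance = 1e-9)
  bad <- lapply(c(1, 1, 1, 1, 600) * 1e-3, function(v) c(tau3 = v))
  expect_true(screen_dispersion(bad)$unstable)
  same <- list(c(a = 1, b = 2), c(a = 1, b = 2), c(a = 1, b = 2))
  expect_equal(screen_dispersion(same)$max_cv, 0)
  expect_warning(screen_dispersion(reps[1:2]), "fewer than 3")
})

test_that("selection recovers the true component count from noisy
          curves", {
  lags <- log_lags(120)
  truths <- list(egfp_params(), r9a_params(), wt_params())
  n_correct <- vapply(seq_along(truths), function(m) {
    sel <- vapply(1:20, function(s) {
      cc <- synthesize_acf(truths[[m]], lags, noise_sd = 0.005,
                           rng_seed = 5000 + 97 * m + s)
      suppressWarnings(
        select_model(cc, 1:3, starts = 4, rng_seed = s)$selected)
    }, 0L)
    mean(sel == length(truths[[m]]$tau))
  }, 0)
  expect_gte(n_correct[1], 0.8)
  expect_gte(n_correct[2], 0.8)
  expect_gte(n_correct[3], 0.8)
})

test_that("a superfluous component is rejected for negligible
          amplitude", {
  lags <- log_lags(120)
  cc <- synthesize_acf(r9a_params(), lags, noise_sd = 0.005,
                       rng_seed = 77)
  sel <- suppressWarnings(select_model(cc, 1:3, starts = 4))
  expect_equal(sel$selected_fit$spec$M, 2L)
  # the third component is refused either as unphysical or because the
  # F-test finds no significant improvement
  ft23 <- Filter(function(ft) ft$complex == 3, sel$f_tests)
  expect_true(any(grepl("candidate3", sel$rationale)) ||
                (length(ft23) && ft23[[1]]$p >= 0.05))
})

test_that("selection is deterministic for fixed seeds and candidate
          order", {
  lags <- log_lags(100)
  cc <- synthesize_acf(wt_params(), lags, noise_sd = 0.004,
                       rng_seed = 13)
  a <- suppressWarnings(select_model(cc, 1:3, starts = 4, rng_seed = 2))
  b <- suppressWarnings(select_model(cc, 1:3, starts = 4, rng_seed = 2))
  expect_identical(a$selected, b$selected)
  expect_equal(a$aicc, b$aicc, tolerance = 1e-12)
})

test_that("F-test p-values are approximately uniform under the null", {
  lags <- log_lags(120)
  ps <- vapply(1:200, function(s) {
    cc <- synthesize_acf(egfp_params(), lags, noise_sd = 0.005,
                         rng_seed = 1000 + s)
    suppressWarnings(
      select_model(cc, 1:2, starts = 4, rng_seed = s)$f_tests[[1]]$p)
  }, 0)
  expect_gte(mean(ps < 0.05), 0.02)
  expect_lte(mean(ps < 0.05), 0.10)
})
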