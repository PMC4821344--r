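test_that("the diffusion model honours its closed-form limits", {
  # amplitude law at tau -> 0
  expect_equal(acf_model(1e-12, N = 2, F = 1, tau = 1e-4), 1 + 1 / 2,
               tolerance = 1e-6)
  # half-decay at tau = tau1 in the 2D (S -> Inf) limit
  expect_equal(acf_model(4e-4, N = 1, F = 1, tau = 4e-4, S = Inf), 1.5,
               tolerance = 1e-12)
  # nearly fully decayed at the upper fit bound for the wild-type-like
  # set: the residual amplitude is the slow component's tail,
  # F3/(1+3.4/tau3)/sqrt(1+3.4/(S^2 tau3)) = 2.5e-3
  p <- wt_params()
  expect_lt(acf_model(3.4, p$N, p$F, p$tau) - 1, 3e-3)
  # monotone non-increasing on a dense grid (free diffusion, no triplet)
  g <- acf_model(10^seq(-6, 1, length.out = 500), p$N, p$F, p$tau)
  expect_true(all(diff(g) <= 1e-12))
  # triplet factor raises the short-lag limit by 1/(1-T)
  gt <- acf_model(1e-9, N = 1, F = 1, tau = 1e-4,
                  triplet_fraction = 0.2, triplet_time = 5e-6)
  expect_equal(gt, 1 + (1 / 0.8), tolerance = 1e-4)
  expect_error(acf_model(c(0, 1e-4), 1, 1, 1e-4), "positive")
  expect_error(acf_model(1e-4, 1, c(0.5, 0.5), c(2e-4, 1e-4)),
               "ascending")
})

test_that("chi-square is the sigma-weighted sum of squares", {
  cc <- correlation_curve(lags = c(1e-4, 1e-3, 1e-2),
                          G = c(1.5, 1.2, 1.05),
                          sigma = c(0.01, 0.02, 0.05))
  expect_equal(chi_square(cc, cc$G), 0)
  expect_equal(chi_square(cc, cc$G + c(0.02, 0, 0)), 4)
  expect_equal(chi_square(cc, cc$G + c(0.01, 0.04, 0.15)), 14)
  expect_error(chi_square(cc, cc$G, mask = c(FALSE, FALSE, FALSE)),
               "empty")
})

test_that("noiseless single-component curves are recovered to optimizer
          precision", {
  lags <- log_lags(100)
  cc <- synthesize_acf(list(N = 2.5, F = 1, tau = 7e-4), lags)
  fit <- fcs_fit(cc, 1, starts = 3)
  expect_equal(fit$params$N, 2.5, tolerance = 1e-6)
  expect_equal(fit$params$tau, 7e-4, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$dof, fit$n_points - fit$K - 1)
})

test_that("an under-specified model fits demonstrably worse than the
          generating one", {
  lags <- log_lags(100)
  cc <- synthesize_acf(r9a_params(), lags, noise_sd = 1e-4,
                       rng_seed = 8)
  f1 <- fcs_fit(cc, 1, starts = 3)
  f2 <- fcs_fit(cc, 2, starts = 6)
  expect_gt(f1$chi2, f2$chi2)
})

test_that("refitting a fit's own model curve is a fixed point", {
  lags <- log_lags(100)
  cc <- synthesize_acf(wt_params(), lags, noise_sd = 0.005,
                       rng_seed = 4)
  fit <- fcs_fit(cc, 3, starts = 8)
  clean <- synthesize_acf(fit$params, lags)
  refit <- fcs_fit(clean, 3, starts = 1, start = fit$params)
  expect_equal(refit$params$tau, fit$params$tau, tolerance = 1e-6)
  expect_equal(refit$params$F, fit$params$F, tolerance = 1e-6)
})

test_that("diffusion times are recovered from noisy three-component
          curves (median relative error < 15%)", {
  lags <- log_lags(120)
  truth <- wt_params()
  errs <- vapply(1:20, function(s) {
    cc <- synthesize_acf(truth, lags, noise_sd = 0.005,
                         rng_seed = 300 + s)
    fit <- fcs_fit(cc, 3, starts = 6, rng_seed = s)
    abs(fit$params$tau - truth$tau) / truth$tau
  }, numeric(3))
  expect_lt(max(apply(errs, 1, median)), 0.15)
})

test_that("fitted amplitudes obey the occupancy sum rule", {
  lags <- log_lags(100)
  cc <- synthesize_acf(wt_params(), lags, noise_sd = 0.003,
                       rng_seed = 12)
  fit <- fcs_fit(cc, 3, starts = 6)
  expect_lte(cc$G[1] - 1,
             (1 / fit$params$N) *
               (1 + fit$params$triplet_fraction /
                  (1 - fit$params$triplet_fraction)) + 0.05)
  expect_equal(sum(fit$params$F), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$params$tau) > 0))
})

test_that("model methods expose the standard fitted-model interface", {
  lags <- log_lags(80)
  cc <- synthesize_acf(list(N = 1, F = 1, tau = 4e-4), lags,
                       noise_sd = 0.004, rng_seed = 6)
  fit <- fcs_fit(cc, 1, starts = 3)
  expect_named(coef(fit)[1:2], c("N", "F1"))
  expect_length(fitted(fit), fit$n_points)
  expect_length(residuals(fit), fit$n_points)
  expect_equal(deviance(fit), fit$chi2)
  expect_equal(predict(fit, newlags = 1e-4),
               acf_model(1e-4, fit$params$N, fit$params$F,
                         fit$params$tau, S = 5), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "correlation_curve")
  expect_output(print(summary(fit)), "AICc")
})
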