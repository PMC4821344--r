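test_that("config validation rejects inconsistent study conditions", {
  expect_error(sim_config(components = data.frame(D = -1, count = 10)),
               "positive")
  expect_error(sim_config(duration = 25, segment_length = 10),
               "integer multiple")
  expect_error(sim_config(bin_width = 0), "positive")
  expect_error(sim_config(box = c(1, 1, 4)), "10 waists")
})

test_that("empty volume with zero background gives an all-zero trace", {
  cfg <- sim_config(components = data.frame(D = 25, count = 0),
                    immobile = list(count = 0, bleach_rate = 0.1),
                    background = 0, bin_width = 1e-3, duration = 1,
                    segment_length = 1, rng_seed = 1)
  sim <- simulate_trace(cfg)
  expect_true(all(sim$trace$counts == 0))
})

test_that("seeded simulation is bit-identical on repeat", {
  cfg <- fast_sim_config(99, count = 20, duration = 0.2,
                         bin_width = 1e-4)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$counts, b$trace$counts)
})

test_that("mean intensity is linear in particle count", {
  rates <- vapply(c(30, 60, 120), function(n) {
    cfg <- sim_config(components = data.frame(D = 25, count = n),
                      box = c(2, 2, 4), brightness = 5e4,
                      bin_width = 1e-3, duration = 30,
                      segment_length = 30, rng_seed = 17)
    sim <- simulate_trace(cfg)
    mean(sim$trace$counts) / cfg$bin_width
  }, 0)
  expect_equal(rates[2] / rates[1], 2, tolerance = 0.05)
  expect_equal(rates[3] / rates[2], 2, tolerance = 0.05)
})

test_that("immobile-only ensemble decays at the configured bleach rate", {
  cfg <- sim_config(components = data.frame(D = 25, count = 0),
                    immobile = list(count = 500, bleach_rate = 0.1),
                    background = 0, box = c(2, 2, 4),
                    brightness = 5e4, bin_width = 1e-3, duration = 30,
                    segment_length = 30, rng_seed = 11)
  sim <- simulate_trace(cfg)
  bf <- fit_photobleach(sim$trace)
  # oracle: surviving-fluorophore count decays as exp(-k t)
  expect_true(bf$bleach_flag)
  expect_equal(bf$k, 0.1, tolerance = 0.2)
})

test_that("simulated one-component ACF carries the analytic diffusion
          time (tau = w^2 / 4D)", {
  taus <- vapply(1:10, function(s) {
    sim <- simulate_trace(fast_sim_config(400 + s))
    cc <- compute_acf(sim$trace, max_lag = 0.05)
    fit <- fcs_fit(cc, fcs_model_spec(1, fit_range = c(50e-6, 0.05)),
                   starts = 4)
    fit$params$tau
  }, 0)
  expect_lt(median(abs(taus - 4e-4) / 4e-4), 0.15)
})

test_that("synthesized ACF decorrelates to 1 and honours the 2D limit", {
  lags <- log_lags(60)
  cc <- synthesize_acf(list(N = 3, F = 1, tau = 1e-4), lags)
  expect_equal(cc$G[length(lags)], 1, tolerance = 1e-3)
  # S -> Inf reduces to the single-factor 2D form
  g2 <- synthesize_acf(list(N = 2, F = 1, tau = 4e-4, S = Inf), lags)
  expect_equal(g2$G, 1 + 0.5 / (1 + lags / 4e-4), tolerance = 1e-12)
  expect_error(synthesize_acf(list(N = 1, F = 1, tau = 1e-4), lags,
                              noise_sd = -1), ">= 0")
})

test_that("noiseless synthesized curves refit to their generating
          parameters", {
  lags <- log_lags(150)
  cc <- synthesize_acf(wt_params(), lags)
  fit <- fcs_fit(cc, 3, starts = 4)
  expect_equal(fit$params$F, wt_params()$F, tolerance = 1e-4)
  expect_equal(fit$params$tau, wt_params()$tau, tolerance = 1e-4)
})

test_that("FRAP simulator honours the half-time definition and bounds", {
  fc <- simulate_frap(t_half = 20, mobile_fraction = 1, noise_sd = 0,
                      offset = 0.2)
  post <- (fc$n_prebleach + 1):length(fc$times)
  y20 <- fc$intensities[post][fc$times[post] == 20]
  expect_equal(y20, 0.2 + 0.8 / 2, tolerance = 1e-12)
  flat <- simulate_frap(t_half = 20, mobile_fraction = 0, noise_sd = 0)
  expect_equal(var(flat$intensities[post]), 0, tolerance = 1e-20)
  expect_error(simulate_frap(20, mobile_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulate_frap(-1), "positive")
})
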