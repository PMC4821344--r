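test_that("constant traces are not flagged as bleaching", {
  set.seed(1)
  tr <- intensity_trace(rpois(6000, 100), bin_width = 0.01)
  # on flat data the exponential may not converge; the constant
  # fallback is the correct (unflagged) answer either way
  bf <- suppressWarnings(fit_photobleach(tr))
  expect_false(bf$bleach_flag)
  expect_equal(bf$y0 + bf$A, 100 * 10, tolerance = 0.05)
})

test_that("a noiseless exponential envelope is recovered within 5%", {
  t <- seq(0.05, 59.95, by = 0.1)
  y <- (200 * exp(-0.1 * t) + 300) * 0.1  # counts per 0.1-s bin
  tr <- intensity_trace(y, bin_width = 0.1)
  bf <- fit_photobleach(tr)
  expect_equal(bf$A / 0.1, 200, tolerance = 0.05)
  expect_equal(bf$k, 0.1, tolerance = 0.05)
  expect_equal(bf$y0 / 0.1, 300, tolerance = 0.05)
  expect_true(bf$bleach_flag)
})

test_that("simulated immobile bleaching is flagged with a rate near the
          per-particle truth", {
  cfg <- sim_config(components = data.frame(D = 25, count = 20),
                    immobile = list(count = 300, bleach_rate = 0.15),
                    box = c(2, 2, 4), brightness = 5e4,
                    bin_width = 1e-3, duration = 30,
                    segment_length = 30, rng_seed = 21)
  bf <- fit_photobleach(simulate_trace(cfg)$trace)
  expect_true(bf$bleach_flag)
  expect_equal(bf$k, 0.15, tolerance = 0.25)
})

test_that("bleach-free simulations are unflagged in at least 95% of
          seeded runs", {
  flags <- vapply(1:100, function(s) {
    cfg <- sim_config(components = data.frame(D = 25, count = 30),
                      box = c(2, 2, 4), brightness = 5e4,
                      bin_width = 1e-3, duration = 12,
                      segment_length = 12, rng_seed = 1200 + s)
    suppressWarnings(
      fit_photobleach(simulate_trace(cfg)$trace)$bleach_flag)
  }, TRUE)
  expect_gte(mean(!flags), 0.95)
})

test_that("excising the bleach window shortens and shifts the trace", {
  tr <- intensity_trace(rep(5, 6000), bin_width = 0.01)  # 60 s
  cut20 <- excise_bleach_window(tr, 20)
  expect_equal(trace_duration(cut20), 40)
  expect_equal(cut20$start_time, 20)
  cut10 <- excise_bleach_window(tr, 10)
  expect_equal(trace_duration(cut10), 50)
  expect_identical(excise_bleach_window(tr, 0), tr)
  expect_error(excise_bleach_window(tr, 60), "shorter")
})

test_that("segmentation yields whole segments and drops the remainder", {
  tr60 <- intensity_trace(rep(5, 6000), bin_width = 0.01)
  expect_length(segment_trace(tr60, 10)$segments, 6)
  expect_length(segment_trace(tr60, 60)$segments, 1)
  tr55 <- intensity_trace(rep(5, 5500), bin_width = 0.01)
  segs <- suppressMessages(segment_trace(tr55, 10))
  expect_length(segs$segments, 5)
  expect_equal(segs$discarded, 5)
  expect_error(segment_trace(tr60, 0), "positive")
})

test_that("excise-then-segment commutes with segment-then-drop", {
  set.seed(3)
  tr <- intensity_trace(rpois(6000, 8), bin_width = 0.01)
  a <- segment_trace(excise_bleach_window(tr, 20), 10)$segments
  b <- segment_trace(tr, 10)$segments[-(1:2)]
  expect_equal(length(a), length(b))
  for (i in seq_along(a))
    expect_identical(a[[i]]$counts, b[[i]]$counts)
})
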