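# shared fixtures: wild-type-like and mutant-like diffusion parameter
# sets (fractions as proportions, times in seconds) and common grids

wt_params <- function()
  list(N = 1, F = c(0.451, 0.414, 0.135),
       tau = c(343.2e-6, 3.28e-3, 98.2e-3))

r9a_params <- function()
  list(N = 1, F = c(0.769, 0.231), tau = c(339.8e-6, 5.99e-3))

egfp_params <- function() list(N = 1, F = 1, tau = 266.7e-6)

TAU_EGFP <- 266.7e-6

log_lags <- function(n = 120, from = 50e-6, to = 3.4)
  10^seq(log10(from), log10(to), length.out = n)

# small fast-running simulation configs
fast_sim_config <- function(rng_seed, D = 25, count = 144,
                            duration = 3, bin_width = 15e-6,
                            brightness = 5e4, ...)
  sim_config(components = data.frame(D = D, count = count),
             box = c(2, 2, 4), waist = 0.2, S = 5,
             brightness = brightness, bin_width = bin_width,
             duration = duration, segment_length = duration,
             rng_seed = rng_seed, ...)

# independent brute-force correlator (plain R, no coarsening)
brute_force_acf <- function(counts, lag_bins) {
  vapply(lag_bins, function(k) {
    n <- length(counts)
    a <- counts[1:(n - k)]
    b <- counts[(k + 1):n]
    mean(a * b) / (mean(a) * mean(b))
  }, 0)
}
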