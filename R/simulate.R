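#' Configuration for the fluorescence-trace simulator
#'
#' Defines the study conditions the Monte-Carlo trace generator emulates:
#' 1-3 freely diffusing fluorescent species plus an immobile, irreversibly
#' photobleaching bound fraction, observed through a 3D-Gaussian confocal
#' volume with Poisson shot noise. Defaults mirror a typical in vivo
#' measurement: 60-s records made of six 10-s segments sampled at the
#' 15.0-microsecond illumination period, a 0.2-um lateral waist and
#' structure parameter S = 5 (axial/lateral ratio of the detection
#' volume, here ~400 nm diameter x ~2000 nm height).
#'
#' @param components `data.frame` with columns `D` (diffusion coefficient,
#'   um^2/s) and `count` (number of particles), one row per mobile species.
#' @param immobile List with `count` (particles) and `bleach_rate` (1/s)
#'   for the immobile, bleaching fraction; `count = 0` disables it.
#' @param box Periodic box side lengths in um (length 1 or 3). Must be at
#'   least 10 lateral waists per axis so the open-volume Gaussian ACF is a
#'   valid oracle for the periodic simulation.
#' @param waist Lateral 1/e^2 beam radius omega, um.
#' @param S Structure parameter (axial/lateral ratio); axial radius is
#'   `S * waist`.
#' @param brightness Detected counts/s per particle at the focus centre.
#' @param background Background count rate, counts/s.
#' @param bin_width Time bin (= Brownian time step), s.
#' @param duration Total trace length, s; must be an integer multiple of
#'   `segment_length`.
#' @param segment_length Length of one contiguous record segment, s.
#' @param rng_seed Integer seed; a seeded configuration reproduces its
#'   trace bit-identically.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(components = data.frame(D = 25, count = 50),
#'                   duration = 1, segment_length = 1, rng_seed = 1)
#' @export
sim_config <- function(components = data.frame(D = 25, count = 100),
                       immobile = list(count = 0, bleach_rate = 0.1),
                       box = c(2, 2, 4),
                       waist = 0.2, S = 5,
                       brightness = 5e4, background = 0,
                       bin_width = 15e-6,
                       duration = 60, segment_length = 10,
                       rng_seed = 1L) {
  if (length(box) == 1L) box <- rep(box, 3L)
  stopifnot(is.data.frame(components), all(c("D", "count") %in%
                                             names(components)))
  if (nrow(components) < 1L || nrow(components) > 3L)
    stop("1 to 3 mobile components are supported")
  if (any(components$D <= 0)) stop("diffusion coefficients must be positive")
  if (any(components$count < 0)) stop("particle counts must be >= 0")
  if (!is.list(immobile) || is.null(immobile$count))
    stop("'immobile' must be list(count=, bleach_rate=)")
  if (is.null(immobile$bleach_rate)) immobile$bleach_rate <- 0
  if (immobile$count < 0 || immobile$bleach_rate < 0)
    stop("immobile count and bleach rate must be >= 0")
  if (bin_width <= 0 || duration <= 0 || segment_length <= 0)
    stop("bin_width, duration and segment_length must be positive")
  if (abs(duration / segment_length - round(duration / segment_length)) >
      1e-9)
    stop("'duration' must be an integer multiple of 'segment_length'")
  if (waist <= 0 || S <= 0 || brightness < 0 || background < 0)
    stop("waist, S must be positive; brightness, background >= 0")
  if (any(box[1:2] < 10 * waist))
    stop("lateral box sides must be >= 10 waists for a valid open-volume",
         " oracle")
  n_total <- sum(components$count) + immobile$count
  fraction <- if (n_total > 0) components$count / n_total else
    rep(0, nrow(components))
  structure(list(components = cbind(components, fraction = fraction),
                 immobile = immobile, box = box, waist = waist, S = S,
                 brightness = brightness, background = background,
                 bin_width = bin_width, duration = duration,
                 segment_length = segment_length,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate a fluorescence fluctuation trace
#'
#' Brownian-dynamics Monte Carlo of the configured species in a periodic
#' box: mobile particles take per-axis Gaussian steps with variance
#' `2 D dt`; each particle contributes a detection weight
#' `exp(-2(x^2+y^2)/w^2 - 2 z^2/(S w)^2)`; immobile particles sit still
#' and bleach irreversibly with rate `k`; counts per bin are Poisson with
#' mean `brightness * sum(weights) * dt + background * dt`.
#'
#' @param config A [sim_config()].
#' @return List with elements `trace` (an [intensity_trace()]) and
#'   `truth` (generating parameters: per-component `D` and `fraction`,
#'   immobile fraction, bleach rate, expected initial amplitude of the
#'   bleaching envelope, and the seed).
#' @examples
#' sim <- simulate_trace(sim_config(
#'   components = data.frame(D = 25, count = 30),
#'   duration = 0.5, segment_length = 0.5, bin_width = 1e-4, rng_seed = 7))
#' sim$trace
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n_bins <- as.integer(round(config$duration / config$bin_width))
  counts <- .sim_trace_kernel(
    n_bins, config$bin_width,
    as.numeric(config$components$D),
    as.integer(config$components$count),
    as.integer(config$immobile$count),
    as.numeric(config$immobile$bleach_rate),
    config$brightness, config$background,
    config$waist, config$S * config$waist, as.numeric(config$box))
  trace <- intensity_trace(counts, bin_width = config$bin_width,
                           metadata = list(source = "simulated",
                                           seed = config$rng_seed))
  # expected envelope of the immobile part: n_imm * brightness * mean
  # Gaussian weight over the box, decaying as exp(-k t)
  wbar <- prod(pmin(1, config$waist * c(1, 1, config$S) *
                      sqrt(pi / 2) / config$box))
  truth <- list(
    components = config$components[, c("D", "fraction")],
    immobile_fraction = config$immobile$count /
      max(1, sum(config$components$count) + config$immobile$count),
    bleach_rate = config$immobile$bleach_rate,
    bleach_amplitude = config$immobile$count * config$brightness * wbar,
    rng_seed = config$rng_seed)
  list(trace = trace, truth = truth)
}

#' Synthesize a correlation curve from model parameters
#'
#' Evaluates the multi-component 3D-Gaussian diffusion ACF exactly on a
#' lag grid and optionally adds i.i.d. Gaussian noise, giving curves with
#' known ground truth for fitting and model-selection experiments.
#'
#' @param params Model parameters as for [acf_model()]: list with `N`,
#'   `F`, `tau`, and optionally `alpha`, `S`, `triplet_fraction`,
#'   `triplet_time`.
#' @param lags Strictly increasing positive lag grid, s.
#' @param noise_sd Per-lag additive Gaussian noise SD (scalar or
#'   vector); 0 gives the noiseless curve.
#' @param rng_seed Integer seed for the noise draw.
#' @param sigma_floor Lower bound stored in the curve's `sigma` field so
#'   weighted fits stay finite.
#' @return A [correlation_curve()].
#' @examples
#' cc <- synthesize_acf(list(N = 1, F = 1, tau = 4e-4),
#'                      lags = 10^seq(-5, 0, length.out = 50))
#' @export
synthesize_acf <- function(params, lags, noise_sd = 0, rng_seed = 1L,
                           sigma_floor = 1e-6) {
  if (any(diff(lags) <= 0) || any(lags <= 0))
    stop("'lags' must be strictly increasing and positive")
  if (any(noise_sd < 0)) stop("'noise_sd' must be >= 0")
  G <- do.call(acf_model, c(list(lags = lags), params))
  sdv <- rep_len(noise_sd, length(lags))
  if (any(sdv > 0)) {
    set.seed(rng_seed)
    G <- G + rnorm(length(lags), 0, sdv)
  }
  correlation_curve(lags = lags, G = G, sigma = pmax(sdv, sigma_floor),
                    n_segments = 1L, mean_intensity = NA_real_)
}

#' Simulate a FRAP recovery curve
#'
#' Normalized single-exponential-association recovery
#' `y(t) = offset + plateau * (1 - exp(-t log(2) / t_half))` sampled at a
#' fixed interval after the bleach, preceded by pre-bleach samples at 1,
#' with optional Gaussian noise. The plateau is
#' `mobile_fraction * (1 - offset)` so a fully mobile pool recovers to 1.
#'
#' @param t_half Recovery half-time, s (> 0).
#' @param mobile_fraction Mobile fraction in `[0, 1]`.
#' @param interval Sampling interval, s.
#' @param duration Post-bleach observation time, s.
#' @param noise_sd Gaussian noise SD on the normalized intensities.
#' @param rng_seed Integer seed.
#' @param n_prebleach Number of pre-bleach frames (>= 3).
#' @param offset Normalized intensity immediately after the bleach
#'   (bleach depth `1 - offset`).
#' @return A [frap_curve()].
#' @examples
#' fc <- simulate_frap(t_half = 20, noise_sd = 0.02, rng_seed = 3)
#' @export
simulate_frap <- function(t_half, mobile_fraction = 1, interval = 2.5,
                          duration = 180, noise_sd = 0, rng_seed = 1L,
                          n_prebleach = 3L, offset = 0.2) {
  if (t_half <= 0) stop("'t_half' must be positive")
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("'mobile_fraction' must be in [0, 1]")
  if (n_prebleach < 3L) stop("at least 3 pre-bleach samples are required")
  k <- log(2) / t_half
  t_post <- seq(0, duration, by = interval)
  plateau <- mobile_fraction * (1 - offset)
  y_post <- offset + plateau * (1 - exp(-k * t_post))
  t_pre <- -rev(seq_len(n_prebleach)) * interval
  y_pre <- rep(1, n_prebleach)
  y <- c(y_pre, y_post)
  if (noise_sd > 0) {
    set.seed(rng_seed)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  frap_curve(times = c(t_pre, t_post), intensities = y,
             n_prebleach = n_prebleach, bleach_time = -interval / 2)
}
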