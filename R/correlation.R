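#' Correlation curve container
#'
#' Normalized autocorrelation curve G(tau) of an intensity trace, with
#' the per-lag dispersion used to weight model fits.
#'
#' @param lags Strictly increasing lag times, s.
#' @param G Correlation values (G -> 1 at full decorrelation).
#' @param sigma Per-lag dispersion; strictly positive where used as fit
#'   weights.
#' @param n_segments Number of segments averaged into the curve.
#' @param mean_intensity Mean count rate of the underlying trace,
#'   counts/s.
#' @return Object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, G, sigma = rep(1, length(lags)),
                              n_segments = 1L, mean_intensity = NA_real_) {
  if (length(lags) != length(G) || length(G) != length(sigma))
    stop("'lags', 'G' and 'sigma' must have equal length")
  if (any(diff(lags) <= 0) || any(lags <= 0))
    stop("'lags' must be strictly increasing and positive")
  structure(list(lags = as.numeric(lags), G = as.numeric(G),
                 sigma = as.numeric(sigma),
                 n_segments = as.integer(n_segments),
                 mean_intensity = as.numeric(mean_intensity)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("Correlation curve:", length(x$lags), "lags from",
      format(min(x$lags), digits = 3), "to",
      format(max(x$lags), digits = 3), "s;",
      x$n_segments, "segment(s)\n")
  cat("  amplitude G(min lag) - 1 =", format(x$G[1L] - 1, digits = 4),
      "\n")
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ..., xlab = "lag (s)",
                                   ylab = expression(G(tau))) {
  plot(x$lags, x$G, log = "x", type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Multi-tau lag index table: m lags at the base resolution, then the
# upper half-octave (m/2+1 .. m) at each doubled bin.
multitau_levels <- function(n, dt, m, max_lag) {
  levels <- list()
  bin <- dt
  level <- 0L
  nn <- n
  repeat {
    ks <- if (level == 0L) seq_len(m) else (m %/% 2L + 1L):m
    ks <- ks[ks * bin <= max_lag & (nn - ks) >= 2L]
    if (length(ks))
      levels[[length(levels) + 1L]] <- list(level = level, bin = bin,
                                            ks = ks)
    if (!length(ks) || m * bin > max_lag) break
    nn <- nn %/% 2L
    if (nn < 2L * m) break
    bin <- bin * 2
    level <- level + 1L
  }
  levels
}

#' Compute the autocorrelation function of a trace
#'
#' Normalized ACF `G(tau) = <I(t) I(t+tau)> / <I>^2` on a quasi-
#' logarithmic multi-tau grid: `m` lags per octave at the trace's native
#' bin, then the upper half-octave at successively pair-averaged (factor
#' 2) resolutions up to `max_lag`. The symmetric normalization (separate
#' means over the two overlapping windows) keeps G -> 1 at long lags even
#' under slow drift. `method = "direct"` computes the same estimator at
#' every requested lag on the raw series without coarsening; it is O(n
#' * lags) and meant for validation on short traces.
#'
#' @param trace An [intensity_trace()] with non-zero mean.
#' @param m Lags per octave (default 16).
#' @param max_lag Largest lag, s (default 3.4, the upper fit bound).
#' @param method `"multitau"` or `"direct"`.
#' @return A [correlation_curve()] (`sigma` set to 1; cross-segment
#'   dispersion comes from [average_segment_acfs()]).
#' @examples
#' tr <- intensity_trace(rpois(20000, 10), bin_width = 1e-4)
#' cc <- compute_acf(tr, max_lag = 0.1)
#' @export
compute_acf <- function(trace, m = 16L, max_lag = 3.4,
                        method = c("multitau", "direct")) {
  stopifnot(inherits(trace, "intensity_trace"))
  method <- match.arg(method)
  x <- trace$counts
  if (mean(x) <= 0) stop("zero-mean trace: ACF normalization undefined")
  dur <- trace_duration(trace)
  max_lag <- min(max_lag, dur / 2)
  if (dur < 2 * max_lag) stop("trace must be at least twice the max lag")
  if (dur < 10 * max_lag)
    warning("trace duration < 10x max lag; long-lag estimates are noisy")

  if (method == "direct") {
    lv <- multitau_levels(length(x), trace$bin_width, m, max_lag)
    taus <- unlist(lapply(lv, function(l) l$ks * l$bin))
    ks <- as.integer(round(taus / trace$bin_width))
    G <- .acf_direct_kernel(as.numeric(x), ks)
  } else {
    lv <- multitau_levels(length(x), trace$bin_width, m, max_lag)
    taus <- G <- numeric(0)
    cur <- as.numeric(x)
    cur_level <- 0L
    for (l in lv) {
      while (cur_level < l$level) {
        n2 <- length(cur) %/% 2L
        cur <- (cur[seq.int(1L, 2L * n2, 2L)] +
                  cur[seq.int(2L, 2L * n2, 2L)]) / 2
        cur_level <- cur_level + 1L
      }
      G <- c(G, .acf_direct_kernel(cur, as.integer(l$ks)))
      taus <- c(taus, l$ks * l$bin)
    }
  }
  ok <- is.finite(G)
  correlation_curve(lags = taus[ok], G = G[ok],
                    sigma = rep(1, sum(ok)), n_segments = 1L,
                    mean_intensity = mean(x) / trace$bin_width)
}

#' Average per-segment ACFs with cross-segment dispersion
#'
#' Computes the ACF of each segment on the common multi-tau grid,
#' averages them per lag, and records the per-lag standard deviation
#' across segments (floored at `sigma_floor`) as the dispersion used to
#' weight model fits.
#'
#' @param segments A [segment_trace()] result (or list of equal-length
#'   [intensity_trace()]s).
#' @param m,max_lag,method Passed to [compute_acf()].
#' @param sigma_floor Lower bound on the per-lag SD.
#' @return A [correlation_curve()] with `n_segments` recorded.
#' @export
average_segment_acfs <- function(segments, m = 16L, max_lag = 3.4,
                                 method = "multitau",
                                 sigma_floor = 1e-6) {
  segs <- if (inherits(segments, "trace_segments")) segments$segments
  else segments
  if (length(segs) < 1L) stop("no segments supplied")
  curves <- lapply(segs, compute_acf, m = m, max_lag = max_lag,
                   method = method)
  lags <- curves[[1L]]$lags
  Gm <- vapply(curves, function(cc) cc$G, numeric(length(lags)))
  if (length(segs) == 1L) {
    warning("single segment: cross-segment dispersion undefined; ",
            "using constant weights")
    return(correlation_curve(lags, as.numeric(Gm),
                             sigma = rep(1, length(lags)),
                             n_segments = 1L,
                             mean_intensity = curves[[1L]]$mean_intensity))
  }
  G <- rowMeans(Gm)
  sig <- pmax(apply(Gm, 1L, sd), sigma_floor)
  correlation_curve(lags, G, sigma = sig, n_segments = length(segs),
                    mean_intensity =
                      mean(vapply(curves, `[[`, 1, "mean_intensity")))
}

#' Rescale a curve's fluctuation amplitude for overlay comparison
#'
#' Rescales `G - 1` so the amplitude at lag `at` equals
#' `reference_amplitude`. Used only to overlay curves of different
#' concentration (amplitude ~ 1/N) when comparing their shapes; never
#' used before fitting.
#'
#' @param curve A [correlation_curve()].
#' @param reference_amplitude Target amplitude at `at`.
#' @param at Lag at which the amplitude is matched (default the first
#'   lag >= 50 us, the start of the standard fit range).
#' @return The rescaled [correlation_curve()].
#' @export
normalize_amplitude <- function(curve, reference_amplitude = 1,
                                at = 50e-6) {
  stopifnot(inherits(curve, "correlation_curve"))
  i <- which(curve$lags >= at)[1L]
  if (is.na(i)) stop("'at' beyond the last lag")
  amp <- curve$G[i] - 1
  if (amp <= 0) stop("non-positive amplitude at the reference lag")
  if (reference_amplitude <= 0) stop("'reference_amplitude' must be > 0")
  s <- reference_amplitude / amp
  correlation_curve(curve$lags, 1 + (curve$G - 1) * s,
                    sigma = curve$sigma * s,
                    n_segments = curve$n_segments,
                    mean_intensity = curve$mean_intensity)
}
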