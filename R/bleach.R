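#' Fit the photobleaching envelope of a trace
#'
#' Stably bound molecules bleach irreversibly at the start of a
#' measurement, producing an exponential decay of the mean intensity.
#' The trace is re-binned to `rebin` seconds (the decay lives on the
#' 0.1-s scale, not on the microsecond shot-noise scale) and the binned
#' intensity is fit by least squares to `y = A exp(-t k) + y0`.
#'
#' A trace is flagged as bleaching when all three hold: the bleached
#' fraction `A / (A + y0)` exceeds `min_fraction`; the decay time `1/k`
#' is shorter than the trace; and the exponential reduces the residual
#' norm by at least `min_improvement` relative to a constant fit. The
#' criterion is scale-free, so it behaves identically for bright and dim
#' cells.
#'
#' @param trace An [intensity_trace()] with at least 100 bins.
#' @param rebin Coarse bin width for the envelope fit, s.
#' @param min_fraction,min_improvement Flag thresholds (see above).
#' @return List of class `bleach_fit`: `A`, `k`, `y0` (counts per coarse
#'   bin and 1/s), `bleach_flag`, `residual_norm` (RMS residual / mean),
#'   `converged`, `rebin`.
#' @examples
#' tr <- intensity_trace(rpois(2000, 50), bin_width = 0.01)
#' fit_photobleach(tr, rebin = 0.1)$bleach_flag
#' @export
fit_photobleach <- function(trace, rebin = 0.1, min_fraction = 0.05,
                            min_improvement = 0.20) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (length(trace$counts) < 100L) stop("trace must have >= 100 bins")
  coarse <- if (trace$bin_width < rebin) rebin_trace(trace, rebin) else trace
  t <- trace_times(coarse) - coarse$start_time
  y <- coarse$counts
  dur <- trace_duration(coarse)

  y0_0 <- mean(y[t > 0.8 * dur])
  A_0 <- max(mean(y[t < 0.1 * dur]) - y0_0, mean(y) * 0.01, 1e-9)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t * k) + y0,
                      start = list(A = A_0, k = 3 / dur, y0 = max(y0_0, 0)),
                      lower = c(A = 0, k = 0, y0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  rss_const <- sum((y - mean(y))^2)
  if (is.null(fit)) {
    warning("photobleach fit did not converge; returning constant fit")
    out <- list(A = 0, k = 0, y0 = mean(y), bleach_flag = FALSE,
                residual_norm = sqrt(rss_const / length(y)) / mean(y),
                converged = FALSE, rebin = coarse$bin_width)
    class(out) <- "bleach_fit"
    return(out)
  }
  p <- coef(fit)
  rss <- sum(residuals(fit)^2)
  improvement <- if (rss_const > 0) 1 - sqrt(rss / rss_const) else 0
  flag <- isTRUE(p[["A"]] / (p[["A"]] + p[["y0"]]) > min_fraction &&
                   p[["k"]] > 0 && 1 / p[["k"]] < trace_duration(trace) &&
                   improvement >= min_improvement)
  out <- list(A = unname(p[["A"]]), k = unname(p[["k"]]),
              y0 = unname(p[["y0"]]), bleach_flag = flag,
              residual_norm = sqrt(rss / length(y)) / mean(y),
              converged = TRUE, rebin = coarse$bin_width)
  class(out) <- "bleach_fit"
  out
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat("Photobleach fit: A =", format(x$A, digits = 4),
      " k =", format(x$k, digits = 4), "/s",
      " y0 =", format(x$y0, digits = 4), "\n")
  cat("  bleaching:", if (x$bleach_flag) "detected" else "not detected",
      " (residual norm", format(x$residual_norm, digits = 3), ")\n")
  invisible(x)
}

#' Remove the initial photobleaching window from a trace
#'
#' Drops the first `window` seconds of a trace (20 s for silk-gland
#' cells, 10 s for HeLa cells by convention) so the bleaching transient
#' does not distort the correlation analysis.
#'
#' @param trace An [intensity_trace()].
#' @param window Seconds to excise from the start (< trace duration).
#' @return The shortened [intensity_trace()] with `start_time` shifted.
#' @examples
#' tr <- intensity_trace(rpois(6000, 5), bin_width = 0.01)
#' excise_bleach_window(tr, window = 20)
#' @export
excise_bleach_window <- function(trace, window) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (window < 0) stop("'window' must be >= 0")
  if (window >= trace_duration(trace))
    stop("'window' must be shorter than the trace")
  if (window == 0) return(trace)
  n_drop <- as.integer(round(window / trace$bin_width))
  intensity_trace(trace$counts[-seq_len(n_drop)],
                  bin_width = trace$bin_width,
                  start_time = trace$start_time + n_drop * trace$bin_width,
                  metadata = trace$metadata)
}

#' Split a trace into equal consecutive segments
#'
#' Measurements are recorded as consecutive fixed-length segments (six
#' 10-s records for a 60-s measurement); per-segment ACFs provide the
#' cross-segment dispersion used as fit weights. A trailing remainder
#' shorter than one segment is discarded.
#'
#' @param trace An [intensity_trace()].
#' @param segment_length Segment length, s (> 0, <= duration).
#' @return List of class `trace_segments`: `segments` (list of
#'   [intensity_trace()]), `excised_prefix` (the trace's start time, s),
#'   `discarded` (trailing seconds dropped).
#' @examples
#' tr <- intensity_trace(rpois(6000, 5), bin_width = 0.01)
#' length(segment_trace(tr, 10)$segments)  # 6
#' @export
segment_trace <- function(trace, segment_length) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (segment_length <= 0) stop("'segment_length' must be positive")
  dur <- trace_duration(trace)
  if (dur < segment_length) stop("trace shorter than one segment")
  bins_per_seg <- as.integer(round(segment_length / trace$bin_width))
  n_seg <- floor(length(trace$counts) / bins_per_seg)
  discarded <- dur - n_seg * bins_per_seg * trace$bin_width
  if (discarded > trace$bin_width / 2)
    message("segment_trace: discarding trailing ",
            format(discarded, digits = 3), " s")
  segments <- lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1L) * bins_per_seg + 1L):(i * bins_per_seg)
    intensity_trace(trace$counts[idx], bin_width = trace$bin_width,
                    start_time = trace$start_time +
                      (i - 1L) * bins_per_seg * trace$bin_width,
                    metadata = trace$metadata)
  })
  structure(list(segments = segments,
                 excised_prefix = trace$start_time,
                 discarded = discarded),
            class = "trace_segments")
}

#' @export
print.trace_segments <- function(x, ...) {
  cat("Trace segments:", length(x$segments), "of",
      format(trace_duration(x$segments[[1L]]), digits = 4), "s each\n")
  invisible(x)
}
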