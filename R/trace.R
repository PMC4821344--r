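#' Binned fluorescence intensity trace
#'
#' Container for a time-binned photon-count record, the raw observable of
#' an FCS measurement: photon counts per bin of width `bin_width`,
#' starting at `start_time`.
#'
#' @param counts Non-negative photon counts per bin.
#' @param bin_width Bin width in seconds (> 0).
#' @param start_time Acquisition start of the first bin, seconds.
#' @param metadata Optional named list (cell context, laser setting,
#'   `source = "simulated"` or `"file"`, ...).
#' @return An object of class `intensity_trace` with elements `counts`,
#'   `bin_width`, `start_time`, `metadata`.
#' @examples
#' tr <- intensity_trace(rpois(1000, 5), bin_width = 1e-3)
#' trace_duration(tr)
#' @export
intensity_trace <- function(counts, bin_width, start_time = 0,
                            metadata = list()) {
  if (!is.numeric(counts) || length(counts) < 1L)
    stop("'counts' must be a non-empty numeric vector")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and non-negative")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a single positive number")
  structure(list(counts = as.numeric(counts),
                 bin_width = as.numeric(bin_width),
                 start_time = as.numeric(start_time),
                 metadata = metadata),
            class = "intensity_trace")
}

#' @rdname intensity_trace
#' @param x,trace An `intensity_trace`.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  length(trace$counts) * trace$bin_width
}

#' Bin times of a trace
#'
#' Centre time of each bin, in seconds.
#' @param trace An [intensity_trace()].
#' @return Numeric vector of bin-centre times.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  trace$start_time + (seq_along(trace$counts) - 0.5) * trace$bin_width
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat("Intensity trace:", length(x$counts), "bins of",
      format(x$bin_width, digits = 4), "s (",
      format(trace_duration(x), digits = 4), "s total )\n")
  cat("  mean rate:",
      format(mean(x$counts) / x$bin_width, digits = 5), "counts/s\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, function(v)
                               paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Re-bin a trace to a coarser bin width
#'
#' Sums counts over consecutive groups of bins. The target width must be
#' an (approximate) integer multiple of the native width; a trailing
#' partial group is discarded.
#'
#' @param trace An [intensity_trace()].
#' @param bin_width Target bin width in seconds.
#' @return A coarser [intensity_trace()].
#' @export
rebin_trace <- function(trace, bin_width) {
  stopifnot(inherits(trace, "intensity_trace"))
  f <- bin_width / trace$bin_width
  if (f < 1 - 1e-9) stop("target bin width is finer than the trace's")
  f <- as.integer(round(f))
  n <- floor(length(trace$counts) / f)
  if (n < 1L) stop("trace shorter than one target bin")
  idx <- rep(seq_len(n), each = f)
  counts <- as.numeric(tapply(trace$counts[seq_len(n * f)], idx, sum))
  intensity_trace(counts, bin_width = f * trace$bin_width,
                  start_time = trace$start_time, metadata = trace$metadata)
}
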