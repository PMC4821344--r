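#' Analysis run configuration
#'
#' Bundles the per-cell-type processing conventions: the photobleach
#' excision window (20 s for silk-gland cells, 10 s for HeLa cells),
#' the segment length, the correlator settings and the candidate model
#' specs.
#'
#' @param preset `"psg"`, `"hela"` or `"custom"`.
#' @param excision_window Seconds excised when bleaching is detected
#'   (preset: psg 20, hela 10).
#' @param segment_length Segment length, s.
#' @param m,max_lag Correlator settings (see [compute_acf()]).
#' @param candidates Candidate component counts (or list of
#'   [fcs_model_spec()]).
#' @param rng_seed Integer seed used by fitting and selection.
#' @return List of class `run_config`.
#' @export
run_config <- function(preset = c("psg", "hela", "custom"),
                       excision_window = NULL, segment_length = 10,
                       m = 16L, max_lag = 3.4, candidates = 1:3,
                       rng_seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(excision_window))
    excision_window <- switch(preset, psg = 20, hela = 10,
                              custom = stop("custom preset requires an",
                                            " explicit excision_window"))
  structure(list(preset = preset, excision_window = excision_window,
                 segment_length = segment_length, m = as.integer(m),
                 max_lag = max_lag, candidates = candidates,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read an intensity trace from a delimited text file
#'
#' Two formats: `"delimited"` expects two columns (time_s, counts) after
#' an optional `# key = value` header block (keys `bin_width`, `seed`,
#' ... are kept as metadata); `"photon_timestamps"` expects one column
#' of monotone arrival times (s) which are binned at `bin_width`
#' (right-closed bins, so a photon at exactly t = k*bin falls in bin k).
#'
#' @param path File path.
#' @param format `"delimited"` or `"photon_timestamps"`.
#' @param bin_width Bin width for timestamp binning, s (default 0.2 us);
#'   for delimited files it must match the header/time column if given.
#' @return An [intensity_trace()].
#' @export
read_trace <- function(path, format = c("delimited",
                                        "photon_timestamps"),
                       bin_width = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    parts <- strsplit(kv, "=")[[1L]]
    if (length(parts) == 2L) {
      key <- trimws(parts[1L]); val <- trimws(parts[2L])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)

  if (format == "photon_timestamps") {
    ts <- as.numeric(body)
    if (any(is.na(ts))) stop("non-numeric timestamp at line ",
                             which(is.na(ts))[1L])
    if (any(diff(ts) < 0)) stop("non-monotone timestamps at line ",
                                which(diff(ts) < 0)[1L] + 1L)
    bw <- if (!is.null(bin_width)) bin_width else
      if (!is.null(meta$bin_width)) meta$bin_width else 0.2e-6
    n <- ceiling(max(ts) / bw)
    counts <- tabulate(pmax(1L, as.integer(ceiling(ts / bw))), nbins = n)
    return(intensity_trace(counts, bin_width = bw,
                           metadata = c(meta, source = "file")))
  }

  fields <- strsplit(trimws(body), "[,\t ]+")
  ncol <- lengths(fields)
  if (any(ncol != 2L))
    stop("ragged row at line ", which(ncol != 2L)[1L])
  tm <- as.numeric(vapply(fields, `[`, "", 1L))
  counts <- as.numeric(vapply(fields, `[`, "", 2L))
  if (any(is.na(tm)) || any(is.na(counts)))
    stop("non-numeric value at line ",
         which(is.na(tm) | is.na(counts))[1L])
  bw_col <- if (length(tm) > 1L) stats::median(diff(tm)) else NULL
  bw_file <- if (!is.null(meta$bin_width)) meta$bin_width else bw_col
  if (is.null(bw_file)) stop("cannot determine the bin width")
  if (!is.null(bw_col) && abs(bw_file - bw_col) > 1e-6 * bw_file)
    stop("header bin_width disagrees with the time column")
  if (!is.null(bin_width) && abs(bin_width - bw_file) > 1e-6 * bw_file)
    stop("requested bin_width disagrees with the file")
  intensity_trace(counts, bin_width = bw_file,
                  start_time = tm[1L] - bw_file / 2,
                  metadata = c(meta, source = "file"))
}

#' Write an intensity trace as delimited text
#'
#' Two columns (bin-centre time_s, counts) after a `# key = value`
#' header carrying the bin width and any scalar metadata; full precision
#' so a write/read round-trip is exact.
#'
#' @param trace An [intensity_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  hdr <- c(sprintf("# bin_width = %.17g", trace$bin_width),
           sprintf("# start_time = %.17g", trace$start_time))
  for (nm in names(trace$metadata)) {
    v <- trace$metadata[[nm]]
    if (length(v) == 1L && (is.numeric(v) || is.character(v)))
      hdr <- c(hdr, sprintf("# %s = %s", nm,
                            if (is.numeric(v)) sprintf("%.17g", v)
                            else as.character(v)))
  }
  rows <- sprintf("%.17g\t%.17g", trace_times(trace), trace$counts)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write / read a correlation curve as delimited text
#'
#' Three columns (lag_s, G, sigma) after a header recording
#' `n_segments` and `mean_intensity`; full precision round-trip.
#'
#' @param curve A [correlation_curve()].
#' @param path File path.
#' @return `write_curve`: `path` invisibly; `read_curve`: a
#'   [correlation_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  hdr <- c(sprintf("# n_segments = %d", curve$n_segments),
           sprintf("# mean_intensity = %.17g", curve$mean_intensity))
  rows <- sprintf("%.17g\t%.17g\t%.17g", curve$lags, curve$G,
                  curve$sigma)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list(n_segments = 1L, mean_intensity = NA_real_)
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", lines[h]), "=")[[1L]]
    if (length(parts) == 2L)
      meta[[trimws(parts[1L])]] <-
        suppressWarnings(as.numeric(trimws(parts[2L])))
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  m <- do.call(rbind, strsplit(trimws(body), "[\t ]+"))
  correlation_curve(lags = as.numeric(m[, 1L]),
                    G = as.numeric(m[, 2L]),
                    sigma = as.numeric(m[, 3L]),
                    n_segments = as.integer(meta$n_segments),
                    mean_intensity = meta$mean_intensity)
}

#' Summarize a set of analyzed cells into a report table
#'
#' Builds the per-construct summary conventional for FCS studies: per
#' construct label, the number of cells, mean +/- SD of each fitted
#' fraction (%) and diffusion time, and the bleach incidence. Written as
#' a tab-delimited file plus a per-cell detail file when `path` is
#' given.
#'
#' @param results List of per-cell results: each a list with `label`
#'   (construct), `fit` (an `fcs_fit`), and optionally `bleach`
#'   (a `bleach_fit`) and `rationale` (from [select_model()]).
#' @param path Optional output path prefix; writes `<path>_summary.tsv`
#'   and `<path>_cells.tsv`.
#' @return The summary `data.frame`, invisibly when writing.
#' @export
write_report <- function(results, path = NULL) {
  if (!length(results)) stop("no results to report")
  labels <- vapply(results, function(r) r$label, "")
  rows <- lapply(unique(labels), function(lb) {
    rs <- results[labels == lb]
    fits <- lapply(rs, `[[`, "fit")
    Ms <- vapply(fits, function(f) f$spec$M, 0L)
    M <- max(Ms)
    Fm <- matrix(NA_real_, length(fits), 3L)
    Tm <- matrix(NA_real_, length(fits), 3L)
    for (i in seq_along(fits)) {
      Fm[i, seq_len(Ms[i])] <- fits[[i]]$params$F
      Tm[i, seq_len(Ms[i])] <- fits[[i]]$params$tau
    }
    bleach <- vapply(rs, function(r)
      if (!is.null(r$bleach)) r$bleach$bleach_flag else NA, TRUE)
    row <- data.frame(construct = lb, n = length(fits), M = M)
    for (j in 1:3) {
      row[[paste0("F", j, "_pct_mean")]] <- 100 * mean(Fm[, j])
      row[[paste0("F", j, "_pct_sd")]] <- 100 * sd(Fm[, j])
      row[[paste0("tau", j, "_mean")]] <- mean(Tm[, j])
      row[[paste0("tau", j, "_sd")]] <- sd(Tm[, j])
    }
    row$bleach <- if (all(is.na(bleach))) NA_character_ else
      if (mean(bleach, na.rm = TRUE) >= 0.5) "+" else "-"
    row
  })
  summary <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(summary, paste0(path, "_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    detail <- do.call(rbind, lapply(seq_along(results), function(i) {
      r <- results[[i]]
      f <- r$fit
      data.frame(cell = i, construct = r$label, M = f$spec$M,
                 N = f$params$N,
                 F = paste(signif(f$params$F, 6), collapse = ";"),
                 tau = paste(signif(f$params$tau, 6), collapse = ";"),
                 chi2 = f$chi2, dof = f$dof,
                 bleach = if (!is.null(r$bleach))
                   r$bleach$bleach_flag else NA,
                 rationale = if (!is.null(r$rationale))
                   paste(r$rationale, collapse = "|") else "")
    }))
    utils::write.table(detail, paste0(path, "_cells.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(invisible(summary))
  }
  summary
}

#' Run the full FCS analysis pipeline on one trace
#'
#' Photobleach detection, conditional excision of the preset bleach
#' window, segmentation, per-segment ACF averaging, candidate-model
#' fitting and model-count adjudication, and derived quantities:
#' the end-to-end path from a raw trace to diffusion parameters.
#'
#' @param trace An [intensity_trace()].
#' @param config A [run_config()].
#' @param calibration Optional [calibrate_waist()] result (or waist,
#'   um) for derived quantities.
#' @param tau_egfp Optional EGFP reference diffusion time, s.
#' @param label Construct label carried into reports.
#' @return List with `bleach`, `curve`, `comparison`, `fit` (the
#'   selected fit), `derived` (if calibration given), `label`.
#' @export
run_pipeline <- function(trace, config = run_config("psg"),
                         calibration = NULL, tau_egfp = NULL,
                         label = "sample") {
  stopifnot(inherits(trace, "intensity_trace"),
            inherits(config, "run_config"))
  bleach <- fit_photobleach(trace)
  work <- if (bleach$bleach_flag &&
                config$excision_window < trace_duration(trace))
    excise_bleach_window(trace, config$excision_window) else trace
  segs <- segment_trace(work, config$segment_length)
  curve <- average_segment_acfs(segs, m = config$m,
                                max_lag = config$max_lag)
  comparison <- select_model(curve, config$candidates,
                             rng_seed = config$rng_seed)
  fit <- comparison$selected_fit
  derived <- if (!is.null(calibration) && !is.null(tau_egfp))
    derived_params(fit, calibration, tau_egfp) else NULL
  list(bleach = bleach, curve = curve, comparison = comparison,
       fit = fit, derived = derived, label = label,
       rationale = comparison$rationale)
}
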