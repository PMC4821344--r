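#' Reference diffusion coefficient of rhodamine 6G
#'
#' Default reference used to calibrate the beam waist from a measured
#' R6G diffusion time (488 nm excitation). Literature values for R6G in
#' water at room temperature range roughly 280-440 um^2/s depending on
#' temperature convention; this default follows the 414 um^2/s (25 C)
#' convention and must be confirmed against the calibration actually
#' used on the instrument.
#' @export
R6G_DIFFUSION_COEFF <- 414

#' Calibrate the lateral beam waist from a reference dye
#'
#' `omega = sqrt(4 D_ref tau_ref)`: the lateral 1/e^2 radius that makes
#' the reference dye's fitted diffusion time consistent with its known
#' diffusion coefficient.
#'
#' @param tau_ref Fitted diffusion time of the reference dye, s.
#' @param D_ref Known diffusion coefficient of the reference, um^2/s.
#' @param reference Label of the reference dye.
#' @return Object of class `fcs_calibration` with `omega` (um),
#'   `D_ref`, `tau_ref`, `reference`.
#' @examples
#' calibrate_waist(400e-6, 25)$omega   # 0.2 um
#' @export
calibrate_waist <- function(tau_ref, D_ref = R6G_DIFFUSION_COEFF,
                            reference = "R6G") {
  if (tau_ref <= 0 || D_ref <= 0)
    stop("'tau_ref' and 'D_ref' must be positive")
  structure(list(omega = sqrt(4 * D_ref * tau_ref), D_ref = D_ref,
                 tau_ref = tau_ref, reference = reference),
            class = "fcs_calibration")
}

#' @export
print.fcs_calibration <- function(x, ...) {
  cat("Waist calibration (", x$reference, "): omega =",
      format(x$omega, digits = 4), "um  ( D_ref =",
      format(x$D_ref, digits = 4), "um^2/s, tau_ref =",
      format(x$tau_ref, digits = 4), "s )\n")
  invisible(x)
}

#' Diffusion coefficient from a diffusion time
#'
#' `D = omega^2 / (4 tau)`.
#'
#' @param tau Diffusion time(s), s.
#' @param calibration An [calibrate_waist()] result, or a numeric
#'   lateral waist in um.
#' @return Diffusion coefficient(s), um^2/s.
#' @examples
#' diffusion_coefficient(3.28e-3, 0.218)   # ~3.62 um^2/s
#' @export
diffusion_coefficient <- function(tau, calibration) {
  if (any(tau <= 0)) stop("'tau' must be positive")
  omega <- if (inherits(calibration, "fcs_calibration"))
    calibration$omega else calibration
  if (!is.numeric(omega) || omega <= 0) stop("invalid calibration")
  omega^2 / (4 * tau)
}

#' Apparent molecular mass from a diffusion time
#'
#' Stokes-Einstein scaling for a spherical diffuser measured against
#' EGFP (27 kDa) under identical conditions:
#' `Mw = 27 (tau / tau_EGFP)^3` kDa. An order-of-magnitude estimator:
#' a species diffusing like a sphere twice as slow is 8x as massive.
#'
#' @param tau Diffusion time(s) of the species, s.
#' @param tau_egfp Diffusion time of EGFP alone, s.
#' @return Apparent mass(es), kDa (unrounded; see [signif()] for the
#'   2-significant-figure reporting convention).
#' @examples
#' signif(apparent_mass(343.2e-6, 266.7e-6), 2)   # 58 kDa
#' @export
apparent_mass <- function(tau, tau_egfp) {
  if (any(tau <= 0) || tau_egfp <= 0)
    stop("'tau' and 'tau_egfp' must be positive")
  27 * (tau / tau_egfp)^3
}

#' Derived physical quantities of a fitted diffusion model
#'
#' Converts each fitted diffusion time into a diffusion coefficient and
#' an apparent molecular mass, and forms mass ratios against a reference
#' monomer mass. Masses and ratios are reported both unrounded and at 2
#' significant figures (ratios of rounded masses at 2 s.f. as well),
#' since order-of-magnitude statements conventionally use the rounded
#' values.
#'
#' @param fit An `fcs_fit`, or a numeric vector of diffusion times (s).
#' @param calibration [calibrate_waist()] result or numeric waist, um.
#' @param tau_egfp Diffusion time of EGFP alone, s.
#' @param monomer_mass Reference monomer mass, kDa (default 51.2, an
#'   EGFP-tagged ~24 kDa protein).
#' @return `data.frame` with one row per component: `tau`, `D`, `mass`,
#'   `mass_2sf`, `mass_ratio` (unrounded mass / monomer),
#'   `mass_ratio_2sf` (rounded mass / monomer, 2 s.f.).
#' @examples
#' derived_params(c(343.2e-6, 3.28e-3, 98.2e-3), 0.218, 266.7e-6)
#' @export
derived_params <- function(fit, calibration, tau_egfp,
                           monomer_mass = 51.2) {
  tau <- if (inherits(fit, "fcs_fit")) fit$params$tau else as.numeric(fit)
  D <- diffusion_coefficient(tau, calibration)
  mass <- apparent_mass(tau, tau_egfp)
  data.frame(component = seq_along(tau), tau = tau, D = D,
             mass = mass, mass_2sf = signif(mass, 2),
             mass_ratio = mass / monomer_mass,
             mass_ratio_2sf = signif(signif(mass, 2) / monomer_mass, 2))
}

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Expected genomic spacing of an IUPAC consensus motif
#'
#' Expected distance between successive occurrences of a degenerate
#' motif on a single strand, assuming independent bases: the reciprocal
#' of the product of per-position match probabilities. Under uniform
#' composition the 9-bp motif `ATNTWTNTA` (7 constrained positions, one
#' 2-fold degenerate) recurs every `4^6 * 2 = 8192` bp.
#'
#' @param motif Character string of IUPAC codes.
#' @param base_frequencies Named base probabilities summing to 1
#'   (default uniform).
#' @return Expected spacing in bp.
#' @examples
#' motif_expected_spacing("ATNTWTNTA")   # 8192
#' @export
motif_expected_spacing <- function(motif,
                                   base_frequencies = c(A = 0.25,
                                                        C = 0.25,
                                                        G = 0.25,
                                                        T = 0.25)) {
  if (!all(c("A", "C", "G", "T") %in% names(base_frequencies)) ||
      abs(sum(base_frequencies) - 1) > 1e-9)
    stop("'base_frequencies' must be named A,C,G,T and sum to 1")
  chars <- strsplit(toupper(motif), "")[[1L]]
  if (!length(chars)) stop("empty motif")
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad)) stop("invalid IUPAC code(s): ",
                        paste(bad, collapse = ", "))
  p <- vapply(chars, function(ch)
    sum(base_frequencies[IUPAC_CODES[[ch]]]), 0)
  1 / prod(p)
}
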