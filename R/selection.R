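#' Corrected Akaike information criterion for a chi-square fit
#'
#' `AICc = N ln(chi2 / N) + 2K + 2K(K+1)/(N - K - 1)`: the least-squares
#' AIC with the small-sample correction. Comparable across candidate
#' models fitted to the same curve with the same weights (the `N ln`
#' term ties absolute values to the weighting scale).
#'
#' @param chi2 Weighted chi-square of the fit (or an `fcs_fit`).
#' @param n_points Number of fitted data points.
#' @param K Number of free parameters.
#' @return The AICc value.
#' @examples
#' aicc(50, 100, 5)    # -58.68
#' @export
aicc <- function(chi2, n_points, K) {
  if (inherits(chi2, "fcs_fit")) {
    f <- chi2
    chi2 <- f$chi2; n_points <- f$n_points; K <- f$K
  }
  if (n_points <= K + 1) stop("need n_points > K + 1")
  if (chi2 <= 0) stop("'chi2' must be positive")
  n_points * log(chi2 / n_points) + 2 * K +
    2 * K * (K + 1) / (n_points - K - 1)
}

#' F-test between nested chi-square fits
#'
#' Tests whether the more complex of two nested fits improves the
#' weighted chi-square more than expected by chance:
#' `F = ((chi2_1 - chi2_2) / (DF1 - DF2)) / (chi2_2 / DF2)` with
#' `DF = n_points - K - 1`, and p the upper tail of the F distribution
#' with `(DF1 - DF2, DF2)` degrees of freedom. If the complex model fits
#' worse, F is clipped at 0 and p = 1.
#'
#' @param simple,complex `fcs_fit` objects (or lists with `chi2` and
#'   `dof`), simple first.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @examples
#' f_test(list(chi2 = 120, dof = 97), list(chi2 = 100, dof = 95))
#' @export
f_test <- function(simple, complex) {
  c1 <- simple$chi2; d1 <- simple$dof
  c2 <- complex$chi2; d2 <- complex$dof
  if (is.null(c1) || is.null(c2) || is.null(d1) || is.null(d2))
    stop("inputs must carry 'chi2' and 'dof'")
  if (d1 <= d2) stop("models not nested: simple must have more dof")
  if (c2 <= 0) stop("complex chi2 must be positive")
  Fv <- ((c1 - c2) / (d1 - d2)) / (c2 / d2)
  if (Fv < 0) Fv <- 0
  list(F = Fv, p = pf(Fv, d1 - d2, d2, lower.tail = FALSE),
       df1 = d1 - d2, df2 = d2)
}

#' Parameter-dispersion screen across replicate fits
#'
#' Computes the coefficient of variation (SD / mean) of every fitted
#' parameter across replicate curves fitted with the same model. A
#' candidate whose parameters scatter wildly across cells is not a
#' usable description even if it fits each curve: the model is flagged
#' unstable when any CV exceeds `threshold` (default 200%).
#'
#' @param replicate_fits List of >= 3 `fcs_fit` objects sharing a spec
#'   (or of named parameter vectors).
#' @param threshold CV above which the model is flagged unstable
#'   (fractional; 2 = 200%).
#' @return List with `cv` (named per-parameter CVs), `max_cv`,
#'   `unstable`.
#' @export
screen_dispersion <- function(replicate_fits, threshold = 2) {
  if (length(replicate_fits) < 3L) {
    warning("fewer than 3 replicates: dispersion screen skipped")
    return(list(cv = NULL, max_cv = NA_real_, unstable = FALSE,
                skipped = TRUE))
  }
  mats <- vapply(replicate_fits, function(f)
    if (inherits(f, "fcs_fit")) coef(f) else as.numeric(f),
    numeric(length(if (inherits(replicate_fits[[1L]], "fcs_fit"))
      coef(replicate_fits[[1L]]) else replicate_fits[[1L]])))
  if (is.null(dim(mats))) mats <- matrix(mats, nrow = 1L)
  cv <- apply(mats, 1L, function(v) {
    m <- mean(v)
    if (m == 0) 0 else sd(v) / abs(m)
  })
  cv <- cv[is.finite(cv)]
  list(cv = cv, max_cv = max(cv), unstable = any(cv > threshold),
      skipped = FALSE)
}

# warm starts for a (M+1)-component spec from a fitted M-component
# model: insert a low-amplitude component below, between and above the
# fitted diffusion times, so nested fits always reach at least the
# simpler model's chi-square
nested_warm_starts <- function(fit, spec) {
  if (spec$M != fit$spec$M + 1L) return(NULL)
  p <- fit$params
  cand_tau <- unique(pmin(pmax(c(min(p$tau) / 8, max(p$tau) * 8,
                                 exp(mean(log(range(p$tau)))) *
                                   c(1, 20)),
                               TAU_LO * 2), TAU_HI / 2))
  lapply(cand_tau, function(tn) {
    tau_all <- c(p$tau, tn * 1.000001)
    o <- order(tau_all)
    F <- c(p$F * 0.95, 0.05)[o]
    list(N = p$N, F = F / sum(F), tau = tau_all[o])
  })
}

# unphysical-parameter screen for one fit: negligible-amplitude
# components or diffusion times pinned at the optimizer bounds
unphysical_codes <- function(fit, min_fraction = 0.01,
                             bound_tol = 1.10) {
  codes <- character(0)
  p <- fit$params
  if (!fit$converged) codes <- c(codes, "not_converged")
  if (any(p$F < min_fraction)) codes <- c(codes, "negligible_fraction")
  if (any(p$tau < TAU_LO * bound_tol) || any(p$tau > TAU_HI / bound_tol))
    codes <- c(codes, "tau_at_bound")
  codes
}

#' Adjudicate the number of diffusion components
#'
#' Fits every candidate model to the curve and selects the component
#' count the way FCS practice demands: candidates with unphysical
#' parameters (non-convergence, a component below 1% amplitude whose
#' diffusion time is unconstrained, a diffusion time pinned at the
#' bounds) are rejected; with >= 3 replicate curves the
#' parameter-dispersion screen (CV > 200%) also rejects; among the
#' survivors, complexity must be earned through the nested F-test
#' (p < 0.05 to accept the more complex model) and confirmed by the AICc
#' ranking. When AICc and the F-test disagree the simpler model wins and
#' a rationale code records the disagreement.
#'
#' @param curve A [correlation_curve()] (typically a segment-averaged
#'   one).
#' @param specs List of nested candidate [fcs_model_spec()]s (or integer
#'   vector of component counts), simplest first.
#' @param replicates Optional list of replicate curves for the
#'   dispersion screen.
#' @param alpha_level F-test acceptance threshold (default 0.05).
#' @param starts,rng_seed Passed to [fcs_fit()].
#' @return Object of class `fcs_model_comparison`: `fits`, `aicc`,
#'   `f_tests`, `dispersion`, `selected` (index into `specs`),
#'   `selected_fit`, `rationale` (codes explaining the decision).
#' @examples
#' cc <- synthesize_acf(list(N = 1, F = 1, tau = 4e-4),
#'                      lags = 10^seq(-4.3, 0.53, length.out = 120),
#'                      noise_sd = 0.005, rng_seed = 2)
#' sel <- select_model(cc, 1:2, starts = 4)
#' sel$selected
#' @export
select_model <- function(curve, specs = 1:3, replicates = NULL,
                         alpha_level = 0.05, starts = 8L, rng_seed = 1L) {
  if (!is.list(specs)) specs <- lapply(specs, fcs_model_spec)
  if (length(specs) < 2L) stop("need >= 2 nested candidates")
  nspec <- length(specs)
  fits <- vector("list", nspec)
  for (i in seq_len(nspec)) {
    warm <- if (i > 1L && !is.null(fits[[i - 1L]]))
      nested_warm_starts(fits[[i - 1L]], specs[[i]]) else NULL
    fits[i] <- list(tryCatch(
      fcs_fit(curve, specs[[i]], starts = starts, rng_seed = rng_seed,
              start = warm),
      error = function(e) NULL))
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("no candidate could be fitted")
  aiccs <- rep(NA_real_, nspec)
  aiccs[ok] <- vapply(fits[ok], aicc, 0)

  phys <- vector("list", nspec)
  for (i in seq_len(nspec))
    phys[[i]] <- if (ok[i]) unphysical_codes(fits[[i]]) else "fit_failed"

  disp <- vector("list", nspec)
  if (!is.null(replicates) && length(replicates) >= 3L) {
    for (i in seq_len(nspec)) {
      rf <- lapply(replicates, function(rc)
        tryCatch(fcs_fit(rc, specs[[i]], starts = starts,
                         rng_seed = rng_seed), error = function(e) NULL))
      rf <- rf[!vapply(rf, is.null, TRUE)]
      disp[[i]] <- if (length(rf) >= 3L) screen_dispersion(rf) else
        list(cv = NULL, max_cv = NA_real_, unstable = FALSE,
             skipped = TRUE)
    }
  }

  eligible <- vapply(seq_len(nspec), function(i)
    ok[i] && length(phys[[i]]) == 0L &&
      !(length(disp) >= i && !is.null(disp[[i]]) &&
          isTRUE(disp[[i]]$unstable)), TRUE)

  rationale <- character(0)
  if (!any(eligible)) {
    eligible[which(ok)[1L]] <- TRUE
    rationale <- c(rationale, "all_candidates_unstable")
  }

  # stepwise F-test from the simplest eligible candidate upward
  ftests <- list()
  sel <- which(eligible)[1L]
  for (j in seq_len(nspec)[-seq_len(sel)]) {
    if (!ok[j]) next
    ft <- f_test(fits[[sel]], fits[[j]])
    ftests[[length(ftests) + 1L]] <-
      c(list(simple = sel, complex = j), ft)
    if (eligible[j] && ft$p < alpha_level) sel <- j
  }

  best_aicc <- which.min(replace(aiccs, !eligible, Inf))
  if (length(best_aicc) && best_aicc != sel) {
    if (aiccs[best_aicc] < aiccs[sel] && best_aicc > sel) {
      rationale <- c(rationale, "aicc_prefers_complex_ftest_simpler")
      warning("AICc favours candidate ", best_aicc,
              " but the F-test does not; keeping the simpler model")
    } else if (best_aicc < sel) {
      # F-test accepted complexity that AICc does not support: keep the
      # simpler model (conservative joint use of both criteria)
      rationale <- c(rationale, "ftest_prefers_complex_aicc_simpler")
      sel <- best_aicc
    }
  }
  for (i in seq_len(nspec)) {
    if (length(phys[[i]]))
      rationale <- c(rationale, paste0("candidate", i, ":",
                                       paste(phys[[i]], collapse = "+")))
    if (length(disp) >= i && !is.null(disp[[i]]) &&
        isTRUE(disp[[i]]$unstable))
      rationale <- c(rationale, paste0("candidate", i,
                                       ":dispersion_unstable"))
  }

  structure(list(fits = fits, aicc = aiccs, f_tests = ftests,
                 dispersion = disp, selected = sel,
                 selected_fit = fits[[sel]], rationale = rationale),
            class = "fcs_model_comparison")
}

#' @export
print.fcs_model_comparison <- function(x, ...) {
  cat("Model comparison over", length(x$fits), "candidates\n")
  for (i in seq_along(x$fits)) {
    if (is.null(x$fits[[i]])) { cat("  [", i, "] fit failed\n"); next }
    cat(sprintf("  [%d] M=%d  chi2=%s  AICc=%s%s\n", i,
                x$fits[[i]]$spec$M,
                format(x$fits[[i]]$chi2, digits = 5),
                format(x$aicc[i], digits = 5),
                if (i == x$selected) "   <- selected" else ""))
  }
  for (ft in x$f_tests)
    cat(sprintf("  F-test %d vs %d: F=%s p=%s\n", ft$simple, ft$complex,
                format(ft$F, digits = 4), format(ft$p, digits = 3)))
  if (length(x$rationale))
    cat("  rationale:", paste(x$rationale, collapse = "; "), "\n")
  invisible(x)
}
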