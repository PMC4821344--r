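#' Multi-component 3D-Gaussian diffusion ACF model
#'
#' Evaluates
#' \deqn{G(\tau) = 1 + \frac{1}{N} \sum_{i=1}^{M} F_i
#'   \left[1 + (\tau/\tau_i)^{\alpha_i}\right]^{-1}
#'   \left[1 + \frac{1}{S^2}(\tau/\tau_i)^{\alpha_i}\right]^{-1/2}}
#' optionally multiplied (fluctuation part only) by the triplet factor
#' `1 + T/(1-T) exp(-tau/tau_T)`. `N` is the mean occupancy of the
#' detection volume, `F_i` and `tau_i` the fraction and diffusion time of
#' component i, `alpha_i = 1` for free Brownian diffusion (< 1 for
#' obstructed diffusion), and `S` the structure parameter (axial/lateral
#' ratio of the detection volume).
#'
#' @param lags Positive lag times, s.
#' @param N Mean occupancy (> 0).
#' @param F Component fractions (recycled against `tau`; must sum to 1).
#' @param tau Component diffusion times, s, strictly ascending.
#' @param alpha Anomalous-diffusion exponents in (0, 1], recycled.
#' @param S Structure parameter (> 0); `Inf` gives the 2D limit.
#' @param triplet_fraction,triplet_time Triplet blinking fraction in
#'   `[0, 1)` and relaxation time, s; the default 0 disables the term.
#' @return Numeric vector of G values.
#' @examples
#' acf_model(1e-4, N = 1, F = 1, tau = 4e-4)      # ~1.74
#' acf_model(1e6, N = 1, F = 1, tau = 4e-4)       # -> 1
#' @export
acf_model <- function(lags, N, F, tau, alpha = 1, S = 5,
                      triplet_fraction = 0, triplet_time = 1e-5) {
  if (any(lags <= 0)) stop("'lags' must be positive")
  if (N <= 0) stop("'N' must be positive")
  M <- length(tau)
  F <- rep_len(F, M)
  alpha <- rep_len(alpha, M)
  if (abs(sum(F) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(tau <= 0)) stop("'tau' must be positive")
  if (M > 1L && any(diff(tau) <= 0))
    stop("'tau' must be strictly ascending")
  if (any(alpha <= 0 | alpha > 1)) stop("'alpha' must be in (0, 1]")
  g <- 0
  for (i in seq_len(M)) {
    r <- (lags / tau[i])^alpha[i]
    ax <- if (is.finite(S)) (1 + r / S^2)^(-0.5) else 1
    g <- g + F[i] / (1 + r) * ax
  }
  if (triplet_fraction > 0) {
    if (triplet_fraction >= 1) stop("'triplet_fraction' must be < 1")
    g <- g * (1 + triplet_fraction / (1 - triplet_fraction) *
                exp(-lags / triplet_time))
  }
  1 + g / N
}

#' Model specification for ACF fitting
#'
#' @param M Number of diffusion components (1-3).
#' @param alpha Per-component mode: `"free"` (alpha fixed at 1),
#'   `"anomalous"` (alpha fitted in (0.1, 1]), or a fixed numeric value;
#'   recycled to length `M`.
#' @param triplet Include the triplet blinking factor (default FALSE;
#'   the fast photophysics lives below the standard 50-us fit start).
#' @param S Structure parameter: a fixed positive value (default 5) or
#'   `"fitted"`.
#' @param fit_range Lag window used for fitting, s (default 50 us to
#'   3.4 s).
#' @return Object of class `fcs_model_spec`.
#' @examples
#' fcs_model_spec(3)
#' fcs_model_spec(2, alpha = c("free", "anomalous"))
#' @export
fcs_model_spec <- function(M, alpha = "free", triplet = FALSE, S = 5,
                           fit_range = c(50e-6, 3.4)) {
  if (!M %in% 1:3) stop("'M' must be 1, 2 or 3")
  alpha <- rep_len(alpha, M)
  bad <- !vapply(alpha, function(a)
    (is.character(a) && a %in% c("free", "anomalous")) ||
      (is.numeric(a) && a > 0 && a <= 1), TRUE)
  if (any(bad)) stop("'alpha' entries must be \"free\", \"anomalous\"",
                     " or a value in (0, 1]")
  if (is.numeric(S) && S <= 0) stop("fixed 'S' must be positive")
  if (fit_range[1L] >= fit_range[2L]) stop("invalid 'fit_range'")
  structure(list(M = as.integer(M), alpha = as.list(alpha),
                 triplet = isTRUE(triplet), S = S,
                 fit_range = as.numeric(fit_range)),
            class = "fcs_model_spec")
}

#' @export
print.fcs_model_spec <- function(x, ...) {
  amode <- vapply(x$alpha, function(a)
    if (is.character(a)) a else paste0("alpha=", format(a)), "")
  cat(x$M, "-component diffusion model (", paste(amode, collapse = ", "),
      "); S ", if (identical(x$S, "fitted")) "fitted" else
        paste("=", format(x$S)),
      if (x$triplet) "; triplet term" else "", "\n", sep = "")
  invisible(x)
}

# number of free parameters of a spec
spec_n_params <- function(spec) {
  K <- 1L + (spec$M - 1L) + spec$M          # N, fractions, taus
  K <- K + sum(vapply(spec$alpha, identical, TRUE, "anomalous"))
  if (identical(spec$S, "fitted")) K <- K + 1L
  if (spec$triplet) K <- K + 2L
  K
}

#' Weighted chi-square of a model against a curve
#'
#' `sum(((model - G) / sigma)^2)` over the lags selected by `mask`.
#'
#' @param curve A [correlation_curve()].
#' @param model_values Model G values on the curve's full lag grid.
#' @param mask Logical vector (or lag-range `c(min, max)`) selecting the
#'   fitted lags; defaults to all.
#' @return The weighted chi-square (dimensionless).
#' @export
chi_square <- function(curve, model_values, mask = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(model_values) != length(curve$G))
    stop("'model_values' must match the curve's lag grid")
  if (is.null(mask)) mask <- rep(TRUE, length(curve$G))
  if (is.numeric(mask) && length(mask) == 2L)
    mask <- curve$lags >= mask[1L] & curve$lags <= mask[2L]
  if (!any(mask)) stop("empty fit mask")
  if (any(curve$sigma[mask] <= 0)) stop("non-positive sigma in fit mask")
  sum(((model_values[mask] - curve$G[mask]) / curve$sigma[mask])^2)
}

# ---- parameter transforms -------------------------------------------------
# theta layout: log N | logit-increment fractions (M-1) | log tau1,
# log increments (M-1) | alpha logits (fitted ones) | log S (if fitted) |
# triplet logit + log tau_T (if on)
TAU_LO <- 1e-6
TAU_HI <- 10

theta_to_params <- function(theta, spec) {
  M <- spec$M
  i <- 1L
  N <- exp(theta[i]); i <- i + 1L
  if (M > 1L) {
    z <- theta[i:(i + M - 2L)]; i <- i + M - 1L
    e <- exp(c(0, z))
    F <- e / sum(e)
  } else F <- 1
  ltau1 <- theta[i]; i <- i + 1L
  tau <- exp(ltau1)
  if (M > 1L) {
    d <- theta[i:(i + M - 2L)]; i <- i + M - 1L
    tau <- exp(cumsum(c(ltau1, log1p(exp(d)))))
  }
  alpha <- numeric(M)
  for (j in seq_len(M)) {
    a <- spec$alpha[[j]]
    if (identical(a, "anomalous")) {
      alpha[j] <- 0.1 + 0.9 * stats::plogis(theta[i]); i <- i + 1L
    } else alpha[j] <- if (is.character(a)) 1 else a
  }
  S <- if (identical(spec$S, "fitted")) { s <- exp(theta[i]); i <- i + 1L; s
  } else spec$S
  if (spec$triplet) {
    Tt <- stats::plogis(theta[i]); i <- i + 1L
    tauT <- exp(theta[i]); i <- i + 1L
  } else { Tt <- 0; tauT <- 1e-5 }
  list(N = N, F = F, tau = tau, alpha = alpha, S = S,
       triplet_fraction = Tt, triplet_time = tauT)
}

params_to_theta <- function(params, spec) {
  M <- spec$M
  theta <- log(params$N)
  if (M > 1L) theta <- c(theta, log(params$F[-1L] / params$F[1L]))
  theta <- c(theta, log(params$tau[1L]))
  if (M > 1L) {
    r <- params$tau[-1L] / params$tau[-M]   # ratios > 1
    theta <- c(theta, log(pmax(r - 1, 1e-8)))
  }
  for (j in seq_len(M))
    if (identical(spec$alpha[[j]], "anomalous")) {
      a <- min(max(params$alpha[j], 0.1 + 1e-6), 1 - 1e-9)
      theta <- c(theta, stats::qlogis((a - 0.1) / 0.9))
    }
  if (identical(spec$S, "fitted")) theta <- c(theta, log(params$S))
  if (spec$triplet)
    theta <- c(theta, stats::qlogis(max(params$triplet_fraction, 1e-4)),
               log(params$triplet_time))
  theta
}

# seeded multi-start initial parameter sets
make_starts <- function(spec, curve, mask, n_starts, rng_seed) {
  amp <- max(curve$G[mask][1L] - 1, 1e-3)
  lo <- max(spec$fit_range[1L], min(curve$lags[mask]))
  hi <- min(spec$fit_range[2L], max(curve$lags[mask]))
  M <- spec$M
  set.seed(rng_seed)
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    if (s == 1L) {
      # deterministic start: taus log-evenly spread over the fit window
      tau <- exp(seq(log(lo * 4), log(hi / 10), length.out = max(M, 2)))
      tau <- tau[seq_len(M)]
    } else {
      tau <- sort(exp(runif(M, log(lo * 2), log(hi / 4))))
      while (M > 1L && any(tau[-1L] / tau[-M] < 1.5))
        tau <- sort(exp(runif(M, log(lo * 2), log(hi / 4))))
    }
    starts[[s]] <- list(N = 1 / amp, F = rep(1 / M, M), tau = tau,
                        alpha = rep(1, M),
                        S = if (identical(spec$S, "fitted")) 5 else spec$S,
                        triplet_fraction = 0.05, triplet_time = 5e-6)
  }
  starts
}

#' Fit a multi-component diffusion model to a correlation curve
#'
#' Weighted least squares: minimizes the chi-square of [acf_model()]
#' against the curve within the spec's fit range (default 50 us to
#' 3.4 s), weighting by the curve's per-lag dispersion. Fractions are
#' constrained to the simplex and diffusion times to be strictly
#' ascending within `[1e-6, 10]` s through an unconstrained
#' reparameterization; optimization is BFGS from `starts` seeded
#' initializations (multi-start defeats label switching and local minima
#' in 3-component fits) and the best chi-square wins. Deterministic for a
#' fixed `rng_seed`.
#'
#' @param curve A [correlation_curve()] covering the fit range.
#' @param spec An [fcs_model_spec()], or an integer taken as the number
#'   of free-diffusion components.
#' @param starts Number of multi-start initializations (default 8).
#' @param rng_seed Seed for the random starts.
#' @param start Optional explicit initial parameter list (`N`, `F`,
#'   `tau`, ...), or a list of such lists; tried before the random
#'   starts.
#' @return Object of class `fcs_fit`: the spec, fitted parameters
#'   (`N`, `F`, `tau`, `alpha`, `S`, triplet terms), asymptotic
#'   uncertainties, `chi2`, `n_points`, `K` (free parameters), `dof`
#'   (`n_points - K - 1`), `converged`, and the data. Supports `print`,
#'   `summary`, `coef`, `predict`, `plot`, `residuals`, `fitted`,
#'   `deviance` and `simulate`.
#' @examples
#' cc <- synthesize_acf(list(N = 1, F = 1, tau = 4e-4),
#'                      lags = 10^seq(-4.3, 0.53, length.out = 120))
#' fit <- fcs_fit(cc, 1)
#' coef(fit)
#' @export
fcs_fit <- function(curve, spec = 3, starts = 8L, rng_seed = 1L,
                    start = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (!inherits(spec, "fcs_model_spec")) spec <- fcs_model_spec(spec)
  mask <- curve$lags >= spec$fit_range[1L] &
    curve$lags <= spec$fit_range[2L]
  K <- spec_n_params(spec)
  if (sum(mask) <= K + 2L)
    stop("too few lags in the fit range for ", K, " parameters")
  if (max(curve$G[mask]) - 1 <= 0)
    stop("degenerate curve: non-positive amplitude in the fit range")
  lags <- curve$lags[mask]
  Gd <- curve$G[mask]
  w <- 1 / curve$sigma[mask]

  resid_fn <- function(theta) {
    p <- theta_to_params(theta, spec)
    if (any(p$tau < TAU_LO) || any(p$tau > TAU_HI) ||
        !all(is.finite(unlist(p))))
      return(rep(1e150, length(lags)))
    Gm <- acf_model(lags, p$N, p$F, p$tau, p$alpha, p$S,
                    p$triplet_fraction, p$triplet_time)
    r <- (Gm - Gd) * w
    r[!is.finite(r)] <- 1e150
    r
  }
  objective <- function(theta) sum(resid_fn(theta)^2)

  init <- make_starts(spec, curve, mask, starts, rng_seed)
  if (!is.null(start)) {
    if (!is.list(start[[1L]])) start <- list(start)
    tmpl <- init[[1L]]
    explicit <- lapply(start, function(s) {
      st <- tmpl
      st[names(s)] <- s
      st
    })
    keep <- max(0L, starts - length(explicit))
    init <- c(explicit, init[seq_len(keep)])
  }
  best <- NULL
  any_conv <- FALSE
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 1e-15)
  for (st in init) {
    th0 <- params_to_theta(st, spec)
    o <- tryCatch(minpack.lm::nls.lm(th0, fn = resid_fn, control = ctrl),
                  error = function(e) NULL)
    if (is.null(o)) next
    val <- sum(o$fvec^2)
    conv <- o$info %in% 1:4
    if (is.null(best) || val < best$value)
      best <- list(par = o$par, value = val, converged = conv)
    any_conv <- any_conv || conv
  }
  if (is.null(best)) stop("all optimization starts failed")
  params <- theta_to_params(best$par, spec)
  dof <- sum(mask) - K - 1L

  # asymptotic uncertainties: delta method through the transform using
  # the numeric Hessian of chi2/2 at the optimum
  unc <- tryCatch({
    H <- stats::optimHess(best$par, function(t) objective(t) / 2)
    cov_t <- solve(H)
    Jn <- numeric_jacobian(function(t) unlist(theta_to_params(t, spec),
                                              use.names = FALSE),
                           best$par)
    v <- diag(Jn %*% cov_t %*% t(Jn))
    v[v < 0] <- NA_real_
    relist_params(sqrt(v), params)
  }, error = function(e) relist_params(rep(NA_real_,
                                           length(unlist(params))), params))

  out <- list(spec = spec, params = params, uncertainties = unc,
              chi2 = best$value, n_points = sum(mask), K = K, dof = dof,
              converged = any_conv && is.finite(best$value),
              curve = curve, mask = mask)
  class(out) <- "fcs_fit"
  out
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

relist_params <- function(v, template) {
  out <- template
  i <- 1L
  for (nm in names(template)) {
    L <- length(template[[nm]])
    out[[nm]] <- v[i:(i + L - 1L)]
    i <- i + L
  }
  out
}

#' @export
coef.fcs_fit <- function(object, ...) {
  p <- object$params
  M <- object$spec$M
  c(setNames(p$N, "N"),
    setNames(p$F, paste0("F", seq_len(M))),
    setNames(p$tau, paste0("tau", seq_len(M))),
    setNames(p$alpha, paste0("alpha", seq_len(M))),
    S = p$S,
    if (object$spec$triplet)
      c(triplet_fraction = p$triplet_fraction,
        triplet_time = p$triplet_time))
}

#' @export
deviance.fcs_fit <- function(object, ...) object$chi2

#' @export
fitted.fcs_fit <- function(object, ...) {
  p <- object$params
  acf_model(object$curve$lags[object$mask], p$N, p$F, p$tau, p$alpha,
            p$S, p$triplet_fraction, p$triplet_time)
}

#' @export
residuals.fcs_fit <- function(object,
                              type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$curve$G[object$mask] - fitted(object)
  if (type == "weighted") r / object$curve$sigma[object$mask] else r
}

#' @export
predict.fcs_fit <- function(object, newlags = NULL, ...) {
  if (is.null(newlags)) return(fitted(object))
  p <- object$params
  acf_model(newlags, p$N, p$F, p$tau, p$alpha, p$S,
            p$triplet_fraction, p$triplet_time)
}

#' @export
print.fcs_fit <- function(x, digits = 4, ...) {
  print(x$spec)
  p <- x$params
  M <- x$spec$M
  cat("  N =", format(p$N, digits = digits), "\n")
  for (i in seq_len(M))
    cat(sprintf("  component %d: F = %s%%  tau = %s s%s\n", i,
                format(100 * p$F[i], digits = digits),
                format(p$tau[i], digits = digits),
                if (p$alpha[i] != 1)
                  paste0("  alpha = ", format(p$alpha[i],
                                              digits = digits)) else ""))
  cat("  chi2 =", format(x$chi2, digits = digits), "on", x$dof,
      "dof (", x$n_points, "lags );",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  M <- object$spec$M
  p <- object$params; u <- object$uncertainties
  tab <- data.frame(
    estimate = c(p$N, p$F, p$tau),
    se = c(u$N, u$F, u$tau),
    row.names = c("N", paste0("F", seq_len(M)),
                  paste0("tau", seq_len(M))))
  structure(list(fit = object, table = tab,
                 aicc = aicc(object$chi2, object$n_points, object$K)),
            class = "summary.fcs_fit")
}

#' @export
print.summary.fcs_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nParameter estimates (asymptotic SE):\n")
  print(format(x$table, digits = digits))
  cat("\nAICc:", format(x$aicc, digits = digits), "\n")
  invisible(x)
}

#' @export
plot.fcs_fit <- function(x, ...) {
  lags <- x$curve$lags[x$mask]
  op <- par(mfrow = c(2, 1), mar = c(0.5, 4, 2, 1))
  on.exit(par(op))
  plot(lags, x$curve$G[x$mask], log = "x", xaxt = "n",
       xlab = "", ylab = expression(G(tau)), ...)
  lines(lags, fitted(x), col = "red", lwd = 2)
  par(mar = c(4, 4, 0.5, 1))
  plot(lags, residuals(x, type = "raw"), log = "x", type = "h",
       xlab = "lag (s)", ylab = "residual")
  abline(h = 0, col = "grey")
  invisible(x)
}

#' Simulate noisy replicate curves from a fitted model
#'
#' Draws `nsim` synthetic curves from the fitted model using the curve's
#' own per-lag dispersion as the noise scale.
#'
#' @param object An `fcs_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of [correlation_curve()]s.
#' @export
simulate.fcs_fit <- function(object, nsim = 1, seed = 1L, ...) {
  lags <- object$curve$lags[object$mask]
  sig <- object$curve$sigma[object$mask]
  lapply(seq_len(nsim), function(i)
    synthesize_acf(object$params, lags, noise_sd = sig,
                   rng_seed = seed + i - 1L))
}
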