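#' Three-dimensional anomalous-diffusion correlation model
#'
#' The model fitted to cochlear FCS curves:
#' \deqn{G(t) = \frac{1}{N}\,\frac{1}{1+(t/\tau_D)^\alpha}\,
#'   \frac{1}{\sqrt{1+(1/S^2)(t/\tau_D)^\alpha}}}
#' where `N` is the mean number of molecules in the detection volume,
#' `tau_D` the diffusion time, `alpha` the anomalous exponent and `S` the
#' axial/lateral aspect ratio of the detection volume. When a triplet
#' fraction `T > 0` is supplied the curve is multiplied by
#' `1 + T/(1-T) * exp(-t/tau_T)`, the usual photophysical correction for
#' reversible dark-state shelving.
#'
#' @param t lag time(s), s, `>= 0`
#' @param N mean molecules in the detection volume (> 0)
#' @param tau_D diffusion time, s (> 0)
#' @param alpha anomalous exponent in (0, 1]
#' @param S aspect ratio (> 0)
#' @param T triplet fraction in `[0, 1)`
#' @param tau_T triplet relaxation time, s
#' @return `G(t)`, dimensionless
#' @export
#' @examples
#' model_G(0, N = 5)            # 1/N at zero lag
#' model_G(1e-3, N = 5, tau_D = 1e-3, alpha = 1, S = 5)
model_G <- function(t, N, tau_D = 1e-3, alpha = 1, S = 5,
                    T = 0, tau_T = 1e-5) {
  stopifnot(all(t >= 0), N > 0, tau_D > 0, alpha > 0, alpha <= 1, S > 0,
            T >= 0, T < 1)
  u <- (t / tau_D)^alpha
  g <- (1 / N) / (1 + u) / sqrt(1 + u / S^2)
  if (T > 0) g <- g * (1 + T / (1 - T) * exp(-t / tau_T))
  g
}

#' Fit the anomalous-diffusion model to a correlation curve
#'
#' Weighted least squares in `G` via Levenberg-Marquardt. `S` is fixed by
#' default (fitting `S` jointly with `alpha` is ill-conditioned); the result
#' records whether it was fixed. Weights default to the inverse pointwise
#' variance across repetitions when the curve was averaged from at least
#' three recordings, otherwise the fit is unweighted.
#'
#' A triplet correction is fitted only "when appropriate": both models are
#' fitted and the triplet term is kept iff it improves AIC by at least
#' `aic_margin` (default 4) and the fitted `tau_T` is below `tau_D / 10`,
#' so that genuine fast photophysics is separated from the diffusion decay.
#'
#' @param curve a [correlation_curve()]
#' @param S aspect ratio; fixed unless `fix_S = FALSE`
#' @param fix_S logical; if `FALSE`, `S` is estimated
#' @param fix_alpha optional value at which to fix `alpha` (e.g. 1 for
#'   ordinary diffusion); `NULL` (default) estimates it
#' @param allow_triplet consider the triplet-corrected model
#' @param aic_margin AIC improvement required to accept the triplet term
#' @param weights optional numeric weights (inverse-variance scale)
#' @param fit_offset estimate an additive baseline `G_inf` alongside the
#'   model (default `TRUE`). The finite-trace correlation estimator sits a
#'   constant `~ -2 sum(G)/n` below the true curve because the mean is
#'   estimated from the same trace; a free baseline absorbs this offset,
#'   which is negligible at the plateau but dominates the tail.
#' @return an `fcs_fit` object: estimates `N`, `tau_D`, `alpha`, `S`,
#'   `triplet_fraction`, `triplet_tau`, flags, `covariance`, `se`,
#'   `residual_norm`, `converged`, `aic`
#' @export
#' @examples
#' lag <- 10^seq(-5, 0, length.out = 60)
#' cv <- correlation_curve(lag, model_G(lag, N = 5, tau_D = 1e-3,
#'                                      alpha = 0.8, S = 5), 1e5)
#' fit_anomalous_diffusion(cv)$N
fit_anomalous_diffusion <- function(curve, S = 5, fix_S = TRUE,
                                    fix_alpha = NULL, allow_triplet = TRUE,
                                    aic_margin = 4, weights = NULL,
                                    fit_offset = TRUE) {
  stopifnot(inherits(curve, "correlation_curve"))
  t <- curve$lags; G <- curve$G
  if (length(t) < 10)
    warning("fewer than 10 lag points; fit may be unstable")
  if (is.null(weights)) {
    if (!is.null(curve$G_se) && curve$n_repetitions_averaged >= 3 &&
        all(curve$G_se > 0)) {
      weights <- 1 / curve$G_se^2
    } else weights <- rep(1, length(t))
  }
  g0 <- max(G[1], 1e-12)
  N0 <- 1 / g0
  half_idx <- which(G <= g0 / 2)
  tau0 <- if (length(half_idx)) t[half_idx[1]] else median(t)

  fit_one <- function(triplet) {
    # parameters on log scale where positive; alpha and T via logistic
    fn <- function(p) {
      N <- exp(p[["lN"]]); tau <- exp(p[["ltau"]])
      a <- if (is.null(fix_alpha)) plogis(p[["qa"]]) else fix_alpha
      Sv <- if (fix_S) S else exp(p[["lS"]])
      Tf <- if (triplet) 0.999 * plogis(p[["qT"]]) else 0
      tT <- if (triplet) exp(p[["ltT"]]) else 1e-5
      off <- if (fit_offset) p[["off"]] * g0 else 0
      model_G(t, N, tau, max(a, 1e-6), Sv, Tf, tT) + off
    }
    p0 <- c(lN = log(N0), ltau = log(tau0))
    if (is.null(fix_alpha)) p0 <- c(p0, qa = qlogis(0.95))
    if (!fix_S) p0 <- c(p0, lS = log(S))
    if (triplet) p0 <- c(p0, qT = qlogis(0.1), ltT = log(tau0 / 50))
    if (fit_offset) p0 <- c(p0, off = 0)
    res <- try(minpack.lm::nls.lm(
      par = p0, fn = function(p) sqrt(weights) * (G - fn(p)),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-12, ptol = 1e-12)), silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    list(res = res, fn = fn, triplet = triplet,
         rss = sum(res$fvec^2),
         npar = length(p0),
         aic = length(t) * log(sum(res$fvec^2) / length(t)) +
           2 * length(p0))
  }

  plain <- fit_one(FALSE)
  if (is.null(plain)) stop("fit failed to start")
  chosen <- plain
  triplet_considered <- FALSE
  # an (effectively) exact plain fit leaves nothing for a triplet term to
  # explain; AIC on near-zero residuals is numerically meaningless
  plain_exact <- sqrt(plain$rss / length(t)) < 1e-8 * max(abs(G))
  if (allow_triplet && !plain_exact) {
    trip <- fit_one(TRUE)
    if (!is.null(trip)) {
      triplet_considered <- TRUE
      p <- trip$res$par
      tauT_hat <- exp(p[["ltT"]])
      tau_hat <- exp(p[["ltau"]])
      if (is.finite(trip$aic) &&
          plain$aic - trip$aic >= aic_margin && tauT_hat < tau_hat / 10)
        chosen <- trip
    }
  }

  p <- chosen$res$par
  N_hat <- exp(p[["lN"]]); tau_hat <- exp(p[["ltau"]])
  a_hat <- if (is.null(fix_alpha)) plogis(p[["qa"]]) else fix_alpha
  S_hat <- if (fix_S) S else exp(p[["lS"]])
  T_hat <- if (chosen$triplet) 0.999 * plogis(p[["qT"]]) else 0
  tT_hat <- if (chosen$triplet) exp(p[["ltT"]]) else NA_real_
  off_hat <- if (fit_offset) p[["off"]] * g0 else 0

  # delta-method covariance on the natural scale for (N, tau_D[, alpha]);
  # Gauss-Newton covariance = sigma^2 (J'J)^-1 with sigma^2 = RSS/(n - p)
  # pseudo-inverse: when alpha sits on its boundary the corresponding
  # Jacobian column degenerates and a plain solve() fails
  # Residuals of a correlation-curve fit are strongly correlated across
  # neighbouring lags (they share the same underlying intensity
  # fluctuations), so the naive least-squares covariance is far too
  # optimistic. An AR(1) effective-sample-size correction based on the
  # lag-1 autocorrelation of the ordered residuals restores honest
  # uncertainty estimates.
  covm <- try({
    s2 <- chosen$rss / max(1, length(t) - chosen$npar)
    r <- chosen$res$fvec
    rho_r <- if (length(r) > chosen$npar + 2) {
      suppressWarnings(stats::cor(r[-length(r)], r[-1]))
    } else 0
    if (!is.finite(rho_r)) rho_r <- 0
    rho_r <- min(max(rho_r, 0), 0.99)
    infl <- (1 + rho_r) / (1 - rho_r)
    infl * s2 * MASS::ginv(chosen$res$hessian)
  }, silent = TRUE)
  if (!inherits(covm, "try-error"))
    dimnames(covm) <- list(names(p), names(p))
  se <- c(N = NA_real_, tau_D = NA_real_, alpha = NA_real_)
  cov_nat <- NULL
  if (!inherits(covm, "try-error") && all(is.finite(diag(covm)))) {
    nm <- names(p)
    jac <- diag(length(p))
    dimnames(jac) <- list(nm, nm)
    jac["lN", "lN"] <- N_hat
    jac["ltau", "ltau"] <- tau_hat
    if ("qa" %in% nm) jac["qa", "qa"] <- a_hat * (1 - a_hat)
    cov_nat <- jac %*% covm %*% t(jac)
    # the pseudo-inverse can leave tiny negative diagonals in degenerate
    # (boundary) directions; clip to zero rather than emit NaN
    dsqrt <- function(v) sqrt(max(v, 0))
    se["N"] <- dsqrt(cov_nat["lN", "lN"])
    se["tau_D"] <- dsqrt(cov_nat["ltau", "ltau"])
    if ("qa" %in% nm) se["alpha"] <- dsqrt(cov_nat["qa", "qa"])
  }
  conv <- chosen$res$info %in% 1:4
  if (!conv) warning("fit did not converge; diagnostics retained")
  structure(list(
    N = N_hat, tau_D = tau_hat, alpha = a_hat, S = S_hat,
    S_fixed = fix_S, alpha_fixed = !is.null(fix_alpha),
    triplet_fraction = T_hat, triplet_tau = tT_hat,
    included_triplet = chosen$triplet,
    triplet_considered = triplet_considered,
    G_inf = off_hat,
    residual_norm = sqrt(chosen$rss), aic = chosen$aic,
    covariance = cov_nat, se = se, converged = conv,
    n_lags = length(t),
    mean_count_rate = curve$mean_count_rate),
    class = "fcs_fit")
}

#' Fit an FCS experiment from repeated recordings
#'
#' The standard acquisition repeats 10-s recordings several times per
#' location. This wrapper averages the per-repetition correlation curves
#' (inverse-variance weights from the repetition spread), fits the
#' anomalous-diffusion model to the average, and derives jackknife
#' (leave-one-repetition-out) standard errors and t-based 95% confidence
#' intervals for `N`, `tau_D` and `alpha`. Unlike the least-squares
#' covariance of a single curve — whose residuals are correlated across
#' lags — the jackknife respects the between-repetition variability.
#'
#' @param curves list of per-repetition [correlation_curve()] objects (>= 3)
#' @param ... passed to [fit_anomalous_diffusion()]
#' @return the `fcs_fit` for the averaged curve, with elements
#'   `jackknife_se` and `conf_int` (rows N, tau_D, alpha) added, plus
#'   `curve` (the averaged curve)
#' @export
fit_fcs_repetitions <- function(curves, ...) {
  stopifnot(length(curves) >= 3)
  avg <- average_correlations(curves)
  fit <- fit_anomalous_diffusion(avg, ...)
  k <- length(curves)
  take <- function(f) c(N = f$N, tau_D = f$tau_D, alpha = f$alpha)
  loo <- sapply(seq_len(k), function(i) {
    take(fit_anomalous_diffusion(average_correlations(curves[-i]), ...))
  })
  theta_bar <- rowMeans(loo)
  se <- sqrt((k - 1) / k * rowSums((loo - theta_bar)^2))
  est <- take(fit)
  tq <- qt(0.975, df = k - 1)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  fit$jackknife_se <- se
  fit$conf_int <- ci
  fit$n_repetitions <- k
  fit$curve <- avg
  fit
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf(
    "Anomalous-diffusion fit: N = %.3g, tau_D = %.3g s, alpha = %.3f, S = %.3g%s\n",
    x$N, x$tau_D, x$alpha, x$S, if (x$S_fixed) " (fixed)" else ""))
  if (x$included_triplet)
    cat(sprintf("  triplet: T = %.3f, tau_T = %.3g s\n",
                x$triplet_fraction, x$triplet_tau))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}
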