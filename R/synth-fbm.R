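#' Fractional Gaussian noise increments (Davies-Harte)
#'
#' Generates `n` increments of fractional Brownian motion with Hurst index
#' `H` over time step `dt`, scaled so that the resulting path has
#' mean-squared displacement `2 * D * t^(2H)` per axis. Uses circulant
#' embedding of the fractional-Gaussian-noise covariance (exact covariance,
#' O(n log n)); falls back to a Cholesky factorisation for short series or
#' when the embedding is not non-negative definite.
#'
#' @param n number of increments
#' @param H Hurst index in (0, 1]
#' @param dt time step (s)
#' @param D generalised diffusion coefficient (units^2 / s^(2H))
#' @return numeric vector of `n` increments
#' @keywords internal
fgn_increments <- function(n, H, dt, D) {
  stopifnot(n >= 1, H > 0, H <= 1, dt > 0, D >= 0)
  if (D == 0) return(numeric(n))
  sig2 <- 2 * D * dt^(2 * H)            # Var of one increment
  if (abs(H - 0.5) < 1e-12) return(rnorm(n, sd = sqrt(sig2)))
  ac <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                             abs(k - 1)^(2 * H))
  if (n >= 32) {
    m <- n
    # first row of the circulant embedding of the Toeplitz fGn covariance
    r <- c(ac(0:m), ac((m - 1):1))
    lam <- Re(fft(r))
    if (min(lam) > -1e-10 * max(lam)) {
      lam <- pmax(lam, 0)
      nn <- length(lam)
      zr <- rnorm(nn); zi <- rnorm(nn)
      w <- complex(real = zr, imaginary = zi)
      # Re and Im of fft(c * w) are two independent draws with covariance
      # (nn * c^2 / 2) * C; c = sqrt(lam / nn) makes Re carry exactly C.
      f <- fft(sqrt(lam / nn) * w)
      return(sqrt(sig2) * Re(f)[seq_len(n)])
    }
  }
  # Cholesky fallback (exact, O(n^3); used only for short series)
  K <- outer(seq_len(n), seq_len(n), function(i, j) ac(i - j))
  L <- chol(K + diag(1e-12, n))
  as.numeric(sqrt(sig2) * (rnorm(n) %*% L))
}

#' Simulate anomalously diffusing molecule paths
#'
#' Generates 3-D trajectories for the molecules of an FCS simulation. Each
#' coordinate is fractional Brownian motion with Hurst index `H = alpha/2`
#' (`alpha = 1` recovers ordinary Brownian motion), so the per-axis
#' mean-squared displacement grows as `2 * D * t^alpha`. Positions are
#' wrapped periodically into the simulation box, keeping the number of
#' molecules in the detection region statistically stationary.
#'
#' @param config an [fcs_sim_config()] object
#' @param n_steps optional override of the number of steps (defaults to
#'   `duration / bin_width`)
#' @return a list with `paths` (array `n_steps` x 3 x `n_molecules`, box-centred
#'   coordinates in um, wrapped) and `unwrapped` (same shape, no wrapping;
#'   used for displacement statistics)
#' @export
#' @examples
#' cfg <- fcs_sim_config(duration = 0.01, bin_width = 1e-3, n_molecules = 3,
#'                       seed = 1)
#' p <- simulate_fbm_paths(cfg)
#' dim(p$paths)
simulate_fbm_paths <- function(config, n_steps = NULL) {
  stopifnot(inherits(config, "fcs_sim_config"))
  n <- if (is.null(n_steps)) config$n_steps else as.integer(n_steps)
  if (n < 1) stop("duration must cover at least one bin")
  if (n > 2e7) stop("step count ", n, " exceeds the 2e7 step limit")
  set.seed(config$seed)
  nm <- config$n_molecules
  L <- config$box_size
  Lz <- config$box_size_z
  paths <- array(NA_real_, c(n, 3, nm))
  unwrapped <- array(NA_real_, c(n, 3, nm))
  start <- cbind(matrix(runif(2 * nm, -L / 2, L / 2), ncol = 2),
                 runif(nm, -Lz / 2, Lz / 2))
  for (m in seq_len(nm)) {
    for (ax in 1:3) {
      Lax <- if (ax == 3) Lz else L
      inc <- fgn_increments(n, H = config$alpha / 2, dt = config$bin_width,
                            D = config$diffusion_coefficient)
      u <- start[m, ax] + cumsum(inc)
      unwrapped[, ax, m] <- u
      paths[, ax, m] <- u - Lax * floor((u + Lax / 2) / Lax)
    }
  }
  list(paths = paths, unwrapped = unwrapped, start = start)
}
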