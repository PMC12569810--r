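#' Configuration for a synthetic FCS experiment
#'
#' Describes a population of fluorophores diffusing (normally or
#' anomalously) through a periodic box, observed by a confocal detection
#' volume modelled as a 3-D Gaussian with lateral 1/e^2 radius
#' `beam_waist_xy` and axial elongation `aspect_ratio_S`. The configuration
#' carries the ground truth that downstream analysis should recover:
#'
#' * `n_effective`: expected number of molecules in the effective detection
#'   volume `V_eff = pi^(3/2) * w^3 * S`; this is what the amplitude of the
#'   autocorrelation estimates (`G(0) = 1/N`).
#' * `tau_D`: `(w^2 / (4 D))^(1/alpha)` — the diffusion time through the
#'   detection volume (`w^2 / (4 D)` for ordinary diffusion).
#' * `brightness_cpm`: expected apparent molecular brightness, i.e.
#'   background-corrected mean count rate divided by `n_effective`. For a
#'   Gaussian profile this is the beam-centre brightness times `2^(-3/2)`.
#'
#' @param n_molecules number of molecules in the box. Exactly one of
#'   `n_molecules` and `n_effective` must be given; the other is derived.
#' @param n_effective expected molecules in the effective detection volume.
#' @param diffusion_coefficient um^2/s (generalised for `alpha != 1`)
#' @param alpha anomalous-diffusion exponent in (0, 1]
#' @param brightness_true photons/s per molecule at beam centre
#' @param background_rate photons/s, uncorrelated background
#' @param beam_waist_xy lateral 1/e^2 radius, um
#' @param aspect_ratio_S axial/lateral ratio of the detection volume
#' @param box_size periodic box edge, um (>= 10 * `beam_waist_xy`)
#' @param duration trace length, s
#' @param bin_width photon-counting bin, s
#' @param seed integer RNG seed; a fixed seed gives identical output
#' @return an object of class `fcs_sim_config`
#' @export
#' @examples
#' fcs_sim_config(n_effective = 5, seed = 1)
fcs_sim_config <- function(n_molecules = NULL, n_effective = NULL,
                           diffusion_coefficient = 2, alpha = 1,
                           brightness_true = 6e4, background_rate = 1000,
                           beam_waist_xy = 0.25, aspect_ratio_S = 5,
                           box_size = 10 * beam_waist_xy,
                           duration = 10, bin_width = 2e-4, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (diffusion_coefficient < 0 || brightness_true < 0 || background_rate < 0)
    stop("rates and the diffusion coefficient must be non-negative")
  if (box_size < 10 * beam_waist_xy)
    stop("box_size must be at least 10 * beam_waist_xy")
  if (duration < bin_width) stop("duration shorter than one bin")
  w <- beam_waist_xy
  # the box is elongated axially so the detection volume (axial radius
  # S * w) never feels the periodic boundary
  box_size_z <- max(box_size, 6 * aspect_ratio_S * w)
  v_eff <- pi^1.5 * w^3 * aspect_ratio_S
  v_box <- box_size^2 * box_size_z
  if (is.null(n_molecules) && is.null(n_effective))
    n_effective <- 5
  if (is.null(n_molecules)) {
    n_molecules <- max(1L, as.integer(round(n_effective * v_box / v_eff)))
  }
  n_effective <- n_molecules * v_eff / v_box
  n_steps <- as.integer(round(duration / bin_width))
  if (abs(n_steps * bin_width - duration) > 1e-9 * duration)
    stop("duration must be an integer number of bins")
  D <- diffusion_coefficient
  # Gaussian displacements with per-axis MSD 2 D t^alpha give
  # G(t) = (1/N) (1 + (t/tau_D)^alpha)^-1 (...)^-1/2 with
  # tau_D^alpha = w^2 / (4 D)
  tau_D <- if (D > 0) (w^2 / (4 * D))^(1 / alpha) else Inf
  # mean detected rate: background + n_mol * eps * <W> with
  # <W> = ((pi/2)^(3/2) w^3 S) / V_box for a box much larger than the beam
  mean_w <- (pi / 2)^1.5 * w^3 * aspect_ratio_S / v_box   # <W> over the box
  mean_rate <- background_rate + n_molecules * brightness_true * mean_w
  structure(list(
    n_molecules = n_molecules, n_effective = n_effective,
    diffusion_coefficient = D, alpha = alpha,
    brightness_true = brightness_true,
    brightness_cpm = brightness_true * 2^-1.5,
    background_rate = background_rate,
    beam_waist_xy = w, aspect_ratio_S = aspect_ratio_S,
    box_size = box_size, box_size_z = box_size_z,
    duration = duration, bin_width = bin_width,
    n_steps = n_steps, tau_D = tau_D, mean_rate = mean_rate,
    seed = as.integer(seed)), class = "fcs_sim_config")
}

#' @export
print.fcs_sim_config <- function(x, ...) {
  cat("FCS simulation config:\n",
      sprintf("  %d molecules (N_eff = %.2f), D = %g um^2/s, alpha = %g\n",
              x$n_molecules, x$n_effective, x$diffusion_coefficient, x$alpha),
      sprintf("  tau_D = %.3g s, expected rate %.3g kHz\n",
              x$tau_D, x$mean_rate / 1000))
  invisible(x)
}

#' Simulate a binned photon-count trace
#'
#' Forward model for a confocal FCS recording: molecules diffuse through a
#' periodic box, each emitting photons at a rate given by the 3-D Gaussian
#' detection profile, on top of a uniform Poisson background. Per-bin counts
#' are Poisson draws around the instantaneous summed intensity.
#'
#' Ground truth (`n_effective`, `tau_D`, `brightness_cpm`, expected mean
#' rate) travels with the returned trace so that parameter-recovery tests
#' never re-derive it.
#'
#' @param config an [fcs_sim_config()]
#' @param site_label recording site, one of `"TM1"`, `"TM2"`, `"TM3"`,
#'   `"EndoL"`
#' @param repetition_index integer tag for repeated recordings
#' @param initial_positions optional `n_molecules` x 3 matrix of start
#'   positions (um, box-centred); default uniform in the box. Useful for
#'   controlled scenarios such as an immobile molecule at the beam centre.
#' @return a `photon_trace` object (see [photon_trace()])
#' @export
#' @examples
#' tr <- simulate_photon_trace(fcs_sim_config(duration = 0.5, seed = 2))
#' mean(tr$counts) / tr$bin_width  # observed count rate, photons/s
simulate_photon_trace <- function(config, site_label = "TM1",
                                  repetition_index = 1L,
                                  initial_positions = NULL) {
  stopifnot(inherits(config, "fcs_sim_config"))
  n <- config$n_steps
  if (n < 1) stop("duration shorter than one bin: empty trace")
  set.seed(config$seed)
  nm <- config$n_molecules
  L <- config$box_size
  w <- config$beam_waist_xy
  wz <- config$aspect_ratio_S * w
  dt <- config$bin_width
  Lz <- config$box_size_z
  init <- if (is.null(initial_positions)) {
    cbind(matrix(runif(2 * nm, -L / 2, L / 2), ncol = 2),
          runif(nm, -Lz / 2, Lz / 2))
  } else {
    stopifnot(nrow(initial_positions) == nm, ncol(initial_positions) == 3)
    as.matrix(initial_positions)
  }
  peak_per_bin <- config$brightness_true * dt
  if (config$alpha == 1 || config$diffusion_coefficient == 0) {
    step_sd <- sqrt(2 * config$diffusion_coefficient * dt)
    lam <- sim_trace_brownian_cpp(init, n, step_sd, L, Lz, w^2, wz^2,
                                  peak_per_bin, TRUE)
  } else {
    # anomalous case: explicit fBm paths, intensity accumulated in R
    lam <- numeric(n)
    for (m in seq_len(nm)) {
      pos <- sapply(1:3, function(ax) {
        Lax <- if (ax == 3) Lz else L
        u <- init[m, ax] +
          cumsum(fgn_increments(n, H = config$alpha / 2, dt = dt,
                                D = config$diffusion_coefficient))
        u - Lax * floor((u + Lax / 2) / Lax)
      })
      lam <- lam + exp(-2 * (pos[, 1]^2 + pos[, 2]^2) / w^2 -
                         2 * pos[, 3]^2 / wz^2)
    }
    lam <- lam * peak_per_bin
  }
  counts <- rpois(n, lam + config$background_rate * dt)
  photon_trace(counts, bin_width = dt,
               background_rate = config$background_rate,
               site_label = site_label,
               repetition_index = repetition_index,
               ground_truth = list(
                 n_effective = config$n_effective,
                 tau_D = config$tau_D, alpha = config$alpha,
                 brightness_cpm = config$brightness_cpm,
                 brightness_peak = config$brightness_true,
                 mean_rate = config$mean_rate,
                 aspect_ratio_S = config$aspect_ratio_S,
                 seed = config$seed))
}
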