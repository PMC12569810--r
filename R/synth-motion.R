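#' Configuration for a synthetic phase-stamped motion sequence
#'
#' Emulates rapid confocal imaging of a sound-driven stereocilia bundle:
#' a static random texture (analytic sum of Gaussian blobs, so it can be
#' sampled at arbitrary subpixel positions) translated by a spatially
#' blended displacement field. Pixels near the bundle base follow the base
#' trajectory, pixels near the tip the tip trajectory; both paths are
#' linear, sinusoidal in stimulus phase and in phase with each other, so
#' the programmed deflection amplitude is `|A_t u_t - A_b u_b|` for unit
#' direction vectors `u`.
#'
#' Defaults reproduce the normal motion pattern of a healthy bundle: base
#' moving 65 nm along an inclined path, tip moving vertically, programmed
#' deflection 33 nm.
#'
#' @param frame_shape c(rows, cols), pixels
#' @param pixel_size nm per pixel
#' @param stimulus_frequency Hz (bookkeeping)
#' @param n_phase_bins phase bins the stream should support (>= 8)
#' @param base_amplitude,tip_amplitude nm, peak displacement from rest
#' @param base_direction,tip_direction rad (0 = +x, pi/2 = +y)
#' @param base_anchor,tip_anchor c(x, y) pixel positions of the two
#'   measurement sites
#' @param noise_sd intensity noise per sample
#' @param samples_per_bin pixel samples emitted per phase bin
#' @param seed integer RNG seed
#' @return object of class `motion_phantom_config`
#' @export
motion_phantom_config <- function(frame_shape = c(64, 64),
                                  pixel_size = 100,
                                  stimulus_frequency = 200,
                                  n_phase_bins = 16L,
                                  base_amplitude = 65,
                                  base_direction = pi / 3,
                                  tip_amplitude = 62.03,
                                  tip_direction = pi / 2,
                                  base_anchor = c(20, 40),
                                  tip_anchor = c(44, 24),
                                  noise_sd = 30, samples_per_bin = 3L,
                                  seed = 1L) {
  stopifnot(n_phase_bins >= 8, base_amplitude >= 0, tip_amplitude >= 0,
            pixel_size > 0, samples_per_bin >= 1)
  max_px <- max(base_amplitude, tip_amplitude) / pixel_size
  if (max_px > min(frame_shape) / 4)
    stop("trajectory amplitude exceeds the frame")
  ub <- c(cos(base_direction), sin(base_direction))
  ut <- c(cos(tip_direction), sin(tip_direction))
  defl <- sqrt(sum((tip_amplitude * ut - base_amplitude * ub)^2))
  structure(list(frame_shape = as.integer(frame_shape),
                 pixel_size = pixel_size,
                 stimulus_frequency = stimulus_frequency,
                 n_phase_bins = as.integer(n_phase_bins),
                 base_amplitude = base_amplitude,
                 base_direction = base_direction,
                 tip_amplitude = tip_amplitude,
                 tip_direction = tip_direction,
                 base_anchor = base_anchor, tip_anchor = tip_anchor,
                 noise_sd = noise_sd,
                 samples_per_bin = as.integer(samples_per_bin),
                 seed = as.integer(seed),
                 deflection_true = defl),
            class = "motion_phantom_config")
}

# analytic blob texture: function of (x, y) vectors -> intensity
make_blob_texture <- function(nr, nc, n_blobs = 70) {
  bx <- runif(n_blobs, 2, nc - 3)
  by <- runif(n_blobs, 2, nr - 3)
  bs <- runif(n_blobs, 1.5, 3.5)
  ba <- runif(n_blobs, 300, 1200)
  function(x, y) {
    out <- rep(200, length(x))
    for (k in seq_len(n_blobs))
      out <- out + ba[k] * exp(-((x - bx[k])^2 + (y - by[k])^2) /
                                 (2 * bs[k]^2))
    out
  }
}

#' Render a phase-stamped image stream of a moving bundle
#'
#' Emits the long-format pixel record set described by a
#' [motion_phantom_config()]: each record carries pixel coordinates, the
#' sampled intensity and the exact stimulus phase of the sample. The
#' ground-truth trajectories (evaluated at the phase-bin centres and
#' centred on the cycle mean) are returned alongside.
#'
#' @param config a [motion_phantom_config()]
#' @return list with `stream` (a [phase_stamped_stream()]) and `truth`
#'   (base/tip [motion_trajectory()] objects and `deflection_amplitude`, nm)
#' @export
#' @examples
#' sim <- render_motion_sequence(motion_phantom_config(seed = 3))
#' sim$truth$deflection_amplitude
render_motion_sequence <- function(config) {
  stopifnot(inherits(config, "motion_phantom_config"))
  set.seed(config$seed)
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  nb <- config$n_phase_bins; spb <- config$samples_per_bin
  ps <- config$pixel_size
  tex0 <- make_blob_texture(nr, nc)
  # the bundle itself is stained and visible: guarantee bright structure
  # at the base and tip measurement sites regardless of the random field
  bundle <- rbind(c(config$base_anchor, 2.2, 1500),
                  c(config$base_anchor + c(3, -2), 1.8, 900),
                  c(config$base_anchor + c(-2, 3), 1.8, 900),
                  c(config$tip_anchor, 2.2, 1500),
                  c(config$tip_anchor + c(-3, 2), 1.8, 900),
                  c(config$tip_anchor + c(2, -3), 1.8, 900))
  tex <- function(x, y) {
    out <- tex0(x, y)
    for (k in seq_len(nrow(bundle)))
      out <- out + bundle[k, 4] *
        exp(-((x - bundle[k, 1])^2 + (y - bundle[k, 2])^2) /
              (2 * bundle[k, 3]^2))
    out
  }
  ub <- c(cos(config$base_direction), sin(config$base_direction))
  ut <- c(cos(config$tip_direction), sin(config$tip_direction))
  # spatial blending of the two trajectories (Gaussian influence regions)
  # symmetric cross-talk between the two influence regions scales the
  # tip-base difference without rotating it, so a generous radius is safe
  sig <- max(8, sqrt(sum((config$tip_anchor - config$base_anchor)^2)) / 2.5)
  wfun <- function(x, y, a) exp(-((x - a[1])^2 + (y - a[2])^2) / (2 * sig^2))

  px <- rep(rep(0:(nc - 1), each = nr), times = nb * spb)
  py <- rep(rep(0:(nr - 1), times = nc), times = nb * spb)
  bin <- rep(rep(0:(nb - 1), each = nr * nc), times = spb)
  phase <- (bin + runif(length(bin))) * 2 * pi / nb
  phase <- pmin(phase, 2 * pi - 1e-12)
  wb <- wfun(px, py, config$base_anchor)
  wt <- wfun(px, py, config$tip_anchor)
  s <- sin(phase)
  dx_px <- (wb * config$base_amplitude * ub[1] +
              wt * config$tip_amplitude * ut[1]) * s / ps
  dy_px <- (wb * config$base_amplitude * ub[2] +
              wt * config$tip_amplitude * ut[2]) * s / ps
  intensity <- tex(px - dx_px, py - dy_px) +
    rnorm(length(px), sd = config$noise_sd)
  stream <- phase_stamped_stream(
    data.frame(x = px, y = py, intensity = intensity, phase = phase),
    frame_shape = config$frame_shape, pixel_size = ps,
    stimulus_frequency = config$stimulus_frequency)

  centers <- 2 * pi * (seq_len(nb) - 0.5) / nb
  sb <- sin(centers)
  base_t <- motion_trajectory(config$base_amplitude * sb %o% ub, centers,
                              anchor = config$base_anchor)
  tip_t <- motion_trajectory(config$tip_amplitude * sb %o% ut, centers,
                             anchor = config$tip_anchor)
  list(stream = stream,
       truth = list(base = base_t, tip = tip_t,
                    deflection_amplitude = config$deflection_true *
                      max(abs(sb)),
                    base_amplitude = config$base_amplitude * max(abs(sb)),
                    tip_amplitude = config$tip_amplitude * max(abs(sb)),
                    seed = config$seed))
}
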