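#' Phase-stamped pixel stream
#'
#' Long-format record set from rapid confocal imaging in which every pixel
#' sample carries the exact phase of the acoustic stimulus at acquisition
#' time (phase is assigned per pixel, not per frame).
#'
#' @param records data.frame with columns `x`, `y` (0-based pixel indices),
#'   `intensity`, `phase` (rad in `[0, 2*pi)`)
#' @param frame_shape c(rows, cols)
#' @param pixel_size nm per pixel
#' @param stimulus_frequency Hz
#' @param level dB SPL (bookkeeping only)
#' @return object of class `phase_stamped_stream`
#' @export
phase_stamped_stream <- function(records, frame_shape, pixel_size,
                                 stimulus_frequency, level = NA_real_) {
  stopifnot(all(c("x", "y", "intensity", "phase") %in% names(records)))
  if (any(records$phase < 0 | records$phase >= 2 * pi))
    stop("phases must lie in [0, 2*pi)")
  structure(list(records = records,
                 frame_shape = as.integer(frame_shape),
                 pixel_size = pixel_size,
                 stimulus_frequency = stimulus_frequency, level = level),
            class = "phase_stamped_stream")
}

#' Reconstruct phase-binned frames from a phase-stamped stream
#'
#' Samples are grouped into `n_bins` half-open phase bins
#' `[2*pi*b/n, 2*pi*(b+1)/n)`; frame `b` is the per-pixel mean intensity of
#' the samples falling in bin `b`. Every pixel must be sampled in every
#' bin; offending pixels are reported otherwise.
#'
#' @param stream a [phase_stamped_stream()]
#' @param n_bins number of phase bins (>= 8)
#' @return 3-D array (rows x cols x n_bins) with attributes `pixel_size`
#'   (nm/px), `phase_centers` (rad)
#' @export
bin_phases <- function(stream, n_bins = 16L) {
  stopifnot(inherits(stream, "phase_stamped_stream"), n_bins >= 8)
  r <- stream$records
  nr <- stream$frame_shape[1]; nc <- stream$frame_shape[2]
  b <- pmin(floor(r$phase / (2 * pi) * n_bins), n_bins - 1L)
  idx <- 1 + r$y + nr * r$x + nr * nc * b
  tot <- nr * nc * n_bins
  sums <- rowsum(r$intensity, idx)
  cnt <- tabulate(idx, nbins = tot)
  if (any(cnt == 0)) {
    miss <- which(cnt == 0)[seq_len(min(5, sum(cnt == 0)))] - 1
    stop("empty phase bin for pixel(s): ",
         paste(sprintf("(x=%d,y=%d,bin=%d)", (miss %% (nr * nc)) %/% nr,
                       miss %% nr, miss %/% (nr * nc)), collapse = " "),
         if (sum(cnt == 0) > 5) " ..." else "")
  }
  fr <- numeric(tot)
  fr[as.integer(rownames(sums))] <- sums[, 1]
  frames <- array(fr / cnt, c(nr, nc, n_bins))
  attr(frames, "pixel_size") <- stream$pixel_size
  attr(frames, "phase_centers") <- 2 * pi * (seq_len(n_bins) - 0.5) / n_bins
  frames
}

# 1-D Gaussian convolution matrix with replicated edges
gauss_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-r:r), 1L), n)       # replicate boundary
    for (q in seq_along(j)) M[i, j[q]] <- M[i, j[q]] + k[q]
  }
  M
}

#' Spatial low-pass filtering of a phase-binned sequence
#'
#' Per-frame separable Gaussian smoothing (replicated edges); the filter is
#' an averaging kernel, so image energy never increases.
#'
#' @param frames 3-D array from [bin_phases()]
#' @param sigma Gaussian sigma in pixels (> 0); values below 0.05 return
#'   the input unchanged
#' @return filtered array, same shape and attributes
#' @export
lowpass_sequence <- function(frames, sigma = 1) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 3)
  if (sigma <= 0) stop("sigma must be positive")
  if (sigma < 0.05) return(frames)
  d <- dim(frames)
  My <- gauss_conv_matrix(d[1], sigma)
  Mx <- gauss_conv_matrix(d[2], sigma)
  out <- frames
  for (b in seq_len(d[3])) out[, , b] <- My %*% frames[, , b] %*% t(Mx)
  out
}

bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1); y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

#' Per-pixel subpixel motion estimation
#'
#' Iterative Lucas-Kanade gradient flow against the cycle-mean image:
#' for each phase bin the per-pixel displacement is found by solving the
#' windowed normal equations of the brightness-constancy constraint, with
#' bilinear warping between iterations for subpixel accuracy. Displacements
#' are reported relative to the cycle mean (zero mean over the cycle by
#' construction of the reference) and converted to nm.
#'
#' Pixels whose structure tensor is near-singular (no texture) carry a
#' `low_confidence` flag instead of fabricated motion.
#'
#' @param frames 3-D array from [bin_phases()] (>= 8 bins)
#' @param pixel_size nm per pixel (defaults to the array attribute)
#' @param window odd window size for the local normal equations
#' @param n_iter warp-and-refine iterations
#' @param min_eig relative structure-tensor eigenvalue below which a pixel
#'   is flagged low-confidence
#' @return a `motion_field`: list with `disp` (rows x cols x bins x 2, nm;
#'   slices `[ , , , 1]` = x, `[ , , , 2]` = y), `low_confidence` (logical
#'   matrix), `phase_centers`, `pixel_size`
#' @export
estimate_motion <- function(frames, pixel_size = attr(frames, "pixel_size"),
                            window = 5L, n_iter = 5L, min_eig = 1e-4) {
  stopifnot(length(dim(frames)) == 3)
  d <- dim(frames)
  if (d[3] < 8) stop("need at least 8 phase bins")
  if (is.null(pixel_size)) stop("pixel_size missing")
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  ref <- apply(frames, c(1, 2), mean)
  if (sd(ref) == 0) stop("texture-free sequence: motion unobservable")
  gx <- ref; gy <- ref
  gx[, 2:(nc - 1)] <- (ref[, 3:nc] - ref[, 1:(nc - 2)]) / 2
  gx[, c(1, nc)] <- 0
  gy[2:(nr - 1), ] <- (ref[3:nr, ] - ref[1:(nr - 2), ]) / 2
  gy[c(1, nr), ] <- 0
  box <- function(m) {
    M <- matrix(1, window, window)
    r <- (window - 1L) %/% 2L
    out <- matrix(0, nr, nc)
    for (dy in -r:r) for (dx in -r:r) {
      ys <- pmin(pmax(1:nr + dy, 1), nr)
      xs <- pmin(pmax(1:nc + dx, 1), nc)
      out <- out + m[ys, xs]
    }
    out
  }
  Axx <- box(gx * gx); Axy <- box(gx * gy); Ayy <- box(gy * gy)
  det <- Axx * Ayy - Axy^2
  tr <- Axx + Ayy
  lam_min <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
  low_conf <- lam_min < min_eig * max(lam_min)
  det[det <= 0] <- NA
  X <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  Y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  disp <- array(0, c(nr, nc, nb, 2))
  for (b in seq_len(nb)) {
    dx <- matrix(0, nr, nc); dy <- matrix(0, nr, nc)
    for (it in seq_len(n_iter)) {
      warped <- matrix(bilinear_sample(frames[, , b],
                                       as.vector(X + dx),
                                       as.vector(Y + dy)), nr, nc)
      err <- warped - ref
      bx <- box(gx * err); by <- box(gy * err)
      ddx <- -(Ayy * bx - Axy * by) / det
      ddy <- -(-Axy * bx + Axx * by) / det
      ddx[is.na(ddx)] <- 0; ddy[is.na(ddy)] <- 0
      # clamp single-iteration updates to keep the linearisation valid
      ddx <- pmin(pmax(ddx, -2), 2); ddy <- pmin(pmax(ddy, -2), 2)
      dx <- dx + ddx; dy <- dy + ddy
    }
    disp[, , b, 1] <- dx * pixel_size
    disp[, , b, 2] <- dy * pixel_size
  }
  # report relative to the cycle mean
  disp[, , , 1] <- disp[, , , 1] - array(apply(disp[, , , 1], c(1, 2), mean),
                                         c(nr, nc, nb))
  disp[, , , 2] <- disp[, , , 2] - array(apply(disp[, , , 2], c(1, 2), mean),
                                         c(nr, nc, nb))
  structure(list(disp = disp, low_confidence = low_conf,
                 phase_centers = attr(frames, "phase_centers") %||%
                   2 * pi * (seq_len(nb) - 0.5) / nb,
                 pixel_size = pixel_size),
            class = "motion_field")
}

#' Build a motion trajectory from per-bin displacements
#'
#' @param displacement n_bins x 2 matrix (nm), columns x/y
#' @param phase_bins bin-centre phases (rad)
#' @param anchor optional c(x, y) pixel location
#' @return object of class `motion_trajectory` with `amplitude` (nm, max
#'   distance from the cycle mean) and `direction` (principal-axis angle,
#'   rad)
#' @export
motion_trajectory <- function(displacement, phase_bins,
                              anchor = c(NA_real_, NA_real_)) {
  displacement <- as.matrix(displacement)
  stopifnot(ncol(displacement) == 2,
            nrow(displacement) == length(phase_bins))
  displacement <- sweep(displacement, 2, colMeans(displacement))
  amp <- max(sqrt(rowSums(displacement^2)))
  dir <- 0.5 * atan2(2 * mean(displacement[, 1] * displacement[, 2]),
                     mean(displacement[, 1]^2) - mean(displacement[, 2]^2))
  structure(list(phase_bins = phase_bins, displacement = displacement,
                 anchor = anchor, amplitude = amp, direction = dir),
            class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf(
    "Motion trajectory: %d phase bins, amplitude %.1f nm, direction %.2f rad\n",
    length(x$phase_bins), x$amplitude, x$direction))
  invisible(x)
}

#' Average trajectories over a 5 x 5 pixel region
#'
#' Bin-wise mean of the trajectories of all pixels in the square
#' neighbourhood centred on `anchor`, the standard noise-reduction step
#' before computing deflection.
#'
#' @param field a `motion_field` from [estimate_motion()]
#' @param anchor c(x, y), 0-based pixel location
#' @param half half-width of the neighbourhood (default 2 -> 5 x 5)
#' @return a [motion_trajectory()]
#' @export
region_average <- function(field, anchor, half = 2L) {
  stopifnot(inherits(field, "motion_field"), length(anchor) == 2)
  d <- dim(field$disp)
  xs <- anchor[1] + (-half:half); ys <- anchor[2] + (-half:half)
  if (min(xs) < 0 || min(ys) < 0 || max(xs) > d[2] - 1 || max(ys) > d[1] - 1)
    stop("anchor too close to the frame border")
  sub <- field$disp[ys + 1, xs + 1, , , drop = FALSE]
  displacement <- cbind(apply(sub[, , , 1, drop = FALSE], 3, mean),
                        apply(sub[, , , 2, drop = FALSE], 3, mean))
  motion_trajectory(displacement, field$phase_centers, anchor = anchor)
}

#' Stereocilia deflection from tip and base trajectories
#'
#' Deflection is the bin-wise vector difference between the motion of the
#' stereocilia bundle tip and its base; its amplitude is the stimulus seen
#' by the mechanotransduction channels. Swapping tip and base negates the
#' trajectory. The normalised deflection divides the amplitude by
#' `reference_amplitude` (defaults to the base amplitude).
#'
#' @param tip,base [motion_trajectory()] objects on identical phase bins
#' @param reference_amplitude nm; default `base$amplitude`
#' @param noise_floor nm; measurement floor propagated into the result
#' @return a `deflection_result`: `deflection_trajectory` (n_bins x 2, nm),
#'   `deflection_amplitude`, `normalised_deflection`, `noise_floor`
#' @export
#' @examples
#' ph <- 2 * pi * (0:15 + 0.5) / 16
#' base <- motion_trajectory(65 * sin(ph) %o% c(cos(1), sin(1)), ph)
#' tip  <- motion_trajectory(62 * sin(ph) %o% c(0, 1), ph)
#' compute_deflection(tip, base)$deflection_amplitude
compute_deflection <- function(tip, base, reference_amplitude = NULL,
                               noise_floor = 30) {
  stopifnot(inherits(tip, "motion_trajectory"),
            inherits(base, "motion_trajectory"))
  if (length(tip$phase_bins) != length(base$phase_bins) ||
      max(abs(tip$phase_bins - base$phase_bins)) > 1e-9)
    stop("tip and base use different phase bins")
  traj <- tip$displacement - base$displacement
  amp <- max(sqrt(rowSums(traj^2)))
  ref <- reference_amplitude %||% base$amplitude
  structure(list(deflection_trajectory = traj,
                 deflection_amplitude = amp,
                 normalised_deflection = if (ref > 0) amp / ref else NA_real_,
                 reference_amplitude = ref,
                 noise_floor = noise_floor,
                 phase_bins = tip$phase_bins),
            class = "deflection_result")
}

#' @export
print.deflection_result <- function(x, ...) {
  cat(sprintf(
    "Deflection: amplitude %.1f nm (normalised %.2f, floor %.0f nm)\n",
    x$deflection_amplitude, x$normalised_deflection, x$noise_floor))
  invisible(x)
}
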