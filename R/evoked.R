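#' Epoch set of evoked-potential recordings
#'
#' @param epochs matrix, repetitions x samples (volts or uV, consistent)
#' @param rate sampling rate, Hz
#' @param stimulus list with `frequency` (Hz), `level` (dB SPL),
#'   `duration` (ms), `rise_fall` (ms)
#' @return object of class `epoch_set`
#' @export
epoch_set <- function(epochs, rate,
                      stimulus = list(frequency = NA, level = NA,
                                      duration = 10, rise_fall = 1)) {
  epochs <- as.matrix(epochs)
  stopifnot(rate > 0, nrow(epochs) >= 1)
  structure(list(epochs = epochs, rate = rate, stimulus = stimulus),
            class = "epoch_set")
}

#' Band-pass filter and average evoked epochs
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, then the
#' arithmetic mean of the first `n_average` epochs. Forward-backward
#' filtering doubles the effective order but adds no phase shift, so
#' cochlear-microphonic phase is unbiased. Amplifier gain is divided out
#' explicitly.
#'
#' @param set an [epoch_set()]
#' @param band c(low, high) passband, Hz (default 300-3000 Hz)
#' @param n_average epochs to average (default all)
#' @param gain recording gain to divide out (default 1)
#' @return list with `waveform` (averaged, filtered), `rate`, `n_average`,
#'   `band`, `gain`
#' @export
preprocess_epochs <- function(set, band = c(300, 3000), n_average = NULL,
                              gain = 1) {
  stopifnot(inherits(set, "epoch_set"))
  n_rep <- nrow(set$epochs)
  if (is.null(n_average)) n_average <- n_rep
  if (n_average > n_rep) stop("n_average exceeds available epochs")
  if (band[2] >= set$rate / 2) stop("band top at or above Nyquist")
  bf <- signal::butter(4, band / (set$rate / 2), type = "pass")
  filt <- t(apply(set$epochs[seq_len(n_average), , drop = FALSE], 1,
                  function(x) signal::filtfilt(bf, x)))
  list(waveform = colMeans(filt) / gain, rate = set$rate,
       n_average = n_average, band = band, gain = gain)
}

#' Input-output function and response threshold
#'
#' Given response amplitudes at a descending series of stimulus levels,
#' the threshold is the lowest level whose amplitude reaches the
#' criterion, refined by linear interpolation between that level and the
#' next lower (sub-criterion) level. When no level reaches the criterion a
#' `not-reached` flag is set.
#'
#' The criterion is configurable in uV; the recommended default is 3x the
#' pre-stimulus noise SD of the averaged trace.
#'
#' @param levels stimulus levels, dB SPL
#' @param amplitudes response amplitudes, uV, same length
#' @param criterion uV
#' @return an `io_function`: `levels` (descending), `response_amplitudes`,
#'   `criterion`, `threshold` (dB SPL or `NA`), `threshold_reached`
#' @export
#' @examples
#' io_function_and_threshold(c(85, 75, 65, 55, 45, 35, 25),
#'                           c(10, 7, 4, 2.2, 1.4, 0.6, 0.1), criterion = 1)
io_function_and_threshold <- function(levels, amplitudes, criterion) {
  if (length(levels) < 2) stop("need at least 2 levels")
  if (length(levels) != length(amplitudes)) stop("length mismatch")
  o <- order(levels, decreasing = TRUE)
  levels <- levels[o]; amplitudes <- amplitudes[o]
  above <- amplitudes >= criterion
  if (!any(above)) {
    thr <- NA_real_; reached <- FALSE
  } else {
    reached <- TRUE
    i <- max(which(above))            # lowest level meeting the criterion
    if (i < length(levels) && amplitudes[i + 1] < criterion &&
        amplitudes[i] > amplitudes[i + 1]) {
      # interpolate the level at which the amplitude crosses the criterion
      f <- (criterion - amplitudes[i + 1]) /
        (amplitudes[i] - amplitudes[i + 1])
      thr <- levels[i + 1] + f * (levels[i] - levels[i + 1])
    } else thr <- levels[i]
  }
  structure(list(levels = levels, response_amplitudes = amplitudes,
                 criterion = criterion, threshold = thr,
                 threshold_reached = reached),
            class = "io_function")
}

#' @export
print.io_function <- function(x, ...) {
  cat(sprintf("I/O function over %d levels; threshold %s dB SPL\n",
              length(x$levels),
              if (x$threshold_reached) sprintf("%.1f", x$threshold)
              else "not reached"))
  invisible(x)
}

# trim a window to a whole number of f0 cycles
whole_cycle_window <- function(n, rate, f0) {
  n_cyc <- floor(n * f0 / rate)
  if (n_cyc < 1) stop("f0 not resolvable: window shorter than one cycle")
  round(n_cyc * rate / f0)
}

# single-frequency Fourier component: c = (2/n) sum x exp(-i 2 pi f0 t)
fourier_component <- function(x, rate, f0) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  (2 / n) * sum(x * exp(-2i * pi * f0 * t))
}

#' Cochlear microphonic amplitude and phase
#'
#' Amplitude and phase of the stimulus-frequency Fourier component of the
#' recorded waveform, trimmed to a whole number of stimulus cycles
#' (rectangular window thereafter). Phase is reported relative to the
#' loudspeaker drive voltage when a drive reference is supplied.
#' Responses whose amplitude falls below `exclusion_uv` are flagged as
#' excluded from phase analysis.
#'
#' @param waveform recorded trace, uV
#' @param rate sampling rate, Hz
#' @param f0 stimulus frequency, Hz
#' @param drive_reference optional drive-voltage trace, same rate/length
#' @param exclusion_uv peak-response exclusion rule for phase (default 10)
#' @return list `amplitude` (uV), `phase` (rad; relative to drive if given),
#'   `phase_excluded`, `n_cycles`
#' @export
#' @examples
#' t <- (0:9999) / 1e4
#' cm_component(50 * sin(2 * pi * 200 * t), 1e4, 200)$amplitude
cm_component <- function(waveform, rate, f0, drive_reference = NULL,
                         exclusion_uv = 10) {
  n <- whole_cycle_window(length(waveform), rate, f0)
  x <- waveform[seq_len(n)]
  cc <- fourier_component(x, rate, f0)
  amp <- Mod(cc); ph <- Arg(cc)
  if (!is.null(drive_reference)) {
    cd <- fourier_component(drive_reference[seq_len(n)], rate, f0)
    ph <- Arg(cc / cd)
  }
  list(amplitude = amp, phase = ph,
       phase_excluded = amp < exclusion_uv,
       n_cycles = round(n * f0 / rate))
}

#' Summating potential
#'
#' Sustained (DC) deviation of the cochlear potential during sound: the
#' mean of the waveform over whole stimulus cycles within the stimulus-on
#' window, minus the pre-stimulus baseline mean. The SP can be positive or
#' negative; group comparisons use the absolute value, which is returned
#' alongside.
#'
#' @param waveform trace, uV
#' @param rate Hz
#' @param f0 stimulus frequency, Hz
#' @param stimulus_on c(start, end) of the stimulus window, s
#' @param baseline c(start, end) of the pre-stimulus segment, s; must be
#'   non-empty
#' @return list `sp` (signed, uV), `sp_abs`
#' @export
summating_potential <- function(waveform, rate, f0,
                                stimulus_on = c(0, length(waveform) / rate),
                                baseline = NULL) {
  i_on <- max(1, floor(stimulus_on[1] * rate) + 1)
  i_off <- min(length(waveform), floor(stimulus_on[2] * rate))
  seg <- waveform[i_on:i_off]
  n <- whole_cycle_window(length(seg), rate, f0)
  base_mean <- 0
  if (!is.null(baseline)) {
    b0 <- max(1, floor(baseline[1] * rate) + 1)
    b1 <- min(length(waveform), floor(baseline[2] * rate))
    if (b1 < b0) stop("baseline segment missing or empty")
    base_mean <- mean(waveform[b0:b1])
  }
  sp <- mean(seg[seq_len(n)]) - base_mean
  list(sp = sp, sp_abs = abs(sp))
}

#' Tuning curve and best frequency
#'
#' Amplitude versus stimulus frequency; the best frequency is the one
#' producing the maximal response (ties resolved to the lowest frequency
#' and flagged).
#'
#' @param frequencies Hz
#' @param amplitudes uV, same length
#' @return list `curve` (data.frame frequency/amplitude, sorted),
#'   `best_frequency`, `tie`
#' @export
#' @examples
#' tuning_curve(c(100, 200, 400), c(3, 9, 4))$best_frequency
tuning_curve <- function(frequencies, amplitudes) {
  if (length(frequencies) < 2) stop("need at least 2 frequencies")
  o <- order(frequencies)
  curve <- data.frame(frequency = frequencies[o], amplitude = amplitudes[o])
  mx <- max(curve$amplitude)
  hit <- which(curve$amplitude == mx)
  list(curve = curve, best_frequency = curve$frequency[hit[1]],
       tie = length(hit) > 1)
}

#' Distortion-product otoacoustic emission components
#'
#' Fourier amplitudes at the two primaries `f1`, `f2` (frequency ratio
#' 1.2) and at the cubic distortion product `2*f1 - f2`, computed on a
#' window trimmed to whole cycles of the frequency spacing so that all
#' three components fall on exact Fourier frequencies. A leakage check
#' rejects windows too short to resolve the components.
#'
#' @param mic_waveform microphone trace
#' @param rate Hz
#' @param f1,f2 primary frequencies, Hz (`f2/f1` must be 1.2 within
#'   `ratio_tol`)
#' @param ratio_tol tolerance on the primary ratio (default 0.01)
#' @return data.frame with `component`, `frequency`, `amplitude`
#' @export
dpoae_extract <- function(mic_waveform, rate, f1, f2, ratio_tol = 0.01) {
  if (abs(f2 / f1 - 1.2) > ratio_tol)
    stop("primary ratio f2/f1 = ", round(f2 / f1, 3),
         "; expected 1.2")
  fdp <- 2 * f1 - f2
  if (fdp <= 0) stop("2*f1 - f2 not resolvable")
  df <- gcd_freq(c(f1, f2, fdp))
  n <- floor(length(mic_waveform) * df / rate) * round(rate / df)
  if (n < round(rate / df) || n > length(mic_waveform))
    stop("spectral leakage: window shorter than one cycle of the ",
         "component spacing (", df, " Hz); use at least ",
         ceiling(rate / df), " samples")
  x <- mic_waveform[seq_len(n)]
  comp <- c(f1 = f1, f2 = f2, dp = fdp)
  amp <- vapply(comp, function(f) Mod(fourier_component(x, rate, f)), 0)
  data.frame(component = c("f1", "f2", "2f1-f2"),
             frequency = as.numeric(comp), amplitude = as.numeric(amp))
}

# greatest common divisor of a set of frequencies (to ~1e-6 Hz)
gcd_freq <- function(f) {
  g2 <- function(a, b) { while (b > 1e-6) { t <- a %% b; a <- b; b <- t }; a }
  Reduce(g2, f)
}

#' Peak latency of an averaged response
#'
#' Latency of the largest (absolute) peak after stimulus onset — the
#' convention used for brainstem-response delay comparisons; no wave
#' labelling is attempted.
#'
#' @param waveform averaged trace
#' @param rate Hz
#' @param onset stimulus onset time, s
#' @return latency in s from onset
#' @export
abr_peak_latency <- function(waveform, rate, onset = 0) {
  i0 <- max(1, floor(onset * rate) + 1)
  seg <- waveform[i0:length(waveform)]
  (which.max(abs(seg)) - 1) / rate
}
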