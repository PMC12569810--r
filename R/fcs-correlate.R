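#' Binned photon-count trace
#'
#' Container for one FCS recording: non-negative integer counts per bin, the
#' bin width, the pre-injection background rate measured for the same
#' preparation, and the recording site (three tectorial-membrane positions
#' and one endolymph position per preparation).
#'
#' @param counts non-negative integer photon counts per bin
#' @param bin_width bin width, s
#' @param background_rate photons/s measured before indicator injection
#' @param site_label one of `"TM1"`, `"TM2"`, `"TM3"`, `"EndoL"`
#' @param repetition_index which of the consecutive repeats this trace is
#' @param ground_truth optional list of simulator ground truth
#' @return object of class `photon_trace`
#' @export
photon_trace <- function(counts, bin_width, background_rate = 0,
                         site_label = "TM1", repetition_index = 1L,
                         ground_truth = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!site_label %in% c("TM1", "TM2", "TM3", "EndoL"))
    stop("site_label must be one of TM1, TM2, TM3, EndoL")
  structure(list(counts = counts, bin_width = bin_width,
                 duration = length(counts) * bin_width,
                 background_rate = background_rate,
                 site_label = site_label,
                 repetition_index = as.integer(repetition_index),
                 ground_truth = ground_truth),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf(
    "Photon trace [%s, rep %d]: %d bins of %.3g s, mean rate %.3g kHz\n",
    x$site_label, x$repetition_index, length(x$counts), x$bin_width,
    mean(x$counts) / x$bin_width / 1000))
  invisible(x)
}

# multi-tau lag grid: `per_octave` linearly spaced lags, then lag spacing
# doubled every octave, up to max_lag (in bins)
multi_tau_lags <- function(n_bins, per_octave = 16L,
                           max_lag = floor(n_bins / 4)) {
  lags <- seq_len(min(per_octave, max_lag))
  step <- 2L
  top <- per_octave
  while (top < max_lag) {
    nxt <- seq(top + step, min(2L * top, max_lag), by = step)
    lags <- c(lags, nxt)
    top <- 2L * top
    step <- 2L * step
  }
  unique(lags[lags >= 1 & lags <= max_lag])
}

#' Autocorrelation of a photon trace
#'
#' Computes the normalised fluctuation autocorrelation
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2` with `dF = F - <F>`, evaluated at a
#' set of positive lags. Two schemes are provided: `"direct"` evaluates the
#' exact estimator at every lag up to `max_lag`; `"multi_tau"` evaluates the
#' same exact estimator on a quasi-logarithmic grid (16 lags per octave,
#' lag spacing doubling each octave, smallest lag one bin), the standard
#' FCS practice for traces spanning many decades. The two schemes agree to
#' machine precision at shared lags.
#'
#' @param trace a [photon_trace()]
#' @param scheme `"multi_tau"` (default) or `"direct"`
#' @param max_lag largest lag in bins (default `n/4`)
#' @param per_octave lags per octave for the multi-tau grid
#' @return a `correlation_curve`: list with `lags` (s), `G`,
#'   `mean_count_rate` (photons/s), `n_repetitions_averaged`
#' @export
#' @examples
#' tr <- simulate_photon_trace(fcs_sim_config(duration = 1, seed = 3))
#' g <- autocorrelate(tr)
#' head(cbind(g$lags, g$G))
autocorrelate <- function(trace, scheme = c("multi_tau", "direct"),
                          max_lag = NULL, per_octave = 16L) {
  stopifnot(inherits(trace, "photon_trace"))
  scheme <- match.arg(scheme)
  x <- trace$counts
  n <- length(x)
  if (n < 2) stop("trace must have at least 2 bins")
  m <- mean(x)
  if (m == 0) stop("zero-mean trace: G normalisation undefined")
  if (is.null(max_lag)) max_lag <- max(1L, floor(n / 4))
  max_lag <- min(max_lag, n - 1L)
  lags <- switch(scheme,
                 direct = seq_len(max_lag),
                 multi_tau = multi_tau_lags(n, per_octave, max_lag))
  G <- acov_lags_cpp(as.numeric(x), as.integer(lags)) / m^2
  correlation_curve(lags * trace$bin_width, G,
                    mean_count_rate = m / trace$bin_width,
                    n_repetitions_averaged = 1L)
}

#' Correlation curve container
#'
#' @param lags lag times, s; strictly increasing and positive
#' @param G dimensionless correlation amplitudes
#' @param mean_count_rate photons/s
#' @param n_repetitions_averaged number of recordings averaged into `G`
#' @param G_se optional pointwise standard error across repetitions
#' @return object of class `correlation_curve`
#' @export
correlation_curve <- function(lags, G, mean_count_rate,
                              n_repetitions_averaged = 1L, G_se = NULL) {
  if (any(diff(lags) <= 0) || any(lags <= 0))
    stop("lags must be strictly increasing and positive")
  if (any(!is.finite(G))) stop("G must be finite")
  structure(list(lags = as.numeric(lags), G = as.numeric(G),
                 mean_count_rate = mean_count_rate,
                 n_repetitions_averaged = as.integer(n_repetitions_averaged),
                 G_se = G_se),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "Correlation curve: %d lags (%.2g..%.2g s), G(first) = %.4g, %.3g kHz, %d rep(s)\n",
    length(x$lags), min(x$lags), max(x$lags), x$G[1],
    x$mean_count_rate / 1000, x$n_repetitions_averaged))
  invisible(x)
}

#' Average correlation curves over repetitions
#'
#' Repeated recordings at one location are averaged pointwise; the mean
#' count rate is averaged and the pointwise standard error across
#' repetitions is retained for use as fit weights.
#'
#' @param curves list of `correlation_curve` objects on identical lag grids
#' @return a single `correlation_curve`
#' @export
average_correlations <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "correlation_curve")))
  lags <- curves[[1]]$lags
  for (cv in curves)
    if (length(cv$lags) != length(lags) ||
        max(abs(cv$lags - lags)) > 1e-12 * max(lags))
      stop("mismatched lag grids")
  Gm <- sapply(curves, function(cv) cv$G)
  Gm <- matrix(Gm, nrow = length(lags))
  k <- length(curves)
  se <- if (k >= 3) apply(Gm, 1, sd) / sqrt(k) else NULL
  correlation_curve(lags, rowMeans(Gm),
                    mean_count_rate =
                      mean(vapply(curves, `[[`, 0, "mean_count_rate")),
                    n_repetitions_averaged = k, G_se = se)
}
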