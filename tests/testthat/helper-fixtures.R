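# small fixtures shared across test files; everything is generated in code

# quick photon trace with modest duration for unit tests
quick_trace <- function(seed = 1, duration = 1, ...) {
  simulate_photon_trace(fcs_sim_config(duration = duration, seed = seed, ...))
}

# correlation curves for one simulated multi-repetition experiment
rep_curves <- function(seed, n_rep = 6, duration = 10, ...) {
  lapply(seq_len(n_rep), function(r) {
    autocorrelate(simulate_photon_trace(
      fcs_sim_config(duration = duration, seed = 1000 * seed + r, ...)))
  })
}

# random simple polygon: jittered radial star around a centre
random_polygon <- function(n = 9, centre = c(0, 0), radius = 10) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.4, 1) * radius
  cbind(x = centre[1] + r * cos(ang), y = centre[2] + r * sin(ang))
}

# random open polyline
random_polyline <- function(n = 6, start = c(0, 0), step = 4) {
  steps <- matrix(runif(2 * (n - 1), -step, step), ncol = 2)
  cbind(x = start[1] + cumsum(c(0, steps[, 1])),
        y = start[2] + cumsum(c(0, steps[, 2])))
}

# dense-sampling oracle for the minimal distance between a polygon
# boundary and a polyline: sample many points along every segment of both
# and take the minimal pairwise point distance (converges from above)
dense_min_distance <- function(poly, line, n_per_edge = 200) {
  sample_edges <- function(p1, p2) {
    t <- seq(0, 1, length.out = n_per_edge)
    do.call(rbind, lapply(seq_len(nrow(p1)), function(i) {
      cbind(p1[i, 1] + t * (p2[i, 1] - p1[i, 1]),
            p1[i, 2] + t * (p2[i, 2] - p1[i, 2]))
    }))
  }
  n <- nrow(poly)
  a <- sample_edges(poly, poly[c(2:n, 1), , drop = FALSE])
  m <- nrow(line)
  b <- sample_edges(line[-m, , drop = FALSE], line[-1, , drop = FALSE])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

# shoelace (continuous) polygon area, the oracle for pixel-count areas
shoelace_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# direct (brute-force) normalised autocorrelation, the oracle for the
# compiled correlator: plain R loop over lags
acov_oracle <- function(x, lags) {
  n <- length(x); m <- mean(x)
  vapply(lags, function(k) {
    sum((x[1:(n - k)] - m) * (x[(k + 1):n] - m)) / (n - k) / m^2
  }, 0)
}
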