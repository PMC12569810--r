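test_that("multi-tau and direct estimators agree with the R oracle", {
  set.seed(1)
  x <- rpois(100, 20)
  tr <- photon_trace(x, bin_width = 1e-3)
  d <- autocorrelate(tr, scheme = "direct")
  m <- autocorrelate(tr, scheme = "multi_tau")
  shared <- match(m$lags, d$lags)
  expect_false(anyNA(shared))
  expect_lt(max(abs(m$G - d$G[shared]) / pmax(abs(d$G[shared]), 1e-15)),
            1e-12)
  # against the plain-R brute-force oracle
  lags_bins <- round(d$lags / tr$bin_width)
  expect_equal(d$G, acov_oracle(x, lags_bins), tolerance = 1e-12)

  # larger trace: relative agreement at shared lags below 1e-9
  set.seed(2)
  x2 <- rpois(10000, 15)
  tr2 <- photon_trace(x2, bin_width = 1e-4)
  d2 <- autocorrelate(tr2, scheme = "direct")
  m2 <- autocorrelate(tr2, scheme = "multi_tau")
  s2 <- match(m2$lags, d2$lags)
  expect_lt(max(abs(m2$G - d2$G[s2]) / pmax(abs(d2$G[s2]), 1e-15)), 1e-9)
})

test_that("closed-form correlations: constant and alternating traces", {
  expect_error(autocorrelate(photon_trace(rep(0, 50), 1e-3)), "zero-mean")
  const <- autocorrelate(photon_trace(rep(7, 64), 1e-3), scheme = "direct")
  expect_true(all(abs(const$G) < 1e-14))
  # alternating 0/2: delta F = -1,+1,... so G(odd) = -1, G(even) = +1
  alt <- autocorrelate(photon_trace(rep(c(0, 2), 32), 1e-3),
                       scheme = "direct", max_lag = 10)
  lag_bins <- round(alt$lags / 1e-3)
  expect_equal(alt$G, ifelse(lag_bins %% 2 == 1, -1, 1), tolerance = 1e-12)
})

test_that("curve averaging is idempotent, linear and variance-reducing", {
  cv <- autocorrelate(quick_trace(seed = 3, duration = 0.5))
  avg7 <- average_correlations(replicate(7, cv, simplify = FALSE))
  expect_equal(avg7$G, cv$G)
  expect_equal(avg7$n_repetitions_averaged, 7L)
  plus <- correlation_curve(cv$lags, rep(1, length(cv$lags)), 1e5)
  minus <- correlation_curve(cv$lags, rep(-1, length(cv$lags)), 1e5)
  expect_equal(average_correlations(list(plus, minus))$G,
               rep(0, length(cv$lags)))
  # variance of the mean of 8 noisy realisations shrinks ~8x
  set.seed(4)
  noisy <- replicate(200, correlation_curve(1:10 * 1e-3, rnorm(10), 1e5),
                     simplify = FALSE)
  means8 <- sapply(seq(1, 200, by = 8), function(i)
    average_correlations(noisy[i:(i + 7)])$G[1])
  expect_equal(var(means8) * 8, 1, tolerance = 0.5)
  # mismatched grids rejected
  other <- correlation_curve(2:11 * 1e-3, rnorm(10), 1e5)
  expect_error(average_correlations(list(noisy[[1]], other)), "lag grids")
})

test_that("model_G limits and shape match the analytic form", {
  expect_equal(model_G(0, N = 5), 1 / 5)
  # lateral-only limit: t = tau_D, alpha = 1, S -> infinity gives 1/(2N)
  expect_equal(model_G(1e-3, N = 4, tau_D = 1e-3, alpha = 1, S = 1e9),
               1 / 8, tolerance = 1e-9)
  # alpha = 1 coincides with the standard 3-D diffusion model
  t <- 10^seq(-6, 2, length.out = 50)
  standard_3d <- function(t, N, tau, S)
    1 / N / (1 + t / tau) / sqrt(1 + t / (S^2 * tau))
  expect_equal(model_G(t, N = 5, tau_D = 1e-3, alpha = 1, S = 5),
               standard_3d(t, 5, 1e-3, 5), tolerance = 1e-12)
  # strictly decreasing and -> 0 for T = 0
  g <- model_G(t, N = 5, tau_D = 1e-3, alpha = 0.7, S = 5)
  expect_true(all(diff(g) < 0))
  expect_lt(g[length(g)], 1e-3 * g[1])
})

test_that("noiseless model curves are recovered to 0.1 percent", {
  lag <- 10^seq(-5, 0.5, length.out = 80)
  g <- model_G(lag, N = 5, tau_D = 1e-3, alpha = 0.8, S = 5)
  ft <- fit_anomalous_diffusion(correlation_curve(lag, g, 1e5), S = 5,
                                allow_triplet = FALSE, fit_offset = FALSE)
  expect_equal(ft$N, 5, tolerance = 1e-3)
  expect_equal(ft$tau_D, 1e-3, tolerance = 1e-3)
  expect_equal(ft$alpha, 0.8, tolerance = 1e-3)
  expect_true(ft$converged)
  expect_true(ft$S_fixed)
})

test_that("triplet term is included only when appropriate", {
  lag <- 10^seq(-6.5, 0, length.out = 90)
  # curve with a genuine fast triplet component
  g_trip <- model_G(lag, N = 5, tau_D = 1e-3, alpha = 1, S = 5,
                    T = 0.2, tau_T = 1e-5)
  ft1 <- fit_anomalous_diffusion(correlation_curve(lag, g_trip, 1e5),
                                 S = 5, fit_offset = FALSE)
  expect_true(ft1$included_triplet)
  expect_equal(ft1$triplet_fraction, 0.2, tolerance = 0.05)
  expect_equal(ft1$triplet_tau, 1e-5, tolerance = 0.1)
  # clean curve: the selection rule declines the triplet term
  g_plain <- model_G(lag, N = 5, tau_D = 1e-3, alpha = 1, S = 5)
  ft0 <- fit_anomalous_diffusion(correlation_curve(lag, g_plain, 1e5),
                                 S = 5, fit_offset = FALSE)
  expect_false(ft0$included_triplet)
})

test_that("molecular brightness follows the rate/N definition", {
  tr <- quick_trace(seed = 6, duration = 1)
  ft <- fit_anomalous_diffusion(autocorrelate(tr), S = 5)
  b <- molecular_brightness(tr, ft)
  mean_rate <- mean(tr$counts) / tr$bin_width
  expect_equal(b$brightness,
               (mean_rate - tr$background_rate) / ft$N)
  # background equal to the mean rate gives zero brightness; a background
  # exceeding it floors the corrected rate at zero with a warning
  tr2 <- tr; tr2$background_rate <- mean_rate
  expect_equal(molecular_brightness(tr2, ft)$brightness, 0)
  tr2$background_rate <- mean_rate * 1.5
  expect_warning(b0 <- molecular_brightness(tr2, ft), "floored")
  expect_equal(b0$brightness, 0)
  # the in-vivo scale: 100 kHz over N = 10 is 10 kHz per molecule
  tr3 <- tr; tr3$background_rate <- 0
  ft3 <- ft; ft3$N <- 10
  tr3$counts <- rep(1e5 * tr3$bin_width, length(tr3$counts))
  expect_equal(molecular_brightness(tr3, ft3)$brightness_khz, 10)
})

test_that("site profiles order sites and surface missing ones", {
  mk <- function(site, b) structure(list(brightness = b,
                                         brightness_khz = b / 1000,
                                         corrected_rate = b * 5, N_used = 5,
                                         site_label = site, floored = FALSE),
                                    class = "brightness_result")
  prof <- site_profile(list(mk("EndoL", 1000), mk("TM2", 3000),
                            mk("TM1", 3500), mk("TM3", 2800)))
  expect_equal(prof$site, c("TM1", "TM2", "TM3", "EndoL"))
  expect_true(all(prof$measured))
  prof2 <- site_profile(list(mk("TM1", 3000)))
  expect_equal(sum(prof2$measured), 1)
  expect_false(prof2$measured[4])
  expect_error(site_profile(list(mk("TM1", 1), mk("TM1", 2))), "duplicate")
})

test_that("a simulated experiment recovers N, tau_D and brightness", {
  # single moderately long trace; acceptance covers the full 50-trace sweep
  cfg <- fcs_sim_config(n_effective = 5, duration = 20, bin_width = 1e-3,
                        diffusion_coefficient = 1, seed = 77)
  tr <- simulate_photon_trace(cfg)
  ft <- fit_anomalous_diffusion(autocorrelate(tr), S = 5)
  expect_true(ft$converged)
  expect_equal(ft$N, cfg$n_effective, tolerance = 0.15)
  expect_equal(ft$tau_D, cfg$tau_D, tolerance = 0.2)
  b <- molecular_brightness(tr, ft)
  expect_equal(b$brightness, cfg$brightness_cpm, tolerance = 0.1)
})
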