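test_that("epoch preprocessing filters and averages correctly", {
  rate <- 2e4
  t <- (0:4095) / rate
  epoch <- 5 * sin(2 * pi * 1000 * t) + 3 * sin(2 * pi * 50 * t)
  set <- epoch_set(rbind(epoch, epoch, epoch), rate)
  out <- preprocess_epochs(set, band = c(300, 3000))
  one <- preprocess_epochs(epoch_set(rbind(epoch), rate), band = c(300, 3000))
  # identical epochs: the average equals one filtered epoch
  expect_equal(out$waveform, one$waveform)
  # in-band 1 kHz passes nearly unchanged; 50 Hz drift removed
  mid <- 1000:3000
  amp1k <- Mod(cochleametrics:::fourier_component(out$waveform[mid], rate, 1000))
  amp50 <- Mod(cochleametrics:::fourier_component(out$waveform[mid], rate, 50))
  expect_equal(amp1k, 5, tolerance = 0.02)
  expect_lt(amp50, 0.2)
  expect_error(preprocess_epochs(set, band = c(300, 2e4)), "Nyquist")
  expect_error(preprocess_epochs(set, n_average = 5), "exceeds")

  # white-noise averaging: residual RMS shrinks ~ 1/sqrt(n)
  set.seed(20)
  noise <- matrix(rnorm(100 * 2000), 100, 2000)
  pre <- preprocess_epochs(epoch_set(noise, rate), band = c(300, 3000))
  single <- preprocess_epochs(epoch_set(noise[1, , drop = FALSE], rate),
                              band = c(300, 3000))
  expect_equal(sd(pre$waveform) * sqrt(100), sd(single$waveform),
               tolerance = 0.25)
})

test_that("threshold interpolation follows the criterion crossing", {
  levels <- c(85, 75, 65, 55, 45, 35, 25)
  amps <- c(10, 6, 3.5, 2, 1.2, 0.6, 0.1)
  io <- io_function_and_threshold(levels, amps, criterion = 1)
  # crossing between 35 (0.6) and 45 (1.2): 35 + 10 * (1 - 0.6)/(1.2 - 0.6)
  expect_equal(io$threshold, 35 + 10 * (1 - 0.6) / (1.2 - 0.6))
  expect_true(io$threshold_reached)
  # all below criterion: not reached
  io2 <- io_function_and_threshold(levels, amps, criterion = 100)
  expect_false(io2$threshold_reached)
  expect_true(is.na(io2$threshold))
  # criterion 0: the lowest tested level
  expect_equal(io_function_and_threshold(levels, amps, 0)$threshold, 25)
  # monotonicity: raising the criterion never lowers the threshold
  crits <- c(0.2, 0.5, 1, 2, 5, 9)
  thr <- sapply(crits, function(cr)
    io_function_and_threshold(levels, amps, cr)$threshold)
  expect_true(all(diff(thr) >= 0))
  expect_error(io_function_and_threshold(85, 10, 1), "2 levels")
})

test_that("CM amplitude and phase are exact for pure tones", {
  rate <- 1e4; f0 <- 200
  t <- (0:(rate / 5 - 1)) / rate
  w <- 50 * sin(2 * pi * f0 * t + 0.9)
  drive <- sin(2 * pi * f0 * t)
  cm <- cm_component(w, rate, f0, drive_reference = drive)
  expect_equal(cm$amplitude, 50, tolerance = 1e-9)
  expect_equal(cm$phase, 0.9, tolerance = 1e-9)
  expect_false(cm$phase_excluded)
  # amplitude invariant to whole-cycle window shifts; phase advances
  # linearly with a known time offset
  k <- rate / f0          # one cycle in samples
  w2 <- 50 * sin(2 * pi * f0 * (t + 3 * k / rate) + 0.9)
  cm2 <- cm_component(w2, rate, f0, drive_reference = drive)
  expect_equal(cm2$amplitude, 50, tolerance = 1e-9)
  expect_equal(cm2$phase, 0.9, tolerance = 1e-9)  # 3 whole cycles: no shift
  dt_off <- 1.25e-3       # quarter cycle
  w3 <- 50 * sin(2 * pi * f0 * (t + dt_off) + 0.9)
  cm3 <- cm_component(w3, rate, f0, drive_reference = drive)
  expect_equal((cm3$phase - cm$phase) %% (2 * pi), pi / 2, tolerance = 1e-6)
  # small responses flagged by the 10 uV exclusion rule
  expect_true(cm_component(w / 10, rate, f0)$phase_excluded)
  expect_error(cm_component(w[1:10], rate, f0), "resolvable")
})

test_that("CM amplitude is unbiased under noise within Monte-Carlo error", {
  rate <- 1e4; f0 <- 200; n <- 2000
  set.seed(30)
  amps <- replicate(100, {
    w <- synth_evoked_waveform(f0, ac_amplitude = 50, dc_offset = 5,
                               noise_sd = 10, duration = n / rate,
                               rate = rate, seed = sample.int(1e6, 1))
    cm_component(w$waveform, rate, f0)$amplitude
  })
  # bias below 3 standard errors of the Monte-Carlo mean
  expect_lt(abs(mean(amps) - 50), 3 * sd(amps) / sqrt(100))
})

test_that("summating potential sign convention and whole-cycle zeroing", {
  rate <- 1e4; f0 <- 200
  t <- (0:1999) / rate
  s <- 40 * sin(2 * pi * f0 * t)
  expect_equal(summating_potential(s + 10, rate, f0)$sp, 10,
               tolerance = 1e-9)
  out <- summating_potential(s - 10, rate, f0)
  expect_equal(out$sp, -10, tolerance = 1e-9)
  expect_equal(out$sp_abs, 10, tolerance = 1e-9)
  # any zero-mean periodic waveform over whole cycles gives zero
  sq <- rep(c(1, 1, -1, -1), 500)
  expect_equal(summating_potential(sq, rate, rate / 4)$sp, 0,
               tolerance = 1e-12)
  # baseline subtraction
  w <- c(rep(2, 500), s + 12)
  out2 <- summating_potential(w, rate, f0, stimulus_on = c(0.05, 0.25),
                              baseline = c(0, 0.05))
  expect_equal(out2$sp, 10, tolerance = 1e-9)
  expect_error(summating_potential(w, rate, f0, baseline = c(0.5, 0.4)),
               "baseline")
})

test_that("tuning curves pick the maximal response", {
  freqs <- seq(60, 820, by = 20)
  amps <- exp(-(freqs - 200)^2 / (2 * 80^2))
  tc <- tuning_curve(freqs, amps)
  expect_equal(tc$best_frequency, 200)
  expect_false(tc$tie)
  # monotone rising: best = highest tested
  expect_equal(tuning_curve(freqs, freqs)$best_frequency, 820)
  # ties resolved to the lowest frequency and flagged
  tc2 <- tuning_curve(c(100, 200, 300), c(5, 9, 9))
  expect_equal(tc2$best_frequency, 200)
  expect_true(tc2$tie)
})

test_that("DPOAE extraction sees cubic intermodulation growing with epsilon", {
  rate <- 5e4
  t <- (0:49999) / rate
  f1 <- 1000; f2 <- 1200
  x <- sin(2 * pi * f1 * t) + 0.8 * sin(2 * pi * f2 * t)
  # clean primaries: distortion product at the noise floor
  clean <- dpoae_extract(x, rate, f1, f2)
  expect_lt(clean$amplitude[clean$component == "2f1-f2"], 1e-9)
  # cubic nonlinearity: 2f1-f2 amplitude = (3/4) eps a1^2 a2, linear in eps
  eps <- c(0.01, 0.02, 0.04)
  dp <- sapply(eps, function(e) {
    d <- dpoae_extract(x + e * x^3, rate, f1, f2)
    d$amplitude[d$component == "2f1-f2"]
  })
  expect_equal(dp, 0.75 * eps * 1^2 * 0.8, tolerance = 0.02)
  expect_equal(dp[2] / dp[1], 2, tolerance = 0.02)
  # wrong primary ratio rejected
  expect_error(dpoae_extract(x, rate, 1000, 1500), "1.2")
})

test_that("peak latency is measured from stimulus onset", {
  rate <- 1e4
  w <- c(rep(0, 100), dnorm(seq(-3, 3, length.out = 201)))
  expect_equal(abr_peak_latency(w, rate, onset = 0.005),
               (100 + 100 - 50) / rate)
})
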