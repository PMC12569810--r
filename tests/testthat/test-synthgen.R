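test_that("fBm paths have the right mean-squared-displacement scaling", {
  # MSD(t) = 2 D t^alpha per axis; check the log-log slope over many paths
  for (alpha in c(0.5, 0.75, 1.0)) {
    set.seed(42)
    n_paths <- 10000
    n_steps <- 64
    dt <- 1e-3
    D <- 1
    inc <- replicate(n_paths, cochleametrics:::fgn_increments(n_steps, H = alpha / 2,
                                             dt = dt, D = D))
    pos <- apply(inc, 2, cumsum)
    lags <- c(1, 2, 4, 8, 16, 32)
    msd <- vapply(lags, function(k) {
      d <- pos[k + seq_len(n_steps - k), , drop = FALSE] -
        pos[seq_len(n_steps - k), , drop = FALSE]
      mean(d^2)
    }, 0)
    slope <- coef(lm(log(msd) ~ log(lags * dt)))[2]
    expect_equal(unname(slope), alpha, tolerance = 0.05 / alpha)
    # absolute level for the Brownian case: MSD(t) = 2 D t
    if (alpha == 1)
      expect_equal(msd[1], 2 * D * dt, tolerance = 0.05)
  }
})

test_that("degenerate diffusion gives constant paths and alpha is validated", {
  cfg <- fcs_sim_config(diffusion_coefficient = 0, n_molecules = 3,
                        duration = 0.01, bin_width = 1e-3, seed = 5)
  p <- simulate_fbm_paths(cfg)
  expect_true(all(apply(p$paths, c(2, 3), function(v) max(v) - min(v)) == 0))
  expect_error(fcs_sim_config(alpha = 0), "alpha")
  expect_error(fcs_sim_config(alpha = 1.2), "alpha")
  expect_error(fcs_sim_config(box_size = 1, beam_waist_xy = 0.25),
               "box_size")
  expect_error(simulate_fbm_paths(cfg, n_steps = 3e7), "limit")
})

test_that("generators are deterministic under a fixed seed", {
  t1 <- quick_trace(seed = 7, duration = 0.2)
  t2 <- quick_trace(seed = 7, duration = 0.2)
  expect_identical(t1$counts, t2$counts)
  p1 <- render_section_phantom(section_phantom_config(seed = 3))
  p2 <- render_section_phantom(section_phantom_config(seed = 3))
  expect_identical(p1$image, p2$image)
  m1 <- render_motion_sequence(motion_phantom_config(seed = 2))
  m2 <- render_motion_sequence(motion_phantom_config(seed = 2))
  expect_identical(m1$stream$records, m2$stream$records)
  b1 <- synth_brightness_table(brightness_table_config(seed = 9))
  b2 <- synth_brightness_table(brightness_table_config(seed = 9))
  expect_identical(b1, b2)
  w1 <- synth_evoked_waveform(200, seed = 4)
  w2 <- synth_evoked_waveform(200, seed = 4)
  expect_identical(w1$waveform, w2$waveform)
})

test_that("photon trace mean rate matches the analytic expectation", {
  # pure background at the in-vivo working count rate
  cfg <- fcs_sim_config(background_rate = 1e5, brightness_true = 0,
                        n_molecules = 1, duration = 10, seed = 11)
  tr <- simulate_photon_trace(cfg)
  rate <- mean(tr$counts) / tr$bin_width
  expect_equal(rate, 1e5, tolerance = 0.02)
  g <- autocorrelate(tr)
  expect_lt(max(abs(g$G)), 5e-3)  # flat correlation: no fluctuations

  # diffusing molecules: empirical rate within 2% of <W>-based expectation
  # (many molecules so number fluctuations stay below the tolerance)
  cfg2 <- fcs_sim_config(n_effective = 20, duration = 20, seed = 12)
  tr2 <- simulate_photon_trace(cfg2)
  rate2 <- mean(tr2$counts) / tr2$bin_width
  expect_equal(rate2, cfg2$mean_rate, tolerance = 0.02)
})

test_that("an immobile molecule at beam centre emits Poisson counts", {
  cfg <- fcs_sim_config(diffusion_coefficient = 0, n_molecules = 1,
                        background_rate = 0, brightness_true = 5e4,
                        duration = 5, bin_width = 1e-3, seed = 13)
  tr <- simulate_photon_trace(cfg, initial_positions = matrix(0, 1, 3))
  # counts are Poisson with rate = brightness at the beam centre
  expect_equal(mean(tr$counts), 50, tolerance = 0.02)
  expect_equal(var(tr$counts) / mean(tr$counts), 1, tolerance = 0.1)
})

test_that("section phantom hits its configured geometry exactly", {
  cfg <- section_phantom_config(gap_true = 6, tm_area_true = 2000,
                                ooc_area_true = 3000, ooc_width_true = 90,
                                pixel_size = 0.5, seed = 21)
  ph <- render_section_phantom(cfg)
  expect_equal(ph$truth$tm_area, 2000, tolerance = 1e-9)
  expect_equal(ph$truth$ooc_area, 3000, tolerance = 1e-9)
  expect_equal(ph$truth$gap, 6)
  # touching structures when the gap is zero
  ph0 <- render_section_phantom(section_phantom_config(gap_true = 0,
                                                       seed = 22))
  expect_equal(min_gap(ph0$geometry$tm_roi, ph0$geometry$reticular_lamina,
                       0.5), 0)
})

test_that("brightness tables realise the configured moments", {
  cfg <- brightness_table_config(n_animals_per_group = 200,
                                 dose_levels = c(0, 1),
                                 intercept = 400, dose_slope = -61,
                                 site_offsets = c(50, 40, 30, 0),
                                 intra_animal_correlation = 0.5,
                                 residual_sd = 40, seed = 31)
  tab <- synth_brightness_table(cfg)
  # marginal means: intercept + slope * dose + site offset
  m <- tapply(tab$brightness, list(tab$site, tab$dose), mean)
  expect_equal(m["TM1", "0"], 450, tolerance = 0.02)
  expect_equal(m["EndoL", "1"], 400 - 61, tolerance = 0.03)
  # within-animal correlation close to rho at large n; computed on
  # residuals from the group/site means so fixed effects do not inflate it
  resid <- tab$brightness -
    ave(tab$brightness, tab$dose, tab$site, FUN = mean)
  wide <- reshape(data.frame(animal = tab$animal, site = tab$site,
                             r = resid),
                  idvar = "animal", timevar = "site", direction = "wide")
  cm <- cor(wide[, -1])
  off_diag <- cm[upper.tri(cm)]
  # pooled within-animal correlation within 0.05 of the configured rho
  expect_lt(abs(mean(off_diag) - 0.5), 0.05)
  expect_error(brightness_table_config(intra_animal_correlation = 1),
               "rho")
})

test_that("evoked waveform generator stores exact ground truth", {
  w <- synth_evoked_waveform(200, ac_amplitude = 50, dc_offset = 10,
                             noise_sd = 0, duration = 0.1, rate = 1e4)
  expect_equal(w$waveform, 10 + 50 * sin(2 * pi * 200 * w$time),
               tolerance = 1e-12)
  expect_equal(mean(w$waveform), 10, tolerance = 1e-12)
  expect_error(synth_evoked_waveform(600, rate = 1000), "twice")
})
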