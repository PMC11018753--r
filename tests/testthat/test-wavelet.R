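test_that("Morlet wavelet has the stated peak, envelope and width", {
  f_b <- 4e-20
  expect_equal(morlet(5e9, f_b, 0), complex(real = 1 / sqrt(pi * f_b)))

  tt <- seq(-1e-9, 1e-9, by = 1e-12)
  env1 <- Mod(morlet(3e9, f_b, tt))
  env2 <- Mod(morlet(7e9, f_b, tt))
  expect_equal(env1, env2, tolerance = 1e-12)

  # numeric FWHM vs closed form 2*sqrt(f_b ln 2)
  half <- max(env1) / 2
  crossing <- approx(env1[tt >= 0], tt[tt >= 0], xout = half)$y
  expect_equal(2 * crossing, 2 * sqrt(f_b * log(2)), tolerance = 1e-3)

  expect_error(morlet(5e9, 0, 0), class = "trbs_invalid_argument")
})

test_that("wavelet spec derives the bandwidth parameter consistently", {
  spec <- wavelet_spec(window_fwhm_z = 520e-9, v_ref = 1497)
  expect_equal(2 * sqrt(spec$f_b * log(2)) * 1497, 520e-9, tolerance = 1e-12)
  # the inverse route recovers the same window
  spec2 <- wavelet_spec(bandwidth_param = spec$f_b, v_ref = 1497)
  expect_equal(spec2$window_fwhm_z, 520e-9, tolerance = 1e-12)
  # N-lambda route: window = N * lambda/2n
  spec3 <- wavelet_spec(n_lambda = 1.6, probe_wavelength = 830e-9,
                        refractive_index = 1.33)
  expect_equal(spec3$window_fwhm_z, 1.6 * 830e-9 / 2.66, tolerance = 1e-12)
  expect_error(wavelet_spec(frequency_grid = c(5e9, 4e9, 3e9)),
               class = "trbs_invalid_argument")
})

test_that("a pure grid-frequency cosine is an eigen-signal of the ridge", {
  tt <- seq(0, 4e-9, by = 3e-12)
  tr <- structure(tibble::tibble(time = tt, amplitude = cos(2 * pi * 5e9 * tt)),
                  class = c("tof_trace", "tbl_df", "tbl", "data.frame"))
  spec <- test_spec()
  spg <- cwt_spectrogram(tr, spec)
  ridge <- extract_ridge(spg)
  interior <- ridge$valid
  # within half a grid step everywhere valid, and exact deep inside
  expect_true(all(abs(ridge$f_B[interior] - 5e9) < 2.5e6))
  deep <- interior & ridge$z > 1.5e-6 & ridge$z < 4e-6
  expect_true(all(abs(ridge$f_B[deep] - 5e9) < 1e3))

  # linearity: amplitudes scale with the trace
  tr2 <- tr
  tr2$amplitude <- 3 * tr$amplitude
  spg2 <- cwt_spectrogram(tr2, spec)
  expect_equal(spg2$coefficients, 3 * spg$coefficients, tolerance = 1e-12)

  expect_error(
    cwt_spectrogram(tr, wavelet_spec(frequency_grid = seq(100e9, 200e9, 1e9))),
    class = "trbs_invalid_argument"
  )
})

test_that("ridge refinement recovers constructed peaks to sub-grid accuracy", {
  # single nonzero coefficient per column
  spg <- structure(list(
    coefficients = rbind(c(0, 0), c(2, 0), c(0, 3)),
    frequency = c(4e9, 4.5e9, 5e9),
    depth = c(1e-6, 2e-6),
    valid = c(TRUE, TRUE),
    wavelet = NULL
  ), class = "trbs_spectrogram")
  r <- extract_ridge(spg)
  expect_equal(r$f_B, c(4.5e9, 5e9))
  expect_equal(r$amplitude, c(2, 3))

  # Gaussian peak sampled on 3+ grid points: vertex to <1% of grid step
  fg <- seq(4e9, 6e9, by = 50e6)
  true_f <- 5.013e9
  col <- exp(-((fg - true_f) / 2e8)^2)
  spg2 <- structure(list(
    coefficients = matrix(col, ncol = 1),
    frequency = fg, depth = 1e-6, valid = TRUE, wavelet = NULL
  ), class = "trbs_spectrogram")
  r2 <- extract_ridge(spg2)
  expect_lt(abs(r2$f_B - true_f), 0.01 * 50e6)

  # all-zero column marked missing
  spg2$coefficients[] <- 0
  r3 <- extract_ridge(spg2)
  expect_true(is.na(r3$f_B))
  expect_false(r3$valid)

  # noise-free homogeneous trace: interior ridge essentially flat
  sim <- simulate_trace(water_stack(), water, fast_cfg())
  ridge <- extract_ridge(cwt_spectrogram(remove_background(sim), test_spec()))
  expect_lt(sd(ridge$f_B[ridge$valid]), 5e6)
})

test_that("CWT ridge matches an independent short-time-Fourier oracle", {
  # noise-free piecewise signal: water then stiffer tissue
  w1500 <- acoustic_medium("water", 1.33, 1000, 1500)
  tis <- acoustic_medium("tissue", 1.38, 1200, 1700)
  stack <- layer_stack(0, list(list(medium = w1500, thickness = 2e-6)), tis)
  tr <- simulate_trace(stack, w1500, fast_cfg(coincidence_amplitude = 0,
                                              thermal_amplitude = 0))
  spec <- wavelet_spec(window_fwhm_z = 520e-9, v_ref = 1500,
                       frequency_grid = seq(4.3e9, 6e9, by = 5e6))
  spg <- cwt_spectrogram(tr, spec)
  ridge <- extract_ridge(spg)
  # compare away from the trace ends, where the finite-support oracle and
  # the circular transform see different data
  idx <- which(ridge$valid & ridge$z > 1e-6 & ridge$z < 5e-6)
  centres_idx <- idx[seq(1, length(idx), by = 40)]
  oracle <- stft_ridge_oracle(
    tr$amplitude, tr$time, spec$window_fwhm_t,
    spec$frequency_grid, spg$time[centres_idx]
  )
  expect_lt(max(abs(ridge$f_B[centres_idx] - oracle)), 2.5e6) # half grid step
})

test_that("ridge transition width scales linearly with the window", {
  w1500 <- acoustic_medium("water", 1.33, 1000, 1500)
  tis <- acoustic_medium("tissue", 1.38, 1200, 1700)
  stack <- layer_stack(0, list(list(medium = w1500, thickness = 2.5e-6)), tis)
  tr <- simulate_trace(stack, w1500, fast_cfg(coincidence_amplitude = 0,
                                              thermal_amplitude = 0))
  widths <- purrr::map_dbl(c(390e-9, 520e-9, 780e-9), function(zwin) {
    spec <- wavelet_spec(window_fwhm_z = zwin, v_ref = 1500,
                         frequency_grid = seq(4.3e9, 6e9, by = 5e6))
    ridge <- extract_ridge(cwt_spectrogram(tr, spec))
    r <- ridge[ridge$valid, ]
    f1 <- 4.807e9; f2 <- 5.653e9
    lo <- f1 + 0.1 * (f2 - f1)
    hi <- f1 + 0.9 * (f2 - f1)
    z10 <- min(r$z[r$f_B > lo & r$z > 1e-6])
    z90 <- min(r$z[r$f_B > hi])
    z90 - z10
  })
  ratios <- widths / c(390e-9, 520e-9, 780e-9)
  expect_lt((max(ratios) - min(ratios)) / mean(ratios), 0.25)
  # and the width is on the order of the window itself
  expect_gt(ratios[2], 0.5)
  expect_lt(ratios[2], 1.5)
})

test_that("time maps to depth by z = vt with left-Riemann profiles", {
  expect_equal(time_to_depth(2.0e-9, 1497), 2.994e-6)
  expect_equal(time_to_depth(0, 1497), 0)
  # piecewise: 1497 m/s for 2 um then 1700 m/s
  dt <- 1e-12
  tt <- seq(0, 3e-9, by = dt)
  t_b <- 2e-6 / 1497
  v <- ifelse(tt < t_b, 1497, 1700)
  z <- time_to_depth(tt, v)
  expect_equal(t_b, 1.336e-9, tolerance = 1e-3)
  z3 <- z[length(z)]
  expect_equal(z3, 4.829e-6, tolerance = 2e-3) # left-Riemann at dt
  expect_error(time_to_depth(tt, -5), class = "trbs_invalid_argument")
})

test_that("reference averaging is a pointwise mean with sqrt-n precision", {
  spec <- test_spec()
  tr <- simulate_trace(water_stack(), water, fast_cfg())
  ref1 <- build_reference(list(tr, tr, tr), spec)
  single <- extract_ridge(cwt_spectrogram(remove_background(tr), spec))
  expect_equal(ref1$f_B_ref, single$f_B)

  # reference of references is the reference (idempotent averaging)
  ref2 <- build_reference(list(
    tibble::tibble(z = ref1$z, f_B = ref1$f_B_ref),
    tibble::tibble(z = ref1$z, f_B = ref1$f_B_ref)
  ), spec)
  expect_equal(ref2$f_B_ref, ref1$f_B_ref)

  # 25 noisy traces: reference std ~ single-trace std / 5
  mk <- function(seed) simulate_trace(
    water_stack(), water, fast_cfg(noise_sigma = 0.1, seed = seed)
  )
  ridges <- purrr::map(1:25, function(i) {
    extract_ridge(cwt_spectrogram(remove_background(mk(i)), spec))
  })
  fmat <- vapply(ridges, function(r) r$f_B, numeric(nrow(ridges[[1]])))
  sel <- ridges[[1]]$valid
  sd_single <- mean(apply(fmat[sel, ], 1, sd))
  ref <- rowMeans(fmat[sel, ])
  # across-depth scatter of the mean profile is far below single-trace noise
  truth <- fB_water
  rmse_ref <- sqrt(mean((ref - truth)^2))
  expect_lt(rmse_ref, sd_single / 5 * 2.5)
  expect_gt(rmse_ref, sd_single / 5 / 2.5)

  expect_error(build_reference(list(), spec), class = "trbs_invalid_argument")
})

test_that("reference compensation cancels common drifts exactly", {
  spec <- test_spec()
  tr <- simulate_trace(water_stack(), water, fast_cfg())
  ridge <- extract_ridge(cwt_spectrogram(remove_background(tr), spec))
  ref <- tibble::tibble(z = ridge$z, f_B_ref = ridge$f_B)
  prof <- compensate(ridge, ref)
  expect_true(all(prof$delta_f[prof$valid] == 0))

  # a +50 MHz drift applied to both profile and reference cancels
  drifted <- ridge
  drifted$f_B <- drifted$f_B + 50e6
  ref_d <- tibble::tibble(z = ridge$z, f_B_ref = ridge$f_B + 50e6)
  prof_d <- compensate(drifted, ref_d)
  expect_equal(prof_d$delta_f, prof$delta_f)

  expect_error(compensate(ridge, ref[-1, ]), class = "trbs_invalid_argument")
})

test_that("ridge precision does not improve with depth under attenuation", {
  # seeded noisy traces in attenuating water: deeper = lower SNR = larger
  # ridge scatter (in expectation)
  spec <- test_spec()
  n_seeds <- 50
  fmat <- vapply(seq_len(n_seeds), function(i) {
    tr <- simulate_trace(
      water_stack(alpha = water$attenuation), water,
      fast_cfg(noise_sigma = 0.1, seed = 5000 + i, sweep_span = 12.5e-9)
    )
    r <- extract_ridge(cwt_spectrogram(remove_background(tr), spec))
    r$f_B
  }, numeric(length(extract_ridge(cwt_spectrogram(remove_background(
    simulate_trace(water_stack(), water,
                   fast_cfg(sweep_span = 12.5e-9))), spec))$f_B)))
  tr0 <- simulate_trace(water_stack(), water, fast_cfg(sweep_span = 12.5e-9))
  z <- extract_ridge(cwt_spectrogram(remove_background(tr0), spec))$z
  sds <- apply(fmat, 1, sd)
  bands <- cut(z, breaks = c(0.5, 1.5, 2.5, 3.5, 4.5) * 1e-6)
  band_sd <- tapply(sds, bands, mean)
  band_sd <- band_sd[!is.na(band_sd)]
  expect_true(all(diff(band_sd) > 0))
})
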