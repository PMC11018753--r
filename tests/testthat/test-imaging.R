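mini_profile <- function(seed = NULL, noise = 0) {
  tr <- simulate_trace(build_cuticle_phantom(), water,
                       fast_cfg(noise_sigma = noise, seed = seed))
  analyze_trace(tr, test_spec(), control = water)
}

test_that("volumes assemble position-independently on a common grid", {
  p1 <- mini_profile()
  profs <- tibble::tibble(ix = c(1L, 2L), iy = c(1L, 1L),
                          profile = list(p1, p1))
  vol <- assemble_volume(profs)
  expect_equal(vol$nx, 2)
  expect_equal(nrow(vol$voxels), 2 * nrow(p1))

  # single position: the volume is just the profile
  vol1 <- assemble_volume(profs[1, ])
  expect_equal(vol1$voxels$delta_f, p1$delta_f)

  # permuting input rows yields the identical volume
  vol_perm <- assemble_volume(profs[c(2, 1), ])
  expect_identical(vol$voxels, vol_perm$voxels)

  bad <- p1[-1, ]
  expect_error(
    assemble_volume(tibble::tibble(ix = c(1L, 2L), iy = c(1L, 1L),
                                   profile = list(p1, bad))),
    class = "trbs_invalid_argument"
  )
})

test_that("frequency binning follows the half-open linear-bin rule", {
  vals <- c(-0.2e9, 0.06e9, 0.3e9, 0.6e9)
  lab <- segment_bins(vals, n_bins = 4, range = c(-0.2e9, 0.6e9))
  expect_equal(as.integer(lab), c(0L, 1L, 2L, 3L))
  expect_equal(attr(lab, "bin_edges"),
               seq(-0.2e9, 0.6e9, length.out = 5))

  # interior edge value goes to the upper bin; top edge closed
  lab2 <- segment_bins(c(0e9, 0.2e9, 0.6e9), 4, c(-0.2e9, 0.6e9))
  expect_equal(as.integer(lab2), c(1L, 2L, 3L))

  # all-equal values with an explicit range share one label
  lab3 <- segment_bins(rep(1e8, 5), 4, c(0, 4e8))
  expect_equal(as.integer(lab3), rep(1L, 5))

  expect_error(segment_bins(vals, 4, c(1e9, 1e9)),
               class = "trbs_invalid_argument")

  # partition property on a real volume: every valid voxel gets one label
  p1 <- mini_profile(seed = 31, noise = 0.1)
  vol <- assemble_volume(tibble::tibble(ix = 1L, iy = 1L,
                                        profile = list(p1)))
  seg <- segment_bins(vol, n_bins = 4)
  expect_s3_class(seg, "segmented_map")
  valid_with_value <- seg$valid & is.finite(seg$delta_f)
  expect_true(all(!is.na(seg$bin[valid_with_value])))
  expect_equal(sum(table(seg$bin)), sum(!is.na(seg$bin)))
})

test_that("Gaussian layer fits are exact on exact models", {
  z <- seq(0, 4e-6, by = 10e-9)
  sigma <- 320e-9 / (2 * sqrt(2 * log(2)))
  y <- 250e6 * exp(-(z - 2e-6)^2 / (2 * sigma^2))
  fit <- fit_layers(tibble::tibble(z = z, delta_f = y), 1)
  expect_lt(abs(fit$fwhm - 320e-9), 1e-9)
  expect_lt(abs(fit$centre - 2e-6), 1e-9)
  expect_lt(abs(fit$amplitude - 250e6) / 250e6, 1e-6)
  # FWHM/sigma ratio is structural
  expect_equal(fit$fwhm / fit$sigma, 2 * sqrt(2 * log(2)))

  # two peaks 3 FWHM apart: centres and widths within 2%
  y2 <- 250e6 * exp(-(z - 1.2e-6)^2 / (2 * sigma^2)) +
    150e6 * exp(-(z - (1.2e-6 + 3 * 320e-9))^2 / (2 * (1.2 * sigma)^2))
  fit2 <- fit_layers(tibble::tibble(z = z, delta_f = y2), 2)
  expect_equal(nrow(fit2), 2)
  expect_lt(abs(fit2$centre[1] - 1.2e-6) / 1.2e-6, 0.02)
  expect_lt(abs(fit2$fwhm[1] - 320e-9) / 320e-9, 0.02)
  expect_lt(abs(fit2$fwhm[2] - 1.2 * 320e-9) / (1.2 * 320e-9), 0.02)

  # asking for more peaks than present warns and fits what is there
  expect_warning(fit3 <- fit_layers(tibble::tibble(z = z, delta_f = y), 3),
                 "peaks")
  expect_lte(nrow(fit3), 2)

  expect_error(fit_layers(tibble::tibble(z = z[1:3], delta_f = y[1:3]), 2),
               class = "trbs_invalid_argument")
})

test_that("tidy/glance/augment expose layer fits in friendly units", {
  z <- seq(0, 4e-6, by = 10e-9)
  sigma <- 320e-9 / (2 * sqrt(2 * log(2)))
  y <- 250e6 * exp(-(z - 2e-6)^2 / (2 * sigma^2))
  fit <- fit_layers(tibble::tibble(z = z, delta_f = y), 1)
  td <- tidy(fit)
  expect_equal(td$fwhm_nm, 320, tolerance = 1e-6)
  expect_equal(td$amplitude_mhz, 250, tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lt(gl$rss, 1)
  au <- augment(fit)
  expect_named(au, c("z", "y", "fit"))
})

test_that("window-aware plateau unmixing recovers layer shifts noise-free", {
  stack <- build_cuticle_phantom()
  tr <- simulate_trace(stack, water, simulation_config(noise_sigma = 0))
  prof <- analyze_trace(tr, test_spec(), control = water)
  est <- layer_plateaus(prof, stack, water, test_spec(), nboot = 0)
  expect_equal(est$layer, c("cortical", "medial", "basal", "hypodermis"))
  expect_lt(max(abs(est$delta_f - c(300e6, 60e6, 300e6, -200e6))), 20e6)

  # raw ridge plateaus are visibly biased for sub-window layers,
  # which is exactly what the unmixing corrects
  mid_medial <- prof$z > 1.9e-6 & prof$z < 2.1e-6
  expect_gt(mean(prof$delta_f[mid_medial], na.rm = TRUE), 100e6)
})

test_that("approach curves activate as the specimen enters the depth range", {
  stack <- step_stack <- layer_stack(
    0, list(),
    acoustic_medium("tissue", 1.38, 1200, 1700, attenuation = 5e5,
                    scatter_strength = 0.8)
  )
  cfg <- fast_cfg(sweep_span = 12.5e-9)
  standoffs <- c(10e-6, 7e-6, 4.5e-6, 2e-6, 0)
  ser <- simulate_approach_series(stack, standoffs, cfg, water)
  spec <- wavelet_spec(window_fwhm_z = 520e-9, v_ref = water$sound_velocity,
                       frequency_grid = seq(4.3e9, 6e9, by = 5e6))
  curve <- approach_curve(ser, spec, control = water)
  base <- curve$weighted_shift[1]
  # far out of range: the second step matches the baseline
  expect_lt(abs(curve$weighted_shift[2] - base), 5e6)
  # entering range: monotone departure from baseline (stiffer specimen)
  dep <- curve$weighted_shift - base
  expect_true(all(diff(dep[2:5]) > 0))
  # in contact: near-surface ridge shows the specimen frequency
  prof0 <- curve$profile[[5]]
  near <- prof0$valid & prof0$z < 1.5e-6
  f_tis <- brillouin_frequency(
    acoustic_medium("t", 1.38, 1200, 1700), 830e-9
  )
  expect_lt(abs(mean(prof0$f_B[near]) - f_tis), 30e6)
})
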