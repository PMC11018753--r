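# shared fixtures and independent oracles, built in code at test time

water <- preset_medium("water")
fB_water <- brillouin_frequency(water, 830e-9)

# fast config for tests: short sweep keeps FFT/CWT sizes small where the
# full 12.5 ns time base is not itself under test
fast_cfg <- function(noise_sigma = 0, seed = NULL, sweep_span = 6e-9, ...) {
  simulation_config(
    optics = optical_config(sweep_span = sweep_span),
    noise_sigma = noise_sigma, seed = seed, ...
  )
}

water_stack <- function(alpha = 0) {
  w <- acoustic_medium("water", water$refractive_index, water$mass_density,
                       water$sound_velocity, attenuation = alpha)
  layer_stack(0, list(), w)
}

# narrow analysis band around the water shift, for speed
test_grid <- function(from = 4.3e9, to = 5.5e9, by = 5e6) seq(from, to, by = by)

test_spec <- function(window_fwhm_z = 520e-9, ...) {
  wavelet_spec(window_fwhm_z = window_fwhm_z, v_ref = water$sound_velocity,
               frequency_grid = test_grid(), ...)
}

# Independent short-time-Fourier ridge oracle: Gaussian window of matched
# FWHM, direct DFT evaluated on the same frequency grid, parabolic vertex
# refinement. Brute force on purpose; evaluated at subsampled centres.
stft_ridge_oracle <- function(x, tt, window_fwhm_t, fgrid, centres) {
  sigma_t <- window_fwhm_t / (2 * sqrt(2 * log(2)))
  df <- fgrid[2] - fgrid[1]
  vapply(centres, function(tc) {
    w <- exp(-(tt - tc)^2 / (2 * sigma_t^2))
    mag <- vapply(fgrid, function(f) {
      Mod(sum(x * w * exp(-2i * pi * f * tt)))
    }, numeric(1))
    i <- which.max(mag)
    if (i == 1 || i == length(fgrid)) return(fgrid[i])
    y <- log(mag[(i - 1):(i + 1)])
    denom <- y[1] - 2 * y[2] + y[3]
    d <- if (denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
    fgrid[i] + max(-0.5, min(0.5, d)) * df
  }, numeric(1))
}

# reference profile from n control traces (seeded)
make_reference <- function(spec, n = 30, noise_sigma = 0.1, seed = 424242,
                           alpha = water$attenuation, n_average = 1,
                           max_depth = 6e-6) {
  stack <- water_stack(alpha = alpha)
  traces <- lapply(seq_len(n), function(i) {
    simulate_trace(stack, water,
                   simulation_config(noise_sigma = noise_sigma,
                                     seed = seed + i,
                                     n_average = n_average))
  })
  build_reference(traces, spec, max_depth = max_depth)
}
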