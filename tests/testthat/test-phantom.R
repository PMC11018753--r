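test_that("homogeneous noise-free trace is the expected damped cosine", {
  alpha <- 2e5
  cfg <- fast_cfg(coincidence_amplitude = 0, thermal_amplitude = 1e-12)
  tr <- simulate_trace(water_stack(alpha), water, cfg)
  f0 <- fB_water
  expected <- exp(-alpha * water$sound_velocity * tr$time) *
    cos(2 * pi * f0 * tr$time)
  # thermal amplitude ~1e-12 is negligible; phase/attenuation integrals exact
  expect_equal(tr$amplitude, expected, tolerance = 1e-9)
})

test_that("zero scatter strength leaves only coincidence and thermal terms", {
  w0 <- acoustic_medium("w0", 1.33, 1000, 1497, scatter_strength = 0)
  cfg <- fast_cfg()
  tr <- simulate_trace(layer_stack(0, list(), w0), w0, cfg)
  expected <- cfg$coincidence_amplitude *
    exp(-4 * log(2) * (tr$time / cfg$coincidence_width)^2) +
    cfg$thermal_amplitude * exp(-tr$time / cfg$thermal_decay)
  expect_identical(tr$amplitude, expected)
})

test_that("two-layer stack switches frequency at the boundary crossing time", {
  w1500 <- acoustic_medium("water", 1.33, 1000, 1500)
  tis <- acoustic_medium("tissue", 1.38, 1200, 1700)
  stack <- layer_stack(0, list(list(medium = w1500, thickness = 2e-6)), tis)
  tr <- simulate_trace(stack, w1500, fast_cfg())
  truth <- attr(tr, "truth")
  expect_equal(truth$regions$t_exit[1], 2e-6 / 1500)
  expect_equal(truth$regions$f_B[1], 4.807e9, tolerance = 1e-3)
  expect_equal(truth$regions$f_B[2], 5.653e9, tolerance = 1e-3)
  expect_equal(truth_frequency(tr, 1e-6), truth$regions$f_B[1])
  # apparent boundary maps through the control velocity
  expect_equal(truth$regions$z_end_apparent[1], 2e-6)
})

test_that("phase is continuous across layer boundaries", {
  stack <- build_cuticle_phantom(standoff = 1e-6)
  cfg <- fast_cfg(coincidence_amplitude = 0, thermal_amplitude = 0)
  tr <- simulate_trace(stack, water, cfg)
  dt <- tr$time[2] - tr$time[1]
  f_max <- max(attr(tr, "truth")$regions$f_B)
  # a continuous-phase cosine cannot jump more than its steepest slope
  expect_lt(max(abs(diff(tr$amplitude))), 2 * pi * f_max * dt * 1.01)
})

test_that("seeded simulation is bit-identical and noise is seed-dependent", {
  cfg <- fast_cfg(noise_sigma = 0.2, seed = 123)
  t1 <- simulate_trace(water_stack(), water, cfg)
  t2 <- simulate_trace(water_stack(), water, cfg)
  expect_identical(t1$amplitude, t2$amplitude)
  cfg2 <- fast_cfg(noise_sigma = 0.2, seed = 124)
  t3 <- simulate_trace(water_stack(), water, cfg2)
  expect_false(identical(t1$amplitude, t3$amplitude))
})

test_that("scan simulation is deterministic with independent substreams", {
  control <- water
  phantom <- scan_phantom(3, 3, 1e-6,
                          function(ix, iy) water_stack(alpha = 1e5), control)
  cfg0 <- fast_cfg(noise_sigma = 0)
  s0 <- simulate_scan(phantom, cfg0)
  amps <- purrr::map(s0$traces$trace, "amplitude")
  for (a in amps[-1]) expect_identical(a, amps[[1]])

  cfg <- fast_cfg(noise_sigma = 0.1, seed = 77)
  s1 <- simulate_scan(phantom, cfg)
  s2 <- simulate_scan(phantom, cfg)
  expect_identical(
    purrr::map(s1$traces$trace, "amplitude"),
    purrr::map(s2$traces$trace, "amplitude")
  )
  # neighbouring positions carry independent draws
  expect_false(identical(s1$traces$trace[[1]]$amplitude,
                         s1$traces$trace[[2]]$amplitude))
  expect_error(simulate_scan(structure(list(grid = tibble::tibble()),
                                       class = "scan_phantom"), cfg),
               class = "trbs_invalid_argument")
})

test_that("cuticle phantom maps configured shifts onto layer velocities", {
  stack <- build_cuticle_phantom()
  expect_length(stack$layers, 4)
  v_hypo <- stack$layers[[4]]$medium$sound_velocity
  expect_lt(v_hypo, water$sound_velocity)
  # each layer reproduces its configured relative shift through 2nv/lambda
  f0 <- brillouin_frequency(water, 830e-9)
  shifts <- purrr::map_dbl(stack$layers, function(ly) {
    brillouin_frequency(ly$medium, 830e-9) - f0
  })
  expect_equal(shifts, c(300e6, 60e6, 300e6, -200e6), tolerance = 1e-9)

  strut <- build_cuticle_phantom(strut = TRUE)
  v_all <- purrr::map_dbl(strut$layers, ~ .x$medium$sound_velocity)
  expect_equal(which.max(v_all), 2L)
  expect_equal(strut$layers[[2]]$medium$name, "strut")

  flat <- build_cuticle_phantom(delta_f = c(cortical = 0, medial = 0,
                                            basal = 0, hypodermis = 0))
  f_flat <- purrr::map_dbl(flat$layers, ~ brillouin_frequency(.x$medium, 830e-9))
  expect_equal(f_flat, rep(f0, 4), tolerance = 1e-12)

  expect_error(build_cuticle_phantom(thickness = c(-1e-9, 1e-9, 1e-9, 1e-9)),
               class = "trbs_invalid_argument")
})

test_that("cell phantom encodes the dome in stand-off and ground truth", {
  ph <- build_cell_phantom(height = 3e-6, nx = 7, ny = 7, pitch = 1e-6,
                           tip_height = 5e-6, footprint_radius = 3e-6)
  truth <- ph$truth_surface
  centre <- truth$height[truth$ix == 4 & truth$iy == 4]
  expect_equal(centre, 3e-6)
  corner <- truth$height[truth$ix == 1 & truth$iy == 1]
  expect_equal(corner, 0)
  # standoff + height = tip height wherever the cell exists
  for (k in c(10, 25, 33)) {
    st <- ph$grid$stack[[k]]
    h <- truth$height[truth$ix == ph$grid$ix[k] & truth$iy == ph$grid$iy[k]]
    expect_equal(st$standoff + h, 5e-6)
  }
  flat <- build_cell_phantom(height = 0, nx = 3, ny = 3)
  expect_true(all(purrr::map_int(flat$grid$stack, ~ length(.x$layers)) == 0))
  expect_error(build_cell_phantom(height = 6e-6, tip_height = 5e-6),
               class = "trbs_invalid_argument")
})

test_that("approach series demands a descending stand-off schedule", {
  stack <- build_cuticle_phantom()
  expect_error(
    simulate_approach_series(stack, c(1e-6, 2e-6), fast_cfg()),
    class = "trbs_invalid_argument"
  )
  ser <- simulate_approach_series(stack, c(8e-6, 4e-6, 0), fast_cfg())
  expect_equal(nrow(ser), 3)
  expect_equal(purrr::map_dbl(ser$trace, ~ attr(.x, "truth")$surface_z),
               c(8e-6, 4e-6, 0))
})
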