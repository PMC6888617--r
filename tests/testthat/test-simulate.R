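test_that("chest displacement reduces to d0 for static or zero-phase cases", {
  still <- chest_motion(d0 = 1.3)
  expect_equal(chest_displacement(still, c(0, 0.7, 5)), rep(1.3, 3))
  m <- chest_motion(d0 = 1, m_b = 5e-3, f_b = 0.35, m_h = 3e-4, f_h = 1.3)
  expect_equal(chest_displacement(m, 0), 1)
  # quarter period of respiration with no heartbeat: full inhale excursion
  m2 <- chest_motion(d0 = 1, m_b = 5e-3, f_b = 0.35)
  expect_equal(chest_displacement(m2, 1 / (4 * 0.35)), 1 + 5e-3)
})

test_that("time of flight is 2d/c and linear", {
  expect_equal(time_of_flight(0), 0)
  expect_equal(time_of_flight(1), 2 / 2.998e8)
  d <- c(0.3, 1, 4.7)
  expect_equal(time_of_flight(2 * d), 2 * time_of_flight(d))
  expect_error(time_of_flight(-1), class = "rher_invalid_input")
})

test_that("the synthesized pulse is normalized with the right spectral shape", {
  spec <- pulse_spec()
  n <- 4096
  tau <- (seq_len(n) - n / 2) / spec$fast_time_rate
  p <- synthesize_pulse(spec, tau)
  expect_equal(max(abs(p)), 1, tolerance = 1e-6)
  expect_equal(synthesize_pulse(spec, 0), 1)
  mag <- Mod(fft(p))[seq_len(n / 2)]
  freq <- (seq_len(n / 2) - 1) * spec$fast_time_rate / n
  pk <- which.max(mag)
  expect_lt(abs(freq[pk] - spec$center_frequency),
            2 * spec$fast_time_rate / n)
  # -10 dB width within 10% of the configured bandwidth
  above <- which(mag >= max(mag) * 10^(-0.5))
  width <- (max(above) - min(above)) * spec$fast_time_rate / n
  expect_lt(abs(width - spec$bandwidth) / spec$bandwidth, 0.1)
})

test_that("pulse and grid Nyquist violations are rejected", {
  expect_error(pulse_spec(fast_time_rate = 10e9),
               class = "rher_invalid_config")
  spec <- pulse_spec()
  coarse <- seq(0, 1e-8, by = 1e-10)  # 10 GS/s grid
  expect_error(synthesize_pulse(spec, coarse),
               class = "rher_invalid_config")
})

test_that("a time-invariant scene gives identical frames", {
  scene <- scene_spec(chest_motion(d0 = 1), target_amplitude = 1,
                      noise_sigma = 0, duration = 1, range_window = c(0.5, 1.5))
  cube <- synthesize_cube(scene)
  expect_true(all(cube$amplitudes == cube$amplitudes[, 1]))
})

test_that("cube synthesis is seed-deterministic", {
  motion <- chest_motion(d0 = 1, m_b = 4e-3, f_b = 0.3, m_h = 2e-4,
                         f_h = 1.2)
  scene <- scene_spec(motion, duration = 2, seed = 42L,
                      range_window = c(0.5, 1.5))
  c1 <- synthesize_cube(scene)
  c2 <- synthesize_cube(scene)
  expect_identical(c1$amplitudes, c2$amplitudes)
  c3 <- synthesize_cube(scene_spec(motion, duration = 2, seed = 43L,
                                   range_window = c(0.5, 1.5)))
  expect_false(identical(c1$amplitudes, c3$amplitudes))
})

test_that("the moving target is located near d0 after DC removal", {
  motion <- chest_motion(d0 = 1, m_b = 4e-3, f_b = 0.35, m_h = 2e-4,
                         f_h = 1.35)
  scene <- scene_spec(motion, noise_sigma = 0, duration = 20)
  cube <- synthesize_cube(scene)
  loc <- locate_target(energy_indicator(remove_dc(cube)))
  # within the pulse-envelope halfwidth: carrier phase favors a
  # well-modulated bin near the envelope peak, not always the exact center
  expect_lt(abs(loc$distance - 1), 0.03)
})

test_that("cube energy scales quadratically with target amplitude", {
  motion <- chest_motion(d0 = 1, m_b = 3e-3, f_b = 0.3)
  base <- scene_spec(motion, target_amplitude = 1, noise_sigma = 0,
                     multipath = data.frame(amplitude = numeric(),
                                            delay = numeric()),
                     duration = 5, range_window = c(0.5, 1.5))
  doubled <- base
  doubled$target_amplitude <- 2
  e1 <- sum(synthesize_cube(base)$amplitudes^2)
  e2 <- sum(synthesize_cube(doubled)$amplitudes^2)
  expect_equal(e2 / e1, 4, tolerance = 1e-10)
})

test_that("the slow-time signal is periodic at the respiration period", {
  motion <- chest_motion(d0 = 1, m_b = 4e-3, f_b = 0.4)
  scene <- scene_spec(motion, noise_sigma = 0, duration = 20,
                      range_window = c(0.8, 1.2))
  cube <- remove_dc(synthesize_cube(scene))
  loc <- locate_target(energy_indicator(cube))
  s <- cube$amplitudes[loc$bin, ]
  lag_grid <- 2:100
  ac <- sapply(lag_grid, function(l) {
    n <- length(s)
    stats::cor(s[1:(n - l)], s[(l + 1):n])
  })
  best <- lag_grid[which.max(ac)]
  expect_lte(abs(best - 50), 1)  # 1/f_b = 2.5 s = 50 frames at 20 fps
})

test_that("subject synthesis draws from the species preset", {
  p <- species_profiles()
  cube <- synthesize_subject("human", seed = 7L)
  m <- cube$provenance$motion
  expect_gte(m$f_b, p$human$resp_freq_range[1])
  expect_lte(m$f_b, p$human$resp_freq_range[2])
  expect_gte(m$m_h, p$human$heart_amp_range[1])
  rb <- synthesize_subject("rabbit", seed = 7L,
                           overrides = list(duration = 2))
  expect_gt(rb$provenance$motion$drift_amp, 0)
  d1 <- synthesize_subject("dog", seed = 1L,
                           overrides = list(duration = 2))
  d2 <- synthesize_subject("dog", seed = 2L,
                           overrides = list(duration = 2))
  expect_false(identical(d1$provenance$motion, d2$provenance$motion))
  # dog/cat heartbeat displacement never below respiration displacement
  expect_gte(d1$provenance$motion$m_h, d1$provenance$motion$m_b)
  expect_error(synthesize_subject("horse"), class = "rher_invalid_input")
})

test_that("preset heart rates respect slow-time Nyquist", {
  for (p in species_profiles()) {
    expect_lt(p$heart_freq_range[2], 20 / 2)
  }
})

test_that("subject synthesis leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(synthesize_subject("cat", seed = 3L,
                               overrides = list(duration = 2)))
  expect_identical(.Random.seed, before)
})
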