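test_that("the energy indicator is the slow-time sum of squares", {
  imp <- signal_cube(c(1, rep(0, 9)))
  expect_equal(energy_indicator(imp)$energies, 1)
  ones <- signal_cube(rep(1, 20))
  expect_equal(energy_indicator(ones)$energies, 20)
  set.seed(3)
  m <- matrix(rnorm(3 * 8), 3)
  cube <- radar_cube(m, 6.43e-3, 20, stage = "dc_removed")
  oracle <- apply(m, 1, function(r) sum(r^2))
  expect_equal(energy_indicator(cube)$energies, oracle)
})

test_that("a raw cube triggers a clutter warning", {
  cube <- signal_cube(rep(1, 10), stage = "raw")
  expect_warning(energy_indicator(cube), "clutter")
})

test_that("target localization takes the first maximum-energy bin", {
  prof <- structure(list(energies = c(0, 5, 1),
                         ranges = c(0, 1, 2) * 6.43e-3,
                         range_bin_spacing = 6.43e-3, start_range = 0),
                    class = "energy_profile")
  loc <- locate_target(prof)
  expect_equal(loc$bin, 2L)
  expect_equal(loc$distance, 6.43e-3)
  tie <- prof
  tie$energies <- c(3, 3)
  tie$ranges <- c(0, 6.43e-3)
  expect_equal(locate_target(tie)$bin, 1L)
  zero <- prof
  zero$energies <- c(0, 0, 0)
  expect_error(locate_target(zero), class = "rher_no_target")
})

test_that("segment mapping covers 1..M monotonically", {
  std <- energy_standard(M = 3, I = 10, reference_energies = c(1, 2, 3))
  expect_equal(segment_of(1, std), 1L)
  expect_equal(segment_of(10, std), 1L)
  expect_equal(segment_of(11, std), 2L)
  expect_equal(segment_of(30, std), 3L)
  segs <- vapply(1:30, segment_of, integer(1), standard = std)
  expect_true(all(diff(segs) >= 0))
  expect_setequal(unique(segs), 1:3)
  expect_error(segment_of(31, std), class = "rher_out_of_range")
  expect_error(segment_of(0, std), class = "rher_out_of_range")
})

test_that("alpha_E is the human reference over the target energy", {
  std <- energy_standard(M = 1, I = 100, reference_energies = 100)
  expect_equal(alpha_e(10, std, 1), 10)
  expect_equal(alpha_e(100, std, 50), 1)
  expect_equal(alpha_e(5, std, 1), 2 * alpha_e(10, std, 1))
  expect_error(alpha_e(0, std, 1), class = "rher_no_target")
})

test_that("the energy gate assigns the boundary to animal", {
  expect_equal(initial_decision(5), "human-candidate")
  expect_equal(initial_decision(50), "animal")
  expect_equal(initial_decision(10), "animal")
  expect_equal(initial_decision(9.999), "human-candidate")
})

test_that("gate decisions are scale-consistent in cube amplitude", {
  cube <- synthesize_subject("human", seed = 31L)
  std <- energy_standard(M = 5, I = ceiling(nrow(cube$amplitudes) / 5),
                         reference_energies = rep(1, 5))
  report_energy <- function(cb) {
    loc <- locate_target(energy_indicator(remove_dc(cb)))
    loc$energy
  }
  e1 <- report_energy(cube)
  scaled <- cube
  scaled$amplitudes <- 3 * scaled$amplitudes
  expect_equal(report_energy(scaled) / e1, 9, tolerance = 1e-8)
})

test_that("calibration averages located energies per segment and inherits", {
  # two humans near 1 m -> one calibrated segment, others inherited
  cubes <- lapply(1:2, function(i) synthesize_subject("human",
                                                      seed = 200 + i))
  std <- calibrate_standard(cubes, M = 5)
  expect_s3_class(std, "energy_standard")
  expect_equal(std$M, 5L)
  expect_equal(sum(!std$inherited), 1L)
  # the calibrated value is the mean of the individually located energies
  energies <- vapply(cubes, function(cb) {
    locate_target(energy_indicator(lowpass(remove_dc(cb))))$energy
  }, numeric(1))
  expect_equal(std$reference_energies[!std$inherited][1], mean(energies))
  # inherited segments carry the nearest calibrated value
  expect_true(all(std$reference_energies == mean(energies)))
  expect_error(calibrate_standard(list()), class = "rher_calibration_error")
})

test_that("humans at two distances calibrate two segments", {
  cubes <- list(
    synthesize_subject("human", seed = 210L),
    synthesize_subject("human", seed = 211L, overrides = list(d0 = 2)))
  std <- calibrate_standard(cubes, M = 5)
  expect_equal(sum(!std$inherited), 2L)
  expect_equal(sum(std$inherited), 3L)
})

test_that("energy standards survive a YAML round trip", {
  std <- energy_standard(M = 2, I = 5, reference_energies = c(3.5, 7.25),
                         inherited = c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_energy_standard(std, path)
  expect_equal(unclass(read_energy_standard(path)), unclass(std))
})
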