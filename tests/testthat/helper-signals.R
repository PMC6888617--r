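# Shared fixtures: tone builders and small cubes, generated in code.

# `duration` seconds sampled at `rate`, endpoint excluded
time_grid <- function(duration = 20, rate = 20) {
  seq(0, duration - 1 / rate, by = 1 / rate)
}

make_tone <- function(freq, duration = 20, rate = 20, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * time_grid(duration, rate) + phase)
}

# single-row cube holding a slow-time signal
signal_cube <- function(x, rate = 20, stage = "dc_removed") {
  radar_cube(matrix(x, nrow = 1), range_bin_spacing = 6.43e-3,
             slow_time_rate = rate, stage = stage)
}

# standard simulated-human calibration used by gate/pipeline tests
# (memoized: several tests reuse the same default calibration)
.cal_cache <- new.env(parent = emptyenv())
calibrated_standard <- function(n_cal = 5, M = 5, base_seed = 100) {
  key <- paste(n_cal, M, base_seed, sep = "_")
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])
  cubes <- lapply(seq_len(n_cal),
                  function(i) synthesize_subject("human", seed = base_seed + i))
  std <- calibrate_standard(cubes, M = M)
  .cal_cache[[key]] <- std
  std
}
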