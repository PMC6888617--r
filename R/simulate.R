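# Physics-based IR-UWB echo simulator: a static multipath background plus a
# pulse echo whose delay is modulated by sinusoidal chest displacement
# (respiration + heartbeat, optional slow body drift), with additive noise.

#' UWB pulse specification
#'
#' @param center_frequency Carrier center frequency in Hz.
#' @param bandwidth -10 dB bandwidth in Hz; must satisfy
#'   `0 < bandwidth < 2 * center_frequency`.
#' @param fast_time_rate Fast-time sampling rate in samples/s; must exceed
#'   twice the highest pulse frequency (`center_frequency + bandwidth/2`).
#'
#' Defaults match a commercial vital-signs radar operating point:
#' 7.29 GHz center frequency, 1.4 GHz bandwidth, 23.328 GS/s sampling.
#' The implied range-bin spacing is `c / (2 * fast_time_rate)` = 6.43 mm.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(center_frequency = 7.29e9, bandwidth = 1.4e9,
                       fast_time_rate = 23.328e9) {
  stopifnot_scalar_number(center_frequency, "center_frequency", positive = TRUE)
  stopifnot_scalar_number(bandwidth, "bandwidth", positive = TRUE)
  stopifnot_scalar_number(fast_time_rate, "fast_time_rate", positive = TRUE)
  if (bandwidth >= 2 * center_frequency) {
    rher_stop("rher_invalid_config",
              "`bandwidth` must be below 2 * center_frequency")
  }
  if (fast_time_rate <= 2 * (center_frequency + bandwidth / 2)) {
    rher_stop("rher_invalid_config",
              "`fast_time_rate` must exceed twice the highest pulse frequency")
  }
  structure(list(center_frequency = center_frequency, bandwidth = bandwidth,
                 fast_time_rate = fast_time_rate),
            class = "pulse_spec")
}

#' Chest-motion kinematics
#'
#' The instantaneous radar-facing chest position is modelled as a nominal
#' stand-off distance plus sinusoidal respiration and heartbeat
#' displacements and an optional low-frequency body-motion drift:
#' `d(t) = d0 + m_b sin(2 pi f_b t + phi_b) + m_h sin(2 pi f_h t + phi_h)
#'  + drift_amp sin(2 pi drift_freq t + phi_d)`.
#'
#' @param d0 Nominal distance in meters (> 0).
#' @param m_b,f_b Respiration displacement amplitude (m) and frequency (Hz).
#' @param m_h,f_h Heartbeat displacement amplitude (m) and frequency (Hz).
#' @param drift_amp,drift_freq Body-drift amplitude (m) and frequency (Hz).
#' @param phase_b,phase_h,phase_drift Phase offsets in radians.
#' @return An object of class `chest_motion`.
#' @export
chest_motion <- function(d0 = 1, m_b = 0, f_b = 0, m_h = 0, f_h = 0,
                         drift_amp = 0, drift_freq = 0,
                         phase_b = 0, phase_h = 0, phase_drift = 0) {
  stopifnot_scalar_number(d0, "d0", positive = TRUE)
  for (nm in c("m_b", "f_b", "m_h", "f_h", "drift_amp", "drift_freq")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0) rher_stop("rher_invalid_input",
                         sprintf("`%s` must be >= 0", nm))
  }
  if (m_b + m_h + drift_amp > 0.1 * d0) {
    rher_stop("rher_invalid_input",
              "total displacement amplitude must be small relative to d0")
  }
  structure(list(d0 = d0, m_b = m_b, f_b = f_b, m_h = m_h, f_h = f_h,
                 drift_amp = drift_amp, drift_freq = drift_freq,
                 phase_b = phase_b, phase_h = phase_h,
                 phase_drift = phase_drift),
            class = "chest_motion")
}

#' Chest displacement at given times
#'
#' @param motion A [chest_motion()].
#' @param t Time(s) in seconds.
#' @return Chest position(s) d(t) in meters.
#' @export
chest_displacement <- function(motion, t) {
  if (!inherits(motion, "chest_motion")) {
    rher_stop("rher_invalid_input", "`motion` must be a chest_motion object")
  }
  motion$d0 +
    motion$m_b * sin(2 * pi * motion$f_b * t + motion$phase_b) +
    motion$m_h * sin(2 * pi * motion$f_h * t + motion$phase_h) +
    motion$drift_amp * sin(2 * pi * motion$drift_freq * t + motion$phase_drift)
}

#' Round-trip time of flight
#'
#' @param distance One-way distance(s) in meters, >= 0.
#' @return `2 * distance / c` in seconds, with c = 2.998e8 m/s.
#' @export
time_of_flight <- function(distance) {
  if (!is.numeric(distance) || any(!is.finite(distance)) ||
      any(distance < 0)) {
    rher_stop("rher_invalid_input", "`distance` must be finite and >= 0")
  }
  2 * distance / RHER_C
}

# Gaussian envelope sd (in fast time) from the -10 dB bandwidth: the pulse
# spectrum envelope is Gaussian, |G(f0 + df)| = exp(-(2 pi df sigma)^2 / 2);
# full width at -10 dB equal to `bandwidth` gives
# sigma = sqrt(2 ln 10^(1/2)) / (pi * bandwidth).
pulse_sigma_tau <- function(spec) {
  sqrt(2 * log(10^0.5)) / (pi * spec$bandwidth)
}

pulse_eval <- function(spec, tau) {
  sigma <- pulse_sigma_tau(spec)
  exp(-tau^2 / (2 * sigma^2)) * cos(2 * pi * spec$center_frequency * tau)
}

#' Synthesize the normalized received pulse
#'
#' A Gaussian-envelope cosine at the carrier frequency, with the envelope
#' width set so the -10 dB spectral width equals the configured bandwidth.
#' Peak magnitude is 1 at `tau = 0`.
#'
#' @param spec A [pulse_spec()].
#' @param tau_grid Uniform fast-time grid in seconds, sampled at
#'   `spec$fast_time_rate`.
#' @return Waveform values on `tau_grid`.
#' @export
synthesize_pulse <- function(spec, tau_grid) {
  if (!inherits(spec, "pulse_spec")) {
    rher_stop("rher_invalid_input", "`spec` must be a pulse_spec")
  }
  if (length(tau_grid) > 1) {
    dt <- diff(tau_grid)
    if (any(abs(dt - dt[1]) > 1e-9 * abs(dt[1]))) {
      rher_stop("rher_invalid_config", "`tau_grid` must be uniform")
    }
    grid_rate <- 1 / dt[1]
    if (grid_rate <= 2 * (spec$center_frequency + spec$bandwidth / 2)) {
      rher_stop("rher_invalid_config",
                "`tau_grid` spacing violates Nyquist for this pulse")
    }
  }
  pulse_eval(spec, tau_grid)
}

#' Scene specification for the echo simulator
#'
#' Describes one static scene with a single breathing subject: the chest
#' kinematics, the echo strength of the subject, static multipath
#' reflectors, the noise level and the recording geometry.
#'
#' @param motion A [chest_motion()].
#' @param target_amplitude Echo amplitude of the subject (dimensionless).
#' @param multipath Data frame with columns `amplitude` and `delay`
#'   (seconds) for the static reflectors; may have zero rows.
#' @param noise_sigma Standard deviation of the additive white Gaussian
#'   noise per sample.
#' @param duration Record duration in seconds.
#' @param slow_time_rate Frame rate in Hz; must exceed `2 * f_h` with
#'   margin so the heartbeat is resolvable.
#' @param range_window Two-element range window in meters; must contain
#'   the subject's `d0`.
#' @param seed Integer seed; the same scene and seed give a bit-identical
#'   cube.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(motion, target_amplitude = 1,
                       multipath = default_multipath(),
                       noise_sigma = 0.01, duration = 20,
                       slow_time_rate = 20, range_window = c(0, 5),
                       seed = 1L) {
  if (!inherits(motion, "chest_motion")) {
    rher_stop("rher_invalid_input", "`motion` must be a chest_motion object")
  }
  stopifnot_scalar_number(target_amplitude, "target_amplitude")
  stopifnot_scalar_number(noise_sigma, "noise_sigma")
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(slow_time_rate, "slow_time_rate", positive = TRUE)
  if (noise_sigma < 0) {
    rher_stop("rher_invalid_config", "`noise_sigma` must be >= 0")
  }
  if (slow_time_rate <= 2 * motion$f_h) {
    rher_stop("rher_invalid_config",
              "`slow_time_rate` must exceed twice the heartbeat frequency")
  }
  if (length(range_window) != 2L || range_window[1] >= range_window[2]) {
    rher_stop("rher_invalid_config", "`range_window` must be an interval")
  }
  if (motion$d0 < range_window[1] || motion$d0 > range_window[2]) {
    rher_stop("rher_invalid_config", "`range_window` must contain d0")
  }
  if (!is.data.frame(multipath) ||
      !all(c("amplitude", "delay") %in% names(multipath))) {
    rher_stop("rher_invalid_config",
              "`multipath` needs columns `amplitude` and `delay`")
  }
  structure(list(motion = motion, target_amplitude = target_amplitude,
                 multipath = multipath, noise_sigma = noise_sigma,
                 duration = duration, slow_time_rate = slow_time_rate,
                 range_window = range_window, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default static multipath background
#'
#' Two static reflectors (e.g. a wall and a piece of furniture) at 0.4 m
#' and 2.2 m.
#'
#' @return A data frame with columns `amplitude` and `delay` (seconds).
#' @export
default_multipath <- function() {
  data.frame(amplitude = c(0.8, 0.5),
             delay = time_of_flight(c(0.4, 2.2)))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthesize a radar cube from a scene
#'
#' Evaluates the received range profile frame by frame: the static
#' multipath background plus the subject echo, a Gaussian-envelope carrier
#' pulse delayed by the round-trip time of flight to the instantaneous
#' chest position, with additive white Gaussian noise. Because the carrier
#' phase of the subject echo depends on the chest position, millimeter
#' displacements produce strong slow-time amplitude modulation at the
#' subject's range bins - the mechanism the whole pipeline exploits.
#'
#' @param scene A [scene_spec()].
#' @param pulse A [pulse_spec()]; the range-bin spacing of the output is
#'   `c / (2 * pulse$fast_time_rate)`.
#' @return A raw-stage [radar_cube()] whose provenance records the seed.
#' @export
synthesize_cube <- function(scene, pulse = pulse_spec()) {
  if (!inherits(scene, "scene_spec")) {
    rher_stop("rher_invalid_input", "`scene` must be a scene_spec")
  }
  dr <- RHER_C / (2 * pulse$fast_time_rate)
  ranges <- seq(scene$range_window[1], scene$range_window[2], by = dr)
  if (length(ranges) < 1L) {
    rher_stop("rher_invalid_config", "empty range window")
  }
  n_frames <- max(2L, floor(scene$duration * scene$slow_time_rate))
  t_slow <- (seq_len(n_frames) - 1) / scene$slow_time_rate
  tau_x <- time_of_flight(ranges)

  static <- numeric(length(ranges))
  if (nrow(scene$multipath) > 0) {
    for (i in seq_len(nrow(scene$multipath))) {
      static <- static + scene$multipath$amplitude[i] *
        pulse_eval(pulse, tau_x - scene$multipath$delay[i])
    }
  }
  tau_d <- time_of_flight(chest_displacement(scene$motion, t_slow))
  # X x N evaluation of the delayed pulse (envelope + carrier phase)
  dtau <- outer(tau_x, tau_d, "-")
  amp <- static + scene$target_amplitude * pulse_eval(pulse, dtau)
  if (scene$noise_sigma > 0) {
    noise <- with_private_seed(scene$seed,
      matrix(rnorm(length(amp), 0, scene$noise_sigma),
             nrow = nrow(amp)))
    amp <- amp + noise
  }
  radar_cube(amp, range_bin_spacing = dr,
             slow_time_rate = scene$slow_time_rate,
             start_range = scene$range_window[1],
             stage = "raw",
             provenance = list(seed = scene$seed,
                               species = scene$species,
                               d0 = scene$motion$d0))
}

#' Simulate one subject of a given species
#'
#' Draws respiration/heartbeat frequencies and displacement amplitudes
#' uniformly from the species preset intervals ([species_profiles()]),
#' with independently drawn phase offsets, and synthesizes the cube at a
#' nominal stand-off of 1 m. For dogs and cats the heartbeat displacement
#' is drawn conditionally at or above the respiration displacement,
#' reflecting their heartbeat-dominated chest return.
#'
#' @param species One of `"human"`, `"dog"`, `"cat"`, `"rabbit"`.
#' @param overrides Named list overriding [scene_spec()] arguments
#'   (e.g. `list(noise_sigma = 0)`) or the drawn motion parameters
#'   (`d0`, `m_b`, `f_b`, `m_h`, `f_h`).
#' @param seed Integer seed driving both the parameter draws and the
#'   noise.
#' @param profiles Preset list, by default [species_profiles()].
#' @return A raw-stage [radar_cube()]; `provenance$motion` records the
#'   drawn kinematics.
#' @export
synthesize_subject <- function(species, overrides = list(), seed = 1L,
                               profiles = species_profiles()) {
  if (!species %in% names(profiles)) {
    rher_stop("rher_invalid_input",
              sprintf("unknown species `%s`", species))
  }
  p <- profiles[[species]]
  draw <- function(iv) runif(1, iv[1], iv[2])
  pars <- with_private_seed(seed, {
    f_b <- draw(p$resp_freq_range)
    f_h <- draw(p$heart_freq_range)
    m_b <- draw(p$resp_amp_range)
    m_h <- if (species %in% c("dog", "cat")) {
      # heartbeat displacement clearly above respiration displacement,
      # matching the heartbeat-dominated chest return of dogs and cats
      min(m_b * runif(1, 1.4, 2.2), p$heart_amp_range[2])
    } else draw(p$heart_amp_range)
    drift_f <- if (p$body_drift_amp > 0) draw(p$drift_freq_range) else 0
    list(f_b = f_b, f_h = f_h, m_b = m_b, m_h = m_h,
         drift_amp = p$body_drift_amp, drift_freq = drift_f,
         phase_b = runif(1, 0, 2 * pi), phase_h = runif(1, 0, 2 * pi),
         phase_drift = runif(1, 0, 2 * pi))
  })
  motion_args <- c(list(d0 = 1), pars)
  motion_over <- intersect(names(overrides), names(motion_args))
  motion_args[motion_over] <- overrides[motion_over]
  motion <- do.call(chest_motion, motion_args)

  scene_args <- list(motion = motion,
                     target_amplitude = p$target_amplitude,
                     seed = seed + 500000L)
  scene_over <- setdiff(intersect(names(overrides),
                                  names(formals(scene_spec))), "motion")
  scene_args[scene_over] <- overrides[scene_over]
  scene <- do.call(scene_spec, scene_args)
  scene$species <- species
  cube <- synthesize_cube(scene)
  cube$provenance$motion <- unclass(motion)
  cube$provenance$subject_seed <- as.integer(seed)
  cube
}
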