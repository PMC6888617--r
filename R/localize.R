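# Target localization by slow-time energy and the stage-1 human/animal
# energy gate with segment-wise human calibration.

#' Slow-time energy per range bin
#'
#' For each range bin x the energy indicator is the summed squared
#' amplitude along slow time, `E_x = sum_n s_x(n)^2`. On DC-removed data a
#' breathing subject stands out as a sharp energy peak at its range.
#'
#' @param cube A [radar_cube()]; should be preprocessed (static clutter
#'   removed), otherwise static reflectors dominate the profile.
#' @return An object of class `energy_profile`: list with `energies`
#'   (one value per range bin), `ranges` (m) and `range_bin_spacing`.
#' @export
energy_indicator <- function(cube) {
  if (!inherits(cube, "radar_cube")) {
    rher_stop("rher_invalid_input", "`cube` must be a radar_cube")
  }
  if (length(cube$amplitudes) == 0L) {
    rher_stop("rher_invalid_input", "empty cube")
  }
  if (identical(cube$stage, "raw")) {
    warning("energy_indicator() on a raw cube: static clutter will dominate; ",
            "run remove_dc() first", call. = FALSE)
  }
  structure(list(energies = rowSums(cube$amplitudes^2),
                 ranges = cube_ranges(cube),
                 range_bin_spacing = cube$range_bin_spacing,
                 start_range = cube$start_range),
            class = "energy_profile")
}

#' Locate the target as the maximum-energy range bin
#'
#' @param profile An [energy_indicator()] result.
#' @return List with `bin` (1-based index; ties broken by the smallest
#'   index), `distance` (m) and `energy`.
#' @export
locate_target <- function(profile) {
  if (!inherits(profile, "energy_profile") ||
      length(profile$energies) == 0L) {
    rher_stop("rher_invalid_input", "`profile` must be a non-empty energy_profile")
  }
  if (all(profile$energies == 0)) {
    rher_stop("rher_no_target", "all-zero energy profile: no target present")
  }
  bin <- which.max(profile$energies)
  list(bin = bin, distance = profile$ranges[bin],
       energy = profile$energies[bin])
}

#' Segment-calibrated human energy standard
#'
#' The detection range is divided into `M` consecutive segments of `I`
#' range bins each; each segment carries a reference energy, the average
#' located-target energy of calibration human subjects in that segment.
#'
#' @param M Number of segments (>= 1).
#' @param I Segment length in range bins (>= 1); `M * I` must cover the
#'   range bins of the cubes the standard is used with.
#' @param reference_energies Numeric vector of length `M`, all > 0.
#' @param inherited Logical vector flagging segments whose reference was
#'   inherited from a neighbour rather than calibrated directly.
#' @return An object of class `energy_standard`.
#' @export
energy_standard <- function(M, I, reference_energies,
                            inherited = rep(FALSE, M)) {
  stopifnot_scalar_number(M, "M", positive = TRUE)
  stopifnot_scalar_number(I, "I", positive = TRUE)
  if (length(reference_energies) != M ||
      any(!is.finite(reference_energies)) || any(reference_energies <= 0)) {
    rher_stop("rher_invalid_input",
              "`reference_energies` must be M positive finite values")
  }
  structure(list(M = as.integer(M), I = as.integer(I),
                 reference_energies = as.numeric(reference_energies),
                 inherited = as.logical(inherited)),
            class = "energy_standard")
}

#' @export
print.energy_standard <- function(x, ...) {
  cat(sprintf("<energy_standard> %d segments x %d bins\n", x$M, x$I))
  for (m in seq_len(x$M)) {
    cat(sprintf("  segment %d: E_human = %.4g%s\n", m,
                x$reference_energies[m],
                if (x$inherited[m]) " (inherited)" else ""))
  }
  invisible(x)
}

#' Segment number of a range bin
#'
#' Bins are grouped into `M` consecutive segments of `I` bins; bin `i`
#' (1-based) falls in segment `floor((i - 1) / I) + 1`.
#'
#' @param i 1-based range-bin index, `1 <= i <= M * I`.
#' @param standard An [energy_standard()].
#' @return Segment number in `1..M`.
#' @export
segment_of <- function(i, standard) {
  if (!inherits(standard, "energy_standard")) {
    rher_stop("rher_invalid_input", "`standard` must be an energy_standard")
  }
  stopifnot_scalar_number(i, "i")
  if (i < 1 || i > standard$M * standard$I) {
    rher_stop("rher_out_of_range",
              sprintf("bin %d outside the calibrated range [1, %d]",
                      as.integer(i), standard$M * standard$I))
  }
  as.integer((i - 1) %/% standard$I + 1L)
}

#' Energy ratio of the human standard to the target
#'
#' `alpha_E = E_m,human / E_i`, where `E_m,human` is the calibrated human
#' reference for the segment containing the target bin and `E_i` the
#' target's energy. Weak echoes (small animals) give large `alpha_E`.
#'
#' @param target_energy The located target's energy `E_i` (> 0).
#' @param standard An [energy_standard()].
#' @param bin_index 1-based target range-bin index.
#' @return The dimensionless ratio `alpha_E`.
#' @export
alpha_e <- function(target_energy, standard, bin_index) {
  stopifnot_scalar_number(target_energy, "target_energy")
  if (target_energy <= 0) {
    rher_stop("rher_no_target", "zero target energy")
  }
  m <- segment_of(bin_index, standard)
  standard$reference_energies[m] / target_energy
}

#' Stage-1 decision from the energy gate
#'
#' Targets whose echo energy is within a factor `threshold` of the human
#' reference (`alpha_E < threshold`) are passed on to the VMD/RHER stage
#' as human candidates; weaker targets are labelled animals immediately.
#' The boundary `alpha_E == threshold` is assigned to animal (the human
#' region is strictly below the threshold).
#'
#' @param alpha_e The energy ratio from [alpha_e()].
#' @param threshold Decision threshold (default 10).
#' @return `"human-candidate"` or `"animal"`.
#' @export
initial_decision <- function(alpha_e, threshold = 10) {
  stopifnot_scalar_number(alpha_e, "alpha_e", positive = TRUE)
  if (alpha_e < threshold) "human-candidate" else "animal"
}

#' Calibrate the human energy standard from human recordings
#'
#' Preprocesses each calibration cube (DC removal + low-pass), locates the
#' target, and averages the located-target energies per range segment.
#' Segments containing no calibration subject inherit the value of the
#' nearest calibrated segment (flagged in the result).
#'
#' @param human_cubes List of raw [radar_cube()]s of human subjects,
#'   sharing the same range geometry.
#' @param M Number of segments (default 5).
#' @param pre A [preprocess_config()].
#' @return An [energy_standard()].
#' @export
calibrate_standard <- function(human_cubes, M = 5,
                               pre = preprocess_config()) {
  if (!is.list(human_cubes) || length(human_cubes) == 0L) {
    rher_stop("rher_calibration_error", "no calibration cubes supplied")
  }
  X <- nrow(human_cubes[[1]]$amplitudes)
  I <- as.integer(ceiling(X / M))
  seg_samples <- vector("list", M)
  for (cube in human_cubes) {
    if (nrow(cube$amplitudes) != X) {
      rher_stop("rher_calibration_error",
                "calibration cubes must share range geometry")
    }
    proc <- lowpass(remove_dc(cube, Q = dc_window(pre, cube)), pre)
    loc <- locate_target(energy_indicator(proc))
    m <- (loc$bin - 1L) %/% I + 1L
    seg_samples[[m]] <- c(seg_samples[[m]], loc$energy)
  }
  refs <- vapply(seg_samples, function(s) {
    if (length(s)) mean(s) else NA_real_
  }, numeric(1))
  inherited <- is.na(refs)
  if (all(inherited)) {
    rher_stop("rher_calibration_error", "no segment could be calibrated")
  }
  calibrated <- which(!inherited)
  for (m in which(inherited)) {
    nearest <- calibrated[which.min(abs(calibrated - m))]
    refs[m] <- refs[nearest]
  }
  energy_standard(M, I, refs, inherited)
}

# Sliding-window length for remove_dc given a config (NULL = full record).
dc_window <- function(pre, cube) {
  if (is.null(pre$window_length)) ncol(cube$amplitudes)
  else min(pre$window_length, ncol(cube$amplitudes))
}

#' Write / read an energy standard as YAML
#'
#' @param standard An [energy_standard()].
#' @param path File path.
#' @return `read_energy_standard()` returns the standard;
#'   `write_energy_standard()` returns `path` invisibly.
#' @export
write_energy_standard <- function(standard, path) {
  yaml::write_yaml(unclass(standard), path, precision = 15)
  invisible(path)
}

#' @rdname write_energy_standard
#' @export
read_energy_standard <- function(path) {
  x <- yaml::read_yaml(path)
  energy_standard(x$M, x$I, unlist(x$reference_energies),
                  unlist(x$inherited))
}
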