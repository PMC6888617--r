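# RHER classification: select respiration and heartbeat modes by human
# frequency band, form the respiratory-and-heartbeat energy ratio, estimate
# rates, and emit the human/animal label.

#' Frequency-band configuration for mode selection
#'
#' The respiration and heartbeat modes are selected by where their center
#' frequencies fall relative to *human* physiology - deliberately so: the
#' monitor protects human monitoring, and an animal whose motion lands in
#' the human bands with the wrong energy balance is exactly what RHER
#' flags.
#'
#' @param resp_band Respiration band in Hz (default `[0.1, 0.7]`,
#'   bracketing resting human breathing of 6-42 breaths/min).
#' @param heart_band Heartbeat band in Hz (default `[0.8, 2.5]`,
#'   bracketing 48-150 beats/min).
#' @param rher_log10_threshold Decision threshold on `log10(RHER)`
#'   (default 0, i.e. RHER = 1): above it the target is labelled human.
#'   The boundary is assigned to animal (fail-safe: prefer rejecting a
#'   pet over accepting one as human).
#' @param fixed_indices If `TRUE`, skip band selection and use the two
#'   lowest-frequency modes as respiration and heartbeat (the fixed
#'   VIMF1/VIMF2 convention; not robust for subjects with strong
#'   low-frequency body motion).
#' @return An object of class `band_config`.
#' @export
band_config <- function(resp_band = c(0.1, 0.7),
                        heart_band = c(0.8, 2.5),
                        rher_log10_threshold = 0,
                        fixed_indices = FALSE) {
  chk <- function(b, name) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 || b[1] > b[2]) {
      rher_stop("rher_invalid_config",
                sprintf("`%s` must be a positive interval", name))
    }
  }
  chk(resp_band, "resp_band")
  chk(heart_band, "heart_band")
  if (resp_band[2] >= heart_band[1]) {
    rher_stop("rher_invalid_config",
              "`resp_band` must lie entirely below `heart_band`")
  }
  stopifnot_scalar_number(rher_log10_threshold, "rher_log10_threshold")
  structure(list(resp_band = resp_band, heart_band = heart_band,
                 rher_log10_threshold = rher_log10_threshold,
                 fixed_indices = isTRUE(fixed_indices)),
            class = "band_config")
}

#' Select the respiration and heartbeat modes
#'
#' Among the modes whose center frequency falls inside each band, the one
#' with the largest time-domain energy is chosen.
#'
#' @param fit A [vmd()] object (modes sorted by center frequency).
#' @param bands A [band_config()].
#' @return List with `u_r`, `u_h` (the selected time-domain modes) and
#'   `indices` (their column indices in `fit$modes`).
#' @export
select_vimfs <- function(fit, bands = band_config()) {
  if (!inherits(fit, "vmd")) {
    rher_stop("rher_invalid_input", "`fit` must be a vmd object")
  }
  if (bands$fixed_indices) {
    if (ncol(fit$modes) < 2L) {
      rher_stop("rher_mode_selection",
                "fixed-index selection needs at least 2 modes")
    }
    return(list(u_r = fit$modes[, 1], u_h = fit$modes[, 2],
                indices = c(1L, 2L)))
  }
  pick <- function(band, label) {
    inside <- which(fit$center_freqs >= band[1] &
                    fit$center_freqs <= band[2])
    if (length(inside) == 0L) {
      rher_stop("rher_mode_selection",
                sprintf("no mode with center frequency in the %s band [%g, %g] Hz",
                        label, band[1], band[2]))
    }
    energies <- colSums(fit$modes[, inside, drop = FALSE]^2)
    inside[which.max(energies)]
  }
  ir <- pick(bands$resp_band, "respiration")
  ih <- pick(bands$heart_band, "heartbeat")
  list(u_r = fit$modes[, ir], u_h = fit$modes[, ih],
       indices = c(ir, ih))
}

#' Respiratory-and-heartbeat energy ratio (RHER)
#'
#' The ratio of the time-domain energies of the respiration and heartbeat
#' modes, `RHER = sum(u_r^2) / sum(u_h^2)`. Human chest returns are
#' respiration-dominated (RHER well above 1); dog, cat and rabbit returns
#' have a heartbeat component of comparable or larger energy (RHER at or
#' below 1).
#'
#' @param u_r,u_h Respiration and heartbeat mode signals.
#' @return The dimensionless energy ratio.
#' @export
rher <- function(u_r, u_h) {
  if (!is.numeric(u_r) || !is.numeric(u_h)) {
    rher_stop("rher_invalid_input", "`u_r` and `u_h` must be numeric")
  }
  eh <- sum(u_h^2)
  if (eh == 0) {
    rher_stop("rher_undefined", "zero-energy heartbeat mode: RHER undefined")
  }
  sum(u_r^2) / eh
}

#' Classify a target from its RHER value
#'
#' @param rher_value RHER value, > 0.
#' @param bands A [band_config()] carrying the log10 threshold.
#' @return `"human"` if `log10(rher_value)` exceeds the threshold,
#'   `"animal"` otherwise (boundary included).
#' @export
classify_rher <- function(rher_value, bands = band_config()) {
  stopifnot_scalar_number(rher_value, "rher_value", positive = TRUE)
  if (log10(rher_value) > bands$rher_log10_threshold) "human" else "animal"
}

#' Estimate respiration and heart rates from the selected modes
#'
#' The rate is the frequency of the FFT magnitude peak of each mode, with
#' three-point quadratic interpolation around the peak bin (the DC bin is
#' excluded).
#'
#' @param u_r,u_h Respiration and heartbeat mode signals.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector `c(resp = ..., heart = ...)` in Hz.
#' @export
estimate_rates <- function(u_r, u_h, rate) {
  c(resp = spectral_peak(u_r, rate), heart = spectral_peak(u_h, rate))
}

# FFT magnitude peak with parabolic interpolation; DC excluded.
spectral_peak <- function(x, rate) {
  n <- length(x)
  mag <- Mod(fft(x))[seq_len(n %/% 2 + 1)]
  if (length(unique(round(mag, 12))) == 1L) {
    rher_stop("rher_undefined", "flat spectrum: rate undefined")
  }
  p <- which.max(mag[-1]) + 1L
  delta <- 0
  if (p > 1L && p < length(mag)) {
    a <- mag[p - 1]; b <- mag[p]; cc <- mag[p + 1]
    den <- a - 2 * b + cc
    if (den != 0) delta <- 0.5 * (a - cc) / den
  }
  (p - 1 + delta) * rate / n
}
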