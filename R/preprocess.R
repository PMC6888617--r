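# Slow-time preprocessing: clutter/DC removal by sliding-mean subtraction
# and a 5 Hz low-pass FIR filter per range bin.

#' Preprocessing configuration
#'
#' @param window_length Sliding-window length Q in frames for
#'   [remove_dc()]; `NULL` (default) uses the full record length, i.e.
#'   per-bin global-mean subtraction, which is adequate for records of
#'   ~20 s.
#' @param cutoff Low-pass cutoff frequency in Hz (default 5, retaining the
#'   respiration and heartbeat band while rejecting high-frequency noise).
#' @param fir_order FIR filter order (taps - 1); even and >= 8. Default
#'   100 (101 taps) at a 20 Hz frame rate.
#' @param zero_phase If `TRUE` (default), compensate the filter's group
#'   delay so spectral peaks are not shifted in time.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(window_length = NULL, cutoff = 5,
                              fir_order = 100, zero_phase = TRUE) {
  if (!is.null(window_length)) {
    stopifnot_scalar_number(window_length, "window_length", positive = TRUE)
  }
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  stopifnot_scalar_number(fir_order, "fir_order", positive = TRUE)
  if (fir_order < 8 || fir_order %% 2 != 0) {
    rher_stop("rher_invalid_config", "`fir_order` must be even and >= 8")
  }
  structure(list(window_length = window_length, cutoff = cutoff,
                 fir_order = as.integer(fir_order),
                 zero_phase = isTRUE(zero_phase)),
            class = "preprocess_config")
}

#' Remove static clutter and DC along slow time
#'
#' Subtracts, for every range bin, the sliding mean of length `Q` along
#' slow time. The window is centered and kept at full length near the
#' record edges by clamping its start into the record, so `Q = N`
#' degenerates to subtracting the per-bin global mean (the default, and
#' sufficient for ~20 s records; use a shorter `Q` to track baseline drift
#' in long recordings).
#'
#' @param cube A [radar_cube()].
#' @param Q Window length in frames, `1 <= Q <= N`; default `N`.
#' @return The cube with stage `"dc_removed"`.
#' @export
remove_dc <- function(cube, Q = ncol(cube$amplitudes)) {
  if (!inherits(cube, "radar_cube")) {
    rher_stop("rher_invalid_input", "`cube` must be a radar_cube")
  }
  n <- ncol(cube$amplitudes)
  stopifnot_scalar_number(Q, "Q", class = "rher_invalid_config")
  if (Q < 1 || Q > n) {
    rher_stop("rher_invalid_config",
              sprintf("Q must be in [1, %d]", n))
  }
  Q <- as.integer(Q)
  out <- cube$amplitudes - t(apply(cube$amplitudes, 1, sliding_mean, Q = Q))
  cube$amplitudes <- out
  cube$stage <- "dc_removed"
  cube
}

# Centered sliding mean of exact length Q; the window start is clamped to
# stay inside [1, n - Q + 1].
sliding_mean <- function(x, Q) {
  n <- length(x)
  if (Q == n) return(rep(mean(x), n))
  cs <- c(0, cumsum(x))
  start <- pmin(pmax(seq_len(n) - (Q - 1L) %/% 2L, 1L), n - Q + 1L)
  (cs[start + Q] - cs[start]) / Q
}

# Hamming-window FIR low-pass coefficients (normalized cutoff wc in (0,1),
# 1 = Nyquist), `order + 1` taps, unity DC gain.
fir_lowpass_coef <- function(order, wc) {
  signal::fir1(order, wc, type = "low")
}

#' Low-pass filter along slow time
#'
#' Applies a linear-phase windowed-sinc (Hamming) FIR low-pass to every
#' range bin along slow time. In zero-phase mode the signal is extended by
#' odd reflection at both ends and the group delay removed, so waveform
#' morphology and peak timing are preserved. Passband gain is within 1%
#' for tones at or below half the cutoff.
#'
#' @param cube A [radar_cube()].
#' @param config A [preprocess_config()].
#' @return The cube with stage `"filtered"`.
#' @export
lowpass <- function(cube, config = preprocess_config()) {
  if (!inherits(cube, "radar_cube")) {
    rher_stop("rher_invalid_input", "`cube` must be a radar_cube")
  }
  fs <- cube$slow_time_rate
  if (config$cutoff >= fs / 2) {
    rher_stop("rher_invalid_config",
              "`cutoff` must be below the slow-time Nyquist frequency")
  }
  n <- ncol(cube$amplitudes)
  # keep the filter shorter than the record on short test cubes
  order <- min(config$fir_order, 2L * ((n - 1L) %/% 2L))
  order <- max(order, 2L)
  h <- fir_lowpass_coef(order, config$cutoff / (fs / 2))
  out <- t(apply(cube$amplitudes, 1, fir_apply, h = h,
                 zero_phase = config$zero_phase))
  cube$amplitudes <- out
  cube$stage <- "filtered"
  cube
}

# Apply FIR `h` to `x`; odd-reflection padding at both ends limits edge
# transients, and in zero-phase mode the integer group delay of the
# linear-phase filter is removed.
fir_apply <- function(x, h, zero_phase = TRUE) {
  n <- length(x)
  order <- length(h) - 1L
  pad <- min(order, n - 1L)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  # standard full convolution: fc[k] = sum_j xp[j] h[k - j + 1]
  fc <- stats::convolve(xp, rev(h), type = "open")
  gd <- if (zero_phase) order %/% 2L else 0L
  fc[pad + gd + seq_len(n)]
}
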