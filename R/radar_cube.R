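# The radar data cube: fast-time (range bins) x slow-time (frames) amplitude
# matrix with sampling metadata. All processing stages share this container.

#' Construct a radar data cube
#'
#' A radar cube stores the sampled echo amplitudes as an `X x N` matrix:
#' rows are fast-time range bins (mapping to distance via the round-trip
#' time of flight), columns are slow-time frames. Chest-wall motion of a
#' subject shows up as modulation along slow time at a fixed range bin.
#'
#' @param amplitudes Numeric matrix, range bins x frames; all finite,
#'   at least 1 row and 2 columns.
#' @param range_bin_spacing Range-bin spacing in meters (> 0).
#' @param slow_time_rate Frame rate in Hz (> 0).
#' @param start_range Range of the first bin in meters (default 0).
#' @param stage Processing stage tag: `"raw"`, `"dc_removed"` or
#'   `"filtered"`.
#' @param provenance Free-form list of metadata (e.g. simulation seed).
#' @return An object of class `radar_cube`.
#' @export
radar_cube <- function(amplitudes, range_bin_spacing, slow_time_rate,
                       start_range = 0, stage = "raw",
                       provenance = list()) {
  if (!is.matrix(amplitudes) || !is.numeric(amplitudes)) {
    rher_stop("rher_invalid_input", "`amplitudes` must be a numeric matrix")
  }
  if (nrow(amplitudes) < 1L || ncol(amplitudes) < 2L) {
    rher_stop("rher_invalid_input",
              "cube needs >= 1 range bin and >= 2 frames")
  }
  if (any(!is.finite(amplitudes))) {
    rher_stop("rher_invalid_input", "cube amplitudes must all be finite")
  }
  stopifnot_scalar_number(range_bin_spacing, "range_bin_spacing",
                          positive = TRUE)
  stopifnot_scalar_number(slow_time_rate, "slow_time_rate", positive = TRUE)
  stopifnot_scalar_number(start_range, "start_range")
  if (!stage %in% c("raw", "dc_removed", "filtered")) {
    rher_stop("rher_invalid_input",
              "`stage` must be one of raw, dc_removed, filtered")
  }
  structure(list(amplitudes = amplitudes,
                 range_bin_spacing = range_bin_spacing,
                 slow_time_rate = slow_time_rate,
                 start_range = start_range,
                 stage = stage,
                 provenance = provenance),
            class = "radar_cube")
}

#' @export
print.radar_cube <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(sprintf("<radar_cube> %d range bins x %d frames (%s)\n",
              d[1], d[2], x$stage))
  cat(sprintf("  range: %.3f-%.3f m (spacing %.2f mm), frame rate %g Hz\n",
              x$start_range,
              x$start_range + (d[1] - 1) * x$range_bin_spacing,
              1e3 * x$range_bin_spacing, x$slow_time_rate))
  if (!is.null(x$provenance$seed)) {
    cat(sprintf("  seed: %d\n", x$provenance$seed))
  }
  invisible(x)
}

#' Range of each bin
#'
#' @param cube A [radar_cube()].
#' @return Numeric vector of bin ranges in meters (bin start positions).
#' @export
cube_ranges <- function(cube) {
  cube$start_range +
    (seq_len(nrow(cube$amplitudes)) - 1) * cube$range_bin_spacing
}

#' Write / read a radar cube as delimited text plus a metadata sidecar
#'
#' The matrix goes to `<path>` as a tab-delimited text file (rows = range
#' bins, full double precision); the metadata goes to `<path>.meta.yaml`.
#' The round trip is lossless.
#'
#' @param cube A [radar_cube()].
#' @param path File path for the matrix; the sidecar is `<path>.meta.yaml`.
#' @return `write_radar_cube()` returns `path` invisibly;
#'   `read_radar_cube()` returns the cube.
#' @export
write_radar_cube <- function(cube, path) {
  if (!inherits(cube, "radar_cube")) {
    rher_stop("rher_invalid_input", "`cube` must be a radar_cube")
  }
  mat <- format(cube$amplitudes, digits = 17, scientific = TRUE, trim = TRUE)
  write.table(mat, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  meta <- list(range_bin_spacing = cube$range_bin_spacing,
               slow_time_rate = cube$slow_time_rate,
               start_range = cube$start_range,
               stage = cube$stage,
               n_range_bins = nrow(cube$amplitudes),
               n_frames = ncol(cube$amplitudes),
               provenance = cube$provenance)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_radar_cube
#' @export
read_radar_cube <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(path) || !file.exists(meta_path)) {
    rher_stop("rher_format_error",
              sprintf("missing cube file or sidecar for `%s`", path))
  }
  meta <- yaml::read_yaml(meta_path)
  for (field in c("range_bin_spacing", "slow_time_rate", "start_range",
                  "stage")) {
    if (is.null(meta[[field]])) {
      rher_stop("rher_format_error",
                sprintf("metadata sidecar is missing field `%s`", field))
    }
  }
  lines <- readLines(path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    rher_stop("rher_format_error",
              sprintf("non-rectangular matrix: row %d has %d fields, row 1 has %d",
                      bad, lens[bad], lens[1]))
  }
  mat <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (any(is.na(mat))) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    rher_stop("rher_format_error",
              sprintf("non-numeric or NaN entry in matrix row %d", bad))
  }
  radar_cube(mat,
             range_bin_spacing = meta$range_bin_spacing,
             slow_time_rate = meta$slow_time_rate,
             start_range = meta$start_range,
             stage = meta$stage,
             provenance = if (is.null(meta$provenance)) list()
                          else meta$provenance)
}
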