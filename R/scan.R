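#' Scan-performance arithmetic
#'
#' Closed-form measurement-rate and SNR-gain formulas for comparing
#' point-by-point volume scanning, resonant-mirror scanning and
#' ROI-restricted (chessboard) acousto-optic scanning.
#'
#' `point_scan_rate()` is the volume rate of point-by-point scanning,
#' `1 / (nx * ny * nz * dwell_time)`.
#'
#' @param nx,ny,nz Pixel counts along the three axes.
#' @param dwell_time Pixel dwell time (s).
#' @return Rate in Hz.
#' @examples
#' point_scan_rate(548, 507, 193, 30e-6)   # ~0.00062 Hz
#' @export
point_scan_rate <- function(nx, ny, nz, dwell_time) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dwell_time > 0)
  1 / (nx * ny * nz * dwell_time)
}

#' @rdname point_scan_rate
#'
#' @description `resonant_volume_rate()` is the volume rate of a resonant
#' scanner covering `n_lines` lines on each of `n_planes` planes, with an
#' optional per-plane settling time for the z-drive.
#'
#' @param line_rate Resonant line rate (Hz).
#' @param n_lines Lines per plane.
#' @param n_planes Number of z planes.
#' @param settle_per_plane Settling time per plane (s).
#' @examples
#' resonant_volume_rate(16e3, 507, 193)          # ~0.16 Hz
#' resonant_volume_rate(16e3, 507, 19, 20e-3)    # ~1 Hz
#' @export
resonant_volume_rate <- function(line_rate, n_lines, n_planes,
                                 settle_per_plane = 0) {
  stopifnot(line_rate > 0, n_lines >= 1, n_planes >= 1,
            settle_per_plane >= 0)
  1 / (n_lines * n_planes / line_rate + n_planes * settle_per_plane)
}

#' @rdname point_scan_rate
#'
#' @description `roi_gain()` is the combined gain `SNR_gain^2 * v_gain`
#' from restricting the scan to regions of interest: the total scanned
#' volume (or area, for the 2-D variant) divided by the summed ROI
#' volumes (areas).
#'
#' @param total Total scanning volume (um^3) or area (um^2).
#' @param roi Vector of ROI volumes (areas), same units.
#' @examples
#' roi_gain(1, rep(1 / 600000, 120))   # ~5000
#' @export
roi_gain <- function(total, roi) {
  if (sum(roi) <= 0) stop("summed ROI volume must be positive")
  if (sum(roi) > total * (1 + 1e-9)) stop("ROIs exceed the total volume")
  total / sum(roi)
}

#' @rdname point_scan_rate
#'
#' @description `speed_gain_ratio()` is the fold change between two
#' measurement rates.
#'
#' @param rate_a,rate_b Rates (Hz); `rate_b` > 0.
#' @export
speed_gain_ratio <- function(rate_a, rate_b) {
  stopifnot(rate_b > 0)
  rate_a / rate_b
}

#' Scanning-strategy comparison table
#'
#' Tabulates the measurement rates of chessboard AO scanning,
#' point-by-point scanning, resonant volume scanning and multi-layer
#' resonant scanning for one geometry, with fold gains relative to each
#' alternative.
#'
#' @param chessboard_rate Achieved chessboard scan rate (Hz).
#' @param nx,ny,nz Pixel counts of the full volume.
#' @param dwell_time Point-scan dwell time (s).
#' @param line_rate Resonant line rate (Hz).
#' @param n_layers Restricted layer count for multi-layer scanning.
#' @param settle_per_layer Per-layer settling time (s).
#' @return Data frame: `method`, `rate_hz`, `speed_gain` (chessboard /
#'   method).
#' @export
scan_comparison <- function(chessboard_rate = 27.8, nx = 548, ny = 507,
                            nz = 193, dwell_time = 30e-6, line_rate = 16e3,
                            n_layers = 19, settle_per_layer = 20e-3) {
  rates <- c(chessboard = chessboard_rate,
             point_by_point = point_scan_rate(nx, ny, nz, dwell_time),
             resonant_volume = resonant_volume_rate(line_rate, ny, nz),
             resonant_multilayer = resonant_volume_rate(line_rate, ny,
                                                        n_layers,
                                                        settle_per_layer))
  data.frame(method = names(rates), rate_hz = unname(rates),
             speed_gain = unname(chessboard_rate / rates))
}
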