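#' Two-dimensional noise power spectrum of an image patch
#'
#' Computes the single-realization 2D NPS of a count-map patch:
#' \deqn{NPS(u,v) = \frac{\Delta x \, \Delta y}{N_x N_y}
#'       \left| \mathrm{DFT}\{ I - \bar I \} \right|^2}
#' with global-mean subtraction only (no windowing, no detrending). Units are
#' counts^2 mm^2. The DC bin is exactly zero. Frequency axes are returned in
#' cycles/mm, in unshifted DFT order, conjugate to x (columns) and y (rows).
#'
#' The ensemble average over M regions that defines the ideal NPS is not
#' taken here: each patch is one realization (`ensemble_size = 1`), which is
#' how the roving-ROI sweep uses it.
#'
#' @param patch numeric matrix of counts, at least 8x8.
#' @param spacing `(dx, dy)` pixel pitch in mm.
#' @return An object of class `"nps2d"`: list with `values` (matrix, same
#'   shape as `patch`), `freq_u` (cycles/mm along columns/x), `freq_v`
#'   (cycles/mm along rows/y), `mean_intensity`, `ensemble_size`, `spacing`.
#' @seealso [quantum_nps_level()], [structured_nps()], [apply_visual_filter()]
#' @export
#' @examples
#' p <- matrix(rpois(64 * 64, 100), 64)
#' nps <- compute_nps_2d(p, spacing = c(1, 1))
#' mean(nps$values[-1])  # ~ 100 for Poisson noise at 1 mm pitch
compute_nps_2d <- function(patch, spacing = c(1, 1)) {
  if (!is.matrix(patch) || nrow(patch) < 8 || ncol(patch) < 8)
    stop("patch must be a matrix of at least 8x8 pixels")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  n_y <- nrow(patch); n_x <- ncol(patch)
  ibar <- mean(patch)
  vals <- Mod(stats::fft(patch - ibar))^2 * prod(spacing) / (n_x * n_y)
  vals[1, 1] <- 0  # exact, not just numerically small
  structure(list(
    values = vals,
    freq_u = fft_freq(n_x) / spacing[1],
    freq_v = fft_freq(n_y) / spacing[2],
    mean_intensity = ibar,
    ensemble_size = 1L,
    spacing = spacing
  ), class = "nps2d")
}

#' Quantum (Poisson) noise power level of a patch
#'
#' For counting noise the per-pixel variance equals the mean, so the quantum
#' component of the NPS is white (flat) at level `mean * dx * dy`
#' (counts^2 mm^2). The patch's own mean is used, giving a local quantum
#' floor per ROI.
#'
#' @inheritParams compute_nps_2d
#' @return Scalar noise power level in counts^2 mm^2.
#' @export
#' @examples
#' quantum_nps_level(matrix(100, 8, 8), c(1, 1))   # 100
#' quantum_nps_level(matrix(250, 8, 8), c(0.5, 0.5)) # 62.5
quantum_nps_level <- function(patch, spacing = c(1, 1)) {
  if (length(patch) == 0) stop("patch must be nonempty")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  mean(patch) * prod(spacing)
}

#' Structured-noise spectrum: quantum component subtracted
#'
#' Subtracts the flat quantum level from every bin of an input NPS, clamping
#' each bin at zero, to leave a spectrum of only the structured noise. Used
#' for display/diagnostics; the SNI ratio itself subtracts the quantum level
#' from the integrated filtered power (see [sni_for_patch()]) because the
#' per-bin clamp is upward-biased for a single noisy realization.
#'
#' @param input_nps an `"nps2d"` object.
#' @param quantum_level flat noise power level in counts^2 mm^2, >= 0.
#' @return A new `"nps2d"` object with clamped values (DC stays 0).
#' @export
structured_nps <- function(input_nps, quantum_level) {
  stopifnot(inherits(input_nps, "nps2d"), quantum_level >= 0)
  out <- input_nps
  out$values <- pmax(input_nps$values - quantum_level, 0)
  out$values[1, 1] <- 0
  out
}
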