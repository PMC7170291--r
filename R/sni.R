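#' Structured noise index of a single patch
#'
#' The SNI is the ratio of visually weighted structured noise power to
#' visually weighted total noise power:
#' \deqn{SNI = \frac{\int NPS_{structure} \, V \, du\, dv}
#'                  {\int NPS_{input} \, V \, du\, dv}}
#' where \eqn{NPS_{structure}} is the input NPS minus the flat quantum
#' (Poisson) level. Integrals are discrete sums over all frequency bins
#' (the DC bin carries zero weight). 0 means purely quantum noise; values
#' approaching 1 mean structure dominates.
#'
#' Because a single-realization NPS fluctuates bin-to-bin (each non-DC bin
#' is approximately exponential about its expectation), the quantum
#' subtraction is applied to the integrated filtered power and the result
#' clamped at zero once -- mathematically identical to integrating the
#' unclamped difference, and unbiased under the null, unlike summing
#' per-bin-clamped residuals.
#'
#' @param patch numeric count matrix, at least 16x16.
#' @param spacing `(dx, dy)` pixel pitch in mm.
#' @param geometry a [viewing_geometry()]; `full_image_width_px` should be
#'   the width of the full image the patch came from (defaults to the patch
#'   width if unset).
#' @param detrend if `TRUE`, remove a least-squares 2D linear ramp before
#'   the transform (off by default; the standard analysis uses global-mean
#'   subtraction only).
#' @return An object of class `"sni_score"`: list with `value` (in [0, 1]),
#'   `numerator`, `denominator` (filtered power integrals, counts^2 mm^2),
#'   and `quantum_level`.
#' @seealso [image_sni()] for the full ROI sweep.
#' @export
#' @examples
#' set.seed(1)
#' sni_for_patch(matrix(rpois(64 * 64, 1000), 64))$value  # small: pure noise
sni_for_patch <- function(patch, spacing = c(1, 1),
                          geometry = viewing_geometry(), detrend = FALSE) {
  if (!is.matrix(patch) || nrow(patch) < 16 || ncol(patch) < 16)
    stop("patch must be at least 16x16")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  if (is.null(geometry$full_image_width_px))
    geometry$full_image_width_px <- ncol(patch)

  q <- quantum_nps_level(patch, spacing)
  work <- patch
  if (detrend) {
    rows <- row(patch) - (nrow(patch) + 1) / 2
    cols <- col(patch) - (ncol(patch) + 1) / 2
    beta_r <- sum(rows * patch) / sum(rows^2)
    beta_c <- sum(cols * patch) / sum(cols^2)
    work <- patch - beta_r * rows - beta_c * cols
  }
  nps <- compute_nps_2d(work, spacing)
  w <- visual_weight_grid(nrow(patch), ncol(patch), spacing, geometry)
  den <- sum(w * nps$values)
  if (den <= 0) {  # constant patch: no noise at all
    return(structure(list(value = 0, numerator = 0, denominator = 0,
                          quantum_level = q), class = "sni_score"))
  }
  num <- max(den - q * sum(w), 0)
  structure(list(
    value = min(num / den, 1),
    numerator = num,
    denominator = den,
    quantum_level = q
  ), class = "sni_score")
}

#' @export
print.sni_score <- function(x, ...) {
  cat(sprintf("<sni_score> %.4f (quantum level %.4g counts^2.mm^2)\n",
              x$value, x$quantum_level))
  invisible(x)
}
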