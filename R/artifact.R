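#' Fourier-domain artifact image
#'
#' Visual isolation of structured nonuniformity: the mean-subtracted image
#' is transformed to the Fourier domain, every coefficient whose magnitude
#' is consistent with pure counting noise is zeroed, and the inverse
#' transform of what survives is the artifact image.
#'
#' Under the Gaussian-noise null matching the quantum variance (per-pixel
#' variance = mean count \eqn{\bar I}), each non-DC coefficient of the
#' unnormalized DFT has magnitude distributed Rayleigh with scale
#' \eqn{\sqrt{N_x N_y \bar I / 2}}. The threshold is the `quantile` of that
#' law; the default `1 - 1/(Nx*Ny)` expects about one false coefficient per
#' image. Retained coefficients keep their full complex value, so Hermitian
#' symmetry (conjugate pairs have equal magnitude) is preserved and the
#' inverse transform is real.
#'
#' @param x count matrix (full flood or patch), at least 16x16.
#' @param quantile probability level of the Rayleigh null used as the
#'   magnitude cutoff. Default `1 - 1/(Nx*Ny)`.
#' @return An object of class `"artifact_image"`: `values` (real matrix,
#'   same shape as `x`), `retained_bins`, `threshold`, `quantile`.
#' @export
#' @examples
#' set.seed(1)
#' a <- artifact_image(matrix(rpois(64 * 64, 500), 64))
#' a$retained_bins  # ~1 expected for a defect-free flood
artifact_image <- function(x, quantile = NULL) {
  if (inherits(x, "flood_image")) x <- x$pixels
  if (!is.matrix(x) || nrow(x) < 16 || ncol(x) < 16)
    stop("input must be at least 16x16")
  n_y <- nrow(x); n_x <- ncol(x)
  n_bins <- n_y * n_x
  if (is.null(quantile)) quantile <- 1 - 1 / n_bins
  stopifnot(quantile > 0, quantile < 1)

  ibar <- mean(x)
  f <- stats::fft(x - ibar)
  scale <- sqrt(n_bins * ibar / 2)
  threshold <- scale * sqrt(-2 * log1p(-quantile))  # Rayleigh quantile
  keep <- Mod(f) > threshold
  keep[1, 1] <- FALSE
  f[!keep] <- 0
  vals <- Re(stats::fft(f, inverse = TRUE)) / n_bins
  structure(list(
    values = vals,
    retained_bins = sum(keep),
    threshold = threshold,
    quantile = quantile
  ), class = "artifact_image")
}

#' @export
print.artifact_image <- function(x, ...) {
  cat(sprintf("<artifact_image> %dx%d, %d coefficients retained (cutoff %.4g)\n",
              nrow(x$values), ncol(x$values), x$retained_bins, x$threshold))
  invisible(x)
}
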