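#' Viewing geometry for the human visual response filter
#'
#' The visual response function is evaluated in cycles/degree, so spatial
#' frequencies in the image must be mapped through the geometry under which
#' a reader views the flood: viewing distance, physical display size, and
#' how many image pixels span that display. The display size always refers
#' to the full image width, so a 64-px roving ROI occupies 64/W of the
#' display and every ROI shares one frequency mapping.
#'
#' @param distance_cm viewing distance in cm (default 150).
#' @param display_cm displayed image width in cm (default 6.5).
#' @param peak_cyc_per_deg frequency (cycles/degree) at which the visual
#'   response peaks (default 4).
#' @param full_image_width_px number of image pixels spanning `display_cm`;
#'   may be left `NULL` and filled from the image being scored.
#' @param filter_exponent power applied to the visual response when
#'   weighting the NPS: 1 (weight by V, the default) or 2 (weight by V^2,
#'   i.e. treat V as an amplitude transfer function).
#' @return An object of class `"viewing_geometry"`.
#' @export
#' @examples
#' g <- viewing_geometry(full_image_width_px = 256)
#' visual_filter_scale(g)  # 0.040625
viewing_geometry <- function(distance_cm = 150, display_cm = 6.5,
                             peak_cyc_per_deg = 4, full_image_width_px = NULL,
                             filter_exponent = 1) {
  stopifnot(distance_cm > 0, display_cm > 0, peak_cyc_per_deg > 0,
            filter_exponent %in% c(1, 2))
  if (!is.null(full_image_width_px)) stopifnot(full_image_width_px > 0)
  structure(list(
    distance_cm = distance_cm,
    display_cm = display_cm,
    peak_cyc_per_deg = peak_cyc_per_deg,
    full_image_width_px = full_image_width_px,
    filter_exponent = filter_exponent
  ), class = "viewing_geometry")
}

#' Scale factor of the visual response function
#'
#' The radial visual response is \eqn{V(r) = r^{1.3} \exp(-c r^2)} with `r`
#' in cycles/degree. Setting \eqn{dV/dr = 0} gives the closed form
#' \eqn{c = 1.3 / (2 r_*^2)} for a peak at \eqn{r_*}; the defaults
#' (peak at 4 cycles/degree) give c = 0.040625 (cycles/degree)^-2.
#'
#' @param geometry a [viewing_geometry()].
#' @return Scalar `c` in (cycles/degree)^-2.
#' @export
visual_filter_scale <- function(geometry) {
  stopifnot(inherits(geometry, "viewing_geometry"))
  1.3 / (2 * geometry$peak_cyc_per_deg^2)
}

#' Convert image spatial frequency to visual cycles/degree
#'
#' Maps a frequency in cycles/pixel to cycles/degree of visual angle under
#' the small-angle approximation:
#' `r = f * (full_image_width_px / display_cm) * distance_cm * pi / 180`.
#' At 150 cm the small-angle error is below 0.1%.
#'
#' @param f_cyc_per_px frequency in cycles/pixel (vector or matrix).
#' @param geometry a [viewing_geometry()] with `full_image_width_px` set.
#' @return Frequencies in cycles/degree, same shape as `f_cyc_per_px`.
#' @export
frequency_to_degrees <- function(f_cyc_per_px, geometry) {
  stopifnot(inherits(geometry, "viewing_geometry"))
  if (is.null(geometry$full_image_width_px))
    stop("full_image_width_px must be set to map frequencies to degrees")
  f_cyc_per_px * (geometry$full_image_width_px / geometry$display_cm) *
    geometry$distance_cm * pi / 180
}

#' Radial human visual response V(r)
#'
#' @param r_deg radial frequency in cycles/degree.
#' @param geometry a [viewing_geometry()].
#' @return V(r) = r^1.3 exp(-c r^2); V(0) = 0.
#' @export
visual_response <- function(r_deg, geometry) {
  cc <- visual_filter_scale(geometry)
  r_deg^1.3 * exp(-cc * r_deg^2)
}

# weight grid W = V(r)^exponent on the unshifted DFT grid of an (n_y, n_x)
# patch; cached, since the roving sweep evaluates the same grid ~170x/image
visual_weight_grid <- function(n_y, n_x, spacing, geometry) {
  key <- paste(n_y, n_x, spacing[1], spacing[2], geometry$distance_cm,
               geometry$display_cm, geometry$peak_cyc_per_deg,
               geometry$full_image_width_px, geometry$filter_exponent,
               sep = "_")
  hit <- .sniqc_cache[[key]]
  if (!is.null(hit)) return(hit)
  # radial frequency in cycles/pixel; anisotropic spacing handled by axis
  fy <- fft_freq(n_y)  # cycles/pixel along rows (y)
  fx <- fft_freq(n_x)  # cycles/pixel along columns (x)
  r_px <- sqrt(outer(fy^2, fx^2, "+"))
  w <- visual_response(frequency_to_degrees(r_px, geometry), geometry)
  w <- w^geometry$filter_exponent
  w[1, 1] <- 0
  .sniqc_cache[[key]] <- w
  w
}

#' Apply the human visual response filter to an NPS
#'
#' Multiplies each NPS bin by `V(r)^filter_exponent`, where `r` is the bin's
#' radial frequency expressed in cycles/degree through the viewing geometry.
#' The DC weight is zero.
#'
#' @param nps an `"nps2d"` object.
#' @param geometry a [viewing_geometry()]; if `full_image_width_px` is
#'   `NULL` it defaults to the patch width (appropriate only when the patch
#'   is the full image).
#' @return The filtered `"nps2d"` object.
#' @export
apply_visual_filter <- function(nps, geometry = viewing_geometry()) {
  stopifnot(inherits(nps, "nps2d"))
  if (is.null(geometry$full_image_width_px))
    geometry$full_image_width_px <- ncol(nps$values)
  w <- visual_weight_grid(nrow(nps$values), ncol(nps$values), nps$spacing,
                          geometry)
  out <- nps
  out$values <- nps$values * w
  out
}
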