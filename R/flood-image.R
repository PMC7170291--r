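#' Flood-field image container
#'
#' A flood image is a 2D map of detected counts plus the acquisition metadata
#' the QC pipeline needs: pixel spacing, station, timestamp and isotope.
#' Pixel geometry follows the usual image convention: x is the column index,
#' y is the row index, origin at the top-left.
#'
#' @param pixels integer matrix of non-negative counts (rows = y, cols = x).
#' @param spacing numeric length-2 `(dx, dy)` pixel pitch in mm. Default 1 mm.
#' @param station station (camera) identifier.
#' @param acquired_at acquisition time (`POSIXct`, or anything
#'   `as.POSIXct()` accepts).
#' @param isotope isotope label, e.g. `"Co-57"` or `"Tc-99m"`.
#' @param spacing_assumed logical; `TRUE` when the spacing was not present in
#'   the source file and the 1 mm default was substituted.
#' @param study_description,series_description free-text descriptions used by
#'   the QC sorting rules.
#'
#' @return An object of class `"flood_image"`: a list with fields `pixels`,
#'   `spacing`, `station`, `acquired_at`, `isotope`, `total_counts`,
#'   `spacing_assumed`, `study_description`, `series_description`.
#' @export
#' @examples
#' f <- flood_image(matrix(100L, 64, 64), station = "CAM1")
#' f$total_counts
flood_image <- function(pixels, spacing = c(1, 1), station = "UNKNOWN",
                        acquired_at = as.POSIXct("2000-01-01 00:00:00", tz = "UTC"),
                        isotope = "Co-57", spacing_assumed = FALSE,
                        study_description = "NM DAILY QC",
                        series_description = "UNIFORMITY FLOOD") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (any(pixels < 0)) stop("pixels must be non-negative counts")
  if (any(abs(pixels - round(pixels)) > 1e-9)) stop("pixels must be integer counts")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  if (any(spacing <= 0)) stop("spacing must be positive")
  storage.mode(pixels) <- "double"
  structure(list(
    pixels = pixels,
    spacing = spacing,
    station = as.character(station),
    acquired_at = as.POSIXct(acquired_at, tz = "UTC"),
    isotope = as.character(isotope),
    total_counts = sum(pixels),
    spacing_assumed = isTRUE(spacing_assumed),
    study_description = as.character(study_description),
    series_description = as.character(series_description)
  ), class = "flood_image")
}

#' @export
print.flood_image <- function(x, ...) {
  cat(sprintf(
    "<flood_image> %dx%d px, %.3g counts, station %s, %s, %s\n",
    nrow(x$pixels), ncol(x$pixels), x$total_counts, x$station,
    x$isotope, format(x$acquired_at, "%Y-%m-%d %H:%M:%S")
  ))
  invisible(x)
}
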