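#' Square region of interest
#'
#' @param row,col 0-based origin (top-left corner) in pixels.
#' @param size side length in pixels (square), >= 16.
#' @return An object of class `"roi"`.
#' @export
roi <- function(row, col, size) {
  stopifnot(row >= 0, col >= 0, size >= 16)
  structure(list(origin = c(row = as.integer(row), col = as.integer(col)),
                 size = as.integer(size)), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> origin (%d,%d) size %d\n",
              x$origin[1], x$origin[2], x$size), sep = "")
  invisible(x)
}

roi_patch <- function(pixels, r) {
  pixels[(r$origin[["row"]] + 1):(r$origin[["row"]] + r$size),
         (r$origin[["col"]] + 1):(r$origin[["col"]] + r$size), drop = FALSE]
}

# centered span of length d inside dim, extra margin pixel to bottom/right
centered_origin <- function(dim, d) (dim - d) %/% 2L

#' The two large overlapping square ROIs
#'
#' Two equally sized square ROIs encompassing the central `fraction`
#' (default 90%) of the image: side `s = round(fraction * min(rows, cols))`,
#' the first anchored at the top-left corner of the centered
#' `fraction*rows x fraction*cols` region, the second at its bottom-right.
#' On a square image the two coincide and a single ROI is returned.
#'
#' @param rows,cols image dimensions in pixels.
#' @param fraction linear fraction of the field covered (default 0.9).
#' @return List of [roi()] objects (length 1 or 2).
#' @export
#' @examples
#' length(large_rois(256, 256))  # 1: the two squares coincide
#' large_rois(256, 180)          # two 162-px squares spanning the center
large_rois <- function(rows, cols, fraction = 0.9) {
  if (min(rows, cols) * fraction < 64)
    stop("image too small for large-ROI analysis")
  s <- round_half_up(fraction * min(rows, cols))
  c_rows <- round_half_up(fraction * rows)
  c_cols <- round_half_up(fraction * cols)
  r0 <- centered_origin(rows, c_rows)
  c0 <- centered_origin(cols, c_cols)
  a <- roi(r0, c0, s)
  b <- roi(r0 + c_rows - s, c0 + c_cols - s, s)
  if (identical(a, b)) list(a) else list(a, b)
}

#' Roving-ROI sweep positions
#'
#' Origins of a small square window (default 64x64 px) swept over the whole
#' image in fixed increments (default 16 px). When a dimension minus the
#' window size is not a multiple of the step, one extra position clamped to
#' that image edge is appended so the sweep covers the entire image.
#'
#' @param rows,cols image dimensions in pixels.
#' @param size window side in pixels.
#' @param step shift increment in pixels.
#' @return List of [roi()] objects in raster (row-major) order.
#' @export
#' @examples
#' length(roving_rois(256, 256))  # 169 positions (13 x 13)
roving_rois <- function(rows, cols, size = 64, step = 16) {
  if (rows < size || cols < size) stop("image smaller than the roving window")
  axis_origins <- function(dim) {
    o <- seq(0L, dim - size, by = step)
    if ((dim - size) %% step != 0) o <- c(o, dim - size)
    unique(o)
  }
  ro <- axis_origins(rows); co <- axis_origins(cols)
  out <- vector("list", length(ro) * length(co))
  k <- 1L
  for (r in ro) for (cc in co) {
    out[[k]] <- roi(r, cc, size)
    k <- k + 1L
  }
  out
}

#' Image-level SNI: maximum over the ROI set
#'
#' Scores every ROI -- the large central square(s) first, then the roving
#' windows in raster order -- with [sni_for_patch()] and assigns the image
#' the maximum score. Ties keep the earliest ROI in that ordering. The
#' result also carries the winning ROI's NPS and the full-image artifact
#' map for the diagnostic quadrant figure.
#'
#' @param flood a [flood_image()] (or a bare count matrix).
#' @param geometry a [viewing_geometry()]; its `full_image_width_px`
#'   defaults to the image width.
#' @param roi_config list with elements `fraction` (large-ROI coverage,
#'   default 0.9), `size` and `step` (roving window, defaults 64 and 16).
#' @param artifact if `TRUE` (default) compute the full-image
#'   [artifact_image()] as part of the result.
#' @return An object of class `"sni_result"`: `image_sni`, `best_roi`,
#'   `per_roi` (data.frame: origin_row, origin_col, size, sni), `best_nps`,
#'   `artifact`.
#' @export
image_sni <- function(flood, geometry = viewing_geometry(),
                      roi_config = list(fraction = 0.9, size = 64, step = 16),
                      artifact = TRUE) {
  px <- if (inherits(flood, "flood_image")) flood$pixels else flood
  spacing <- if (inherits(flood, "flood_image")) flood$spacing else c(1, 1)
  if (is.null(geometry$full_image_width_px))
    geometry$full_image_width_px <- ncol(px)
  fraction <- roi_config$fraction %||% 0.9
  size <- roi_config$size %||% 64
  step <- roi_config$step %||% 16

  rois <- c(large_rois(nrow(px), ncol(px), fraction),
            roving_rois(nrow(px), ncol(px), size, step))
  scores <- numeric(length(rois))
  for (i in seq_along(rois))
    scores[i] <- sni_for_patch(roi_patch(px, rois[[i]]), spacing, geometry)$value
  best <- which.max(scores)  # first index attaining the max
  best_patch <- roi_patch(px, rois[[best]])

  structure(list(
    image_sni = scores[best],
    best_roi = rois[[best]],
    per_roi = data.frame(
      origin_row = vapply(rois, function(r) r$origin[["row"]], integer(1)),
      origin_col = vapply(rois, function(r) r$origin[["col"]], integer(1)),
      size = vapply(rois, function(r) r$size, integer(1)),
      sni = scores
    ),
    best_nps = compute_nps_2d(best_patch, spacing),
    artifact = if (artifact) artifact_image(px) else NULL
  ), class = "sni_result")
}

#' @export
print.sni_result <- function(x, ...) {
  cat(sprintf("<sni_result> image SNI %.4f at ROI (%d,%d) size %d (%d ROIs)\n",
              x$image_sni, x$best_roi$origin[1], x$best_roi$origin[2],
              x$best_roi$size, nrow(x$per_roi)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
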