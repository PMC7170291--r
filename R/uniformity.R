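#' NEMA-style 9-point smoothing
#'
#' Convolution with the standard 3x3 kernel `[[1,2,1],[2,4,2],[1,2,1]]/16`;
#' at edges the kernel is renormalized over its in-bounds taps so a constant
#' image stays constant.
#'
#' @param image numeric matrix, at least 3x3.
#' @return Smoothed matrix, same shape.
#' @export
nema_smooth <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3)
    stop("image must be at least 3x3")
  k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3)
  num <- matrix(0, nrow(image), ncol(image))
  den <- matrix(0, nrow(image), ncol(image))
  n <- nrow(image); m <- ncol(image)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    rs <- max(1, 1 + dr):min(n, n + dr)   # destination rows
    cs <- max(1, 1 + dc):min(m, m + dc)
    num[rs, cs] <- num[rs, cs] + w * image[rs - dr, cs - dc]
    den[rs, cs] <- den[rs, cs] + w
  }
  num / den
}

#' UFOV / CFOV field-of-view masks
#'
#' The useful field of view (UFOV) is the centered 90% of the full field in
#' each linear dimension; the central field of view (CFOV) is the centered
#' 75% of the UFOV dimensions. Dimensions are rounded half-up; regions are
#' centered with any odd leftover margin pixel falling on the bottom/right.
#'
#' @param rows,cols image dimensions, each >= 16.
#' @param kind `"ufov"` or `"cfov"`.
#' @return An object of class `"fov_mask"`: `kind` and `rect`
#'   `(row0, col0, rows, cols)` as 0-based half-open pixel bounds.
#' @export
#' @examples
#' fov_mask(256, 256, "ufov")$rect  # 230 x 230 centered
#' fov_mask(256, 256, "cfov")$rect  # 173 x 173 centered
fov_mask <- function(rows, cols, kind = c("ufov", "cfov")) {
  kind <- match.arg(kind)
  if (rows < 16 || cols < 16) stop("image must be at least 16x16")
  u_r <- round_half_up(0.9 * rows)
  u_c <- round_half_up(0.9 * cols)
  if (kind == "ufov") {
    d_r <- u_r; d_c <- u_c
  } else {
    d_r <- round_half_up(0.75 * u_r)
    d_c <- round_half_up(0.75 * u_c)
  }
  structure(list(
    kind = kind,
    rect = c(row0 = centered_origin(rows, d_r),
             col0 = centered_origin(cols, d_c),
             rows = d_r, cols = d_c)
  ), class = "fov_mask")
}

#' Integral uniformity over a field of view
#'
#' The traditional pixel-value uniformity metric:
#' `IU = 100 * (max - min) / (max + min)` over the (by default NEMA-smoothed)
#' pixels inside the mask. IU is invariant to global intensity scaling.
#'
#' @param image count matrix.
#' @param mask a [fov_mask()]; defaults to the UFOV of `image`.
#' @param smooth apply [nema_smooth()] first (default `TRUE`).
#' @return IU in percent.
#' @export
#' @examples
#' img <- matrix(100, 64, 64); img[30, 30] <- 110; img[35, 35] <- 90
#' integral_uniformity(img, fov_mask(64, 64, "ufov"), smooth = FALSE)
integral_uniformity <- function(image, mask = NULL, smooth = TRUE) {
  if (inherits(image, "flood_image")) image <- image$pixels
  if (is.null(mask)) mask <- fov_mask(nrow(image), ncol(image), "ufov")
  stopifnot(inherits(mask, "fov_mask"))
  r <- mask$rect
  if (r[["row0"]] + r[["rows"]] > nrow(image) ||
      r[["col0"]] + r[["cols"]] > ncol(image))
    stop("mask does not fit inside the image")
  img <- if (smooth) nema_smooth(image) else image
  sub <- img[(r[["row0"]] + 1):(r[["row0"]] + r[["rows"]]),
             (r[["col0"]] + 1):(r[["col0"]] + r[["cols"]])]
  mx <- max(sub); mn <- min(sub)
  if (mx + mn == 0) stop("integral uniformity undefined: all-zero region")
  100 * (mx - mn) / (mx + mn)
}
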