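#' Sorting rule for incoming DICOMs
#'
#' Cameras send every study to the physics share, so genuine uniformity QC
#' floods must be separated from clinical and calibration studies using
#' header attributes only: station allow-list, description tokens, minimum
#' total counts and allowed matrix sizes.
#'
#' @param allowed_stations character vector of station names.
#' @param series_tokens tokens matched (case-insensitively) against the
#'   study and series descriptions; one match suffices.
#' @param min_counts minimum total counts (default 1e6).
#' @param matrix_sizes list of allowed `(rows, cols)` pairs.
#' @return An object of class `"sort_rule"`.
#' @export
sort_rule <- function(allowed_stations,
                      series_tokens = c("UNIFORMITY", "FLOOD", "DAILY QC"),
                      min_counts = 1e6,
                      matrix_sizes = list(c(256, 256), c(128, 128),
                                          c(64, 64))) {
  stopifnot(min_counts >= 0)
  structure(list(allowed_stations = as.character(allowed_stations),
                 series_tokens = as.character(series_tokens),
                 min_counts = min_counts,
                 matrix_sizes = matrix_sizes),
            class = "sort_rule")
}

#' Is this image a genuine uniformity QC flood?
#'
#' Pure function of header fields (plus the pixel-sum count). Criteria are
#' checked in order -- station, description, counts, matrix size -- and the
#' reason names the first one that fails.
#'
#' @param flood a [flood_image()].
#' @param rule a [sort_rule()].
#' @return List `(accepted, reason)`; reason is `"ok"` when accepted.
#' @export
is_qc_flood <- function(flood, rule) {
  stopifnot(inherits(flood, "flood_image"), inherits(rule, "sort_rule"))
  if (!(flood$station %in% rule$allowed_stations))
    return(list(accepted = FALSE, reason = "station"))
  desc <- toupper(paste(flood$study_description, flood$series_description))
  hit <- any(vapply(rule$series_tokens,
                    function(t) grepl(toupper(t), desc, fixed = TRUE),
                    logical(1)))
  if (!hit) return(list(accepted = FALSE, reason = "description"))
  if (flood$total_counts < rule$min_counts)
    return(list(accepted = FALSE, reason = "low_counts"))
  dims_ok <- any(vapply(rule$matrix_sizes, function(ms)
    ms[1] == nrow(flood$pixels) && ms[2] == ncol(flood$pixels), logical(1)))
  if (!dims_ok) return(list(accepted = FALSE, reason = "matrix_size"))
  list(accepted = TRUE, reason = "ok")
}

# next free path: base.ext, base_1.ext, base_2.ext, ...
noclobber_path <- function(dir, base, ext) {
  p <- file.path(dir, paste0(base, ext))
  i <- 0L
  while (file.exists(p)) {
    i <- i + 1L
    p <- file.path(dir, paste0(base, "_", i, ext))
  }
  p
}

#' Archive an analyzed flood by station
#'
#' Copies (or rewrites) the DICOM under `root/images/<station>/` and the
#' quadrant figure under `root/figures/<station>/`. Filenames embed station
#' and timestamp; existing files are never overwritten -- collisions get a
#' numeric suffix.
#'
#' @param flood a [flood_image()].
#' @param result the matching [image_sni()] result.
#' @param root archive root directory (created as needed).
#' @param source_path original DICOM to copy; when `NULL` the flood is
#'   re-serialized with [write_synthetic_dicom()].
#' @return List `(dicom_path, figure_path)`.
#' @export
archive_flood <- function(flood, result, root, source_path = NULL) {
  st <- gsub("[^A-Za-z0-9_-]", "_", flood$station)
  img_dir <- file.path(root, "images", st)
  fig_dir <- file.path(root, "figures", st)
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  base <- paste0(st, "_", format(flood$acquired_at, "%Y%m%d_%H%M%S"))

  dcm <- noclobber_path(img_dir, base, ".dcm")
  if (!is.null(source_path) && file.exists(source_path)) {
    file.copy(source_path, dcm)
  } else {
    write_synthetic_dicom(flood, dcm)
  }
  fig <- noclobber_path(fig_dir, base, ".png")
  render_quadrant_figure(flood, result, fig)
  list(dicom_path = dcm, figure_path = fig)
}

# rescale a matrix to [0,1] (constant -> 0.5) and resize to side s
# by nearest-neighbour index (deterministic, no graphics device)
panel_gray <- function(m, s = 256) {
  rng <- range(m)
  g <- if (diff(rng) == 0) matrix(0.5, nrow(m), ncol(m))
       else (m - rng[1]) / diff(rng)
  ri <- pmin(nrow(g), pmax(1, ceiling(seq_len(s) * nrow(g) / s)))
  ci <- pmin(ncol(g), pmax(1, ceiling(seq_len(s) * ncol(g) / s)))
  g[ri, ci]
}

#' Render the four-quadrant diagnostic figure
#'
#' The standard layout used for alert attachments: input flood upper left,
#' artifact image upper right, highest-SNI ROI lower left, the 2D NPS of
#' that ROI (log-scaled, origin centered) lower right. Written as a PNG
#' bitmap with the layout, station, timestamp and SNI recorded in the PNG
#' text metadata, so the output is byte-deterministic for fixed inputs.
#'
#' @param flood a [flood_image()].
#' @param result the matching [image_sni()] result (with artifact).
#' @param path output path.
#' @param panel_px side of each quadrant in pixels (default 256).
#' @return `path`, invisibly.
#' @export
render_quadrant_figure <- function(flood, result, path, panel_px = 256) {
  stopifnot(inherits(result, "sni_result"))
  art <- if (!is.null(result$artifact)) result$artifact$values
         else matrix(0, nrow(flood$pixels), ncol(flood$pixels))
  best_patch <- roi_patch(flood$pixels, result$best_roi)
  nps_v <- result$best_nps$values
  # center the origin and compress the huge dynamic range for display
  sh_r <- seq_len(nrow(nps_v)); sh_r <- c(sh_r[sh_r > nrow(nps_v) / 2], sh_r[sh_r <= nrow(nps_v) / 2])
  sh_c <- seq_len(ncol(nps_v)); sh_c <- c(sh_c[sh_c > ncol(nps_v) / 2], sh_c[sh_c <= ncol(nps_v) / 2])
  nps_disp <- log1p(nps_v[sh_r, sh_c])

  s <- panel_px
  canvas <- matrix(1, 2 * s + 3, 2 * s + 3)  # white 1-px frame/separators
  canvas[2:(s + 1), 2:(s + 1)] <- panel_gray(flood$pixels, s)
  canvas[2:(s + 1), (s + 3):(2 * s + 2)] <- panel_gray(art, s)
  canvas[(s + 3):(2 * s + 2), 2:(s + 1)] <- panel_gray(best_patch, s)
  canvas[(s + 3):(2 * s + 2), (s + 3):(2 * s + 2)] <- panel_gray(nps_disp, s)

  png::writePNG(canvas, path, text = c(
    title = "SNI quadrant figure",
    layout = "UL=input;UR=artifact;LL=best_roi;LR=nps",
    station = flood$station,
    acquired = format(flood$acquired_at, "%Y-%m-%d %H:%M:%S"),
    sni = sprintf("%.4f", result$image_sni),
    best_roi = sprintf("(%d,%d)x%d", result$best_roi$origin[1],
                       result$best_roi$origin[2], result$best_roi$size)
  ))
  invisible(path)
}
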