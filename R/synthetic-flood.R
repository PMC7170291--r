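#' Parameterized sensitivity defect
#'
#' Multiplicative nonuniformity applied to an ideal flat sensitivity map.
#' Four conventional defect classes emulate the failure modes daily flood QC
#' is meant to catch:
#' \describe{
#'   \item{`pmt_dropout`}{Gaussian-profile sensitivity dip of depth
#'     `amplitude` and FWHM `width` px, as from a failing photomultiplier
#'     tube.}
#'   \item{`gradient`}{unit-mean linear ramp with peak-to-peak swing
#'     `2*amplitude` along `orientation` degrees.}
#'   \item{`sinusoid`}{`1 + amplitude*sin(2*pi*f*(row*cos + col*sin))` with
#'     `f = width` cycles/pixel.}
#'   \item{`edge_band`}{border strip of `width` px on the side selected by
#'     `orientation` (0 top, 90 right, 180 bottom, 270 left) raised by
#'     `amplitude`.}
#' }
#'
#' @param kind one of `"pmt_dropout"`, `"gradient"`, `"sinusoid"`,
#'   `"edge_band"`.
#' @param amplitude dimensionless fraction of mean sensitivity in [0, 1).
#' @param center `(row, col)` defect center in pixels (pmt_dropout); image
#'   center when `NULL`.
#' @param width FWHM in px (pmt_dropout), spatial frequency in cycles/px
#'   (sinusoid), or band width in px (edge_band).
#' @param orientation degrees (gradient/sinusoid direction, edge_band side).
#' @return An object of class `"defect_spec"`.
#' @export
#' @examples
#' defect_spec("pmt_dropout", amplitude = 0.2, width = 32)
defect_spec <- function(kind = c("pmt_dropout", "gradient", "sinusoid",
                                 "edge_band"),
                        amplitude, center = NULL, width = NULL,
                        orientation = 0) {
  kind <- match.arg(kind)
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1)")
  if (is.null(width)) {
    width <- switch(kind, pmt_dropout = 32, gradient = 1,
                    sinusoid = 0.05, edge_band = 16)
  }
  if (width <= 0) stop("width must be positive")
  structure(list(kind = kind, amplitude = amplitude, center = center,
                 width = width, orientation = orientation),
            class = "defect_spec")
}

defect_field <- function(d, rows, cols) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  switch(d$kind,
    pmt_dropout = {
      cen <- d$center %||% c((rows + 1) / 2, (cols + 1) / 2)
      sigma <- d$width / (2 * sqrt(2 * log(2)))
      d2 <- (rr - cen[1])^2 + (cc - cen[2])^2
      1 - d$amplitude * exp(-d2 / (2 * sigma^2))
    },
    gradient = {
      th <- d$orientation * pi / 180
      p <- (cc - (cols + 1) / 2) * cos(th) + (rr - (rows + 1) / 2) * sin(th)
      span <- max(abs(p))
      if (span == 0) matrix(1, rows, cols) else 1 + d$amplitude * p / span
    },
    sinusoid = {
      th <- d$orientation * pi / 180
      1 + d$amplitude * sin(2 * pi * d$width * (rr * cos(th) + cc * sin(th)))
    },
    edge_band = {
      w <- ceiling(d$width)
      band <- switch(as.character(d$orientation %% 360),
        "0" = rr <= w, "90" = cc > cols - w,
        "180" = rr > rows - w, "270" = cc <= w,
        rr <= w)  # default: top
      1 + d$amplitude * band
    }
  )
}

#' Build a relative sensitivity map from defect specs
#'
#' The map is the product of a flat field and each defect's multiplicative
#' field, renormalized to unit mean. A map that becomes non-positive
#' anywhere is rejected with an error naming the offending defect.
#'
#' @param shape `(rows, cols)`, each >= 64.
#' @param defects list of [defect_spec()] objects (may be empty).
#' @return An object of class `"sensitivity_map"`: `values` (unit-mean
#'   matrix, all > 0) and `shape`.
#' @export
#' @examples
#' m <- make_sensitivity_map(c(64, 64), list())
#' range(m$values)  # all ones
make_sensitivity_map <- function(shape, defects = list()) {
  rows <- shape[1]; cols <- shape[2]
  if (rows < 64 || cols < 64) stop("shape dimensions must be >= 64")
  vals <- matrix(1, rows, cols)
  for (d in defects) {
    stopifnot(inherits(d, "defect_spec"))
    vals <- vals * defect_field(d, rows, cols)
    if (any(vals <= 0))
      stop(sprintf("defect '%s' (amplitude %.3g) drives sensitivity non-positive",
                   d$kind, d$amplitude))
  }
  vals <- vals / mean(vals)
  structure(list(values = vals, shape = c(rows, cols)),
            class = "sensitivity_map")
}

# deterministic 31-bit seed from a base seed plus station/day labels
derive_seed <- function(seed, station = "", day = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(paste0(station, "#", day)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Simulate a Poisson flood acquisition
#'
#' Draws per-pixel counts independently from Poisson distributions with
#' means `total_counts * map / sum(map)`, i.e. a flood of the requested
#' total over a detector with the given relative sensitivity. The caller's
#' RNG state is left untouched.
#'
#' @param map a [make_sensitivity_map()] result (or a bare positive matrix).
#' @param total_counts expected total counts, >= 1e4. Default 5e6, a typical
#'   daily flood.
#' @param seed integer seed; identical seeds give identical images.
#' @param station,acquired_at,isotope metadata passed to [flood_image()].
#' @param spacing pixel pitch in mm.
#' @param ... further metadata for [flood_image()] (e.g.
#'   `series_description`).
#' @return A [flood_image()].
#' @export
#' @examples
#' m <- make_sensitivity_map(c(64, 64), list())
#' f <- simulate_flood(m, total_counts = 1e6, seed = 1)
simulate_flood <- function(map, total_counts = 5e6, seed = 1,
                           station = "SIM1",
                           acquired_at = as.POSIXct("2024-01-01 06:00:00",
                                                    tz = "UTC"),
                           isotope = "Co-57", spacing = c(1, 1), ...) {
  vals <- if (inherits(map, "sensitivity_map")) map$values else map
  stopifnot(all(vals > 0))
  if (total_counts < 1e4) stop("total_counts must be >= 1e4")
  mu <- total_counts * vals / sum(vals)
  px <- withr_seed(seed, matrix(stats::rpois(length(mu), mu), nrow(vals)))
  flood_image(px, spacing = spacing, station = station,
              acquired_at = acquired_at, isotope = isotope, ...)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a multi-day, multi-station QC campaign
#'
#' One flood per station per day. The defect schedule maps day numbers to
#' defect lists; an entry may restrict itself to named stations via a
#' `stations` field. Each image's truth label is `TRUE` when any scheduled
#' defect with amplitude at or above `service_level` (the "service-worthy"
#' threshold, default 0.10) applied to that station that day -- labels are a
#' deterministic function of the schedule. Per-image seeds are derived from
#' `seed`, the station name and the day by a fixed mixing rule.
#'
#' @param n_days number of days, >= 1.
#' @param stations character vector of station names.
#' @param defect_schedule named list: `"day"` -> either a list of
#'   [defect_spec()]s (all stations) or
#'   `list(defects = list(...), stations = c(...))`.
#' @param seed campaign base seed.
#' @param shape image dimensions (default `c(256, 256)`).
#' @param total_counts expected counts per flood (default 5e6).
#' @param service_level truth threshold on defect amplitude (default 0.10).
#' @param start_date first acquisition date.
#' @return An object of class `"qc_campaign"`: list with `images` (list of
#'   entries `flood`, `day`, `station`, `truth`, `defects`) and `manifest`
#'   (data.frame: day, date, station, n_defects, max_amplitude, truth).
#' @export
simulate_campaign <- function(n_days, stations, defect_schedule = list(),
                              seed = 1, shape = c(256, 256),
                              total_counts = 5e6, service_level = 0.10,
                              start_date = as.Date("2024-01-01")) {
  stopifnot(n_days >= 1, length(stations) >= 1)
  images <- list()
  rows <- list()
  k <- 1L
  for (day in seq_len(n_days)) {
    entry <- defect_schedule[[as.character(day)]]
    for (st in stations) {
      defects <- list()
      if (!is.null(entry)) {
        if (!is.null(entry$defects)) {
          if (is.null(entry$stations) || st %in% entry$stations)
            defects <- entry$defects
        } else {
          defects <- entry  # plain defect list: applies to every station
        }
      }
      truth <- any(vapply(defects, function(d) d$amplitude, numeric(1)) >=
                     service_level)
      map <- make_sensitivity_map(shape, defects)
      fl <- simulate_flood(
        map, total_counts = total_counts,
        seed = derive_seed(seed, st, day), station = st,
        acquired_at = as.POSIXct(paste(start_date + day - 1, "06:00:00"),
                                 tz = "UTC"))
      images[[k]] <- list(flood = fl, day = day, station = st,
                          truth = truth, defects = defects)
      rows[[k]] <- data.frame(
        day = day, date = start_date + day - 1, station = st,
        n_defects = length(defects),
        max_amplitude = if (length(defects))
          max(vapply(defects, function(d) d$amplitude, numeric(1))) else 0,
        truth = truth)
      k <- k + 1L
    }
  }
  structure(list(images = images, manifest = do.call(rbind, rows)),
            class = "qc_campaign")
}

#' Write a campaign manifest as CSV
#'
#' @param campaign a [simulate_campaign()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_campaign_manifest <- function(campaign, path) {
  utils::write.csv(campaign$manifest, path, row.names = FALSE)
  invisible(path)
}
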