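#' Match QC alerts to a service log: sensitivity and false positives
#'
#' A service event (restricted to image-quality-related entries) counts as a
#' true positive when any record for its station inside `[start, end]`
#' exceeds the threshold on the chosen metric; otherwise it is a false
#' negative. False positives are counted as *runs*: a maximal stretch of
#' consecutive alerting days for one station that overlaps no event counts
#' once, because a single unresolved issue produces several poor floods in
#' a row.
#'
#' @param records data.frame with columns `station`, `date` (or
#'   `acquired_at`), and the metric column (`sni` or `iu_ufov`).
#' @param events data.frame with columns `station`, `start_date`,
#'   `end_date`, `image_quality_related` (logical), `note`.
#' @param metric `"sni"` or `"iu"` (`iu` uses the `iu_ufov` column).
#' @param threshold alert threshold on the metric (SNI 0.60 / IU 5.0 are the
#'   usual operating points).
#' @return An object of class `"sensitivity_report"`: `true_positives`,
#'   `false_negatives`, `false_positives`, `sensitivity` (NaN with
#'   `undefined = TRUE` when there are no qualifying events), `metric`,
#'   `threshold`, `period`.
#' @export
#' @examples
#' recs <- data.frame(station = "A", date = as.Date("2024-01-01") + 0:5,
#'                    sni = c(.2, .7, .7, .2, .2, .8))
#' ev <- data.frame(station = "A", start_date = as.Date("2024-01-02"),
#'                  end_date = as.Date("2024-01-03"),
#'                  image_quality_related = TRUE, note = "PMT")
#' match_alerts_to_events(recs, ev, "sni", 0.6)
match_alerts_to_events <- function(records, events, metric = c("sni", "iu"),
                                   threshold = 0.60) {
  metric <- match.arg(metric)
  col <- if (metric == "sni") "sni" else "iu_ufov"
  events <- events[as.logical(events$image_quality_related), , drop = FALSE]
  rec_date <- if ("date" %in% names(records)) as.Date(records$date)
              else as.Date(substr(records$acquired_at, 1, 10))
  vals <- records[[col]]
  alert <- !is.na(vals) & vals > threshold

  if (nrow(events) == 0) {
    fp <- count_alert_runs(records$station, rec_date, alert, events)
    return(structure(list(true_positives = 0L, false_negatives = 0L,
                          false_positives = fp, sensitivity = NaN,
                          undefined = TRUE, metric = metric,
                          threshold = threshold,
                          period = range(rec_date)),
                     class = "sensitivity_report"))
  }

  tp <- 0L
  for (i in seq_len(nrow(events))) {
    inwin <- records$station == events$station[i] &
      rec_date >= as.Date(events$start_date[i]) &
      rec_date <= as.Date(events$end_date[i])
    if (any(alert & inwin)) tp <- tp + 1L
  }
  fn <- nrow(events) - tp
  fp <- count_alert_runs(records$station, rec_date, alert, events)
  structure(list(true_positives = tp, false_negatives = fn,
                 false_positives = fp,
                 sensitivity = tp / (tp + fn), undefined = FALSE,
                 metric = metric, threshold = threshold,
                 period = range(rec_date)),
            class = "sensitivity_report")
}

# maximal runs of consecutive alerting days per station, counted once each,
# excluding runs that overlap any event window for that station
count_alert_runs <- function(stations, dates, alert, events) {
  fp <- 0L
  for (st in unique(stations[alert])) {
    d <- sort(unique(dates[alert & stations == st]))
    if (length(d) == 0) next
    run_id <- cumsum(c(1, diff(d) > 1))
    for (g in split(d, run_id)) {
      overlaps <- nrow(events) > 0 && any(
        events$station == st &
          as.Date(events$start_date) <= max(g) &
          as.Date(events$end_date) >= min(g))
      if (!overlaps) fp <- fp + 1L
    }
  }
  fp
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> %s > %.2g: %d/%d detected (%s), %d false-positive runs\n",
    x$metric, x$threshold, x$true_positives,
    x$true_positives + x$false_negatives,
    if (x$undefined) "undefined" else sprintf("%.1f%%", 100 * x$sensitivity),
    x$false_positives))
  invisible(x)
}

#' Per-system coefficient of variation of the SNI
#'
#' Sample standard deviation (n-1) over mean of a station's SNI values in a
#' period; the day-to-day consistency measure trended quarterly.
#'
#' @param records data.frame with `station`, `sni` and `date`/`acquired_at`.
#' @param station station name.
#' @param period optional `c(start, end)` dates (inclusive).
#' @return CV as a fraction, or `NA` (with a warning) for fewer than two
#'   records.
#' @export
#' @examples
#' r <- data.frame(station = "A", date = Sys.Date() + 1:2, sni = c(.4, .6))
#' system_cv(r, "A")  # ~0.283
system_cv <- function(records, station, period = NULL) {
  v <- select_period(records, period)
  v <- v$sni[v$station == station]
  v <- v[!is.na(v)]
  if (length(v) < 2) {
    warning("system_cv undefined: fewer than 2 records for ", station)
    return(NA_real_)
  }
  stats::sd(v) / mean(v)
}

#' Fleet-average coefficient of variation
#'
#' The fleet CV for a period divides the average per-station standard
#' deviation by the average per-station mean (stations with at least two
#' records contribute).
#'
#' @inheritParams system_cv
#' @return CV as a fraction.
#' @export
fleet_cv <- function(records, period = NULL) {
  r <- select_period(records, period)
  sds <- c(); mus <- c()
  for (st in unique(r$station)) {
    v <- r$sni[r$station == st]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    sds <- c(sds, stats::sd(v)); mus <- c(mus, mean(v))
  }
  if (length(sds) == 0) stop("no station with a defined system CV")
  mean(sds) / mean(mus)
}

select_period <- function(records, period) {
  if (is.null(period)) return(records)
  d <- if ("date" %in% names(records)) as.Date(records$date)
       else as.Date(substr(records$acquired_at, 1, 10))
  records[d >= as.Date(period[1]) & d <= as.Date(period[2]), , drop = FALSE]
}

#' Trend table for one detector
#'
#' Chronologically sorted per-day rows of SNI and IU with the threshold
#' lines used on trend charts (0.50 SNI, 5.0% IU) and a flag for days
#' exceeding the SNI threshold.
#'
#' @param records QC records data.frame.
#' @param station station name.
#' @param sni_threshold,iu_threshold chart threshold lines.
#' @return data.frame: `date`, `sni`, `iu_ufov`, `iu_cfov`, `alert_level`,
#'   `sni_threshold`, `iu_threshold`, `sni_exceeds`.
#' @export
trend_table <- function(records, station, sni_threshold = 0.50,
                        iu_threshold = 5.0) {
  r <- records[records$station == station, , drop = FALSE]
  d <- if ("date" %in% names(r)) as.Date(r$date)
       else as.Date(substr(r$acquired_at, 1, 10))
  o <- order(d)
  thr_len <- rep(1, nrow(r))  # keep threshold columns valid on empty input
  data.frame(
    date = d[o],
    sni = r$sni[o],
    iu_ufov = if ("iu_ufov" %in% names(r)) r$iu_ufov[o] else NA_real_ * thr_len,
    iu_cfov = if ("iu_cfov" %in% names(r)) r$iu_cfov[o] else NA_real_ * thr_len,
    alert_level = if ("alert_level" %in% names(r)) r$alert_level[o]
                  else rep(NA_character_, nrow(r)),
    sni_threshold = sni_threshold * thr_len,
    iu_threshold = iu_threshold * thr_len,
    sni_exceeds = !is.na(r$sni[o]) & r$sni[o] > sni_threshold
  )
}
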