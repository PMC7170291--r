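ANALYSIS_VERSION <- "sniqc-0.1.0"

#' Two-level alert configuration
#'
#' The operating points used clinically: a lower threshold of 0.50 notifying
#' physics staff only, and an upper threshold of 0.60 adding clinical and
#' engineering staff. "Exceeds" is strict by default; boundary values do not
#' alert.
#'
#' @param lower_threshold,upper_threshold SNI thresholds,
#'   `0 < lower <= upper < 1`.
#' @param recipients_lower,recipients_upper notification channel lists.
#' @param comparison `"gt"` (strictly greater, default) or `"ge"`.
#' @return An object of class `"alert_config"`.
#' @export
alert_config <- function(lower_threshold = 0.50, upper_threshold = 0.60,
                         recipients_lower = c("physics"),
                         recipients_upper = c("physics", "clinical",
                                              "engineering"),
                         comparison = c("gt", "ge")) {
  stopifnot(lower_threshold > 0, lower_threshold <= upper_threshold,
            upper_threshold < 1)
  structure(list(lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold,
                 recipients_lower = recipients_lower,
                 recipients_upper = recipients_upper,
                 comparison = match.arg(comparison)),
            class = "alert_config")
}

#' Classify an SNI value against the alert thresholds
#'
#' @param sni SNI value.
#' @param config an [alert_config()].
#' @return `"upper"`, `"lower"` or `"none"`.
#' @export
#' @examples
#' classify_alert(0.55, alert_config())  # "lower"
#' classify_alert(0.65, alert_config())  # "upper"
#' classify_alert(0.50, alert_config())  # "none": strict comparison
classify_alert <- function(sni, config = alert_config()) {
  stopifnot(inherits(config, "alert_config"))
  exceeds <- if (config$comparison == "gt") function(x, t) x > t
             else function(x, t) x >= t
  if (exceeds(sni, config$upper_threshold)) "upper"
  else if (exceeds(sni, config$lower_threshold)) "lower"
  else "none"
}

#' Pipeline configuration
#'
#' Bundles everything [process_image()] needs. `archive_root`, `outbox` and
#' `store` are created on demand.
#'
#' @param rule a [sort_rule()].
#' @param alerts an [alert_config()].
#' @param geometry a [viewing_geometry()].
#' @param roi list(fraction, size, step) for the ROI sweep.
#' @param archive_root archive directory.
#' @param outbox directory for file-based notifications.
#' @param store CSV path of the results store.
#' @param notifier function(record, figure_path, config) used to deliver
#'   alerts; default [notify()].
#' @return An object of class `"qc_config"`.
#' @export
qc_config <- function(rule, alerts = alert_config(),
                      geometry = viewing_geometry(),
                      roi = list(fraction = 0.9, size = 64, step = 16),
                      archive_root = file.path(tempdir(), "sniqc-archive"),
                      outbox = file.path(tempdir(), "sniqc-outbox"),
                      store = file.path(tempdir(), "sniqc-records.csv"),
                      notifier = notify) {
  structure(list(rule = rule, alerts = alerts, geometry = geometry,
                 roi = roi, archive_root = archive_root, outbox = outbox,
                 store = store, notifier = notifier),
            class = "qc_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the fields of [sort_rule()], [alert_config()],
#' [viewing_geometry()] and the ROI block from a YAML file; absent fields
#' keep their defaults. See `inst/extdata/config.yaml` for the dialect.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [qc_config()].
#' @return A [qc_config()].
#' @export
read_qc_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  rule <- do.call(sort_rule, c(
    list(allowed_stations = y$sort$allowed_stations %||% "SIM1"),
    y$sort[intersect(names(y$sort),
                     c("series_tokens", "min_counts"))],
    if (!is.null(y$sort$matrix_sizes))
      list(matrix_sizes = lapply(y$sort$matrix_sizes, as.numeric))))
  alerts <- do.call(alert_config, y$alerts %||% list())
  geometry <- do.call(viewing_geometry, y$geometry %||% list())
  roi <- utils::modifyList(list(fraction = 0.9, size = 64, step = 16),
                           y$roi %||% list())
  qc_config(rule = rule, alerts = alerts, geometry = geometry, roi = roi,
            ...)
}

empty_record <- function() data.frame(
  station = NA_character_, acquired_at = NA_character_,
  isotope = NA_character_, total_counts = NA_real_, sni = NA_real_,
  best_roi = NA_character_, iu_ufov = NA_real_, iu_cfov = NA_real_,
  alert_level = "none", status = "analyzed", reason = "",
  archive_dicom = NA_character_, archive_figure = NA_character_,
  analysis_version = ANALYSIS_VERSION, stringsAsFactors = FALSE)

#' Analyze one incoming DICOM end to end
#'
#' read -> sort (non-QC images get a skip record) -> SNI sweep -> artifact
#' image -> IU over UFOV and CFOV -> alert classification -> notification
#' (if alerted) -> archive -> one record. A failure at any stage yields a
#' record with `status = "error"`; no input is silently dropped.
#'
#' @param path DICOM file path.
#' @param config a [qc_config()].
#' @return A one-row data.frame QC record.
#' @export
process_image <- function(path, config) {
  stopifnot(inherits(config, "qc_config"))
  rec <- empty_record()
  tryCatch({
    fl <- read_flood_dicom(path)
    rec$station <- fl$station
    rec$acquired_at <- format(fl$acquired_at, "%Y-%m-%d %H:%M:%S")
    rec$isotope <- fl$isotope
    rec$total_counts <- fl$total_counts

    gate <- is_qc_flood(fl, config$rule)
    if (!gate$accepted) {
      rec$status <- "skipped"
      rec$reason <- gate$reason
      return(rec)
    }

    res <- image_sni(fl, config$geometry, config$roi)
    rec$sni <- res$image_sni
    rec$best_roi <- sprintf("(%d,%d)x%d", res$best_roi$origin[1],
                            res$best_roi$origin[2], res$best_roi$size)
    rec$iu_ufov <- integral_uniformity(
      fl$pixels, fov_mask(nrow(fl$pixels), ncol(fl$pixels), "ufov"))
    rec$iu_cfov <- integral_uniformity(
      fl$pixels, fov_mask(nrow(fl$pixels), ncol(fl$pixels), "cfov"))
    rec$alert_level <- classify_alert(res$image_sni, config$alerts)

    paths <- archive_flood(fl, res, config$archive_root, source_path = path)
    rec$archive_dicom <- paths$dicom_path
    rec$archive_figure <- paths$figure_path

    if (rec$alert_level != "none")
      try(config$notifier(rec, paths$figure_path, config), silent = TRUE)
    rec
  }, error = function(e) {
    rec$status <- "error"
    rec$reason <- conditionMessage(e)
    rec
  })
}

#' File-based alert notification
#'
#' Default notification channel: one plain-text message per alert dropped in
#' the configured outbox directory, carrying station, timestamp, SNI, the
#' recipient list for the alert level and the figure attachment path. An
#' SMTP transport can be plugged in via `qc_config(notifier = ...)`.
#'
#' @param record one-row QC record with `alert_level != "none"`.
#' @param figure_path quadrant-figure attachment path.
#' @param config a [qc_config()] (uses `alerts` and `outbox`).
#' @return One-row data.frame delivery log entry.
#' @export
notify <- function(record, figure_path, config) {
  stopifnot(record$alert_level %in% c("lower", "upper"))
  recipients <- if (record$alert_level == "upper")
    config$alerts$recipients_upper else config$alerts$recipients_lower
  dir.create(config$outbox, recursive = TRUE, showWarnings = FALSE)
  fname <- noclobber_path(
    config$outbox,
    paste0("alert_", gsub("[^A-Za-z0-9]", "_", record$station), "_",
           gsub("[^0-9]", "", record$acquired_at)), ".txt")
  writeLines(c(
    paste("level:", record$alert_level),
    paste("station:", record$station),
    paste("acquired:", record$acquired_at),
    paste("sni:", sprintf("%.4f", record$sni)),
    paste("recipients:", paste(recipients, collapse = ",")),
    paste("attachment:", figure_path)
  ), fname)
  data.frame(time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
             station = record$station, level = record$alert_level,
             recipients = paste(recipients, collapse = ","),
             message = fname, stringsAsFactors = FALSE)
}

#' Detect stations with missing daily QC
#'
#' @param expected_stations stations that must submit a flood.
#' @param records QC records for the date in question.
#' @param cutoff_time `POSIXct`; only accepted records acquired strictly
#'   before the cutoff count as present.
#' @return Character vector of missing stations.
#' @export
detect_missing <- function(expected_stations, records, cutoff_time) {
  if (is.null(records) || nrow(records) == 0)
    return(as.character(expected_stations))
  ok <- records$status == "analyzed" &
    as.POSIXct(records$acquired_at, tz = "UTC") <
      as.POSIXct(cutoff_time, tz = "UTC")
  setdiff(as.character(expected_stations), unique(records$station[ok]))
}

#' Append a record to the results store
#'
#' The store is an append-only CSV keyed by
#' `(station, acquired_at, analysis_version)`; appending a duplicate key is
#' an error, so re-analysis with a new code version coexists with history.
#'
#' @param store CSV path.
#' @param record one-row data.frame from [process_image()].
#' @return `store`, invisibly.
#' @export
append_record <- function(store, record) {
  existing <- read_records(store)
  if (!is.null(existing) && nrow(existing) > 0) {
    dup <- existing$station == record$station &
      existing$acquired_at == record$acquired_at &
      existing$analysis_version == record$analysis_version
    if (any(dup, na.rm = TRUE))
      stop("duplicate record: ", record$station, " @ ", record$acquired_at)
  }
  utils::write.table(record, store, sep = ",", row.names = FALSE,
                     col.names = !file.exists(store), append = file.exists(store),
                     qmethod = "double")
  invisible(store)
}

#' Read the results store
#'
#' @param store CSV path.
#' @return data.frame of records, or `NULL` when the store does not exist.
#' @export
read_records <- function(store) {
  if (!file.exists(store)) return(NULL)
  utils::read.csv(store, stringsAsFactors = FALSE)
}
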