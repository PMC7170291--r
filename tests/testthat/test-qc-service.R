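test_that("alert classification at the clinical thresholds", {
  cfg <- alert_config()
  expect_equal(classify_alert(0.55, cfg), "lower")
  expect_equal(classify_alert(0.65, cfg), "upper")
  expect_equal(classify_alert(0.50, cfg), "none")  # strict comparison
  expect_equal(classify_alert(0.60, cfg), "lower")
  expect_equal(classify_alert(0.0, cfg), "none")
  # monotone: raising SNI never lowers the level
  lv <- c(none = 0, lower = 1, upper = 2)
  codes <- lv[vapply(seq(0, 0.99, by = 0.01), classify_alert, "", config = cfg)]
  expect_true(all(diff(codes) >= 0))
  # inclusive comparison is selectable
  expect_equal(classify_alert(0.50, alert_config(comparison = "ge")), "lower")
  expect_error(alert_config(lower_threshold = 0.7, upper_threshold = 0.6))
})

local_pipeline <- function() {
  root <- file.path(tempdir(), paste0("svc-", as.integer(runif(1) * 1e8)))
  qc_config(
    rule = sort_rule(c("CAM_A", "CAM_B"), min_counts = 1e5,
                     matrix_sizes = list(c(128, 128))),
    archive_root = file.path(root, "archive"),
    outbox = file.path(root, "outbox"),
    store = file.path(root, "records.csv"))
}

test_that("pipeline produces exactly one record per input of every kind", {
  cfg <- local_pipeline()
  dir <- tempfile("in"); dir.create(dir)

  clean <- quick_flood(128, 400, seed = 51, station = "CAM_A")
  write_synthetic_dicom(clean, file.path(dir, "clean.dcm"))
  bad <- dropout_flood(0.25, side = 128, counts = 128^2 * 400, seed = 52,
                       station = "CAM_B")
  write_synthetic_dicom(bad, file.path(dir, "defect.dcm"))
  nonqc <- quick_flood(128, 400, seed = 53, station = "CAM_A",
                       study_description = "BONE SCAN",
                       series_description = "WB")
  write_synthetic_dicom(nonqc, file.path(dir, "nonqc.dcm"))
  writeLines("not dicom", file.path(dir, "junk.dcm"))

  recs <- do.call(rbind, lapply(list.files(dir, full.names = TRUE),
                                process_image, config = cfg))
  expect_equal(nrow(recs), 4)  # conservation of inputs
  expect_setequal(recs$status, c("analyzed", "analyzed", "skipped", "error"))

  rc <- recs[recs$status == "analyzed" & recs$station == "CAM_A", ]
  expect_equal(rc$alert_level, "none")
  expect_true(file.exists(rc$archive_dicom))
  expect_true(file.exists(rc$archive_figure))
  expect_match(rc$archive_dicom, "images/CAM_A")

  rb <- recs[recs$status == "analyzed" & recs$station == "CAM_B", ]
  expect_equal(rb$alert_level, "upper")
  expect_gt(rb$sni, 0.6)
  # notification landed in the outbox with the figure attached
  msgs <- list.files(cfg$outbox, full.names = TRUE)
  expect_length(msgs, 1)
  body <- readLines(msgs[1])
  expect_true(any(grepl("level: upper", body)))
  expect_true(any(grepl("physics,clinical,engineering", body)))
  expect_true(any(grepl(basename(rb$archive_figure), body)))

  rs <- recs[recs$status == "skipped", ]
  expect_equal(rs$reason, "description")
  expect_true(is.na(rs$sni))
})

test_that("lower alerts notify physics only", {
  cfg <- local_pipeline()
  rec <- sniqc:::empty_record()
  rec$station <- "CAM_A"; rec$acquired_at <- "2024-01-01 06:00:00"
  rec$sni <- 0.55; rec$alert_level <- "lower"
  entry <- notify(rec, "fig.png", cfg)
  expect_equal(entry$recipients, "physics")
  body <- readLines(entry$message)
  expect_true(any(grepl("recipients: physics$", body)))
})

test_that("missing-station detection honors the cutoff", {
  recs <- data.frame(station = c("A", "B"), status = "analyzed",
                     acquired_at = c("2024-01-01 06:00:00",
                                     "2024-01-01 09:30:00"))
  cutoff <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  expect_setequal(detect_missing(c("A", "B", "C"), recs, cutoff), c("B", "C"))
  eod <- as.POSIXct("2024-01-01 23:59:00", tz = "UTC")
  expect_equal(detect_missing(c("A", "B"), recs, eod), character(0))
  expect_setequal(detect_missing(c("A", "B"), NULL, eod), c("A", "B"))
})

test_that("record store is append-only with duplicate-key rejection", {
  store <- tempfile(fileext = ".csv")
  rec <- sniqc:::empty_record()
  rec$station <- "CAM_A"; rec$acquired_at <- "2024-01-01 06:00:00"
  rec$sni <- 0.3
  append_record(store, rec)
  expect_error(append_record(store, rec), "duplicate")
  rec2 <- rec; rec2$acquired_at <- "2024-01-02 06:00:00"
  append_record(store, rec2)
  got <- read_records(store)
  expect_equal(nrow(got), 2)
  expect_equal(got$acquired_at,
               c("2024-01-01 06:00:00", "2024-01-02 06:00:00"))
  # bulk: order preserved
  store2 <- tempfile(fileext = ".csv")
  for (i in 1:200) {
    r <- sniqc:::empty_record(); r$station <- "S"
    r$acquired_at <- sprintf("2024-01-01 06:%02d:%02d", i %/% 60, i %% 60)
    append_record(store2, r)
  }
  expect_equal(nrow(read_records(store2)), 200)
})

test_that("YAML configuration round-trips into the pipeline objects", {
  cfg <- read_qc_config(system.file("extdata", "config.yaml",
                                    package = "sniqc"))
  expect_s3_class(cfg, "qc_config")
  expect_true("SIM1" %in% cfg$rule$allowed_stations)
  expect_equal(cfg$alerts$lower_threshold, 0.50)
  expect_equal(cfg$alerts$upper_threshold, 0.60)
  expect_equal(cfg$geometry$filter_exponent, 1)
  expect_equal(cfg$roi$step, 16)
})
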