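test_that("sensitivity worked examples: 7/7, 24/26 and 8/26", {
  fx7 <- sensitivity_fixture(7, 7)
  r7 <- match_alerts_to_events(fx7$records, fx7$events, "sni", 0.60)
  expect_equal(r7$sensitivity, 1)

  fx <- sensitivity_fixture(26, 24, n_iu_detected = 8)
  r_sni <- match_alerts_to_events(fx$records, fx$events, "sni", 0.60)
  expect_equal(r_sni$true_positives, 24L)
  expect_equal(r_sni$false_negatives, 2L)
  expect_equal(100 * r_sni$sensitivity, 92.3, tolerance = 0.001)

  r_iu <- match_alerts_to_events(fx$records, fx$events, "iu", 5.0)
  expect_equal(r_iu$true_positives, 8L)
  expect_equal(100 * r_iu$sensitivity, 30.8, tolerance = 0.001)
})

test_that("false positives count maximal alert runs, not alert days", {
  d0 <- as.Date("2024-03-01")
  # 8 alerting days in 5 maximal runs across two stations, no events
  records <- data.frame(
    station = c(rep("FP1", 6), rep("FP2", 6)),
    date = c(d0 + c(1, 2, 3, 10, 12, 13), d0 + c(2, 20, 21, 22, 23, 24)),
    sni = 0.9)
  events <- data.frame(station = character(0), start_date = as.Date(character(0)),
                       end_date = as.Date(character(0)),
                       image_quality_related = logical(0), note = character(0))
  rep_ <- match_alerts_to_events(records, events, "sni", 0.60)
  expect_equal(rep_$false_positives, 5L)
  expect_true(rep_$undefined)
  expect_true(is.nan(rep_$sensitivity))
  # run-collapsing never exceeds per-day counting
  expect_lte(rep_$false_positives, sum(records$sni > 0.6))
  # a run overlapping an event is not a false positive
  ev <- data.frame(station = "FP1", start_date = d0 + 2, end_date = d0 + 3,
                   image_quality_related = TRUE, note = "repair")
  rep2 <- match_alerts_to_events(records, ev, "sni", 0.60)
  expect_equal(rep2$false_positives, 4L)
  expect_equal(rep2$true_positives, 1L)
})

test_that("multi-day repairs count as one instance", {
  d0 <- as.Date("2024-05-01")
  records <- data.frame(station = "A", date = d0 + 0:4,
                        sni = c(0.7, 0.8, 0.75, 0.2, 0.2))
  ev <- data.frame(station = "A", start_date = d0, end_date = d0 + 2,
                   image_quality_related = TRUE, note = "PMT swap")
  r <- match_alerts_to_events(records, ev, "sni", 0.60)
  expect_equal(r$true_positives, 1L)
  expect_equal(r$false_positives, 0L)
})

test_that("non-image-quality events are excluded", {
  d0 <- as.Date("2024-06-01")
  records <- data.frame(station = "A", date = d0, sni = 0.3)
  ev <- data.frame(station = "A", start_date = d0, end_date = d0,
                   image_quality_related = FALSE, note = "software update")
  r <- match_alerts_to_events(records, ev, "sni", 0.60)
  expect_true(r$undefined)
})

test_that("coefficient-of-variation arithmetic", {
  d0 <- Sys.Date()
  r <- data.frame(station = "A", date = d0 + 1:2, sni = c(0.4, 0.6))
  expect_equal(system_cv(r, "A"), sd(c(0.4, 0.6)) / 0.5, tolerance = 1e-12)
  expect_equal(system_cv(r, "A"), 0.2828, tolerance = 1e-3)
  # scale invariance
  r2 <- r; r2$sni <- 2 * r$sni
  expect_equal(system_cv(r2, "A"), system_cv(r, "A"))
  # constant series
  rc <- data.frame(station = "A", date = d0 + 1:3, sni = 0.5)
  expect_equal(system_cv(rc, "A"), 0)
  expect_warning(cv1 <- system_cv(rc[1, ], "A"), "undefined")
  expect_true(is.na(cv1))
})

test_that("fleet CV is mean SD over mean mean, and degenerates correctly", {
  d0 <- Sys.Date()
  # two stations engineered to (sd, mean) = (0.04, 0.4) and (0.06, 0.6)
  mk <- function(st, target_sd, target_mean) {
    v <- c(-1, 1) / sqrt(2) * target_sd + target_mean
    data.frame(station = st, date = d0 + 1:2, sni = v)
  }
  r <- rbind(mk("A", 0.04, 0.4), mk("B", 0.06, 0.6))
  expect_equal(fleet_cv(r), 0.05 / 0.5, tolerance = 1e-12)
  # one station: fleet CV equals the system CV
  one <- mk("A", 0.04, 0.4)
  expect_equal(fleet_cv(one), system_cv(one, "A"))
  # all stations constant
  rc <- data.frame(station = rep(c("A", "B"), each = 2), date = d0 + 1:4,
                   sni = 0.5)
  expect_equal(fleet_cv(rc), 0)
})

test_that("trend table is chronological with threshold columns and flags", {
  r <- data.frame(station = "A",
                  date = as.Date("2024-01-01") + c(2, 0, 1),
                  sni = c(0.55, 0.3, 0.7), iu_ufov = c(4, 3, 6),
                  iu_cfov = c(3, 2, 5), alert_level = c("lower", "none", "upper"))
  tt <- trend_table(r, "A")
  expect_equal(nrow(tt), 3)
  expect_true(!is.unsorted(tt$date))
  expect_equal(tt$sni, c(0.3, 0.7, 0.55))
  expect_true(all(tt$sni_threshold == 0.5) && all(tt$iu_threshold == 5))
  expect_equal(tt$sni_exceeds, tt$sni > 0.5)
  # flags agree with the alert classifier at the lower threshold
  expect_equal(tt$sni_exceeds,
               vapply(tt$sni, classify_alert, "", config = alert_config()) != "none")
})

test_that("adding a detected event never decreases sensitivity", {
  fx <- sensitivity_fixture(10, 6)
  base <- match_alerts_to_events(fx$records, fx$events, "sni", 0.60)
  fx2 <- sensitivity_fixture(11, 7)
  more <- match_alerts_to_events(fx2$records, fx2$events, "sni", 0.60)
  expect_gte(more$sensitivity, base$sensitivity)
})
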