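# Shared fixtures and independent oracles.

# Direct double-sum evaluation of the 2D NPS, written against the definition
# (explicit complex exponentials per frequency bin) and independent of fft().
nps_direct <- function(patch, spacing = c(1, 1)) {
  n <- nrow(patch); m <- ncol(patch)
  dev <- patch - mean(patch)
  out <- matrix(0, n, m)
  for (k in 0:(n - 1)) {
    for (l in 0:(m - 1)) {
      ph <- exp(-2i * pi * (k * (row(patch) - 1) / n +
                              l * (col(patch) - 1) / m))
      out[k + 1, l + 1] <- Mod(sum(dev * ph))^2
    }
  }
  out <- out * prod(spacing) / (n * m)
  out[1, 1] <- 0
  out
}

# small defect-free flood
quick_flood <- function(side = 64, lambda = 500, seed = 1, ...) {
  m <- make_sensitivity_map(c(side, side), list())
  simulate_flood(m, total_counts = lambda * side^2, seed = seed, ...)
}

# flood with a single centered PMT-dropout defect
dropout_flood <- function(amplitude, side = 256, counts = 5e6, seed = 1,
                          center = NULL, width = 32, ...) {
  defects <- if (amplitude > 0)
    list(defect_spec("pmt_dropout", amplitude, center = center,
                     width = width)) else list()
  simulate_flood(make_sensitivity_map(c(side, side), defects),
                 total_counts = counts, seed = seed, ...)
}

# service-log sensitivity fixture: n_events single-day events on distinct
# stations; the first n_detected get an alerting SNI record in-window and
# n_iu_detected get an alerting IU record. Mirrors worked-example arithmetic.
sensitivity_fixture <- function(n_events, n_detected, n_iu_detected = 0) {
  d0 <- as.Date("2024-01-01")
  st <- sprintf("EV%02d", seq_len(n_events))
  events <- data.frame(station = st, start_date = d0 + seq_len(n_events),
                       end_date = d0 + seq_len(n_events),
                       image_quality_related = TRUE, note = "service")
  records <- data.frame(
    station = st, date = d0 + seq_len(n_events),
    sni = ifelse(seq_len(n_events) <= n_detected, 0.80, 0.55),
    iu_ufov = ifelse(seq_len(n_events) <= n_iu_detected, 6.0, 4.0))
  list(records = records, events = events)
}
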