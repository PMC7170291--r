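test_that("fast-transform NPS matches the direct double-sum definition", {
  set.seed(11)
  for (i in 1:12) {
    n <- sample(8:16, 1); m <- sample(8:16, 1)
    sp <- sample(c(0.5, 1, 2.3), 2, replace = TRUE)
    p <- matrix(rpois(n * m, 50), n, m)
    nps <- compute_nps_2d(p, sp)
    ref <- nps_direct(p, sp)
    expect_lt(max(abs(nps$values - ref)) / max(ref), 1e-10)
  }
})

test_that("constant patch has an identically zero spectrum", {
  nps <- compute_nps_2d(matrix(7, 8, 8))
  expect_true(all(nps$values == 0))
  expect_identical(nps$values[1, 1], 0)
})

test_that("white Gaussian noise gives a flat spectrum at variance x pixel area", {
  set.seed(12)
  p <- matrix(rnorm(64 * 64, 100, 2), 64)
  nps <- compute_nps_2d(p, c(1, 1))
  expect_equal(mean(nps$values[-1]), 4, tolerance = 0.1)
})

test_that("quantum level is mean times pixel area", {
  expect_equal(quantum_nps_level(matrix(100, 8, 8), c(1, 1)), 100)
  expect_equal(quantum_nps_level(matrix(250, 8, 8), c(0.5, 0.5)), 62.5)
  # Poisson floods measure at the predicted flat level
  set.seed(13)
  devs <- replicate(20, {
    p <- matrix(rpois(64 * 64, 500), 64)
    mean(compute_nps_2d(p)$values[-1]) / quantum_nps_level(p)
  })
  expect_equal(mean(devs), 1, tolerance = 0.05)
})

test_that("structured spectrum clamps the quantum subtraction at zero per bin", {
  nps <- compute_nps_2d(matrix(rpois(64, 100), 8))
  nps$values[2, 1] <- 120; nps$values[3, 1] <- 80
  s <- structured_nps(nps, 100)
  expect_equal(s$values[2, 1], 20)
  expect_equal(s$values[3, 1], 0)
  expect_true(all(s$values >= 0))
  expect_identical(s$values[1, 1], 0)
  # every bin at the quantum level -> all-zero spectrum
  nps$values[] <- 100
  expect_true(all(structured_nps(nps, 100)$values == 0))
})

test_that("visual response peaks at 4 cycles/degree with the closed-form scale", {
  g <- viewing_geometry(full_image_width_px = 256)
  expect_equal(visual_filter_scale(g), 0.040625)
  r <- seq(0.01, 20, by = 0.001)
  expect_equal(r[which.max(visual_response(r, g))], 4, tolerance = 1e-3)
  # doubling the peak frequency quarters the scale factor
  g8 <- viewing_geometry(peak_cyc_per_deg = 8)
  expect_equal(visual_filter_scale(g8), 0.040625 / 4)
})

test_that("frequency-to-degree mapping follows the viewing geometry", {
  g <- viewing_geometry(full_image_width_px = 256)
  expect_equal(frequency_to_degrees(0, g), 0)
  expect_equal(frequency_to_degrees(1 / 256, g),
               (1 / 6.5) * 150 * pi / 180, tolerance = 1e-12)
  g2 <- viewing_geometry(distance_cm = 300, full_image_width_px = 256)
  expect_equal(frequency_to_degrees(0.1, g2), 2 * frequency_to_degrees(0.1, g))
})

test_that("visual filtering zeroes DC and is linear in the spectrum", {
  set.seed(14)
  nps <- compute_nps_2d(matrix(rpois(32 * 32, 200), 32))
  g <- viewing_geometry(full_image_width_px = 256)
  f1 <- apply_visual_filter(nps, g)
  expect_identical(f1$values[1, 1], 0)
  nps3 <- nps; nps3$values <- 3 * nps$values
  f3 <- apply_visual_filter(nps3, g)
  expect_equal(sum(f3$values) / sum(f1$values), 3, tolerance = 1e-12)
})

test_that("SNI is zero for constant input and bounded in [0,1]", {
  expect_equal(sni_for_patch(matrix(5, 32, 32))$value, 0)
  set.seed(15)
  for (i in 1:20) {
    v <- sni_for_patch(matrix(rpois(32 * 32, sample(c(10, 100, 1e4), 1)), 32))$value
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("SNI is invariant to pixel spacing", {
  set.seed(16)
  p <- matrix(rpois(64 * 64, 300), 64)
  g <- viewing_geometry(full_image_width_px = 256)
  a <- sni_for_patch(p, c(0.5, 0.5), g)$value
  b <- sni_for_patch(p, c(2, 2), g)$value
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("structure-free Poisson patches score low", {
  set.seed(17)
  vals <- replicate(100, sni_for_patch(matrix(rpois(64 * 64, 1000), 64),
                                       geometry = viewing_geometry(
                                         full_image_width_px = 256))$value)
  expect_gte(mean(vals < 0.2), 0.95)
})

test_that("a strong fixed sinusoid drives SNI toward 1", {
  set.seed(18)
  rr <- matrix(seq_len(64), 64, 64)
  mu <- 2e6 * (1 + 0.05 * sin(2 * pi * 0.05 * rr))
  p <- matrix(rpois(4096, mu), 64)
  v <- sni_for_patch(p, geometry = viewing_geometry(full_image_width_px = 256))$value
  expect_gt(v, 0.95)
})

test_that("expected SNI increases with sinusoid amplitude at fixed counts", {
  g <- viewing_geometry(full_image_width_px = 256)
  rr <- matrix(seq_len(64), 64, 64)
  means <- sapply(c(0, 0.01, 0.03, 0.05), function(a) {
    mean(sapply(1:25, function(s) {
      mu <- 1000 * (1 + a * sin(2 * pi * 0.05 * rr))
      p <- sniqc:::withr_seed(1000 + s, matrix(rpois(4096, mu), 64))
      sni_for_patch(p, geometry = g)$value
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("SNI is non-decreasing in total counts for a fixed fractional defect", {
  g <- viewing_geometry(full_image_width_px = 256)
  rr <- matrix(seq_len(64), 64, 64)
  shape <- 1 + 0.03 * sin(2 * pi * 0.05 * rr)
  means <- sapply(c(200, 2000, 20000), function(lam) {
    mean(sapply(1:15, function(s)
      sni_for_patch(sniqc:::withr_seed(s, matrix(rpois(4096, lam * shape), 64)),
                    geometry = g)$value))
  })
  expect_true(all(diff(means) >= 0))
})
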