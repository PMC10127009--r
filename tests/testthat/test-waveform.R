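test_that("station resampling places exact stations on simple geometry", {
  # straight segment of length 10: stations at integer arc lengths on the line
  pts <- cbind(seq(0, 10, length.out = 50), 0)
  sf <- resample_stations(pts, 1)
  expect_equal(sf$stations, 0:10)
  expect_equal(sf$points[, 1], 0:10, tolerance = 1e-9)
  expect_equal(sf$points[, 2], rep(0, 11), tolerance = 1e-12)
  # a polyline already sampled at exactly 1 um keeps its vertices
  poly <- cbind(0:12, 0)
  sf2 <- resample_stations(poly, 1)
  expect_equal(sf2$points, unname(cbind(0:12, 0)), tolerance = 1e-12)
  # degenerate input
  expect_error(resample_stations(rbind(c(0, 0), c(0, 0), c(1, 0))),
               "degenerate")
  expect_error(resample_stations(cbind(c(0, 0.5), c(0, 0)), 1), "shorter")
})

test_that("quarter-circle stations lie on the circle", {
  pts <- circle_points(20, pi / 2, n = 4000)
  sf <- resample_stations(pts, 1)
  radii <- sqrt(rowSums(sf$points^2))
  expect_true(all(abs(radii - 20) < 1e-2))
  # resampling is length-preserving: last station <= length < last + spacing
  last <- sf$stations[length(sf$stations)]
  expect_lte(last, 20 * pi / 2 + 1e-9)
  expect_gt(last + 1, 20 * pi / 2)
})

test_that("discrete curvature matches analytic values on canonical shapes", {
  # straight line: exactly zero
  sf <- resample_stations(cbind(seq(0, 15, 0.1), 0), 1)
  expect_true(all(sf$curvature[-1] == 0))
  # CCW circle of radius 10: kappa = +0.1 at interior stations
  sf <- resample_stations(circle_points(10, 1.8 * pi, n = 6000), 1)
  interior <- !sf$boundary & !is.na(sf$curvature)
  expect_true(all(abs(sf$curvature[interior] - 0.1) < 1e-3))
  # CW circle: sign flips
  cw <- circle_points(10, 1.8 * pi, n = 6000)
  cw[, 2] <- -cw[, 2]
  sfc <- resample_stations(cw, 1)
  interior <- !sfc$boundary & !is.na(sfc$curvature)
  expect_true(all(abs(sfc$curvature[interior] + 0.1) < 1e-3))
})

test_that("sinusoid curvature profile matches the analytic oracle within 1%", {
  a <- 0.5; lambda <- 20
  sf <- resample_stations(sinusoid_points(a, lambda, 40), 1)
  prof <- curvature_profile(sf)
  keep <- !prof$boundary & !is.na(prof$curvature)
  # compare at the station's x position (x ~ arc length for this gentle slope)
  xs <- sf$points[keep, 1]
  truth <- sinusoid_curvature(a, lambda, xs)
  scale <- max(abs(truth))
  expect_true(all(abs(prof$curvature[keep] - truth) <= 0.01 * scale))
})

test_that("total absolute turn over a quarter circle is pi/2", {
  # radius chosen so the quarter arc (100.2 um) is long relative to the
  # 1-um station spacing: the sub-station fencepost at the tip then
  # contributes well under the 1% tolerance
  r <- 200.4 / pi
  sf <- resample_stations(circle_points(r, pi / 2, n = 8000), 1)
  keep <- !is.na(sf$curvature)
  total <- sum(abs(sf$curvature[keep])) * sf$spacing
  expect_equal(total, pi / 2, tolerance = 0.01)
})

test_that("curvature is rigid-motion invariant and reflection-odd", {
  pts <- sinusoid_points(0.8, 15, 30)
  sf0 <- resample_stations(pts, 1)
  moved <- rigid_transform(pts, angle = 1.1, shift = c(-40, 12.5))
  sf1 <- resample_stations(moved, 1)
  expect_equal(sf1$curvature, sf0$curvature, tolerance = 1e-9)
  mirrored <- cbind(pts[, 1], -pts[, 2])
  sf2 <- resample_stations(mirrored, 1)
  expect_equal(sf2$curvature, -sf0$curvature, tolerance = 1e-9)
})

test_that("waveform normalization registers rigidly and is idempotent", {
  pts <- sinusoid_points(0.6, 18, 25)
  sf <- resample_stations(pts, 1)
  nw <- normalize_waveform(sf)
  expect_equal(nw$points[1, ], c(0, 0), tolerance = 1e-12)
  expect_lt(abs(atan2(nw$points[2, 2], nw$points[2, 1])), 1e-9)
  # already normalized station geometry is unchanged (idempotence)
  sf_n <- sf
  sf_n$points <- nw$points
  nw2 <- normalize_waveform(sf_n)
  expect_equal(nw2$points, nw$points, tolerance = 1e-12)
  # rigidly moved input registers to the same waveform
  moved <- rigid_transform(pts, angle = pi / 2, shift = c(7, -3))
  nw_m <- normalize_waveform(resample_stations(moved, 1))
  expect_equal(nw_m$points, nw$points, tolerance = 1e-8)
  # mirror image registers to the mirrored waveform
  nw_r <- normalize_waveform(resample_stations(cbind(pts[, 1], -pts[, 2]), 1))
  expect_equal(nw_r$points, cbind(nw$points[, 1], -nw$points[, 2]),
               tolerance = 1e-8)
  # curvature is unaffected by normalization: registering the dense
  # polyline with the same rigid transform leaves the profile intact
  base_ang <- atan2(sf$points[2, 2] - sf$points[1, 2],
                    sf$points[2, 1] - sf$points[1, 1])
  dense_n <- rigid_transform(sweep(pts, 2, sf$points[1, ]), angle = -base_ang)
  expect_equal(resample_stations(dense_n, 1)$curvature, sf$curvature,
               tolerance = 1e-9)
  expect_error(normalize_waveform(structure(list(stations = 0:1),
                                            class = "station_frame")),
               "3 stations")
})

test_that("collect_series assembles a stations-by-frames curvature matrix", {
  sim <- simulate_sperm(quick_truth(tail_amplitude = 0, duration = 0.06))
  ser <- collect_series(sim$trace, "tail", 1, 10)
  expect_equal(ncol(ser$samples), 10)
  expect_true(all(abs(ser$samples) < 1e-9))
  expect_error(collect_series(sim$trace, "tail", 5, 50), "exceeds")
  # travelling wave at f = 50 Hz, 150 fps: per-station mean ~ 0 and
  # variance ~ A(s)^2 / 2 (sine sampled uniformly in phase)
  sim2 <- simulate_sperm(quick_truth(frequency = 50, duration = 0.06,
                                     tail_amplitude = 0.15))
  ser2 <- collect_series(sim2$trace, "tail", 1, 10)
  expect_true(all(abs(rowMeans(ser2$samples)) < 0.02))
  v <- apply(ser2$samples, 1, var)
  expect_true(all(abs(v - 0.15^2 / 2) / (0.15^2 / 2) < 0.25))
})

test_that("head series split into nucleus and acrosome at the boundary", {
  simP <- simulate_sperm(quick_truth("Paramacrobiotus sp.", duration = 0.06))
  hsP <- collect_series(simP$trace, "head", 1, 10)
  spP <- split_head_regions(hsP, species_presets("Paramacrobiotus sp."))
  expect_equal(spP$nucleus$stations, 1:21)
  expect_equal(spP$acrosome$stations, 22:59)
  simM <- simulate_sperm(quick_truth("Macrobiotus shonaicus", duration = 0.06))
  hsM <- collect_series(simM$trace, "head", 1, 10)
  spM <- split_head_regions(hsM, species_presets("Macrobiotus shonaicus"))
  expect_equal(spM$nucleus$stations, 1:11)
  expect_equal(spM$acrosome$stations, 12:13)
  # tail series cannot be split; short heads warn
  ts <- collect_series(simM$trace, "tail", 1, 10)
  expect_error(split_head_regions(ts, species_presets("Macrobiotus shonaicus")),
               "head")
  short <- hsM
  keep <- hsM$stations <= 9
  short$stations <- hsM$stations[keep]
  short$samples <- hsM$samples[keep, , drop = FALSE]
  expect_warning(split_head_regions(short,
                                    species_presets("Macrobiotus shonaicus")),
                 "acrosome")
})
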