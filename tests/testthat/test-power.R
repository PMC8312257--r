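test_that("millivolt to device-unit conversion matches the closed form", {
  cal <- amplifierCalibration(gainCode = 255)
  # zero-mean 1 mV at gain code 255: 250 * 48644.8683623726 / 1200
  out <- mvToDeviceUnits(c(1, -1), cal)
  expect_equal(out[1], 10134.3476, tolerance = 1e-7)
  expect_equal(out[1], 250 * 48644.8683623726 / 1200, tolerance = 1e-12)
  # constant input is all offset
  expect_true(all(mvToDeviceUnits(rep(3.7, 10), cal) == 0))
  # homogeneity for zero-mean input
  s <- sin(1:100)
  s <- s - mean(s)
  expect_equal(mvToDeviceUnits(2 * s, cal), 2 * mvToDeviceUnits(s, cal))
  expect_error(mvToDeviceUnits(s, new("AmplifierCalibration",
                                      gainCode = 0, fpv = 1)),
               "gainCode")
})

test_that("window hop and overlap follow the interval formula", {
  r <- computeHopAndOverlap(fftConfig(256, 0.1, 100, fs = 500))
  expect_equal(r$overlap, 0.8)
  expect_equal(r$hopSamples, 50L)
  r <- computeHopAndOverlap(fftConfig(64, 0.248, 100, fs = 250))
  expect_equal(r$overlap, 0, tolerance = 1e-12)
  r <- computeHopAndOverlap(fftConfig(1024, 0.05, 100, fs = 1000))
  expect_equal(r$overlap, 0.95)
  expect_equal(r$hopSamples, 50L)
  big <- computeHopAndOverlap(fftConfig(64, 1, 100, fs = 250))
  expect_true(big$skips)                      # windows skip samples
})

test_that("device Hann window matches its closed form at all loads", {
  cfg <- fftConfig(256, 0.1, 100, fs = 250)
  w <- hannWindow(cfg)
  L <- fftSizeActual(cfg)
  expect_length(w, L)
  expect_equal(w[1], 0)
  expect_equal(w[L], 0)
  # midpoint n = N/2 evaluates to 1; N is odd for the device lengths so
  # the two central samples sit just below it
  expect_equal(max(w), 1, tolerance = 1e-4)
  N <- L - 1
  expect_equal(0.5 * (1 - cos(2 * pi * (N / 2) / N)), 1)
  expect_equal(w, 0.5 * (1 - cos(2 * pi * (0:N) / N)), tolerance = 1e-12)
  w25 <- hannWindow(fftConfig(256, 0.1, 25, fs = 250))
  expect_equal(w25[1], 0.75)                  # blend toward flat
  expect_equal(w25[L], 0.75)
  expect_equal(max(w25), 1, tolerance = 1e-4)
  expect_error(fftConfig(256, 0.1, 60, fs = 250), "windowLoad")
})

test_that("band bins enumerate centers inside the band, edges inclusive", {
  cfg <- fftConfig(1024, 0.1, 100, fs = 500)
  bins <- bandBinIndices(powerBand(8.05, 12.20), cfg)
  expect_equal(bins, 17:24)
  centers <- bins * 500 / 1024
  expect_true(all(centers >= 8.05 & centers <= 12.20))
  # brute-force enumeration oracle
  brute <- Filter(function(k) {
    f <- k * cfg@fs / cfg@size
    f >= 8.05 && f <= 12.20
  }, 0:(cfg@size / 2))
  expect_equal(bins, unlist(brute))
  # one-bin band and the full band
  c1 <- 20 * 500 / 1024
  expect_length(bandBinIndices(powerBand(c1 - 1e-9, c1 + 1e-9), cfg), 1L)
  expect_length(bandBinIndices(powerBand(0, 250), cfg), 513L)
  expect_error(bandBinIndices(powerBand(8, 12),
                              fftConfig(1024, 0.1, 100, fs = 14)),
               "configuration error")
})

test_that("short-time FFT concentrates a bin-centered sine and counts windows", {
  cfg <- fftConfig(256, 0.1, 100, fs = 250)
  z <- shortTimeFFTAmplitude(rep(0, 1000), cfg)
  expect_true(all(z$amplitude == 0))
  expect_equal(nrow(z$amplitude),
               floor((1000 - fftSizeActual(cfg)) /
                       computeHopAndOverlap(cfg)$hopSamples) + 1)
  # sine at an exact bin center: energy confined to that bin
  k <- 30
  f <- k * cfg@fs / cfg@size
  x <- sin(2 * pi * f * (0:2499) / cfg@fs)
  a <- shortTimeFFTAmplitude(x, cfg)
  mid <- colMeans(a$amplitude)
  expect_gt(mid[k + 1] / max(mid[c(k - 1, k + 3)]), 10)
  expect_warning(shortTimeFFTAmplitude(rep(0, 10), cfg), "shorter")
})

test_that("band power is quadratic in amplitude and silent on silence", {
  cfg <- fftConfig(256, 0.1, 100, fs = 250)
  band <- powerBand(18, 22)
  sil <- calculateNewPower(rep(0, 2000), cfg = cfg, band = band)
  expect_true(all(sil$power == 0))
  x <- sin(2 * pi * 20 * (0:1999) / 250)
  p1 <- calculateNewPower(x, cfg = cfg, band = band)
  p2 <- calculateNewPower(2 * x, cfg = cfg, band = band)
  expect_equal(p2$power, 4 * p1$power, tolerance = 1e-9)
})

test_that("windows never span gaps in a combined table", {
  t0 <- 1.6e12
  n <- 5000
  x <- sin(2 * pi * 20 * (0:(n - 1)) / 250)
  tt <- t0 + (0:(n - 1)) * 4
  hole <- 2000:2300
  tab <- data.frame(DerivedTime = tt[-hole], TD_ch1 = x[-hole])
  cfg <- fftConfig(256, 0.1, 100, fs = 250)
  res <- calculateNewPower(tab, 1, cfg, powerBand(18, 22))
  # every window lies wholly inside one continuous segment
  L <- fftSizeActual(cfg)
  holeStart <- tt[hole[1]]; holeEnd <- tt[hole[length(hole)]]
  winStartTimes <- res$time - (L - 1) * 4
  expect_false(any(winStartTimes < holeStart & res$time > holeEnd))
})

test_that("window matching pairs nearest times within tolerance", {
  off <- data.frame(time = c(100, 200, 300, 450), power = 1:4)
  on <- data.frame(time = c(103, 197, 305, 400), power = 1:4)
  m <- matchPowerSeries(off, on, tolMs = 10)
  expect_equal(m$offIdx, 1:3)
  expect_equal(m$onIdx, 1:3)
  all <- matchPowerSeries(off, on)
  expect_equal(all$onIdx, c(1, 2, 3, 4))
})

test_that("gain calibration recovers the scale factor by least squares", {
  set.seed(1)
  x <- runif(200, 10, 1000)
  tm <- seq_along(x) * 100
  off <- data.frame(time = tm, power = x)
  expect_equal(calibrateFFTGain(off, data.frame(time = tm, power = 2 * x)),
               2, tolerance = 1e-12)
  noisy <- 2 * x + rnorm(200, 0, mean(2 * x) / 100)
  g <- calibrateFFTGain(off, data.frame(time = tm, power = noisy))
  expect_gt(g, 1.98); expect_lt(g, 2.02)
  expect_error(
    calibrateFFTGain(off, data.frame(time = tm + 1e7, power = x)),
    "calibration error")
})

test_that("agreement metrics match a brute-force loop implementation", {
  set.seed(2)
  a <- runif(1000, 50, 150)
  b <- a + rnorm(1000)
  m <- comparePowerSeries(a, b)
  # loop oracle
  se <- 0; ad <- 0
  for (i in seq_along(a)) {
    se <- se + (a[i] - b[i])^2
    ad <- ad + abs(a[i] - b[i])
  }
  expect_equal(m$rmse, sqrt(se / 1000), tolerance = 1e-12)
  expect_equal(m$nrmse, sqrt(se / 1000) / (max(a) - min(a)),
               tolerance = 1e-12)
  expect_equal(m$pctDiff, 100 * (ad / 1000) / mean(a), tolerance = 1e-12)
  ident <- comparePowerSeries(a, a)
  expect_equal(unlist(ident), c(rmse = 0, nrmse = 0, pctDiff = 0))
  shifted <- comparePowerSeries(a, a + 3)
  expect_equal(shifted$rmse, 3, tolerance = 1e-12)
  expect_error(comparePowerSeries(rep(1, 5), rep(1, 5)),
               "undefined-metric")
})

test_that("full-band power grows with signal variance", {
  cfg <- fftConfig(256, 0.1, 100, fs = 250)
  band <- powerBand(0, 125)
  set.seed(3)
  base <- rnorm(2000)
  p <- vapply(c(0.5, 1, 2), function(s)
    mean(calculateNewPower(s * base, cfg = cfg, band = band)$power),
    numeric(1))
  expect_true(all(diff(p) > 0))
})
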