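test_that("gap report works at stream-native rate, not grid rate", {
  sim <- simulateSession(cleanConfig(duration = 8, seed = 22L))
  d <- withr::local_tempdir()
  writeSession(d, sim$contents)
  store <- processSession(d)
  gr <- gapReport(store)
  expect_equal(nrow(gr[gr$stream == "td", ]), 0L)   # unimpaired: no gaps
  # accelerometry is sparse on the TD grid but has no native gaps either
  expect_equal(nrow(gr[gr$stream == "accel", ]), 0L)

  # remove one 50-sample packet from a clean 250 Hz stream: one 0.2 s gap
  pk <- makePackets(rep(50L, 10))
  td <- reconstructStream(pk[-5, ])
  store2 <- new("RCSStore", streams = list(td = td), settings = list(),
                events = data.frame(), metadata = list())
  gr2 <- gapReport(store2)
  expect_equal(nrow(gr2), 1L)
  expect_equal(gr2$durationS, 0.2, tolerance = 1e-9)
})

test_that("gap-aware PSD equals plain Welch on continuous data", {
  fs <- 250
  n <- fs * 30
  set.seed(4)
  x <- sin(2 * pi * 10 * (0:(n - 1)) / fs) + rnorm(n, 0, 0.1)
  tt <- 1.6e12 + (0:(n - 1)) * 4
  tab <- data.frame(DerivedTime = tt, TD_ch1 = x)
  res <- gapAwarePSD(tab, "TD_ch1", windowS = 2, overlapFrac = 0.5)
  expect_equal(res$freq[which.max(res$psd)], 10)

  # independent plain-Welch oracle (simple loop)
  nWin <- 2 * fs; hop <- nWin / 2
  w <- 0.5 * (1 - cos(2 * pi * (0:(nWin - 1)) / (nWin - 1)))
  acc <- 0; cnt <- 0
  for (s in seq(1, n - nWin + 1, by = hop)) {
    seg <- x[s:(s + nWin - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    half <- nWin / 2
    P <- Mod(X[1:(half + 1)])^2 / (fs * sum(w^2))
    P[2:half] <- P[2:half] * 2
    acc <- acc + P; cnt <- cnt + 1
  }
  expect_equal(res$nWindowsUsed, cnt)
  expect_equal(res$psd, acc / cnt, tolerance = 1e-12)
})

test_that("gap-aware PSD skips windows that would span a hole", {
  fs <- 250
  n <- fs * 30
  x <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  tt <- 1.6e12 + (0:(n - 1)) * 4
  full <- data.frame(DerivedTime = tt, TD_ch1 = x)
  hole <- (15 * fs):(16 * fs)                 # 1 s hole mid-recording
  holed <- full[-hole, ]
  a <- gapAwarePSD(full, "TD_ch1", 2, 0.5)
  b <- gapAwarePSD(holed, "TD_ch1", 2, 0.5)
  expect_equal(b$freq[which.max(b$psd)], 10)  # peak unchanged
  expect_lt(b$nWindowsUsed, a$nWindowsUsed)
  allNa <- data.frame(DerivedTime = tt[1:10], TD_ch1 = rep(NA_real_, 10))
  expect_error(gapAwarePSD(allNa, "TD_ch1"), "insufficient-data|missing")
})

test_that("sessions concatenate into one monotone store with a seam gap", {
  c1 <- cleanConfig(duration = 6, seed = 31L, streams = "td",
                    tdChannels = 1)
  c2 <- cleanConfig(duration = 6, seed = 32L, streams = "td",
                    tdChannels = 1)
  c2@sessionStart <- c1@sessionStart + 20000    # 14 s after session 1 ends
  mk <- function(cfg) {
    d <- withr::local_tempdir(.local_envir = parent.frame(2))
    sim <- simulateSession(cfg)
    writeSession(d, sim$contents)
    processSession(d)
  }
  s1 <- mk(c1); s2 <- mk(c2)
  both <- combineSessions(list(s1, s2))
  tt <- derivedTime(storeStream(both, "td"))
  expect_true(all(diff(tt) > 0))
  gaps <- which(diff(tt) > 6)
  expect_equal(length(gaps), 1L)                # exactly the seam
  # seam shows up as a long gap relative to the 6 s rule
  expect_gt(diff(tt)[gaps] / 1000, 6)
  # grid phase is shared across the seam
  k <- (tt - storeStream(both, "td")@tRef) / 4
  expect_lt(max(abs(k - round(k))), 1e-6)
  expect_identical(combineSessions(list(s1)), s1)
  expect_error(combineSessions(list(s1, s1)), "conflict error")
})

test_that("event report is chronological with local time and span flags", {
  t0 <- 1.6e12
  td <- mkSeries(t0 + (0:999) * 4, 250)
  ev <- data.frame(time = c(t0 + 5000, t0 + 1000, t0 - 60000),
                   type = c("b", "a", "early"),
                   payload = c("", "", ""), stringsAsFactors = FALSE)
  store <- new("RCSStore", streams = list(td = td), settings = list(),
               events = ev, metadata = list(utcOffset = -480))
  rep <- eventReport(store)
  expect_equal(rep$type, c("early", "a", "b"))
  expect_equal(rep$inSpan, c(FALSE, TRUE, FALSE))
  expect_equal(as.numeric(rep$localTime[1]) * 1000,
               rep$time[1] - 480 * 60000)
  empty <- new("RCSStore", streams = list(td = td), settings = list(),
               events = data.frame(), metadata = list())
  expect_equal(nrow(eventReport(empty)), 0L)
})

test_that("stream plots share one time axis and embed decoded settings", {
  sim <- simulateSession(cleanConfig(duration = 6, seed = 33L))
  d <- withr::local_tempdir()
  writeSession(d, sim$contents)
  store <- processSession(d)
  f <- file.path(withr::local_tempdir(), "streams.png")
  plotStreams(store, c("td", "accel", "power", "stim"), file = f)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 1000)
  fig <- plotStreams(store, c("td", "power"))
  expect_s3_class(fig, "patchwork")
  expect_error(plotStreams(store, "bogus"), "configuration error")
})
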