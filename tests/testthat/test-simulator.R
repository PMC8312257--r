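test_that("same config and seed give byte-identical session files", {
  cfg <- simulationConfig(duration = 4, seed = 9L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulateSession(cfg)
  writeSession(d1, s1$contents, s1$truth)
  s2 <- simulateSession(cfg)
  writeSession(d2, s2$contents, s2$truth)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
})

test_that("unimpaired session reconstructs ground truth exactly", {
  sim <- simulateSession(cleanConfig(duration = 8, seed = 2L))
  td <- reconstructStream(parseStreamDocument(sim$contents$RawDataTD.json))
  expect_equal(derivedTime(td), sim$truth$streams$td$sampleTimes,
               tolerance = 0)
  expect_equal(unname(streamSamples(td)[, 1]),
               sim$truth$streams$td$signal[, 1], tolerance = 0)
})

test_that("packet scheduling stamps timing from the last sample", {
  # two adjacent packets at 250 Hz, second carrying 50 samples: elapsed
  # tick count is 50/250 s * 1e4 ticks/s = 2000
  t0 <- 1.6e12
  times <- t0 + (0:99) * 4
  pk <- schedulePackets(times, c(50, 50), fs = 250, sessionStart = t0)
  expect_equal(nrow(pk), 2L)
  expect_equal((pk$systemTick[2] - pk$systemTick[1]) %% 65536, 2000)
  # 20 s of stream: whole-second timestamps span at most 21 values
  times20 <- t0 + (0:(20 * 250 - 1)) * 4
  pk20 <- schedulePackets(times20, c(25, 125), fs = 250, sessionStart = t0)
  expect_lte(length(unique(pk20$timestamp)), 21L)
  # single packet holds everything, sequence counter starts where told
  one <- schedulePackets(times[1:100], c(100, 100), fs = 250,
                         sessionStart = t0, seqStart = 17L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$dataTypeSequence, 17L)
  expect_error(schedulePackets(numeric(0), c(10, 10), 250),
               "empty-stream")
})

test_that("transport impairments: identity, total loss, calibrated noise", {
  pk <- makePackets(rep(10L, 1000L))
  ident <- applyTransportImpairments(pk, 0, 0, 0)
  expect_identical(ident$packets, pk)
  gone <- applyTransportImpairments(pk, 1, 0, 0)
  expect_equal(nrow(gone$packets), 0L)
  expect_true(all(gone$log$event == "dropped"))
  set.seed(31)
  jit <- applyTransportImpairments(pk, 0, 0, pgtJitterSd = 50)
  sdErr <- sd(jit$packets$packetGenTime - jit$packets$trueGenTime)
  expect_gt(sdErr, 40)
  expect_lt(sdErr, 60)
})

test_that("drop fraction follows the configured loss rate", {
  pk <- makePackets(rep(10L, 10000L))
  set.seed(77)
  res <- applyTransportImpairments(pk, dropProbability = 0.05)
  frac <- mean(res$log$event == "dropped")
  sd3 <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_gt(frac, 0.05 - sd3)
  expect_lt(frac, 0.05 + sd3)
})

test_that("sample conservation: streamed plus dropped equals generated", {
  sim <- simulateSession(simulationConfig(duration = 20,
                                          dropProbability = 0.1,
                                          seed = 13L))
  tr <- sim$truth$streams$td
  recs <- sim$contents$RawDataTD.json$Packets
  inJson <- sum(vapply(recs, function(r) length(r$ChannelSamples[[1]]),
                       integer(1)))
  droppedIdx <- tr$log$creationIndex[tr$log$event == "dropped"]
  inDropped <- sum(tr$scheduled$nSamples[droppedIdx])
  expect_equal(inJson + inDropped, length(tr$sampleTimes))
})

test_that("clock consistency: tick and timestamp agree without drift", {
  sim <- simulateSession(cleanConfig(duration = 6, seed = 4L))
  pk <- parseStreamDocument(sim$contents$RawDataTD.json)
  # any two packets less than one tick cycle apart
  for (i in c(1, 3)) {
    for (j in c(i + 1, i + 2)) {
      dtick <- ((pk$systemTick[j] - pk$systemTick[i]) %% 65536) * 1e-4
      dts <- pk$timestamp[j] - pk$timestamp[i]
      expect_lte(abs(dtick - dts), 1)
    }
  }
})

test_that("stream-side power engine matches the off-device arithmetic", {
  set.seed(8)
  sig <- 0.02 * sin(2 * pi * 10 * (0:4999) / 250) + rnorm(5000, 0, 0.005)
  cfg <- fftConfig(256, 0.1, 100, fs = 250)
  band <- powerBand(8, 12)
  emu <- emulateFFTPowerStream(sig, cfg, list(band))
  off <- calculateNewPower(sig, cfg = cfg, band = band)
  expect_equal(unname(emu$power[, 1]), off$power, tolerance = 1e-12)
  expect_equal(emu$endIndex, off$time)
  # zero input -> zero power
  z <- emulateFFTPowerStream(rep(0, 2000), cfg, list(band))
  expect_true(all(z$power == 0))
  expect_error(emulateFFTPowerStream(sig, cfg, list(powerBand(100, 130))),
               "configuration error")
})

test_that("disabled streams leave empty documents the loader tolerates", {
  sim <- simulateSession(cleanConfig(duration = 4, seed = 6L,
                                     streams = "td"))
  expect_length(sim$contents$RawDataPower.json$Packets, 0L)
  d <- withr::local_tempdir()
  writeSession(d, sim$contents)
  sess <- loadSession(d)
  expect_true("td" %in% names(sess$streams))
  expect_false("power" %in% names(sess$streams))
})
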