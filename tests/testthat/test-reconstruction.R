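test_that("packet rejection applies each rule against the previous kept packet", {
  pk <- makePackets(rep(50L, 8))
  clean <- rejectInvalidPackets(pk)
  expect_identical(clean$packets, pk)          # clean stream untouched
  expect_equal(nrow(clean$log), 0L)

  bad <- pk
  bad$packetGenTime[3] <- -1                   # negative PacketGenTime
  res <- rejectInvalidPackets(bad)
  expect_equal(res$log$index, 3L)
  expect_equal(res$log$rule, "negative_packetGenTime")

  bad <- pk
  bad$packetGenTime[4] <- bad$packetGenTime[3] - 600   # backward > 500 ms
  res <- rejectInvalidPackets(bad)
  expect_equal(res$log$rule[res$log$index == 4], "packetGenTime_backward")

  bad <- pk
  bad$timestamp[5] <- bad$timestamp[5] + 25 * 3600     # 25 h from median
  res <- rejectInvalidPackets(bad)
  expect_equal(res$log$rule[res$log$index == 5], "timestamp_outlier")

  bad <- pk
  bad$packetGenTime[6] <- bad$packetGenTime[6] + 3000  # 3 s vs timestamp
  res <- rejectInvalidPackets(bad)
  expect_equal(res$log$rule[res$log$index == 6], "clock_disagreement")
})

test_that("chunking splits at losses and survives counter rollovers", {
  pk <- makePackets(rep(50L, 6))
  expect_equal(nrow(identifyChunks(pk)), 1L)   # unimpaired: one chunk

  holed <- pk[-3, ]                            # one dropped packet
  ch <- identifyChunks(holed)
  expect_equal(nrow(ch), 2L)
  expect_equal(ch$endPacket[1], 2L)            # boundary at the drop

  roll <- makePackets(rep(50L, 4), seq0 = 254L)
  expect_equal(roll$dataTypeSequence, c(254L, 255L, 0L, 1L))
  expect_equal(nrow(identifyChunks(roll)), 1L) # mod-256 rollover is fine

  # sampling-rate change forces a boundary even with consistent counters
  mix <- makePackets(rep(50L, 4))
  mix$sampleRate[3:4] <- 500
  expect_gte(nrow(identifyChunks(mix)), 2L)
})

test_that("chunk partition matches exhaustive minimal partition on small streams", {
  bruteBoundaries <- function(pk) {
    n <- nrow(pk)
    if (n < 2) return(integer(0))
    pred <- vapply(seq_len(n - 1), function(i)
      rcstream:::.packetContinuity(pk[i:(i + 1), , drop = FALSE]),
      logical(1))
    best <- NULL
    for (mask in 0:(2^(n - 1) - 1)) {
      bnd <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
      if (all(pred[setdiff(seq_len(n - 1), bnd)]) &&
          (is.null(best) || length(bnd) < length(best)))
        best <- bnd
    }
    best
  }
  set.seed(99)
  for (trial in 1:20) {
    n <- sample(2:5, 1)
    pk <- makePackets(sample(20:80, n, replace = TRUE))
    # randomly corrupt counters to create boundaries
    if (runif(1) < 0.7) {
      i <- sample(n, 1)
      pk$dataTypeSequence[i] <- (pk$dataTypeSequence[i] + sample(1:3, 1)) %% 256
    }
    if (runif(1) < 0.3) {
      i <- sample(n, 1)
      pk$systemTick[i] <- (pk$systemTick[i] + 5000L) %% 65536L
    }
    got <- identifyChunks(pk)
    expect_equal(got$endPacket[-nrow(got)], bruteBoundaries(pk),
                 label = sprintf("trial %d", trial))
  }
})

test_that("gap classification uses the 6 s timestamp threshold", {
  expect_equal(classifyGap(100, 105), "short")  # 5 s
  expect_equal(classifyGap(100, 106), "long")   # exactly 6 s
  expect_equal(classifyGap(100, 100), "short")  # fs-change boundary
})

test_that("adjusted anchor averages per-packet clock offsets", {
  one <- makePackets(50L)
  expect_equal(adjustedAnchor(one), one$packetGenTime[1])

  pk <- makePackets(rep(50L, 3))
  pk$packetGenTime[2] <- pk$packetGenTime[2] + 10
  pk$packetGenTime[3] <- pk$packetGenTime[3] + 20
  expect_equal(adjustedAnchor(pk), pk$packetGenTime[1] + 15)

  # zero-jitter simulated chunk: anchor is the true last-sample time of
  # the first packet
  sim <- simulateSession(cleanConfig(duration = 5, seed = 12L))
  pks <- parseStreamDocument(sim$contents$RawDataTD.json)
  anchor <- adjustedAnchor(pks)
  trueFirst <- sim$truth$streams$td$scheduled$trueGenTime[1]
  expect_equal(anchor, trueFirst, tolerance = 1e-9)
})

test_that("per-chunk derived times count back from the anchor", {
  tt <- deriveTimesForChunk(anchor = 1000, totalSamples = 3,
                            firstPacketSamples = 3, fs = 250)
  expect_equal(tt, c(992, 996, 1000))
  long <- deriveTimesForChunk(5e5, 1000, 40, 500)
  expect_true(all(diff(long) == 2))
})

test_that("tick-counter gap bridging handles rollover and refuses long gaps", {
  # ticks 65000 -> 500 wraps: (500 - 65000) mod 65536 = 1036 ticks
  out <- deriveTimesGapMethod(0, 65000L, 500L, "short")
  expect_equal(out, 103.6)
  expect_error(deriveTimesGapMethod(0, 1L, 2L, "long"), "usage error")
})

test_that("grid snapping shifts whole chunks to the nearest grid point", {
  tRef <- 1.6e12
  onGrid <- tRef + (10:15) * 4
  expect_equal(snapToGrid(onGrid, tRef, 250), onGrid)
  shifted <- snapToGrid(tRef + 1.4 * 4 + (0:3) * 4, tRef, 250)
  expect_equal(shifted[1], tRef + 4)            # 1.4 steps -> 1 step
  halfway <- snapToGrid(tRef + 6 + (0:3) * 4, tRef, 250)
  expect_equal(halfway[1], tRef + 4)            # tie rounds earlier
  expect_true(all(diff(shifted) == 4))
})

test_that("reconstruction invariants hold under loss, jitter and rollover", {
  cfg <- simulationConfig(duration = 90, tdFs = 250, tdChannels = 1,
                          dropProbability = 0.05, reorderProbability = 0,
                          pgtJitterSd = 30, seed = 5L, streams = "td")
  sim <- simulateSession(cfg)
  td <- reconstructStream(parseStreamDocument(sim$contents$RawDataTD.json))
  tt <- derivedTime(td)
  expect_true(all(diff(tt) > 0))                       # strictly increasing
  within <- diff(td@provenance) == 0
  expect_true(all(diff(tt)[within] == 4))              # exact spacing
  k <- (tt - td@tRef) / 4
  expect_lt(max(abs(k - round(k))), 1e-6)              # all on the grid
  # 90 s session crosses the tick counter cycle (~6.55 s) many times with
  # no cycle-sized discontinuity: every sample stays close to truth
  tr <- sim$truth$streams$td
  droppedIdx <- tr$log$creationIndex[tr$log$event == "dropped"]
  keptMask <- rep(TRUE, nrow(tr$scheduled))
  keptMask[droppedIdx] <- FALSE
  ends <- cumsum(tr$scheduled$nSamples)
  keptSamples <- unlist(mapply(function(e, n, k)
    if (k) (e - n + 1):e else NULL,
    ends, tr$scheduled$nSamples, keptMask))
  err <- tt - tr$sampleTimes[keptSamples]
  expect_lt(max(abs(err)), 500)
})

test_that("tick-counter short-gap method is exact without drift", {
  cfg <- simulationConfig(duration = 30, tdFs = 250, tdChannels = 1,
                          dropProbability = 0.05, reorderProbability = 0,
                          pgtJitterSd = 0, systemTickDriftPpm = 0,
                          seed = 8L, streams = "td")
  sim <- simulateSession(cfg)
  pk <- parseStreamDocument(sim$contents$RawDataTD.json)
  td <- reconstructStream(pk, method = "gap")
  tr <- sim$truth$streams$td
  droppedIdx <- tr$log$creationIndex[tr$log$event == "dropped"]
  keptMask <- rep(TRUE, nrow(tr$scheduled)); keptMask[droppedIdx] <- FALSE
  ends <- cumsum(tr$scheduled$nSamples)
  keptSamples <- unlist(mapply(function(e, n, k)
    if (k) (e - n + 1):e else NULL,
    ends, tr$scheduled$nSamples, keptMask))
  expect_gte(nrow(streamChunks(td)), 2)   # the gap path was exercised
  expect_equal(derivedTime(td), tr$sampleTimes[keptSamples],
               tolerance = 1e-9)
})

test_that("empty or fully rejected streams degrade with a warning", {
  expect_warning(out <- reconstructStream(NULL), "empty-stream")
  expect_equal(length(out), 0L)
  pk <- makePackets(rep(10L, 3))
  pk$packetGenTime <- -1
  expect_warning(out <- reconstructStream(pk), "rejected")
  expect_equal(nrow(out@rejectionLog), 3L)
})
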