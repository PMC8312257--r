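# Per-stream time reconstruction: packet cleaning, continuity chunking,
# gap classification, unix-time anchoring, and per-sample DerivedTime on a
# uniform 1/fs grid.

#' Reject packets with faulty or unplaceable timing metadata
#'
#' Four rules, applied per packet in received order (first failing rule is
#' logged): (1) timestamp further than 24 h from the stream's median
#' timestamp; (2) negative PacketGenTime; (3) PacketGenTime more than
#' 500 ms earlier than the previous KEPT packet's; (4) elapsed
#' PacketGenTime disagreeing with elapsed timestamp by more than 2 s,
#' again relative to the previous kept packet.
#'
#' @param packets packet data.frame in received order.
#' @param constants A [ClockConstants-class].
#' @return List: `packets` (kept rows) and `log` (data.frame: index, rule).
#' @export
rejectInvalidPackets <- function(packets, constants = clockConstants()) {
  n <- nrow(packets)
  if (n == 0) return(list(packets = packets,
                          log = data.frame(index = integer(0),
                                           rule = character(0))))
  medTs <- median(packets$timestamp)
  keep <- logical(n)
  rule <- character(0)
  idx <- integer(0)
  prevKept <- NA_integer_
  for (i in seq_len(n)) {
    r <- NULL
    if (abs(packets$timestamp[i] - medTs) > constants@outlierWindow) {
      r <- "timestamp_outlier"
    } else if (packets$packetGenTime[i] < 0) {
      r <- "negative_packetGenTime"
    } else if (!is.na(prevKept)) {
      dPgt <- (packets$packetGenTime[i] -
                 packets$packetGenTime[prevKept]) / 1000
      dTs <- packets$timestamp[i] - packets$timestamp[prevKept]
      if (dPgt < -constants@backwardLimit) r <- "packetGenTime_backward"
      else if (abs(dPgt - dTs) > constants@disagreementLimit)
        r <- "clock_disagreement"
    }
    if (is.null(r)) {
      keep[i] <- TRUE
      prevKept <- i
    } else {
      idx <- c(idx, i)
      rule <- c(rule, r)
    }
  }
  out <- packets[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(packets = out,
       log = data.frame(index = idx, rule = rule,
                        packetGenTime = packets$packetGenTime[idx],
                        stringsAsFactors = FALSE))
}

# Continuity predicate between adjacent cleaned packets i and i+1: the
# sequence counter advances by exactly 1 (mod 256), the sampling rate is
# unchanged, the elapsed tick counter matches the expected duration of
# packet i+1's samples within tolerance, and the elapsed timestamp agrees
# within its 1 s resolution.
.packetContinuity <- function(packets, constants = clockConstants()) {
  n <- nrow(packets)
  if (n < 2) return(logical(0))
  dSeq <- (packets$dataTypeSequence[-1] -
             packets$dataTypeSequence[-n]) %% constants@seqModulus
  sameFs <- packets$sampleRate[-1] == packets$sampleRate[-n]
  expected <- packets$nSamples[-1] / packets$sampleRate[-1]  # seconds
  tickEl <- ((packets$systemTick[-1] - packets$systemTick[-n]) %%
               constants@tickModulus) * constants@tickSeconds
  tickOk <- abs(tickEl - expected) <=
    constants@tickToleranceTicks * constants@tickSeconds
  tsOk <- abs((packets$timestamp[-1] - packets$timestamp[-n]) -
                expected) <= 1
  dSeq == 1 & sameFs & tickOk & tsOk
}

#' Identify continuous chunks of packets
#'
#' A chunk is a maximal run of adjacent packets sampled without loss:
#' sequence counter advancing by one (mod 256), constant sampling rate,
#' and elapsed tick counter / timestamp both consistent with the number of
#' samples carried. Sampling-rate changes always start a new chunk.
#'
#' @param packets cleaned packet data.frame (received order).
#' @param constants A [ClockConstants-class].
#' @return data.frame: startPacket, endPacket, nSamples, fs; one row per
#'   chunk in packet order.
#' @export
identifyChunks <- function(packets, constants = clockConstants()) {
  n <- nrow(packets)
  if (n == 0)
    return(data.frame(startPacket = integer(0), endPacket = integer(0),
                      nSamples = integer(0), fs = numeric(0)))
  cont <- .packetContinuity(packets, constants)
  bounds <- which(!cont)
  start <- c(1L, bounds + 1L)
  end <- c(bounds, n)
  data.frame(
    startPacket = start, endPacket = end,
    nSamples = vapply(seq_along(start), function(i)
      sum(packets$nSamples[start[i]:end[i]]), integer(1)),
    fs = packets$sampleRate[start])
}

#' Classify the gap preceding a chunk
#'
#' Gaps shorter than 6 s (by elapsed timestamp between the last packet of
#' the previous chunk and the first packet of the next) stay within one
#' tick-counter cycle and are "short"; gaps of 6 s or more may span a full
#' cycle and are "long".
#'
#' @param prevEndTimestamp timestamp (s) of the previous chunk's last
#'   packet.
#' @param nextStartTimestamp timestamp of the next chunk's first packet.
#' @param constants A [ClockConstants-class].
#' @return "short" or "long".
#' @export
classifyGap <- function(prevEndTimestamp, nextStartTimestamp,
                        constants = clockConstants()) {
  if (nextStartTimestamp - prevEndTimestamp < constants@shortGapThreshold)
    "short" else "long"
}

#' Adjusted anchor time of a chunk
#'
#' Every packet's PacketGenTime is a noisy estimate of its last sample's
#' unix time. Within a chunk the expected elapsed time from the first
#' packet's last sample to packet j's last sample is the intervening
#' sample count divided by the rate, so each later packet provides an
#' offset estimate `PGT_j - (PGT_1 + expected_j)`. The anchor is the first
#' packet's PacketGenTime corrected by the mean of these offsets
#' (single-packet chunks: the PacketGenTime itself).
#'
#' @param chunkPackets packet data.frame of one chunk.
#' @return Unix milliseconds of the chunk's first packet's LAST sample.
#' @export
adjustedAnchor <- function(chunkPackets) {
  n <- nrow(chunkPackets)
  if (n == 0) stop("empty chunk", call. = FALSE)
  pgt <- chunkPackets$packetGenTime
  if (n == 1) return(pgt[1])
  fs <- chunkPackets$sampleRate[1]
  expectedMs <- c(0, cumsum(chunkPackets$nSamples[-1])) / fs * 1000
  offsets <- pgt - (pgt[1] + expectedMs)
  pgt[1] + mean(offsets[-1])
}

#' Derived times for one chunk
#'
#' The anchor is the time of the first packet's last sample; sample m of
#' the chunk (1-indexed, `c1` samples in the first packet) gets
#' `anchor + (m - c1) * 1000/fs`. Assumes only whole packets are missing,
#' never samples within a packet.
#'
#' @param anchor unix ms of the first packet's last sample.
#' @param totalSamples samples in the chunk.
#' @param firstPacketSamples samples in the chunk's first packet.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of unix ms, uniformly spaced at 1000/fs.
#' @export
deriveTimesForChunk <- function(anchor, totalSamples, firstPacketSamples,
                                fs) {
  anchor + (seq_len(totalSamples) - firstPacketSamples) * (1000 / fs)
}

#' Bridge a short gap with the tick counter
#'
#' For gaps confirmed shorter than one tick-counter cycle, the elapsed
#' time between the previous chunk's last packet and the next chunk's
#' first packet is read directly off the hardware counter:
#' `((tickNext - tickPrev) mod 2^16) * 1e-4` seconds, and the next chunk
#' is anchored at the previous chunk's last derived time plus that
#' elapsed. Use only when the tick clock is known to be accurate: any rate
#' error accumulates over the recording, unlike the default
#' PacketGenTime-based anchoring.
#'
#' @param prevLastDerivedMs last derived time of the previous chunk (ms).
#' @param prevLastTick,nextFirstTick systemTick values of the packets on
#'   either side of the gap.
#' @param gapClass classification from [classifyGap()]; must be "short".
#' @param constants A [ClockConstants-class].
#' @return Anchor time (unix ms) for the next chunk's first packet's last
#'   sample.
#' @export
deriveTimesGapMethod <- function(prevLastDerivedMs, prevLastTick,
                                 nextFirstTick, gapClass = "short",
                                 constants = clockConstants()) {
  if (!identical(gapClass, "short"))
    stop("usage error: the tick-counter gap method applies only to short gaps",
         call. = FALSE)
  elapsed <- ((nextFirstTick - prevLastTick) %% constants@tickModulus) *
    constants@tickSeconds
  prevLastDerivedMs + elapsed * 1000
}

#' Snap a chunk onto the reference grid
#'
#' Applies one common shift to all of a chunk's derived times so that its
#' first time lands on the nearest point of the grid
#' `{tRef + k * 1000/fs}`; a tie at exactly half a grid step rounds toward
#' the earlier point. Inter-sample spacing is preserved exactly.
#'
#' @param chunkTimes uniformly spaced times (ms).
#' @param tRef grid origin (ms).
#' @param fs sampling rate in Hz.
#' @return Shifted times, exactly on the grid.
#' @export
snapToGrid <- function(chunkTimes, tRef, fs) {
  step <- 1000 / fs
  k <- roundHalfDown((chunkTimes[1] - tRef) / step)
  tRef + (k + seq_along(chunkTimes) - 1) * step
}

#' Reconstruct one stream's DerivedTime series
#'
#' Full per-stream pipeline: reject invalid packets, identify continuity
#' chunks, anchor each chunk to unix time (default: jitter-averaged
#' PacketGenTime; optionally the tick-counter bridge for short gaps), snap
#' chunks two onward to the first chunk's 1/fs grid, and emit every
#' sample's DerivedTime with chunk provenance. Gaps between chunks are
#' left empty here; they become explicit missing values during
#' harmonization.
#'
#' @param packets packet data.frame in received order.
#' @param method "default" (PacketGenTime anchoring for all chunks) or
#'   "gap" (tick-counter bridging across short gaps; long gaps still use
#'   the default anchoring).
#' @param constants A [ClockConstants-class].
#' @return A [DerivedTimeSeries-class]. Empty (with a warning) when no
#'   packets survive cleaning.
#' @export
reconstructStream <- function(packets, method = c("default", "gap"),
                              constants = clockConstants()) {
  method <- match.arg(method)
  emptySeries <- function(log) {
    new("DerivedTimeSeries", derivedTime = numeric(0),
        samples = matrix(0, 0, 1), fs = NA_real_, tRef = NA_real_,
        chunks = data.frame(), provenance = integer(0), rejectionLog = log)
  }
  if (is.null(packets) || nrow(packets) == 0) {
    warning("empty-stream result: no packets")
    return(emptySeries(data.frame(index = integer(0),
                                  rule = character(0))))
  }
  cleaned <- rejectInvalidPackets(packets, constants)
  pk <- cleaned$packets
  if (nrow(pk) == 0) {
    warning("empty-stream result: all packets rejected")
    return(emptySeries(cleaned$log))
  }
  chunks <- identifyChunks(pk, constants)
  nC <- nrow(chunks)
  anchors <- vapply(seq_len(nC), function(i)
    adjustedAnchor(pk[chunks$startPacket[i]:chunks$endPacket[i], ,
                      drop = FALSE]),
    numeric(1))
  # received order may interleave swapped packets; process chunks in
  # anchor-time order so the stream is assembled chronologically
  ord <- order(anchors)
  chunks <- chunks[ord, , drop = FALSE]
  anchors <- anchors[ord]
  rownames(chunks) <- NULL

  fsRef <- chunks$fs[1]
  gapClass <- character(nC)
  timesList <- vector("list", nC)
  tRef <- NA_real_
  prevEnd <- -Inf
  prevEndTick <- NA_integer_
  prevEndTimestamp <- NA_real_
  for (i in seq_len(nC)) {
    cp <- pk[chunks$startPacket[i]:chunks$endPacket[i], , drop = FALSE]
    fs <- chunks$fs[i]
    step <- 1000 / fs
    c1 <- cp$nSamples[1]
    total <- chunks$nSamples[i]
    if (i == 1) {
      gapClass[i] <- "first"
      tt <- deriveTimesForChunk(anchors[i], total, c1, fs)
      tRef <- tt[1]
      tt <- tRef + (seq_len(total) - 1) * step  # exact grid arithmetic
    } else {
      gapClass[i] <- classifyGap(prevEndTimestamp, cp$timestamp[1],
                                 constants)
      if (method == "gap" && gapClass[i] == "short" &&
          fs == fsRef && !is.na(prevEndTick)) {
        anchor <- deriveTimesGapMethod(prevEnd, prevEndTick,
                                       cp$systemTick[1], "short",
                                       constants)
      } else {
        anchor <- anchors[i]
      }
      tt <- deriveTimesForChunk(anchor, total, c1, fs)
      tt <- snapToGrid(tt, tRef, fs)
      if (tt[1] <= prevEnd) {
        # overlap after snapping (heavy jitter on tiny chunks): push the
        # chunk to the first free grid slot to keep DerivedTime strictly
        # increasing with exact spacing
        shift <- (floor((prevEnd - tt[1]) / step) + 1) * step
        tt <- tt + shift
      }
    }
    timesList[[i]] <- tt
    prevEnd <- tt[total]
    prevEndTick <- cp$systemTick[nrow(cp)]
    prevEndTimestamp <- cp$timestamp[nrow(cp)]
  }
  chunks$gapClass <- gapClass
  chunks$anchor <- anchors
  chunks$firstTime <- vapply(timesList, `[`, numeric(1), 1)
  chunks$lastTime <- vapply(timesList, function(x) x[length(x)],
                            numeric(1))

  sampleMat <- do.call(rbind, unlist(lapply(seq_len(nC), function(i)
    pk$samples[chunks$startPacket[i]:chunks$endPacket[i]]),
    recursive = FALSE))
  prov <- rep.int(seq_len(nC), chunks$nSamples)
  new("DerivedTimeSeries",
      derivedTime = unlist(timesList, use.names = FALSE),
      samples = sampleMat, fs = fsRef, tRef = tRef, chunks = chunks,
      provenance = prov, rejectionLog = cleaned$log)
}
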