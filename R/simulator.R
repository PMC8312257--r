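# Synthetic session generation: signals, packet scheduling, transport
# impairments, stream-side emulation of the on-device power engine, and
# serialization to the session JSON dialect (see inst/schema).

# --- signal synthesis -------------------------------------------------------

# Pink (1/f) noise with unit RMS via spectral shaping of white noise.
.pinkNoise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))            # guard DC
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

# Smoothed random walk with unit RMS, for accelerometer motion.
.motionNoise <- function(n, fs) {
  w <- cumsum(rnorm(n))
  k <- max(3L, as.integer(fs))         # ~1 s moving average
  sm <- stats::filter(w, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  s <- sd(sm)
  if (s == 0) sm else sm / s
}

.renderSignal <- function(spec, tSec, fs) {
  switch(spec@kind,
    sine = spec@amplitude * sin(2 * pi * spec@frequency * tSec),
    burst_sine = {
      cycle <- spec@burstOn + spec@burstOff
      if (cycle <= 0) stop("burst_sine needs positive burstOn+burstOff",
                           call. = FALSE)
      gate <- (tSec %% cycle) < spec@burstOn
      spec@amplitude * sin(2 * pi * spec@frequency * tSec) * gate
    },
    one_over_f_noise = spec@amplitude * .pinkNoise(length(tSec)),
    accel_motion = spec@amplitude * .motionNoise(length(tSec), fs),
    stop("unknown signal kind: ", spec@kind, call. = FALSE))
}

.renderStreamSignals <- function(specs, nChannels, n, fs, t0Sec) {
  tSec <- t0Sec + (seq_len(n) - 1) / fs
  out <- matrix(0, n, nChannels)
  for (spec in specs) {
    ch <- spec@channel
    if (ch >= 1 && ch <= nChannels)
      out[, ch] <- out[, ch] + .renderSignal(spec, tSec, fs)
  }
  out
}

# --- packet scheduling ------------------------------------------------------

#' Partition a sample stream into transmission packets
#'
#' Assigns every sample of a uniformly sampled stream to exactly one packet
#' of a random size drawn from `packetSizeRange`, and stamps each packet
#' with the timing variables of the transport: the timing fields describe
#' the LAST sample of the packet. `systemTick` is the hardware tick counter
#' (`floor(elapsed * 1e4 * (1 + drift))` mod 2^16), `timestamp` the
#' firmware whole-second counter since 2000-03-01, `packetGenTime` the
#' transmitter's unix-ms estimate of creation time (jitter is added later
#' by [applyTransportImpairments()]), and `dataTypeSequence` a mod-256
#' packet counter.
#'
#' @param sampleTimes numeric vector of true unix ms, uniformly spaced.
#' @param packetSizeRange integer [min, max] samples per packet.
#' @param fs sampling rate in Hz.
#' @param sessionStart unix ms defining tick-counter zero.
#' @param driftPpm tick-counter rate error in parts per million.
#' @param seqStart initial dataTypeSequence value.
#' @param samples optional numeric matrix (one row per sample) carried
#'   into the packets.
#' @param rxLatencyMs fixed receive latency added to PacketRxUnixTime.
#' @return data.frame of packets with timing columns, `nSamples`, a
#'   `samples` list column of matrices, and `trueGenTime` (ground truth,
#'   stripped before serialization).
#' @export
schedulePackets <- function(sampleTimes, packetSizeRange, fs,
                            sessionStart = sampleTimes[1], driftPpm = 0,
                            seqStart = 0L, samples = NULL,
                            rxLatencyMs = 50) {
  n <- length(sampleTimes)
  if (n == 0) stop("empty-stream error: no samples to packetize",
                   call. = FALSE)
  lo <- packetSizeRange[1]; hi <- packetSizeRange[2]
  sizes <- integer(0)
  while (sum(sizes) < n) {
    need <- ceiling((n - sum(sizes)) / lo) + 1L
    sizes <- c(sizes, sample.int(hi - lo + 1L, need, replace = TRUE) +
                 lo - 1L)
  }
  cut <- which(cumsum(sizes) >= n)[1]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- n - sum(sizes[-cut])
  sizes <- sizes[sizes > 0]
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  tLast <- sampleTimes[ends]
  elapsedSec <- (tLast - sessionStart) / 1000
  tick <- floor(elapsedSec * 1e4 * (1 + driftPpm * 1e-6)) %% 65536
  sampMats <- if (is.null(samples)) {
    lapply(sizes, function(k) matrix(0, k, 1))
  } else {
    mapply(function(s, e) samples[s:e, , drop = FALSE], starts, ends,
           SIMPLIFY = FALSE)
  }
  data.frame(
    systemTick = as.integer(tick),
    timestamp = unixMsToTimestamp(tLast),
    packetGenTime = round(tLast),
    packetRxUnixTime = round(tLast + rxLatencyMs),
    dataTypeSequence = as.integer((seqStart + seq_along(sizes) - 1L) %% 256),
    sampleRate = fs,
    nSamples = as.integer(sizes),
    samples = I(sampMats),
    trueGenTime = tLast
  )
}

#' Apply transport impairments to scheduled packets
#'
#' Models the lossy, unacknowledged transport: each packet is dropped
#' independently with `dropProbability`; surviving adjacent pairs are
#' swapped with `reorderProbability`; `packetGenTime` receives independent
#' Gaussian noise with SD `pgtJitterSd` ms (rounded to integer ms, the
#' transmitter's clock resolution).
#'
#' @param packets data.frame from [schedulePackets()].
#' @param dropProbability per-packet loss probability in [0, 1].
#' @param reorderProbability per-adjacent-pair swap probability.
#' @param pgtJitterSd Gaussian jitter SD on PacketGenTime, ms.
#' @return List: `packets` (survivors in received order) and `log`
#'   (data.frame of per-packet events: kept/dropped/swapped).
#' @export
applyTransportImpairments <- function(packets, dropProbability = 0,
                                      reorderProbability = 0,
                                      pgtJitterSd = 0) {
  n <- nrow(packets)
  log <- data.frame(creationIndex = seq_len(n), event = "kept",
                    stringsAsFactors = FALSE)
  if (pgtJitterSd > 0)
    packets$packetGenTime <- round(packets$trueGenTime +
                                     rnorm(n, 0, pgtJitterSd))
  dropped <- if (dropProbability > 0) runif(n) < dropProbability
             else rep(FALSE, n)
  log$event[dropped] <- "dropped"
  kept <- packets[!dropped, , drop = FALSE]
  keptIdx <- which(!dropped)
  m <- nrow(kept)
  if (reorderProbability > 0 && m >= 2) {
    i <- 1L
    ord <- seq_len(m)
    while (i < m) {
      if (runif(1) < reorderProbability) {
        ord[c(i, i + 1L)] <- ord[c(i + 1L, i)]
        log$event[keptIdx[c(i, i + 1L)]] <- "swapped"
        i <- i + 2L
      } else i <- i + 1L
    }
    kept <- kept[ord, , drop = FALSE]
  }
  rownames(kept) <- NULL
  list(packets = kept, log = log)
}

# --- stream-side power engine ----------------------------------------------

#' Emulate the on-device FFT power stream
#'
#' Runs the device's band-power arithmetic windows-forward over a
#' time-domain millivolt signal, exactly as [calculateNewPower()] does
#' off-device (the two share one implementation), producing the power
#' series the device would have streamed. With `quantize = TRUE` the
#' values are rounded to integer device units, as streamed by the
#' hardware.
#'
#' @param tdSignalMv numeric millivolt vector (one channel).
#' @param cfg An [FFTConfig-class].
#' @param bands list of [PowerBand-class] objects.
#' @param cal An [AmplifierCalibration-class].
#' @param quantize round to integer device units (default FALSE).
#' @return List with `endIndex` (window-end sample indices) and `power`
#'   (matrix, windows x bands).
#' @export
emulateFFTPowerStream <- function(tdSignalMv, cfg, bands,
                                  cal = amplifierCalibration(),
                                  quantize = FALSE) {
  for (b in bands)
    if (b@fLo < 0 || b@fHi > cfg@fs / 2)
      stop("configuration error: band outside [0, fs/2]", call. = FALSE)
  res <- lapply(bands, function(b)
    .bandPowerCore(tdSignalMv, cfg, b, cal, quantize))
  list(endIndex = res[[1]]$endIndex,
       power = do.call(cbind, lapply(res, `[[`, "power")))
}

# --- session assembly -------------------------------------------------------

.packetsToRecords <- function(packets, channelNames, rateField = "SampleRate",
                              rateValue = NULL) {
  lapply(seq_len(nrow(packets)), function(i) {
    rec <- list(
      SystemTick = packets$systemTick[i],
      Timestamp = packets$timestamp[i],
      PacketGenTime = packets$packetGenTime[i],
      PacketRxUnixTime = packets$packetRxUnixTime[i],
      DataTypeSequence = packets$dataTypeSequence[i]
    )
    rec[[rateField]] <- if (is.null(rateValue)) packets$sampleRate[i]
                        else rateValue
    m <- packets$samples[[i]]
    rec$ChannelSamples <- stats::setNames(
      lapply(seq_len(ncol(m)), function(j) unname(m[, j])), channelNames)
    rec
  })
}

.simStream <- function(sampleTimes, samples, fs, config, seqStart = 0L) {
  sched <- schedulePackets(sampleTimes, config@packetSizeRange, fs,
                           sessionStart = config@sessionStart,
                           driftPpm = config@systemTickDriftPpm,
                           seqStart = seqStart, samples = samples)
  imp <- applyTransportImpairments(sched, config@dropProbability,
                                   config@reorderProbability,
                                   config@pgtJitterSd)
  list(scheduled = sched, received = imp$packets, log = imp$log)
}

#' Simulate a full streaming session
#'
#' Generates every enabled stream (time domain, accelerometry, emulated
#' power, FFT, adaptive), packetizes each independently, applies transport
#' impairments, and returns both the session documents (one per dialect
#' file, ready for [writeSession()]) and the ground truth needed to
#' validate reconstruction: true unix time of every generated sample and
#' the full drop/reorder log per stream.
#'
#' @param config A [SimulationConfig-class].
#' @return List with `contents` (named list, filename -> document) and
#'   `truth` (list with per-stream `sampleTimes`, `signal`, scheduled
#'   packet table including dropped packets, and impairment log).
#' @examples
#' sim <- simulateSession(simulationConfig(duration = 5, seed = 7))
#' names(sim$contents)
#' @export
simulateSession <- function(config) {
  validObject(config)
  set.seed(config@seed)
  truth <- list(streams = list(), config = list(
    tdFs = config@tdFs, accelFs = config@accelFs,
    sessionStart = config@sessionStart, seed = config@seed))
  contents <- list()

  tdSpecs <- Filter(function(s) s@target == "td", config@signalSpecs)
  accSpecs <- Filter(function(s) s@target == "accel", config@signalSpecs)

  nTd <- round(config@duration * config@tdFs)
  tdTimes <- config@sessionStart + (seq_len(nTd) - 1) * (1000 / config@tdFs)
  tdSig <- .renderStreamSignals(tdSpecs, config@tdChannels, nTd,
                                config@tdFs, 0)

  if ("td" %in% config@streams) {
    st <- .simStream(tdTimes, tdSig, config@tdFs, config)
    contents[["RawDataTD.json"]] <- list(
      SchemaVersion = 1L, StreamType = "TimeDomain",
      Packets = .packetsToRecords(
        st$received, paste0("Ch", seq_len(config@tdChannels)),
        rateValue = .encodeSampleRate(config@tdFs)))
    truth$streams$td <- list(sampleTimes = tdTimes, signal = tdSig,
                             scheduled = st$scheduled, log = st$log)
  }

  if ("accel" %in% config@streams) {
    nAc <- round(config@duration * config@accelFs)
    acTimes <- config@sessionStart + (seq_len(nAc) - 1) *
      (1000 / config@accelFs)
    acSig <- .renderStreamSignals(accSpecs, 3L, nAc, config@accelFs, 0)
    st <- .simStream(acTimes, acSig, config@accelFs, config)
    contents[["RawDataAccel.json"]] <- list(
      SchemaVersion = 1L, StreamType = "Accelerometry",
      Packets = .packetsToRecords(st$received, c("X", "Y", "Z"),
                                  rateField = "SampleRateHz"))
    truth$streams$accel <- list(sampleTimes = acTimes, signal = acSig,
                                scheduled = st$scheduled, log = st$log)
  }

  if ("power" %in% config@streams && length(config@powerBands)) {
    cal <- amplifierCalibration(gainCode = config@gainCode)
    cfg <- config@fftConfig
    ch <- vapply(config@powerBands, function(b) b@tdChannel, integer(1))
    emu <- lapply(seq_along(config@powerBands), function(i)
      .bandPowerCore(tdSig[, ch[i]], cfg, config@powerBands[[i]], cal,
                     quantize = TRUE))
    endIdx <- emu[[1]]$endIndex
    pw <- do.call(cbind, lapply(emu, `[[`, "power"))
    pwTimes <- tdTimes[endIdx]
    hop <- computeHopAndOverlap(cfg)$hopSamples
    pwFs <- config@tdFs / hop
    st <- .simStream(pwTimes, pw, pwFs, config)
    contents[["RawDataPower.json"]] <- list(
      SchemaVersion = 1L, StreamType = "Power",
      Packets = .packetsToRecords(
        st$received, paste0("Band", seq_along(config@powerBands)),
        rateField = "SampleRateHz"))
    truth$streams$power <- list(sampleTimes = pwTimes, signal = pw,
                                scheduled = st$scheduled, log = st$log)
  }
  if (!"power" %in% names(truth$streams))
    contents[["RawDataPower.json"]] <- list(
      SchemaVersion = 1L, StreamType = "Power", Packets = list())
  for (f in c("RawDataTD.json", "RawDataAccel.json", "RawDataFFT.json",
              "AdaptiveLog.json"))
    if (is.null(contents[[f]]))
      contents[[f]] <- list(
        SchemaVersion = 1L,
        StreamType = c(RawDataTD.json = "TimeDomain",
                       RawDataAccel.json = "Accelerometry",
                       RawDataFFT.json = "FFT",
                       AdaptiveLog.json = "Adaptive")[[f]],
        Packets = list())

  contents[["DeviceSettings.json"]] <- list(
    SchemaVersion = 1L,
    Metadata = list(DeviceId = "SIM-0001",
                    SessionId = sprintf("Session%d", config@seed),
                    UtcOffsetMinutes = config@utcOffset),
    TimeDomainSettings = list(list(
      Time = config@sessionStart,
      Channels = lapply(seq_len(config@tdChannels), function(j) list(
        Channel = j, SampleRate = .encodeSampleRate(config@tdFs),
        GainCode = config@gainCode, HpfCode = 0L, LpfCode = 2L,
        Contacts = sprintf("+%d-%d", 2 * j, 2 * j - 2))))),
    FftConfig = list(Size = config@fftConfig@size,
                     IntervalSeconds = config@fftConfig@interval,
                     WindowLoad = config@fftConfig@windowLoad),
    PowerBands = lapply(seq_along(config@powerBands), function(i) {
      b <- config@powerBands[[i]]
      list(Band = i, LowerHz = b@fLo, UpperHz = b@fHi, GainG = b@gainG,
           TdChannel = b@tdChannel)
    }),
    AdaptiveConfig = list())

  contents[["StimLog.json"]] <- list(
    SchemaVersion = 1L,
    StimSettings = list(list(Time = config@sessionStart, Group = "A",
                             Contacts = "+1-2", AmplitudeMa = 2.0,
                             PulseWidthUs = 60L, RateHz = 130)))
  contents[["EventLog.json"]] <- list(
    SchemaVersion = 1L,
    Events = list(list(Time = config@sessionStart + 1000,
                       Type = "session", Payload = "start")))
  contents[["TimeSync.json"]] <- list(SchemaVersion = 1L, Records = list())
  contents[["ErrorLog.json"]] <- list(SchemaVersion = 1L, Records = list())
  contents[["DiagnosticsLog.json"]] <- list(SchemaVersion = 1L,
                                            Records = list())
  contents <- contents[.SESSION_FILES]
  list(contents = contents, truth = truth)
}

#' Write a simulated session to disk
#'
#' Serializes the 11 dialect JSON files plus a clearly marked ground-truth
#' sidecar (`_groundtruth.json`, not device data). With `malform`, the
#' trailing closing brackets of the selected files are omitted to exercise
#' JSON repair in the loader.
#'
#' @param folder output directory (created if absent).
#' @param contents,truth from [simulateSession()].
#' @param malform character vector of filenames to truncate (or TRUE for
#'   RawDataTD.json); default none.
#' @return The folder path, invisibly.
#' @export
writeSession <- function(folder, contents, truth = NULL, malform = NULL) {
  if (!dir.exists(folder) &&
      !dir.create(folder, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create ", folder, call. = FALSE)
  if (isTRUE(malform)) malform <- "RawDataTD.json"
  for (f in names(contents)) {
    txt <- jsonlite::toJSON(contents[[f]], auto_unbox = TRUE, digits = NA,
                            null = "null")
    if (f %in% malform) {
      # drop the final run of closing brackets/braces
      txt <- sub("[]}]+$", "", as.character(txt))
    }
    writeLines(as.character(txt), file.path(folder, f))
  }
  if (!is.null(truth)) {
    tr <- list(
      note = "SYNTHETIC ground truth sidecar; not device data",
      streams = lapply(truth$streams, function(s) list(
        sampleTimes = s$sampleTimes,
        dropped = s$log$creationIndex[s$log$event == "dropped"],
        swapped = s$log$creationIndex[s$log$event == "swapped"],
        packetTrueGenTime = s$scheduled$trueGenTime,
        packetNSamples = s$scheduled$nSamples)),
      config = truth$config)
    writeLines(as.character(jsonlite::toJSON(tr, auto_unbox = TRUE,
                                             digits = NA)),
               file.path(folder, "_groundtruth.json"))
  }
  invisible(folder)
}
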