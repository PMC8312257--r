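#' On-device FFT engine configuration
#'
#' Parameters of the device's short-time FFT engine. The device advertises
#' nominal transform sizes of 64, 256, or 1024 points but fills each window
#' with only 62, 250, or 1000 real samples respectively (the remainder is
#' zero-padded), and recomputes the transform every `interval` seconds.
#' The Hann "window load" setting (25, 50, or 100 percent) controls the
#' depth of the taper.
#'
#' @slot size integer, nominal FFT size: 64, 256 or 1024 points.
#' @slot interval numeric, seconds between successive transforms.
#' @slot windowLoad numeric, Hann window load in percent: 25, 50 or 100.
#' @slot fs numeric, sampling rate of the time-domain input in Hz.
#' @export
setClass("FFTConfig", representation(
  size = "integer", interval = "numeric", windowLoad = "numeric",
  fs = "numeric"
))

setValidity("FFTConfig", function(object) {
  msg <- character()
  if (!object@size %in% c(64L, 256L, 1024L))
    msg <- c(msg, "size must be one of 64, 256, 1024")
  if (length(object@interval) != 1 || object@interval <= 0)
    msg <- c(msg, "interval must be a positive number of seconds")
  if (!object@windowLoad %in% c(25, 50, 100))
    msg <- c(msg, "windowLoad must be 25, 50 or 100 (percent)")
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be a positive sampling rate in Hz")
  if (length(msg)) msg else TRUE
})

#' Create an FFT engine configuration
#'
#' @param size nominal FFT size (64, 256 or 1024 points).
#' @param interval seconds between successive transforms.
#' @param windowLoad Hann window load in percent (25, 50 or 100).
#' @param fs time-domain sampling rate in Hz.
#' @return An [FFTConfig-class] object.
#' @examples
#' cfg <- fftConfig(size = 1024, interval = 0.1, windowLoad = 100, fs = 500)
#' fftSizeActual(cfg)
#' @export
fftConfig <- function(size = 256, interval = 0.1, windowLoad = 100, fs = 250) {
  new("FFTConfig", size = as.integer(size), interval = as.numeric(interval),
      windowLoad = as.numeric(windowLoad), fs = as.numeric(fs))
}

#' Actual number of real samples per transform window
#'
#' The device fills a nominal 64/256/1024-point transform with only
#' 62/250/1000 real samples; the rest is zero-padded.
#'
#' @param cfg An [FFTConfig-class] object (or a nominal size).
#' @return Integer count of real samples per window.
#' @export
fftSizeActual <- function(cfg) {
  size <- if (is(cfg, "FFTConfig")) cfg@size else as.integer(cfg)
  out <- c("64" = 62L, "256" = 250L, "1024" = 1000L)[as.character(size)]
  if (is.na(out)) stop("unknown FFT size: ", size, call. = FALSE)
  unname(out)
}

setMethod("show", "FFTConfig", function(object) {
  cat(sprintf(
    "FFTConfig: %d points (%d actual), interval %g s, window load %g%%, fs %g Hz\n",
    object@size, fftSizeActual(object), object@interval, object@windowLoad,
    object@fs))
})

#' Power band definition
#'
#' One on-device power channel: the sum of squared single-sided FFT
#' amplitudes over all frequency bins whose centers fall inside
#' `[fLo, fHi]`, multiplied by the gain factor G (device default 2).
#'
#' @slot fLo,fHi numeric band edges in Hz.
#' @slot gainG numeric gain factor applied to the summed squared amplitudes.
#' @slot tdChannel integer, index of the time-domain channel feeding the band.
#' @export
setClass("PowerBand", representation(
  fLo = "numeric", fHi = "numeric", gainG = "numeric", tdChannel = "integer"
))

setValidity("PowerBand", function(object) {
  msg <- character()
  if (object@fLo < 0 || object@fHi <= object@fLo)
    msg <- c(msg, "band edges must satisfy 0 <= fLo < fHi")
  if (object@gainG <= 0) msg <- c(msg, "gainG must be positive")
  if (object@tdChannel < 1L) msg <- c(msg, "tdChannel must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a power band
#'
#' @param fLo,fHi band edges in Hz.
#' @param gainG gain factor G (device default 2).
#' @param tdChannel time-domain channel index feeding the band.
#' @return A [PowerBand-class] object.
#' @export
powerBand <- function(fLo, fHi, gainG = 2, tdChannel = 1L) {
  new("PowerBand", fLo = as.numeric(fLo), fHi = as.numeric(fHi),
      gainG = as.numeric(gainG), tdChannel = as.integer(tdChannel))
}

setMethod("show", "PowerBand", function(object) {
  cat(sprintf("PowerBand: %.2f-%.2f Hz, G = %g, TD channel %d\n",
              object@fLo, object@fHi, object@gainG, object@tdChannel))
})

#' Amplifier calibration for millivolt to device-unit conversion
#'
#' Constants of the conversion from millivolts to internal fixed-point
#' device units: the per-channel amplifier gain trim code and the on-device
#' fixed-point constant 48,644.8683623726.
#'
#' @slot gainCode integer amplifier gain trim code (per sense channel).
#' @slot fpv on-device fixed-point value constant.
#' @export
setClass("AmplifierCalibration", representation(
  gainCode = "numeric", fpv = "numeric"
))

setValidity("AmplifierCalibration", function(object) {
  if (object@gainCode <= 0) "gainCode must be positive" else TRUE
})

#' Create an amplifier calibration
#'
#' @param gainCode amplifier gain trim code (positive; typical value 255).
#' @param fpv fixed-point constant; the device value is the default.
#' @return An [AmplifierCalibration-class] object.
#' @export
amplifierCalibration <- function(gainCode = 255, fpv = 48644.8683623726) {
  new("AmplifierCalibration", gainCode = as.numeric(gainCode),
      fpv = as.numeric(fpv))
}

#' Synthetic signal component specification
#'
#' One additive component of a simulated stream. Kinds: `sine` (steady
#' sinusoid), `burst_sine` (sinusoid gated on for `burstOn` s, off for
#' `burstOff` s), `one_over_f_noise` (pink noise with RMS = amplitude),
#' `accel_motion` (smoothed random motion for accelerometer axes).
#' `target` selects the stream ("td" or "accel"); `channel` the channel
#' index within it (accel axes: 1 = X, 2 = Y, 3 = Z).
#'
#' @slot kind character, one of the four kinds above.
#' @slot amplitude numeric; millivolts for TD, g for accelerometry (RMS for
#'   noise kinds, peak for sinusoids).
#' @slot frequency numeric Hz (sinusoid kinds).
#' @slot burstOn,burstOff numeric seconds (burst_sine only).
#' @slot channel integer channel index.
#' @slot target character, "td" or "accel".
#' @export
setClass("SignalSpec", representation(
  kind = "character", amplitude = "numeric", frequency = "numeric",
  burstOn = "numeric", burstOff = "numeric", channel = "integer",
  target = "character"
))

setValidity("SignalSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("sine", "burst_sine", "one_over_f_noise",
                          "accel_motion"))
    msg <- c(msg, "unknown signal kind")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (!object@target %in% c("td", "accel"))
    msg <- c(msg, "target must be 'td' or 'accel'")
  if (length(msg)) msg else TRUE
})

#' Create a signal component specification
#'
#' @param kind one of "sine", "burst_sine", "one_over_f_noise",
#'   "accel_motion".
#' @param amplitude amplitude (mV for TD, g for accel).
#' @param frequency frequency in Hz (sinusoid kinds).
#' @param burstOn,burstOff on/off durations in seconds for burst_sine.
#' @param channel channel index within the target stream.
#' @param target "td" or "accel".
#' @return A [SignalSpec-class] object.
#' @export
signalSpec <- function(kind, amplitude, frequency = 0, burstOn = 0,
                       burstOff = 0, channel = 1L, target = "td") {
  if (kind == "accel_motion") target <- "accel"
  new("SignalSpec", kind = kind, amplitude = as.numeric(amplitude),
      frequency = as.numeric(frequency), burstOn = as.numeric(burstOn),
      burstOff = as.numeric(burstOff), channel = as.integer(channel),
      target = target)
}

#' Clock and rejection-rule constants
#'
#' Fixed constants of the packet timing model: the 16-bit hardware tick
#' counter advances in 1e-4 s units and rolls over every 2^16 ticks
#' (~6.5535 s); the firmware timestamp counts whole seconds since
#' 2000-03-01T00:00:00Z; the per-stream packet sequence counter rolls over
#' at 256. Remaining slots are packet-rejection and chunking thresholds.
#'
#' @slot tickSeconds seconds per hardware tick (1e-4).
#' @slot tickModulus tick counter rollover (2^16).
#' @slot timestampEpochUnix unix seconds of the firmware timestamp epoch.
#' @slot seqModulus sequence counter rollover (256).
#' @slot shortGapThreshold seconds; gaps below this (by timestamp) can be
#'   bridged unambiguously within one tick-counter cycle.
#' @slot outlierWindow seconds; packets with timestamp further than this
#'   from the stream median are rejected (24 h).
#' @slot backwardLimit seconds; maximum tolerated backward step of
#'   PacketGenTime relative to the previous kept packet (0.5 s).
#' @slot disagreementLimit seconds; maximum tolerated disagreement between
#'   elapsed PacketGenTime and elapsed timestamp (2 s).
#' @slot tickToleranceTicks ticks; slack in the chunk-continuity check on
#'   elapsed systemTick (10 ticks = 1 ms).
#' @export
setClass("ClockConstants", representation(
  tickSeconds = "numeric", tickModulus = "numeric",
  timestampEpochUnix = "numeric", seqModulus = "numeric",
  shortGapThreshold = "numeric", outlierWindow = "numeric",
  backwardLimit = "numeric", disagreementLimit = "numeric",
  tickToleranceTicks = "numeric"
))

setValidity("ClockConstants", function(object) {
  vals <- c(object@tickSeconds, object@tickModulus, object@timestampEpochUnix,
            object@seqModulus, object@shortGapThreshold, object@outlierWindow,
            object@backwardLimit, object@disagreementLimit,
            object@tickToleranceTicks)
  if (any(vals <= 0)) "all clock constants must be positive" else TRUE
})

#' Create the clock-constants object
#'
#' @param shortGapThreshold,outlierWindow,backwardLimit,disagreementLimit,tickToleranceTicks
#'   override the default thresholds (all in seconds except the last,
#'   in ticks).
#' @return A [ClockConstants-class] object.
#' @export
clockConstants <- function(shortGapThreshold = 6, outlierWindow = 86400,
                           backwardLimit = 0.5, disagreementLimit = 2,
                           tickToleranceTicks = 10) {
  new("ClockConstants", tickSeconds = 1e-4, tickModulus = 65536,
      timestampEpochUnix = .TIMESTAMP_EPOCH_UNIX, seqModulus = 256,
      shortGapThreshold = shortGapThreshold, outlierWindow = outlierWindow,
      backwardLimit = backwardLimit, disagreementLimit = disagreementLimit,
      tickToleranceTicks = tickToleranceTicks)
}

#' Maximum elapsed time representable in one tick-counter cycle
#'
#' The 16-bit tick counter holds values 0..65535 in units of 1e-4 s, so the
#' largest unambiguous elapsed time within one cycle is 6.5535 s.
#'
#' @param constants A [ClockConstants-class] object.
#' @return Seconds.
#' @export
tickCycleSeconds <- function(constants = clockConstants()) {
  (constants@tickModulus - 1) * constants@tickSeconds
}

#' Session simulation configuration
#'
#' Everything needed to generate one synthetic streaming session: signal
#' content, stream rates, packetization, transport impairments, and the
#' on-device spectral engine settings.
#'
#' @slot duration session length in seconds.
#' @slot tdFs time-domain sampling rate, one of 250, 500, 1000 Hz.
#' @slot tdChannels number of time-domain channels (1-4; at most 2 at
#'   1000 Hz).
#' @slot accelFs accelerometer rate, one of 4, 8, 16, 32, 64 Hz.
#' @slot packetSizeRange integer [min, max] samples per packet.
#' @slot dropProbability per-packet loss probability.
#' @slot reorderProbability per-adjacent-pair swap probability.
#' @slot pgtJitterSd SD in ms of Gaussian noise on PacketGenTime.
#' @slot systemTickDriftPpm rate error of the hardware tick counter
#'   relative to true time, in parts per million.
#' @slot sessionStart unix milliseconds of the first sample.
#' @slot utcOffset minutes offset for local-time presentation.
#' @slot seed integer RNG seed.
#' @slot signalSpecs list of [SignalSpec-class] objects.
#' @slot fftConfig [FFTConfig-class] for the emulated power engine.
#' @slot powerBands list of [PowerBand-class] (at most 8).
#' @slot gainCode amplifier gain trim code used by the emulated engine.
#' @slot streams character vector of enabled streams among
#'   "td", "accel", "power", "fft", "adaptive".
#' @export
setClass("SimulationConfig", representation(
  duration = "numeric", tdFs = "numeric", tdChannels = "integer",
  accelFs = "numeric", packetSizeRange = "integer",
  dropProbability = "numeric", reorderProbability = "numeric",
  pgtJitterSd = "numeric", systemTickDriftPpm = "numeric",
  sessionStart = "numeric", utcOffset = "numeric", seed = "integer",
  signalSpecs = "list", fftConfig = "FFTConfig", powerBands = "list",
  gainCode = "numeric", streams = "character"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!object@tdFs %in% c(250, 500, 1000))
    msg <- c(msg, "tdFs must be 250, 500 or 1000 Hz")
  if (object@tdChannels < 1L || object@tdChannels > 4L)
    msg <- c(msg, "tdChannels must be between 1 and 4")
  if (object@tdFs == 1000 && object@tdChannels > 2L)
    msg <- c(msg, "at most 2 channels may be sampled at 1000 Hz")
  if (!object@accelFs %in% c(4, 8, 16, 32, 64))
    msg <- c(msg, "accelFs must be one of 4, 8, 16, 32, 64 Hz")
  if (length(object@packetSizeRange) != 2 ||
      object@packetSizeRange[1] < 1L ||
      object@packetSizeRange[1] > object@packetSizeRange[2])
    msg <- c(msg, "packetSizeRange must be [min, max] with 1 <= min <= max")
  for (p in c("dropProbability", "reorderProbability")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, paste(p, "must lie in [0, 1]"))
  }
  if (object@pgtJitterSd < 0) msg <- c(msg, "pgtJitterSd must be >= 0")
  if (length(object@powerBands) > 8)
    msg <- c(msg, "at most 8 power bands may be streamed")
  for (s in object@signalSpecs) {
    if (s@target == "td" && s@kind %in% c("sine", "burst_sine") &&
        s@frequency >= object@tdFs / 2)
      msg <- c(msg, "signal frequency must be below tdFs/2")
    if (s@target == "td" && s@channel > object@tdChannels)
      msg <- c(msg, "signalSpec channel exceeds tdChannels")
  }
  if (!all(object@streams %in% c("td", "accel", "power", "fft", "adaptive")))
    msg <- c(msg, "unknown stream name in streams")
  if (length(msg)) msg else TRUE
})

#' Create a session simulation configuration
#'
#' Defaults describe a bench-style recording: two time-domain channels at
#' 250 Hz carrying a 25 uV 20 Hz sinusoid over pink background noise,
#' 64 Hz three-axis accelerometry with smooth motion, one alpha-band power
#' channel from the emulated FFT engine (256-point transform every 0.1 s,
#' 100% window load), mild transport impairment (2% packet loss, 0.5%
#' adjacent reordering, 15 ms PacketGenTime jitter) and an 80 ppm hardware
#' tick drift.
#'
#' @param duration,tdFs,tdChannels,accelFs,packetSizeRange,dropProbability,reorderProbability,pgtJitterSd,systemTickDriftPpm,sessionStart,utcOffset,seed,signalSpecs,fftConfig,powerBands,gainCode,streams
#'   see [SimulationConfig-class].
#' @return A validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(duration = 60, tdFs = 250, tdChannels = 2,
                             accelFs = 64, packetSizeRange = c(25, 125),
                             dropProbability = 0.02,
                             reorderProbability = 0.005,
                             pgtJitterSd = 15, systemTickDriftPpm = 80,
                             sessionStart = 1.6e12, utcOffset = 0,
                             seed = 1L, signalSpecs = NULL,
                             fftConfig = NULL, powerBands = NULL,
                             gainCode = 255, streams = c("td", "accel",
                                                         "power")) {
  if (is.null(signalSpecs)) {
    signalSpecs <- list(
      signalSpec("sine", amplitude = 0.025, frequency = 20, channel = 1L),
      signalSpec("one_over_f_noise", amplitude = 0.01, channel = 1L),
      signalSpec("one_over_f_noise", amplitude = 0.01, channel = 2L),
      signalSpec("accel_motion", amplitude = 0.2, channel = 1L),
      signalSpec("accel_motion", amplitude = 0.2, channel = 2L),
      signalSpec("accel_motion", amplitude = 0.2, channel = 3L)
    )
  }
  if (is.null(fftConfig))
    fftConfig <- rcstream::fftConfig(size = 256, interval = 0.1,
                                     windowLoad = 100, fs = tdFs)
  if (is.null(powerBands)) powerBands <- list(powerBand(8.05, 12.20))
  signalSpecs <- signalSpecs[vapply(signalSpecs, function(s) {
    s@target == "td" || "accel" %in% streams
  }, logical(1))]
  keep <- vapply(signalSpecs, function(s) {
    !(s@target == "td" && s@channel > tdChannels)
  }, logical(1))
  new("SimulationConfig", duration = as.numeric(duration),
      tdFs = as.numeric(tdFs), tdChannels = as.integer(tdChannels),
      accelFs = as.numeric(accelFs),
      packetSizeRange = as.integer(packetSizeRange),
      dropProbability = as.numeric(dropProbability),
      reorderProbability = as.numeric(reorderProbability),
      pgtJitterSd = as.numeric(pgtJitterSd),
      systemTickDriftPpm = as.numeric(systemTickDriftPpm),
      sessionStart = as.numeric(sessionStart),
      utcOffset = as.numeric(utcOffset), seed = as.integer(seed),
      signalSpecs = signalSpecs[keep], fftConfig = fftConfig,
      powerBands = powerBands, gainCode = as.numeric(gainCode),
      streams = streams)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %g s, TD %d ch @ %g Hz, accel @ %g Hz\n",
    object@duration, object@tdChannels, object@tdFs, object@accelFs))
  cat(sprintf(
    "  impairments: drop %.3g, reorder %.3g, PGT jitter %.3g ms, tick drift %g ppm\n",
    object@dropProbability, object@reorderProbability, object@pgtJitterSd,
    object@systemTickDriftPpm))
  cat(sprintf("  streams: %s; %d power band(s); seed %d\n",
              paste(object@streams, collapse = ", "),
              length(object@powerBands), object@seed))
})

#' One stream's samples on its reconstructed time base
#'
#' Result of per-stream time reconstruction: every retained sample with its
#' DerivedTime (unix milliseconds on the uniform 1/fs grid anchored by the
#' first chunk), provenance (which continuity chunk it came from), the
#' chunk table, and the packet-rejection log.
#'
#' @slot derivedTime numeric vector of unix milliseconds, strictly
#'   increasing, on the grid `tRef + k * 1000/fs`.
#' @slot samples numeric matrix, one row per derived time, one column per
#'   channel.
#' @slot fs numeric sampling rate in Hz.
#' @slot tRef numeric, unix ms of the grid origin (first derived time of
#'   the first chunk).
#' @slot chunks data.frame describing each continuity chunk (packet range,
#'   sample count, gap class, anchor).
#' @slot provenance integer vector of chunk ids, one per sample.
#' @slot rejectionLog data.frame of rejected packets and the rule that
#'   removed each.
#' @export
setClass("DerivedTimeSeries", representation(
  derivedTime = "numeric", samples = "matrix", fs = "numeric",
  tRef = "numeric", chunks = "data.frame", provenance = "integer",
  rejectionLog = "data.frame"
))

setValidity("DerivedTimeSeries", function(object) {
  msg <- character()
  n <- length(object@derivedTime)
  if (n > 0 && nrow(object@samples) != n)
    msg <- c(msg, "samples must have one row per derived time")
  if (n > 1 && any(diff(object@derivedTime) <= 0))
    msg <- c(msg, "derivedTime must be strictly increasing")
  if (n > 0 && length(object@provenance) != n)
    msg <- c(msg, "provenance must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' @describeIn DerivedTimeSeries-class number of samples
#' @param x,object a DerivedTimeSeries.
#' @export
setMethod("length", "DerivedTimeSeries", function(x) length(x@derivedTime))

#' Accessors for DerivedTimeSeries
#'
#' @param x A [DerivedTimeSeries-class].
#' @return `derivedTime()` the time vector; `streamSamples()` the sample
#'   matrix; `streamFs()` the rate; `streamChunks()` the chunk table.
#' @name DerivedTimeSeries-accessors
NULL

#' @rdname DerivedTimeSeries-accessors
#' @export
derivedTime <- function(x) x@derivedTime

#' @rdname DerivedTimeSeries-accessors
#' @export
streamSamples <- function(x) x@samples

#' @rdname DerivedTimeSeries-accessors
#' @export
streamFs <- function(x) x@fs

#' @rdname DerivedTimeSeries-accessors
#' @export
streamChunks <- function(x) x@chunks

setMethod("show", "DerivedTimeSeries", function(object) {
  n <- length(object@derivedTime)
  cat(sprintf(
    "DerivedTimeSeries: %d samples x %d channel(s) @ %g Hz, %d chunk(s)\n",
    n, ncol(object@samples), object@fs, nrow(object@chunks)))
  if (n > 0)
    cat(sprintf("  span: %.3f .. %.3f s (unix); %d packet(s) rejected\n",
                object@derivedTime[1] / 1000, object@derivedTime[n] / 1000,
                nrow(object@rejectionLog)))
})

#' Compact per-session store of reconstructed streams
#'
#' Holds each stream's [DerivedTimeSeries-class] plus decoded settings,
#' events and metadata. Persisted per stream as columnar Parquet with JSON
#' settings via [saveStore()] / [loadStore()].
#'
#' @slot streams named list of [DerivedTimeSeries-class] objects.
#' @slot settings list with decoded device settings (TD channel settings
#'   timeline, FFT config, power bands, stimulation timeline).
#' @slot events data.frame of event markers.
#' @slot metadata list (device id, session id, UTC offset, ...).
#' @export
setClass("RCSStore", representation(
  streams = "list", settings = "list", events = "data.frame",
  metadata = "list"
))

#' @describeIn RCSStore-class stream names present in the store
#' @param x,object an RCSStore.
#' @export
setMethod("names", "RCSStore", function(x) names(x@streams))

#' Extract one stream from a store
#'
#' @param store An [RCSStore-class].
#' @param name Stream name ("td", "accel", "power", ...).
#' @return A [DerivedTimeSeries-class].
#' @export
storeStream <- function(store, name) {
  if (!name %in% names(store@streams))
    stop("stream not in store: ", name, call. = FALSE)
  store@streams[[name]]
}

#' @rdname storeStream
#' @export
storeSettings <- function(store) store@settings

#' @rdname storeStream
#' @export
storeMetadata <- function(store) store@metadata

#' @rdname storeStream
#' @export
storeEvents <- function(store) store@events

setMethod("show", "RCSStore", function(object) {
  cat(sprintf("RCSStore: %d stream(s) [%s], %d event(s)\n",
              length(object@streams),
              paste(names(object@streams), collapse = ", "),
              nrow(object@events)))
  for (nm in names(object@streams)) {
    s <- object@streams[[nm]]
    cat(sprintf("  %-6s %d samples @ %g Hz\n", nm, length(s@derivedTime),
                s@fs))
  }
})
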