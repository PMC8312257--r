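# Shared fixtures: clean packet streams built directly (for reconstruction
# unit tests) and small simulation configs.

# A clean, timing-consistent packet stream: one packet per element of
# nSamples, timing fields describing each packet's last sample.
makePackets <- function(nSamples, fs = 250, start = 1.6e12, seq0 = 0L,
                        tickDriftPpm = 0) {
  ends <- cumsum(nSamples)
  tLast <- start + (ends - 1) * 1000 / fs
  elapsedSec <- (tLast - start) / 1000
  data.frame(
    systemTick = as.integer(floor(elapsedSec * 1e4 *
                                    (1 + tickDriftPpm * 1e-6)) %% 65536),
    timestamp = floor(tLast / 1000 - 951868800),
    packetGenTime = round(tLast),
    packetRxUnixTime = round(tLast + 50),
    dataTypeSequence = as.integer((seq0 + seq_along(nSamples) - 1L) %% 256),
    sampleRate = fs,
    nSamples = as.integer(nSamples),
    samples = I(lapply(nSamples, function(k)
      matrix(seq_len(k), k, 1, dimnames = list(NULL, "Ch1")))),
    trueGenTime = tLast
  )
}

# Small clean session config (no transport impairment) for round trips.
cleanConfig <- function(duration = 8, seed = 42L, ...) {
  simulationConfig(duration = duration, seed = seed, dropProbability = 0,
                   reorderProbability = 0, pgtJitterSd = 0,
                   systemTickDriftPpm = 0, ...)
}

# Build a minimal DerivedTimeSeries by hand (harmonization tests).
mkSeries <- function(times, fs, vals = NULL, tRef = times[1],
                     channels = "ch1") {
  n <- length(times)
  m <- matrix(if (is.null(vals)) as.numeric(seq_len(n)) else vals, n,
              length(channels))
  colnames(m) <- channels
  new("DerivedTimeSeries", derivedTime = times, samples = m, fs = fs,
      tRef = tRef,
      chunks = data.frame(startPacket = 1L, endPacket = 1L,
                          nSamples = n, fs = fs),
      provenance = rep(1L, n),
      rejectionLog = data.frame(index = integer(0), rule = character(0)))
}
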