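#' On/off-device power agreement experiment
#'
#' End-to-end validation run: simulate a bench-style session whose
#' time-domain channel carries an amplitude-modulated 10 Hz sinusoid over
#' pink noise while the stream-side engine emits the integer-quantized
#' on-device band-power series; write the session to disk, reload and
#' reconstruct it, recompute the band power off-device from the stored
#' time-domain samples with identical FFT settings, and compare the two
#' series over time-matched windows.
#'
#' @param seed RNG seed for the simulated session.
#' @param duration session length in seconds (default 300).
#' @param tdFs time-domain rate in Hz (default 500).
#' @param fftSize nominal FFT size (default 1024).
#' @param intervalS FFT interval in seconds (default 0.1).
#' @param windowLoad Hann window load percent (default 100).
#' @param band band edges in Hz (default 8.05-12.20).
#' @return List: `rmse`, `nrmse`, `pctDiff` (see [comparePowerSeries()])
#'   and `nWindows` (matched windows compared).
#' @export
powerAgreementExperiment <- function(seed = 1L, duration = 300,
                                     tdFs = 500, fftSize = 1024,
                                     intervalS = 0.1, windowLoad = 100,
                                     band = c(8.05, 12.20)) {
  cfg <- simulationConfig(
    duration = duration, tdFs = tdFs, tdChannels = 1,
    dropProbability = 0, reorderProbability = 0, pgtJitterSd = 0,
    systemTickDriftPpm = 0, seed = seed,
    signalSpecs = list(
      signalSpec("burst_sine", amplitude = 0.05, frequency = 10,
                 burstOn = 5, burstOff = 5, channel = 1L),
      signalSpec("one_over_f_noise", amplitude = 0.02, channel = 1L)),
    fftConfig = fftConfig(fftSize, intervalS, windowLoad, fs = tdFs),
    powerBands = list(powerBand(band[1], band[2])),
    streams = c("td", "power"))
  sim <- simulateSession(cfg)
  folder <- tempfile("rcs-session-")
  on.exit(unlink(folder, recursive = TRUE), add = TRUE)
  writeSession(folder, sim$contents)
  store <- processSession(folder)
  tab <- createCombinedTable(store, include = "td")
  off <- calculateNewPower(tab, 1, cfg@fftConfig, cfg@powerBands[[1]])
  onS <- storeStream(store, "power")
  on <- data.frame(time = derivedTime(onS),
                   power = streamSamples(onS)[, 1])
  m <- matchPowerSeries(off, on, tolMs = intervalS * 500)
  if (length(m$offIdx) < 10) stop("too few matched windows", call. = FALSE)
  met <- comparePowerSeries(on$power[m$onIdx], off$power[m$offIdx])
  c(met, list(nWindows = length(m$offIdx)))
}

#' Two-device drift experiment
#'
#' Simulates two independent devices recording the same deterministic
#' motion on their accelerometer X axis (plus device-specific noise,
#' impairments, and opposite hardware-tick drifts), reconstructs each
#' independently, and measures the cross-correlation lag between the two
#' reconstructed motion signals at the start and end of the recording. A
#' faithful time base keeps the two lags equal: any accumulated drift
#' would separate them.
#'
#' @param seed base RNG seed (device 2 uses seed + 1).
#' @param duration recording length in seconds (default 1800).
#' @param accelFs accelerometer rate in Hz (default 64).
#' @param windowS length of the comparison windows at either end, seconds.
#' @return List: `lagStartS`, `lagEndS` (cross-correlation peak lags in
#'   seconds), `lagDiffS` (absolute difference), `samplePeriodS`.
#' @export
twoDeviceDriftExperiment <- function(seed = 1L, duration = 1800,
                                     accelFs = 64, windowS = 60) {
  simDevice <- function(sd, drift) {
    cfg <- simulationConfig(
      duration = duration, tdFs = 250, tdChannels = 1, accelFs = accelFs,
      dropProbability = 0.02, reorderProbability = 0, pgtJitterSd = 20,
      systemTickDriftPpm = drift, seed = sd,
      signalSpecs = list(
        signalSpec("burst_sine", amplitude = 0.5, frequency = 1.5,
                   burstOn = 2, burstOff = 3, channel = 1L,
                   target = "accel"),
        signalSpec("accel_motion", amplitude = 0.05, channel = 2L)),
      streams = "accel")
    sim <- simulateSession(cfg)
    reconstructStream(parseStreamDocument(sim$contents$RawDataAccel.json))
  }
  s1 <- simDevice(seed, 80)
  s2 <- simDevice(seed + 1L, -80)
  step <- 1000 / accelFs
  lagAt <- function(t0, t1) {
    g <- seq(t0, t1, by = step)
    fill <- function(s) {
      v <- numeric(length(g))
      sel <- s@derivedTime >= t0 - step / 2 & s@derivedTime <= t1 + step / 2
      k <- round((s@derivedTime[sel] - t0) / step) + 1
      inb <- k >= 1 & k <= length(g)
      v[k[inb]] <- s@samples[sel, 1][inb]
      v
    }
    cc <- stats::ccf(fill(s1), fill(s2), lag.max = 2 * accelFs,
                     plot = FALSE)
    cc$lag[which.max(cc$acf)] * step / 1000
  }
  t0 <- max(s1@derivedTime[1], s2@derivedTime[1])
  t1 <- min(max(s1@derivedTime), max(s2@derivedTime))
  lagStart <- lagAt(t0, t0 + windowS * 1000)
  lagEnd <- lagAt(t1 - windowS * 1000, t1)
  list(lagStartS = lagStart, lagEndS = lagEnd,
       lagDiffS = abs(lagEnd - lagStart), samplePeriodS = step / 1000)
}
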