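#' Convert millivolts to internal device units
#'
#' Removes the offset voltage (mean over the full input) and scales to the
#' device's fixed-point units:
#' `rcs = (s - mean(s)) * (250 * gainCode / 255) * (fpv / 1000) / 1.2`.
#'
#' @param signalMv numeric vector in millivolts.
#' @param cal An [AmplifierCalibration-class].
#' @return Numeric vector in device (RCS) units.
#' @examples
#' x <- c(1, -1)  # zero-mean 1 mV
#' mvToDeviceUnits(x, amplifierCalibration(gainCode = 255))[1]  # 10134.35
#' @export
mvToDeviceUnits <- function(signalMv, cal = amplifierCalibration()) {
  if (!length(signalMv)) stop("empty signal", call. = FALSE)
  if (cal@gainCode <= 0)
    stop("calibration error: gainCode must be positive", call. = FALSE)
  (signalMv - mean(signalMv)) * (250 * cal@gainCode / 255) *
    (cal@fpv / 1000) / 1.2
}

#' Window hop and overlap of the running FFT
#'
#' The engine recomputes its transform every `interval` seconds, so
#' consecutive windows of `fftSizeActual` real samples overlap by
#' `1 - fs * interval / fftSizeActual`. A negative overlap (windows that
#' skip samples) is permitted and flagged.
#'
#' @param cfg An [FFTConfig-class].
#' @return List with `hopSamples` (integer), `overlap` (fraction) and
#'   `skips` (logical, TRUE when overlap < 0).
#' @examples
#' computeHopAndOverlap(fftConfig(256, 0.1, 100, fs = 500))  # overlap 0.8
#' @export
computeHopAndOverlap <- function(cfg) {
  validObject(cfg)
  if (cfg@interval <= 0)
    stop("configuration error: fft interval must be positive", call. = FALSE)
  actual <- fftSizeActual(cfg)
  hop <- as.integer(round(cfg@fs * cfg@interval))
  overlap <- 1 - (cfg@fs * cfg@interval) / actual
  list(hopSamples = hop, overlap = overlap, skips = overlap < 0)
}

#' Device Hann window with window-load setting
#'
#' The full-load window over `L = N + 1` points is
#' `w(n) = 0.5 * (1 - cos(2*pi*n/N))`, `0 <= n <= N`, with
#' `L = fftSizeActual`. Reduced loads (25%, 50%) blend linearly toward a
#' flat window: `w_l = (1 - l/100) + (l/100) * w_100`, reproducing the
#' shallower taper the device applies at reduced load.
#'
#' @param cfg An [FFTConfig-class]; `windowLoad` selects 25, 50 or 100.
#' @return Numeric weight vector of length `fftSizeActual(cfg)`.
#' @export
hannWindow <- function(cfg) {
  if (!cfg@windowLoad %in% c(25, 50, 100))
    stop("configuration error: window load must be 25, 50 or 100",
         call. = FALSE)
  L <- fftSizeActual(cfg)
  N <- L - 1
  w100 <- 0.5 * (1 - cos(2 * pi * (0:N) / N))
  l <- cfg@windowLoad / 100
  (1 - l) + l * w100
}

#' Frequency bins inside a power band
#'
#' Single-sided bins have center frequencies `k * fs / size` for
#' `k = 0 .. size/2`. A bin belongs to the band when its center lies in
#' `[fLo, fHi]`, inclusive at both edges.
#'
#' @param band A [PowerBand-class].
#' @param cfg An [FFTConfig-class].
#' @return Integer vector of bin indices `k` (0-based, DC = 0).
#' @examples
#' bandBinIndices(powerBand(8.05, 12.20), fftConfig(1024, 0.1, 100, 500))
#' @export
bandBinIndices <- function(band, cfg) {
  if (band@fLo < 0 || band@fHi > cfg@fs / 2)
    stop("configuration error: band must lie within [0, fs/2]",
         call. = FALSE)
  k <- 0:(cfg@size / 2)
  centers <- k * cfg@fs / cfg@size
  keep <- centers >= band@fLo & centers <= band@fHi
  if (!any(keep)) {
    near <- k[order(abs(centers - (band@fLo + band@fHi) / 2))][1:2]
    stop(sprintf(
      "configuration error: no bin centers inside [%g, %g] Hz; nearest bins %s",
      band@fLo, band@fHi, paste(sort(near), collapse = ", ")), call. = FALSE)
  }
  k[keep]
}

#' Short-time single-sided FFT amplitudes, device style
#'
#' Slides a window of `fftSizeActual` consecutive samples forward by the
#' hop implied by the FFT interval, applies the device Hann window,
#' zero-pads to the nominal size, and returns single-sided amplitudes
#' `|X(k)| / size`, doubled for bins strictly between DC and Nyquist.
#' Each window is stamped with the index of its last sample.
#'
#' @param signalRcs numeric vector in device units.
#' @param cfg An [FFTConfig-class].
#' @return List with `endIndex` (last-sample index per window) and
#'   `amplitude` (matrix, windows x bins, `size/2 + 1` columns).
#' @export
shortTimeFFTAmplitude <- function(signalRcs, cfg) {
  actual <- fftSizeActual(cfg)
  n <- length(signalRcs)
  if (n < actual) {
    warning("signal shorter than one FFT window; empty result")
    return(list(endIndex = integer(0),
                amplitude = matrix(0, 0, cfg@size / 2 + 1)))
  }
  hop <- computeHopAndOverlap(cfg)$hopSamples
  starts <- seq.int(1L, n - actual + 1L, by = hop)
  w <- hannWindow(cfg)
  # windows as columns: actual x nWindows, tapered then zero-padded
  idx <- outer(0:(actual - 1L), starts, "+")
  wins <- matrix(signalRcs[idx], nrow = actual) * w
  padded <- rbind(wins, matrix(0, cfg@size - actual, ncol(wins)))
  X <- mvfft(padded)
  half <- cfg@size / 2
  amp <- Mod(X[1:(half + 1), , drop = FALSE]) / cfg@size
  if (half > 1) amp[2:half, ] <- amp[2:half, ] * 2
  list(endIndex = as.integer(starts + actual - 1L), amplitude = t(amp))
}

# Shared band-power chain: mV signal -> device units -> windowed FFT ->
# gain-scaled band power. Used identically by the off-device recomputation
# and the simulator's stream-side engine so the two are arithmetically one.
# `removeOffset = FALSE` lets callers pre-convert the signal.
.bandPowerCore <- function(signalMv, cfg, band, cal, quantize = FALSE) {
  rcs <- mvToDeviceUnits(signalMv, cal)
  stft <- shortTimeFFTAmplitude(rcs, cfg)
  bins <- bandBinIndices(band, cfg) + 1L  # to 1-based columns
  power <- band@gainG *
    rowSums(stft$amplitude[, bins, drop = FALSE]^2)
  if (quantize) power <- round(power)
  list(endIndex = stft$endIndex, power = power)
}

#' Recompute a device band-power series off-device
#'
#' Runs the full device-equivalent chain on stored time-domain data:
#' millivolts to device units (offset removed over the full input), running
#' Hann-tapered zero-padded FFT, gain-scaled sum of squared single-sided
#' amplitudes over the band's bins. When the input is a combined data
#' table, the signal is split at gaps so that no analysis window spans
#' missing data, and each power value is stamped with the DerivedTime of
#' its window's last sample.
#'
#' @param x A combined data table (from [createCombinedTable()]) or a
#'   numeric millivolt vector.
#' @param channel For a combined table: TD channel index.
#' @param cfg An [FFTConfig-class].
#' @param band A [PowerBand-class].
#' @param cal An [AmplifierCalibration-class].
#' @param quantize Round power values to integer device units (the device
#'   streams integers); default FALSE.
#' @return data.frame with columns `time` (unix ms; window end) and
#'   `power` (device units). For vector input, `time` is the window-end
#'   sample index.
#' @export
calculateNewPower <- function(x, channel = 1L, cfg, band,
                              cal = amplifierCalibration(),
                              quantize = FALSE) {
  if (is.numeric(x)) {
    res <- .bandPowerCore(x, cfg, band, cal, quantize)
    return(data.frame(time = res$endIndex, power = res$power))
  }
  col <- if (is.character(channel)) channel
         else grep(sprintf("^TD_[Cc]h%d$", channel), names(x), value = TRUE)
  if (length(col) != 1 || !col %in% names(x))
    stop("configuration error: channel column not present: TD channel ",
         channel, call. = FALSE)
  keep <- !is.na(x[[col]])
  if (!any(keep)) stop("configuration error: channel is entirely missing",
                       call. = FALSE)
  tt <- x$DerivedTime[keep]
  sig <- x[[col]][keep]
  step <- 1000 / cfg@fs
  # split at gaps: spacing beyond one grid step ends a continuous segment
  brk <- which(diff(tt) > step * 1.5)
  segStart <- c(1L, brk + 1L)
  segEnd <- c(brk, length(tt))
  # offset voltage is removed over the FULL input, then segments are
  # windowed independently so no transform spans a gap
  rcsAll <- (sig - mean(sig)) * (250 * cal@gainCode / 255) *
    (cal@fpv / 1000) / 1.2
  bins <- bandBinIndices(band, cfg) + 1L
  out <- vector("list", length(segStart))
  for (i in seq_along(segStart)) {
    seg <- segStart[i]:segEnd[i]
    if (length(seg) < fftSizeActual(cfg)) next
    stft <- shortTimeFFTAmplitude(rcsAll[seg], cfg)
    power <- band@gainG * rowSums(stft$amplitude[, bins, drop = FALSE]^2)
    if (quantize) power <- round(power)
    out[[i]] <- data.frame(time = tt[seg][stft$endIndex], power = power)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    warning("no continuous segment long enough for one FFT window")
    return(data.frame(time = numeric(0), power = numeric(0)))
  }
  do.call(rbind, out)
}

#' Match window times between two power series
#'
#' Nearest-neighbor match of window-end times, keeping pairs closer than
#' `tolMs`. Streams are packetized and anchored independently, so their
#' reconstructed window times can differ by a few milliseconds of anchor
#' error; a tolerance of half the FFT interval pairs windows unambiguously.
#'
#' @param off,on data.frames with `time` (unix ms) and `power`.
#' @param tolMs maximum time difference for a match, ms.
#' @return List: `offIdx`, `onIdx` (aligned index vectors into the two
#'   series).
#' @export
matchPowerSeries <- function(off, on, tolMs = Inf) {
  ot <- on$time
  idx <- findInterval(off$time, ot)
  c1 <- pmax(idx, 1L)
  c2 <- pmin(idx + 1L, length(ot))
  d1 <- abs(ot[c1] - off$time)
  d2 <- abs(ot[c2] - off$time)
  best <- ifelse(d2 < d1, c2, c1)
  ok <- pmin(d1, d2) <= tolMs
  list(offIdx = which(ok), onIdx = best[ok])
}

#' Calibrate the FFT gain factor from matched series
#'
#' Least-squares estimate of the gain G that best maps an off-device power
#' series (computed at G = 1) onto the on-device reference:
#' `G_hat = sum(x*y) / sum(x^2)` over time-matched samples.
#'
#' @param offDevice data.frame `time`, `power` computed with G = 1.
#' @param onDevice data.frame `time`, `power` from the device.
#' @param tol matching tolerance on time, ms.
#' @return Estimated gain (scalar).
#' @export
calibrateFFTGain <- function(offDevice, onDevice, tol = 1e-6) {
  m <- match(round(offDevice$time / tol) * tol,
             round(onDevice$time / tol) * tol)
  ok <- !is.na(m)
  if (sum(ok) < 10)
    stop("calibration error: fewer than 10 matched samples", call. = FALSE)
  x <- offDevice$power[ok]
  y <- onDevice$power[m[ok]]
  sum(x * y) / sum(x * x)
}

#' Agreement metrics between two power series
#'
#' RMSE, normalized RMSE (RMSE divided by the max-min range of the
#' reference `a`), and percentage difference
#' `100 * mean(|a - b|) / mean(a)`, with `a` the on-device reference.
#'
#' @param a numeric reference series (on-device).
#' @param b numeric comparison series, same length.
#' @return List with `rmse`, `nrmse`, `pctDiff`.
#' @export
comparePowerSeries <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("series must be aligned with at least 2 samples", call. = FALSE)
  rng <- max(a) - min(a)
  if (rng == 0) stop("undefined-metric error: reference has zero range",
                     call. = FALSE)
  if (mean(a) == 0) stop("undefined-metric error: reference has zero mean",
                         call. = FALSE)
  rmse <- sqrt(mean((a - b)^2))
  list(rmse = rmse, nrmse = rmse / rng,
       pctDiff = 100 * mean(abs(a - b)) / mean(a))
}
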