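# Reporting and analysis on reconstructed sessions: gap inventories,
# event tables, gap-aware spectral estimation, multi-session
# concatenation, and static multi-panel stream plots.

#' Inventory of gaps per stream
#'
#' A gap is a missing span at the stream's NATIVE rate: consecutive
#' derived times further apart than one native sample period. Structural
#' missingness of slow streams on the time-domain grid is not a gap. The
#' cause is attributed from provenance: "rejected" when a rejected
#' packet's PacketGenTime falls inside the gap, otherwise
#' "dropped_or_stopped".
#'
#' @param store An [RCSStore-class].
#' @return data.frame: stream, gapStart (unix ms, last sample before the
#'   gap), durationS (missing span in seconds), cause.
#' @export
gapReport <- function(store) {
  rows <- list()
  for (nm in names(store@streams)) {
    s <- store@streams[[nm]]
    tt <- s@derivedTime
    if (length(tt) < 2) next
    step <- 1000 / s@fs
    d <- diff(tt)
    gi <- which(d > step * 1.5)
    rejPgt <- if (nrow(s@rejectionLog) > 0 &&
                  "packetGenTime" %in% names(s@rejectionLog))
      s@rejectionLog$packetGenTime else numeric(0)
    for (g in gi) {
      inGap <- any(rejPgt > tt[g] & rejPgt < tt[g + 1])
      rows[[length(rows) + 1L]] <- data.frame(
        stream = nm, gapStart = tt[g], durationS = (d[g] - step) / 1000,
        cause = if (inGap) "rejected" else "dropped_or_stopped",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(stream = character(0), gapStart = numeric(0),
                      durationS = numeric(0), cause = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$stream, out$gapStart), , drop = FALSE]
}

# Welch periodogram of one continuous segment; returns accumulated
# spectrum and window count.
.welchAccumulate <- function(x, fs, nWin, hop) {
  if (length(x) < nWin) return(list(acc = NULL, n = 0L))
  w <- 0.5 * (1 - cos(2 * pi * (0:(nWin - 1)) / (nWin - 1)))  # Hann
  starts <- seq.int(1L, length(x) - nWin + 1L, by = hop)
  idx <- outer(0:(nWin - 1L), starts, "+")
  segs <- matrix(x[idx], nrow = nWin)
  segs <- segs - matrix(colMeans(segs), nWin, ncol(segs), byrow = TRUE)
  segs <- segs * w
  X <- mvfft(segs)
  half <- floor(nWin / 2)
  P <- Mod(X[1:(half + 1), , drop = FALSE])^2 / (fs * sum(w^2))
  if (half > 1) P[2:half, ] <- P[2:half, ] * 2
  list(acc = rowSums(P), n = length(starts))
}

#' Gap-aware Welch power spectral density
#'
#' Splits a channel at its gaps into continuous segments, discards
#' segments shorter than one analysis window, and averages Hann-tapered
#' periodograms across all windows from all segments, so that no analysis
#' window ever spans missing data. On gap-free data this reduces exactly
#' to plain Welch averaging.
#'
#' @param x combined data table (from [createCombinedTable()]) or a
#'   [DerivedTimeSeries-class].
#' @param channel column name (combined table) or channel index (series).
#' @param windowS analysis window length in seconds.
#' @param overlapFrac fractional overlap of consecutive windows in [0, 1).
#' @return List: `freq` (Hz), `psd` (power/Hz, one-sided),
#'   `nWindowsUsed`.
#' @export
gapAwarePSD <- function(x, channel, windowS = 2, overlapFrac = 0.5) {
  if (is(x, "DerivedTimeSeries")) {
    tt <- x@derivedTime
    sig <- x@samples[, channel]
    fs <- x@fs
  } else {
    if (!channel %in% names(x))
      stop("channel not found: ", channel, call. = FALSE)
    keep <- !is.na(x[[channel]])
    if (!any(keep))
      stop("insufficient-data error: channel entirely missing",
           call. = FALSE)
    tt <- x$DerivedTime[keep]
    sig <- x[[channel]][keep]
    stepNative <- median(diff(tt))
    fs <- 1000 / stepNative
  }
  step <- 1000 / fs
  nWin <- round(windowS * fs)
  hop <- max(1L, round(nWin * (1 - overlapFrac)))
  brk <- which(diff(tt) > step * 1.5)
  segStart <- c(1L, brk + 1L)
  segEnd <- c(brk, length(tt))
  acc <- NULL
  nUsed <- 0L
  for (i in seq_along(segStart)) {
    seg <- segStart[i]:segEnd[i]
    res <- .welchAccumulate(sig[seg], fs, nWin, hop)
    if (res$n > 0) {
      acc <- if (is.null(acc)) res$acc else acc + res$acc
      nUsed <- nUsed + res$n
    }
  }
  if (nUsed == 0)
    stop("insufficient-data error: no continuous segment holds one window",
         call. = FALSE)
  list(freq = (0:(floor(nWin / 2))) * fs / nWin, psd = acc / nUsed,
       nWindowsUsed = nUsed)
}

#' Concatenate stores from multiple sessions
#'
#' Streams are concatenated on unix time; the span between sessions shows
#' up downstream as a long gap. Later sessions are shifted by less than
#' half a sample so their grids share the first session's phase; sessions
#' whose time-domain rate differs are kept on their own grid segments and
#' flagged. Settings timelines and events are merged chronologically.
#'
#' @param stores list of [RCSStore-class] objects.
#' @return An [RCSStore-class]; attribute `fsSegments` is TRUE on the
#'   metadata when rates differ across sessions.
#' @export
combineSessions <- function(stores) {
  if (length(stores) == 1) return(stores[[1]])
  spans <- t(vapply(stores, function(st) {
    rng <- range(unlist(lapply(st@streams, function(s)
      range(s@derivedTime))))
    rng
  }, numeric(2)))
  ord <- order(spans[, 1])
  stores <- stores[ord]
  spans <- spans[ord, , drop = FALSE]
  if (any(spans[-1, 1] <= spans[-nrow(spans), 2]))
    stop("conflict error: session time ranges overlap", call. = FALSE)
  first <- stores[[1]]
  mixedFs <- FALSE
  outStreams <- first@streams
  for (i in 2:length(stores)) {
    st <- stores[[i]]
    for (nm in names(st@streams)) {
      s <- st@streams[[nm]]
      if (nm %in% names(outStreams)) {
        ref <- outStreams[[nm]]
        if (s@fs == ref@fs) {
          step <- 1000 / ref@fs
          # snap this session's whole stream to the first session's phase
          delta <- (ref@tRef +
                      roundHalfDown((s@derivedTime[1] - ref@tRef) / step) *
                      step) - s@derivedTime[1]
          s@derivedTime <- s@derivedTime + delta
        } else mixedFs <- TRUE
        chunksB <- s@chunks
        chunksB$startPacket <- chunksB$startPacket + 0L  # packet indices
        outStreams[[nm]] <- new("DerivedTimeSeries",
          derivedTime = c(ref@derivedTime, s@derivedTime),
          samples = rbind(ref@samples, s@samples),
          fs = ref@fs, tRef = ref@tRef,
          chunks = rbind(ref@chunks, chunksB),
          provenance = c(ref@provenance,
                         s@provenance + max(ref@provenance, 0L)),
          rejectionLog = rbind(ref@rejectionLog, s@rejectionLog))
      } else outStreams[[nm]] <- s
    }
  }
  settings <- first@settings
  for (i in 2:length(stores)) {
    td2 <- stores[[i]]@settings$td
    if (!is.null(td2) && nrow(td2))
      settings$td <- rbind(settings$td, td2)
    st2 <- stores[[i]]@settings$stim
    if (!is.null(st2) && nrow(st2))
      settings$stim <- rbind(settings$stim %||%
                               st2[0, , drop = FALSE], st2)
  }
  if (!is.null(settings$td) && nrow(settings$td))
    settings$td <- settings$td[order(settings$td$time), , drop = FALSE]
  if (!is.null(settings$stim) && nrow(settings$stim))
    settings$stim <- settings$stim[order(settings$stim$time), ,
                                   drop = FALSE]
  events <- do.call(rbind, lapply(stores, storeEvents))
  if (!is.null(events) && nrow(events))
    events <- events[order(events$time), , drop = FALSE]
  else events <- first@events
  md <- first@metadata
  md$nSessions <- length(stores)
  md$fsSegments <- mixedFs
  new("RCSStore", streams = outStreams, settings = settings,
      events = events, metadata = md)
}

#' Chronological event report
#'
#' @param store An [RCSStore-class].
#' @return data.frame: time (unix ms), localTime (POSIXct, UTC offset
#'   applied), type, payload, inSpan (whether the event falls inside the
#'   recorded data span).
#' @export
eventReport <- function(store) {
  ev <- store@events
  if (!nrow(ev))
    return(data.frame(time = numeric(0), localTime = as.POSIXct(character(0)),
                      type = character(0), payload = character(0),
                      inSpan = logical(0)))
  off <- (store@metadata$utcOffset %||% 0) * 60000
  span <- range(unlist(lapply(store@streams, function(s)
    if (length(s)) range(s@derivedTime) else NULL)))
  out <- ev[order(ev$time), , drop = FALSE]
  out$localTime <- as.POSIXct((out$time + off) / 1000,
                              origin = "1970-01-01", tz = "UTC")
  out$inSpan <- out$time >= span[1] & out$time <= span[2]
  rownames(out) <- NULL
  out[, c("time", "localTime", "type", "payload", "inSpan")]
}

#' Static multi-panel stream plot
#'
#' One panel per requested stream on a shared time axis. Panel titles
#' carry decoded settings (sense contacts and filters for time-domain
#' channels, band edges for power); stimulation-parameter changes are
#' drawn as a step line; event markers are overlaid as vertical lines.
#'
#' @param store An [RCSStore-class].
#' @param streams streams to plot (default all present among td, accel,
#'   power); "stim" adds the stimulation-amplitude timeline panel.
#' @param file output path (.png or .svg); NULL returns the patchwork
#'   object without writing.
#' @param width,height,dpi device parameters for [ggplot2::ggsave()].
#' @return The file path (or the plot object), invisibly.
#' @export
plotStreams <- function(store, streams = NULL, file = NULL, width = 10,
                        height = NULL, dpi = 120) {
  present <- names(store@streams)
  if (is.null(streams))
    streams <- intersect(c("td", "accel", "power"), present)
  unknown <- setdiff(streams, c(present, "stim"))
  if (length(unknown))
    stop("configuration error: unknown stream(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  xlim <- range(unlist(lapply(store@streams[intersect(streams, present)],
                              function(s) range(s@derivedTime)))) / 1000
  panels <- list()
  ev <- store@events
  addEvents <- function(p) {
    if (nrow(ev))
      p <- p + ggplot2::geom_vline(xintercept = ev$time / 1000,
                                   linetype = "dotted", colour = "grey40")
    p
  }
  titleFor <- function(nm, col) {
    if (nm == "td" && !is.null(store@settings$td) &&
        nrow(store@settings$td)) {
      chIdx <- suppressWarnings(as.integer(sub("^[Cc]h", "", col)))
      if (is.na(chIdx)) chIdx <- 1L
      row <- store@settings$td[store@settings$td$channel == chIdx, ,
                               drop = FALSE]
      if (nrow(row))
        return(sprintf("TD %s | contacts %s | HPF %g Hz LPF %g Hz | %g Hz",
                       col, row$contacts[1], row$hpf[1], row$lpf[1],
                       row$fs[1]))
    }
    if (nm == "power" && length(store@settings$powerBands)) {
      b <- store@settings$powerBands[[1]]
      return(sprintf("Power | %.2f-%.2f Hz | G = %g", b@fLo, b@fHi,
                     b@gainG))
    }
    paste(nm, col)
  }
  for (nm in intersect(streams, present)) {
    s <- store@streams[[nm]]
    df <- data.frame(t = s@derivedTime / 1000)
    cols <- colnames(s@samples)
    if (is.null(cols)) cols <- paste0("ch", seq_len(ncol(s@samples)))
    long <- do.call(rbind, lapply(seq_along(cols), function(j)
      data.frame(t = df$t, value = s@samples[, j], channel = cols[j])))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = t, y = value,
                                            colour = channel)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::coord_cartesian(xlim = xlim) +
      ggplot2::labs(title = titleFor(nm, cols[1]), x = NULL, y = nm) +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(legend.position = "right")
    panels[[length(panels) + 1L]] <- addEvents(p)
  }
  if ("stim" %in% streams && !is.null(store@settings$stim) &&
      nrow(store@settings$stim)) {
    st <- store@settings$stim
    stEnd <- rbind(st, utils::tail(st, 1))
    stEnd$time[nrow(stEnd)] <- xlim[2] * 1000
    p <- ggplot2::ggplot(stEnd,
                         ggplot2::aes(x = time / 1000, y = amplitudeMa)) +
      ggplot2::geom_step(colour = "firebrick") +
      ggplot2::coord_cartesian(xlim = xlim) +
      ggplot2::labs(
        title = sprintf("Stim | %s | %g us @ %g Hz", st$contacts[1],
                        st$pulseWidthUs[1], st$rateHz[1]),
        x = "unix time (s)", y = "mA") +
      ggplot2::theme_minimal(base_size = 9)
    panels[[length(panels) + 1L]] <- addEvents(p)
  }
  if (!length(panels)) stop("nothing to plot", call. = FALSE)
  fig <- patchwork::wrap_plots(panels, ncol = 1)
  if (is.null(file)) return(invisible(fig))
  if (is.null(height)) height <- 2 * length(panels)
  ggplot2::ggsave(file, fig, width = width, height = height, dpi = dpi)
  invisible(file)
}
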