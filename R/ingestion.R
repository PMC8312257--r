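# Session-folder ingestion: strict-then-repaired JSON parsing, per-stream
# packet extraction, and decoding of settings/events into readable tables.

#' Repair a truncated JSON document
#'
#' Session files are occasionally cut short, typically with their closing
#' brackets omitted. This appends the minimal suffix of closing
#' brackets/braces that balances the document (respecting strings and
#' escapes) and fails with a byte offset when the delimiters cannot be
#' balanced.
#'
#' @param text a single JSON string (possibly truncated).
#' @return The balanced text (unchanged if already balanced).
#' @examples
#' repairMalformedJson('[{"a":1}')  # -> [{"a":1}]
#' @export
repairMalformedJson <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  stack <- character(0)
  inString <- FALSE
  escaped <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (inString) {
      if (escaped) escaped <- FALSE
      else if (ch == "\\") escaped <- TRUE
      else if (ch == '"') inString <- FALSE
      next
    }
    if (ch == '"') inString <- TRUE
    else if (ch == "{" || ch == "[") stack <- c(stack, ch)
    else if (ch == "}" || ch == "]") {
      want <- if (ch == "}") "{" else "["
      if (!length(stack) || stack[length(stack)] != want)
        stop(sprintf("parse error: mismatched '%s' at byte %d", ch, i),
             call. = FALSE)
      stack <- stack[-length(stack)]
    }
  }
  if (inString)
    stop("parse error: unterminated string at byte ", length(chars),
         call. = FALSE)
  if (!length(stack)) return(text)
  closers <- rev(vapply(stack, function(x) if (x == "{") "}" else "]",
                        character(1)))
  paste0(text, paste(closers, collapse = ""))
}

#' Decode a sample-rate code
#'
#' Session files carry the time-domain sampling rate as a code:
#' 0 = 250 Hz, 1 = 500 Hz, 2 = 1000 Hz, 240 = channel disabled.
#'
#' @param code integer code.
#' @return Sampling rate in Hz, or `NA` for a disabled channel.
#' @export
decodeSampleRate <- function(code) {
  key <- as.character(code)
  if (!key %in% names(.SAMPLE_RATE_CODEBOOK))
    stop("decode error: unknown sample-rate code ", code, call. = FALSE)
  unname(.SAMPLE_RATE_CODEBOOK[[key]])
}

# Parse one stream document (already deserialized) into the packet
# data.frame used by reconstruction. Returns NULL for an empty stream.
.packetsFromDocument <- function(doc) {
  recs <- doc$Packets
  if (is.null(recs) || length(recs) == 0) return(NULL)
  rate <- vapply(recs, function(r) {
    if (!is.null(r$SampleRateHz)) as.numeric(r$SampleRateHz)
    else decodeSampleRate(r$SampleRate)
  }, numeric(1))
  mats <- lapply(recs, function(r) {
    cs <- r$ChannelSamples
    do.call(cbind, lapply(cs, as.numeric))
  })
  chn <- names(recs[[1]]$ChannelSamples)
  data.frame(
    systemTick = vapply(recs, function(r) as.integer(r$SystemTick),
                        integer(1)),
    timestamp = vapply(recs, function(r) as.numeric(r$Timestamp),
                       numeric(1)),
    packetGenTime = vapply(recs, function(r) as.numeric(r$PacketGenTime),
                           numeric(1)),
    packetRxUnixTime = vapply(recs,
                              function(r) as.numeric(r$PacketRxUnixTime),
                              numeric(1)),
    dataTypeSequence = vapply(recs,
                              function(r) as.integer(r$DataTypeSequence),
                              integer(1)),
    sampleRate = rate,
    nSamples = vapply(mats, nrow, integer(1)),
    samples = I(lapply(mats, function(m) {
      colnames(m) <- chn
      m
    }))
  )
}

#' Parse a stream document into a packet table
#'
#' @param doc a deserialized stream document (list with `Packets`).
#' @return A packet data.frame in received (file) order, or `NULL` for an
#'   empty stream.
#' @export
parseStreamDocument <- function(doc) .packetsFromDocument(doc)

#' Decode time-domain channel settings
#'
#' Turns raw settings records into a readable timeline: one row per
#' channel per settings change, with the sampling rate decoded from its
#' code, the numeric amplifier gain code preserved (needed for the
#' device-unit conversion), filter codes decoded to Hz, and the electrode
#' contact string split into anode/cathode labels.
#'
#' @param rawRecords the `TimeDomainSettings` list of a DeviceSettings
#'   document.
#' @return data.frame: time, channel, fs, gainCode, hpf, lpf, contacts,
#'   anode, cathode.
#' @export
decodeTdSettings <- function(rawRecords) {
  if (is.null(rawRecords) || !length(rawRecords))
    return(data.frame(time = numeric(0), channel = integer(0),
                      fs = numeric(0), gainCode = numeric(0),
                      hpf = numeric(0), lpf = numeric(0),
                      contacts = character(0), anode = integer(0),
                      cathode = integer(0)))
  rows <- list()
  for (rec in rawRecords) {
    for (chrec in rec$Channels) {
      if (is.null(chrec$GainCode))
        stop("settings error: missing gain code for channel ",
             chrec$Channel, call. = FALSE)
      cts <- chrec$Contacts
      m <- regmatches(cts, regexec("^\\+([0-9]+)-([0-9]+)$", cts))[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        time = as.numeric(rec$Time), channel = as.integer(chrec$Channel),
        fs = decodeSampleRate(chrec$SampleRate),
        gainCode = as.numeric(chrec$GainCode),
        hpf = unname(.HPF_CODEBOOK[as.character(chrec$HpfCode)]),
        lpf = unname(.LPF_CODEBOOK[as.character(chrec$LpfCode)]),
        contacts = cts,
        anode = if (length(m)) as.integer(m[2]) else NA_integer_,
        cathode = if (length(m)) as.integer(m[3]) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$time, out$channel), , drop = FALSE]
}

#' Extract event markers
#'
#' @param doc a deserialized EventLog document.
#' @return data.frame of events sorted by time: time (unix ms), type,
#'   payload. Unparseable entries are skipped.
#' @export
extractEvents <- function(doc) {
  evs <- doc$Events
  empty <- data.frame(time = numeric(0), type = character(0),
                      payload = character(0), stringsAsFactors = FALSE)
  if (is.null(evs) || !length(evs)) return(empty)
  rows <- lapply(evs, function(e) {
    t <- suppressWarnings(as.numeric(e$Time))
    if (is.null(e$Time) || is.na(t)) return(NULL)
    data.frame(time = t, type = as.character(e$Type %||% ""),
               payload = as.character(e$Payload %||% ""),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read one JSON file with strict parse, falling back to bracket repair.
.readSessionFile <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) NULL)
  if (!is.null(parsed)) return(list(doc = parsed, repaired = FALSE))
  fixed <- repairMalformedJson(txt)
  list(doc = jsonlite::fromJSON(fixed, simplifyVector = FALSE),
       repaired = TRUE)
}

#' Load a session folder
#'
#' Reads each of the 11 session files independently; a missing, empty or
#' unparseable file is logged and skipped so the remaining streams still
#' load. Truncated files are repaired before parsing and flagged. Packets
#' are returned in file order, i.e. the order in which they were received.
#'
#' @param folder path to a session folder.
#' @return List: `streams` (named list of packet data.frames for td,
#'   accel, power, fft, adaptive — absent streams omitted), `settings`
#'   (decoded settings list), `events` (data.frame), and `loadReport`
#'   (data.frame: file, status, repaired, nPackets, note).
#' @export
loadSession <- function(folder) {
  if (!dir.exists(folder))
    stop("I/O error: session folder not found: ", folder, call. = FALSE)
  report <- data.frame(file = .SESSION_FILES, status = "ok",
                       repaired = FALSE, nPackets = NA_integer_,
                       note = "", stringsAsFactors = FALSE)
  docs <- list()
  for (i in seq_along(.SESSION_FILES)) {
    f <- .SESSION_FILES[i]
    path <- file.path(folder, f)
    if (!file.exists(path)) {
      report$status[i] <- "absent"
      report$note[i] <- "file missing; stream omitted"
      next
    }
    res <- tryCatch(.readSessionFile(path), error = function(e) e)
    if (inherits(res, "error")) {
      report$status[i] <- "unreadable"
      report$note[i] <- conditionMessage(res)
      next
    }
    docs[[f]] <- res$doc
    report$repaired[i] <- res$repaired
    if (res$repaired) report$note[i] <- "repaired truncated JSON"
  }

  streams <- list()
  for (nm in names(.STREAM_FILE_MAP)) {
    f <- .STREAM_FILE_MAP[[nm]]
    if (is.null(docs[[f]])) next
    pk <- tryCatch(.packetsFromDocument(docs[[f]]), error = function(e) {
      report$note[report$file == f] <<- conditionMessage(e)
      report$status[report$file == f] <<- "unparseable"
      NULL
    })
    i <- which(report$file == f)
    if (is.null(pk)) {
      if (report$status[i] == "ok")
        report$note[i] <- "empty stream; omitted"
      next
    }
    report$nPackets[i] <- nrow(pk)
    streams[[nm]] <- pk
  }

  settings <- list(td = NULL, fftConfig = NULL, powerBands = list(),
                   stim = NULL)
  metadata <- list()
  ds <- docs[["DeviceSettings.json"]]
  if (!is.null(ds)) {
    metadata <- list(
      deviceId = ds$Metadata$DeviceId %||% NA_character_,
      sessionId = ds$Metadata$SessionId %||% NA_character_,
      utcOffset = as.numeric(ds$Metadata$UtcOffsetMinutes %||% 0))
    settings$td <- decodeTdSettings(ds$TimeDomainSettings)
    if (!is.null(ds$FftConfig) && length(ds$FftConfig))
      settings$fftConfig <- fftConfig(
        size = ds$FftConfig$Size, interval = ds$FftConfig$IntervalSeconds,
        windowLoad = ds$FftConfig$WindowLoad,
        fs = if (nrow(settings$td)) settings$td$fs[1] else 250)
    settings$powerBands <- lapply(ds$PowerBands, function(b)
      powerBand(b$LowerHz, b$UpperHz, b$GainG %||% 2,
                b$TdChannel %||% 1L))
  }
  sl <- docs[["StimLog.json"]]
  if (!is.null(sl) && length(sl$StimSettings)) {
    settings$stim <- do.call(rbind, lapply(sl$StimSettings, function(s)
      data.frame(time = as.numeric(s$Time), group = as.character(s$Group),
                 contacts = as.character(s$Contacts),
                 amplitudeMa = as.numeric(s$AmplitudeMa),
                 pulseWidthUs = as.numeric(s$PulseWidthUs),
                 rateHz = as.numeric(s$RateHz),
                 stringsAsFactors = FALSE)))
    settings$stim <- settings$stim[order(settings$stim$time), ,
                                   drop = FALSE]
  }
  events <- if (!is.null(docs[["EventLog.json"]]))
    extractEvents(docs[["EventLog.json"]])
  else extractEvents(list())

  if (!length(streams) && is.null(ds))
    stop("empty-session error: no usable stream or settings files in ",
         folder, call. = FALSE)
  list(streams = streams, settings = settings, events = events,
       metadata = metadata, loadReport = report)
}
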