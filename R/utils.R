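# Internal numeric helpers shared across modules.

# Seconds between the unix epoch and the device timestamp epoch
# (2000-03-01T00:00:00Z). Device `timestamp` counts whole seconds from the
# latter; unix_seconds = timestamp + .TIMESTAMP_EPOCH_UNIX.
.TIMESTAMP_EPOCH_UNIX <- 951868800

# Round to nearest integer with ties going DOWN (toward earlier time).
# Grid snapping and nearest-grid alignment both use this tie rule so that
# the direction of a half-interval tie is deterministic and stable.
roundHalfDown <- function(x) ceiling(x - 0.5)

# Unix milliseconds -> device timestamp (integer seconds since 2000-03-01).
unixMsToTimestamp <- function(ms) floor(ms / 1000 - .TIMESTAMP_EPOCH_UNIX)

# Device timestamp -> unix seconds.
timestampToUnixSeconds <- function(ts) ts + .TIMESTAMP_EPOCH_UNIX

# Sample-rate codebook for the session dialect. Codes are stored in the
# JSON files; 240 marks a disabled channel.
.SAMPLE_RATE_CODEBOOK <- c("0" = 250, "1" = 500, "2" = 1000, "240" = NA_real_)

.encodeSampleRate <- function(hz) {
  code <- names(.SAMPLE_RATE_CODEBOOK)[match(hz, .SAMPLE_RATE_CODEBOOK)]
  if (is.na(code)) stop("no sample-rate code for ", hz, " Hz", call. = FALSE)
  as.integer(code)
}

# High-pass / low-pass filter codebooks (repo-defined, Hz).
.HPF_CODEBOOK <- c("0" = 0.85, "1" = 1.2, "2" = 3.3, "3" = 8.6)
.LPF_CODEBOOK <- c("0" = 50, "1" = 100, "2" = 450, "3" = 1700)

# The 11 session files of the dialect.
.SESSION_FILES <- c(
  "RawDataTD.json", "RawDataAccel.json", "RawDataPower.json",
  "RawDataFFT.json", "AdaptiveLog.json", "DeviceSettings.json",
  "StimLog.json", "TimeSync.json", "EventLog.json", "ErrorLog.json",
  "DiagnosticsLog.json"
)

.STREAM_FILE_MAP <- c(
  td = "RawDataTD.json", accel = "RawDataAccel.json",
  power = "RawDataPower.json", fft = "RawDataFFT.json",
  adaptive = "AdaptiveLog.json"
)
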