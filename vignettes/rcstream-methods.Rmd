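---
title: "Reconstructing and emulating packetized neurostimulator telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and emulating packetized neurostimulator telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcstream)
```

## The problem

Chronically implanted bidirectional neurostimulators stream local field
potentials, accelerometry, and on-board spectral features to an external
receiver over an unacknowledged transport. Packets carry a variable
number of samples and a single set of timing variables describing only
the packet's **last** sample; packets can be lost or arrive out of
order; and the device exposes three mutually inconsistent clocks:

* `systemTick` — a 16-bit hardware counter in units of 1e-4 s that rolls
  over every 2^16 ticks (~6.5535 s);
* `timestamp` — a firmware counter of whole seconds since
  2000-03-01T00:00:00Z (1 s resolution);
* `PacketGenTime` — a transmitter-side unix-millisecond estimate of
  packet creation, whose offset from true time varies from packet to
  packet.

None of these suffices alone: the tick counter rolls over, the timestamp
is too coarse, and differencing `PacketGenTime` yields irregular
inter-sample intervals that corrupt time-frequency analysis. Worse, one
timestamp second does not reliably equal 10,000 ticks — the two clocks
drift apart by seconds over a long recording. The package reconstructs a
per-sample unix time base ("DerivedTime") that is uniform at exactly
1/Fs within continuous data, correctly placed across gaps, and common to
all streams.

## Time reconstruction

Processing is per stream (each stream is packetized independently):

1. **Packet rejection.** Packets are removed, in received order, when
   their timestamp lies more than 24 h from the stream median, their
   PacketGenTime is negative, their PacketGenTime steps backward more
   than 500 ms relative to the previous kept packet, or their elapsed
   PacketGenTime disagrees with elapsed timestamp by more than 2 s
   (again versus the previous kept packet). The reference is always the
   previous *kept* packet; after a rejection the next comparison spans
   it.
2. **Chunking.** Adjacent packets belong to one continuous chunk iff the
   sequence counter advances by exactly 1 (mod 256), the sampling rate
   is unchanged, the elapsed tick counter matches the expected duration
   of the second packet's samples within 10 ticks (1 ms), and elapsed
   timestamp agrees within its 1 s resolution. The 10-tick tolerance is
   our choice: far above floating-point error, far below one sample
   period at any supported rate. Within a chunk the device is known to
   have sampled gaplessly, so sample times are pure arithmetic.
3. **Anchoring.** Each chunk is anchored to unix time through its
   packets' PacketGenTime values: every packet j implies an offset
   `PGT_j - (PGT_1 + elapsed_j)` where `elapsed_j` is the intervening
   sample count over Fs, and the anchor is `PGT_1` plus the mean offset
   (the mean, not median, implements the "average offset" rule; the
   choice is isolated in `adjustedAnchor()`). Averaging over a chunk of
   n packets shrinks the per-packet jitter by roughly sqrt(n).
4. **Grid snapping.** Chunks after the first are shifted, as a whole, to
   the nearest multiple of 1/Fs relative to the first chunk's origin, so
   inter-sample spacing is *exactly* 1/Fs everywhere. A tie at half a
   grid step rounds toward earlier time (deterministic and
   direction-stable). If heavy jitter ever snaps a chunk onto or before
   the end of its predecessor, the chunk is pushed to the first free
   grid slot; this preserves strict monotonicity at the cost of a
   one-sample placement error in a pathological case.
5. **Short-gap alternative.** For gaps under 6 s (by timestamp) the tick
   counter has provably not wrapped, so the caller may instead bridge
   the gap with elapsed ticks (`method = "gap"`). This is exact when the
   tick clock is accurate but accumulates its rate error over the
   recording, which is why PacketGenTime anchoring is the default; the
   6 s threshold is the classification boundary between short and long
   gaps.

Received order is preserved at load; order repair happens in time logic:
chunks are assembled in anchor-time order, which restores locally swapped
packets without any transport-level heuristics. `PacketRxUnixTime` is
carried through but never used for DerivedTime — it is unreliable after
drops.

The timestamp epoch conversion is `unix_seconds = timestamp +
951,868,800` (2000-03-01T00:00:00Z). All internal times are UTC unix
milliseconds; the session's UTC offset is applied only in presentation
columns. At the supported rates every grid step (4, 2, 1, 15.625, ... ms)
is exactly representable in binary floating point and the grid is
computed as `tRef + k * step` from integer k, so within-chunk spacing is
exact to the bit — the tests assert equality, not tolerance.

## Harmonization

The time-domain stream has the highest rate and owns the unified grid;
the grid extends in exact steps to cover earlier/later samples of other
streams, and each other stream's samples move to their nearest grid
point (ties toward earlier, displacement never more than half a TD
sample period). Missing entries are explicit `NA`s; columns that would
be entirely missing are dropped. When no time-domain stream exists the
highest-rate stream owns the grid, with a loud warning. The persisted
store keeps each stream compact (columnar Parquet plus JSON settings)
instead of materializing the sparse combined table, the same
small-on-disk intent as the original sparse-matrix design it replaces.

## The on-device power engine, off-device

The spectral engine is replicated step by step:

* **Unit conversion.** Millivolts become internal fixed-point units via
  `(s - mean(s)) * (250 * gainCode / 255) * (fpv / 1000) / 1.2` with
  `fpv = 48,644.8683623726`. The offset is the mean of the full input,
  subtracted once — not per window.
* **Windowing.** Nominal transform sizes 64/256/1024 use only
  62/250/1000 real samples ("actual" points), zero-padded up to the
  nominal size. Window overlap is `1 - fs * interval / actual`; the hop
  is `round(fs * interval)` samples, and a negative overlap (skipping
  samples between windows) is permitted and flagged.
* **Hann load.** The 100% window is `0.5 * (1 - cos(2*pi*n/N))` over
  `L = N + 1 = actual` points. The 25%/50% loads are implemented as a
  linear blend toward flat, `(1 - l) + l * w100`: this reproduces the
  reduced taper depth, equals the closed form at 100%, and is isolated
  in `hannWindow()` because the device's exact reduced-load shapes are
  not publicly specified.
* **Single-sided scaling.** Amplitudes are `|X(k)|/size`, doubled
  strictly between DC and Nyquist. Any fixed convention works because
  the stream-side emulator and the off-device recomputation share one
  implementation (`.bandPowerCore`), making the emulator a valid oracle;
  absolute hardware fidelity of this scaling cannot be established from
  public documentation and is not claimed.
* **Band power.** Bins whose center `k * fs / size` lies inside the band
  (inclusive at both edges) are summed as squared amplitudes and scaled
  by the gain factor G (default 2); G can be re-estimated per dataset by
  least squares (`calibrateFFTGain()`). The device streams integer
  power, so the emulator quantizes by rounding when asked.

Windows never span gaps: the off-device path splits the signal at
missing data and windows each continuous segment separately. The same
rule drives the gap-aware Welch PSD in the reporting module, which on
continuous data reduces exactly (to 1e-12) to plain Welch averaging.

## What the simulator emulates — and what it does not

The simulator generates every stream sample-by-sample with known true
unix times, packetizes with variable packet sizes, stamps the timing
variables from each packet's last sample (tick drift applied to
`systemTick` only, Gaussian jitter on `PacketGenTime`, fixed receive
latency on `PacketRxUnixTime`), and then drops and locally swaps packets
at configured rates. Defaults describe a plausible bench recording: 2%
packet loss, 0.5% adjacent reordering, 15 ms PacketGenTime jitter SD,
80 ppm tick drift (the order of magnitude implied by multi-second
drift over a 10 h recording). The jitter is modeled Gaussian and
independent per packet; the real transmitter's error distribution is not
published, so this is a stand-in, not a device claim — conclusions that
depend on jitter *shape* rather than scale should not lean on it.
Signal content (sinusoids, bursts, pink noise, smoothed motion) is
deliberately simple; the simulator validates *time handling and
arithmetic*, not neural realism, and passing tests say nothing about
physiological artifact content, amplifier nonlinearity, or
non-stationary loss bursts of real home recordings.

## Validation set-up and problem sizes

The validation suite exercises, at desk scale: a 5-minute 500 Hz session
for on/off-device power agreement (1024-point transform, 100% load,
8.05–12.20 Hz band, integer quantization on — the observed disagreement
is pure quantization, about 0.29 units RMSE over ~3,000 windows); a
20-minute 250 Hz session at 5% loss and 50 ms jitter for reconstruction
accuracy (≥ 99% of samples within 100 ms of truth; spacing exact; no
duplicates — these thresholds are test design choices, not published
values); a 30-minute two-device experiment sharing one deterministic
motion signal, where the cross-correlation lag between independently
reconstructed accelerometer streams changes by less than one sample
period between the first and last minute; and 90-second sessions
spanning many tick-counter cycles to confirm rollover handling. Closed
forms (unit conversion, overlap triplets, Hann endpoints) and
brute-force equivalences (exhaustive chunk partitions on ≤ 5 packets,
loop-computed agreement metrics, enumerated band bins) pin the
arithmetic independently of the implementation under test.

## Known limitations

* Reduced-load Hann shapes and the absolute single-sided FFT scaling are
  stated conventions, not verified hardware behavior.
* Individual missing samples *inside* a packet are assumed impossible
  (only whole packets go missing); the chunking logic inherits this
  assumption.
* The adaptive-detector stream is carried through ingestion and storage
  but its on-device linear-discriminant computation is not emulated.
* Sessions with mid-recording sampling-rate changes are split at the
  change and concatenation keeps mixed-rate sessions on separate grid
  segments; no resampling is attempted.
* The percentage-difference metric is defined here as
  `100 * mean(|a-b|) / mean(a)` with `a` the on-device reference; other
  definitions exist, and the choice is isolated in
  `comparePowerSeries()`.
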