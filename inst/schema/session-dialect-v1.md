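# Session JSON dialect, version 1

A session folder holds 11 JSON documents, one per stream or log. All
documents carry `"SchemaVersion": 1`.

## Files

| File                | Content                                   |
|---------------------|-------------------------------------------|
| RawDataTD.json      | time-domain packets (`StreamType: "TimeDomain"`) |
| RawDataAccel.json   | accelerometer packets (`"Accelerometry"`) |
| RawDataPower.json   | on-device band-power packets (`"Power"`)  |
| RawDataFFT.json     | on-device FFT packets (`"FFT"`)           |
| AdaptiveLog.json    | adaptive-detector packets (`"Adaptive"`)  |
| DeviceSettings.json | metadata + decoded-able settings          |
| StimLog.json        | stimulation settings timeline             |
| TimeSync.json       | reserved (`Records: []`)                  |
| EventLog.json       | event markers                             |
| ErrorLog.json       | reserved                                  |
| DiagnosticsLog.json | reserved                                  |

A simulator-written folder may additionally contain `_groundtruth.json`,
a clearly marked synthetic sidecar that is never produced by a device.

## Stream documents

```json
{
  "SchemaVersion": 1,
  "StreamType": "TimeDomain",
  "Packets": [
    {
      "SystemTick": 12345,
      "Timestamp": 662256000,
      "PacketGenTime": 1600000000123,
      "PacketRxUnixTime": 1600000000173,
      "DataTypeSequence": 7,
      "SampleRate": 0,
      "ChannelSamples": {"Ch1": [0.01, ...], "Ch2": [...]}
    }
  ]
}
```

Per-packet timing variables (all describing the packet's LAST sample):

- `SystemTick` — hardware counter, units of 1e-4 s, rolls over at 2^16.
- `Timestamp` — firmware counter, whole seconds since 2000-03-01T00:00:00Z.
- `PacketGenTime` — transmitter estimate of creation time, unix ms
  (integer); offset varies packet to packet.
- `PacketRxUnixTime` — receiver wall clock, unix ms; unreliable after
  drops.
- `DataTypeSequence` — per-stream packet counter, rolls over at 256.

Time-domain packets carry `SampleRate` as a code
(0 = 250 Hz, 1 = 500 Hz, 2 = 1000 Hz, 240 = disabled); accelerometer and
power packets carry `SampleRateHz` literally (power rate = TD rate /
transform hop). Channel keys: `Ch1..Ch4` (TD), `X/Y/Z` (accel),
`Band1..Band8` (power).

## DeviceSettings.json

```json
{
  "SchemaVersion": 1,
  "Metadata": {"DeviceId": "...", "SessionId": "...", "UtcOffsetMinutes": 0},
  "TimeDomainSettings": [
    {"Time": 1600000000000,
     "Channels": [{"Channel": 1, "SampleRate": 0, "GainCode": 255,
                    "HpfCode": 0, "LpfCode": 2, "Contacts": "+2-0"}]}
  ],
  "FftConfig": {"Size": 256, "IntervalSeconds": 0.1, "WindowLoad": 100},
  "PowerBands": [{"Band": 1, "LowerHz": 8.05, "UpperHz": 12.2,
                   "GainG": 2, "TdChannel": 1}],
  "AdaptiveConfig": {}
}
```

Codebooks (decoded by the loader): HPF code {0: 0.85, 1: 1.2, 2: 3.3,
3: 8.6} Hz; LPF code {0: 50, 1: 100, 2: 450, 3: 1700} Hz; contacts
`"+A-C"` = anode contact A, cathode contact C. `GainCode` stays numeric:
it enters the millivolt-to-device-unit conversion.

## StimLog.json / EventLog.json

```json
{"SchemaVersion": 1,
 "StimSettings": [{"Time": 1600000000000, "Group": "A", "Contacts": "+1-2",
                    "AmplitudeMa": 2.0, "PulseWidthUs": 60, "RateHz": 130}]}
{"SchemaVersion": 1,
 "Events": [{"Time": 1600000001000, "Type": "task", "Payload": "start"}]}
```
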