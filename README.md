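# optopattern

Most optogenetic mapping studies drive neurons with tonic (fixed-interval) or
continuous light, which discards any information carried by the temporal
arrangement of a neuron's spikes. `optopattern` is a toolkit for the
alternative, biomimetic approach: take a sorted extracellular recording of a
single unit, turn its spike times into a laser pulse schedule that mirrors
them one-for-one, and deliver that schedule — or matched controls that
selectively destroy its temporal structure — in a real-time place-preference
(RT-PP) session. It is written for systems neuroscientists designing
stimulation patterns from their own recordings, and for anyone who needs the
surrounding plumbing: unit classification, burst detection, pulse-file
rendering, and closed-loop gated playback, all reproducible from seeds.

## What it computes

**Unit classification.** Putative GABAergic VTA units are identified by two
features of the baseline (drug-free) recording: mean-waveform peak-to-trough
time *w* and firing rate *r* = N/T over the fixed-length segment. The unit is
labeled putative GABA iff

    w ≤ 0.3 ms  and  r ≥ 15 spikes/s

with both boundaries inclusive. Peak-to-trough is measured at sample
resolution (no sub-sample interpolation; at 30 kHz the grid is 0.033 ms).

**Burst detection.** The four-parameter interval algorithm: maximal runs of
spikes with consecutive ISIs ≤ 10 ms are formed, adjacent runs closer than
10 ms are merged, and candidates with fewer than 4 spikes or a
first-to-last span under 20 ms are discarded. All four parameters are
configurable via `burst_params()`.

**The four stimulation modes.**

| mode | construction |
|---|---|
| biomimetic | one 3 ms pulse `[t, t+3ms)` per spike at `t`; overlapping pulses merge (OR of trigger squares) |
| shuffled | the source ISI sequence is uniformly permuted (first spike anchored), then rendered biomimetically — same ISI multiset, count, span and mean rate, no temporal order |
| tonic | evenly spaced 3 ms pulses at the source train's mean rate `N/T` — same frequency, no temporal structure |
| continuous | 30 s on / 60 s off duty cycle from t = 0 |

**Gated playback.** RT-PP delivery: the stimulation file is *played* on entry
into the laser-paired compartment and *paused* on exit, so a file clock
advances only during paired-side dwell and no pattern element is lost. There
is no rewind and no looping. Preference is scored as paired-side dwell time,
normalized across days as `100 × (test − pretest) / pretest`.

**Synthetic data.** Gamma-renewal spike trains (independent rate and CV, with
an absolute refractory floor), biphasic waveforms with exact peak-to-trough
construction, and two-state exponential occupancy traces make every stage
testable without recorded data; `study_train_configs()` carries the three
source-recording presets (18.8 and 22.2 Hz morphine-condition trains, the
second with sparse bursts, and a 16.7 Hz baseline train, 900 s each).

## Worked example

```r
library(optopattern)

# 15-min morphine-condition recording emulated at 18.8 spikes/s
train <- simulate_train(mean_rate = 18.8, duration = 900, isi_cv = 1,
                        seed = 42, condition = "morphine", unit_id = "cell1",
                        dose_mg_per_kg = 5)
train
#> <spike_train> unit 'cell1', condition morphine: 16699 spikes over 900.0 s (18.55 spikes/s)

# classify the unit from its mean waveform and drug-free rate
wf <- simulate_waveform(0.00025, sample_rate = 30000, seed = 42)
baseline <- simulate_train(mean_rate = 16.7, duration = 900, seed = 43,
                           condition = "baseline", unit_id = "cell1")
classify(baseline, wf)
#> <unit_label> putative_GABA (peak-to-trough 0.267 ms, baseline 17.0 spikes/s)

# burst scan at the default four-parameter criteria
bursts <- detect_bursts(train)
burst_summary(bursts, train)$n_bursts
#> [1] 10

# the four stimulation modes
biomimetic <- biomimetic_pattern(train)
biomimetic
#> <pulse_schedule> [biomimetic] 16372 on-interval(s) over 900.0 s, light-on 49.933 s total
shuffled <- biomimetic_pattern(shuffle_isis(train, seed = 7))
tonic <- tonic_pattern(mean_rate(train), 900)
continuous <- continuous_pattern(900)
continuous
#> <pulse_schedule> [continuous] 10 on-interval(s) over 900.0 s, light-on 300.000 s total

# gated RT-PP playback: file pauses when the animal leaves the paired side
occ <- simulate_occupancy(bias = 0.65, mean_dwell = 40,
                          session_length = 1200, seed = 99)
gated_playback(biomimetic, occ)
#> <playback_log> 11057 pulse(s) emitted, file position 606.01 s, 1 truncated
preference_score(occ)
#> [1] 606.0062
percent_change(test_score = preference_score(occ), pretest_score = 540)
#> [1] 12.22337
```

The classification report shows the waveform's peak-to-trough measured on
the 30 kHz sample grid (0.25 ms requested, 8 samples = 0.267 ms realized)
and the baseline rate of 17.0 spikes/s — both inside the putative-GABA
region. The 18.8 Hz train yields 16,699 spikes; 327 spike pairs fall closer
than the 3 ms pulse width and merge, leaving 16,372 light intervals. During
the simulated 20-min session the animal spends 606 s on the paired side, so
the 900 s file advances to position 606 s and 11,057 of the pulses are
emitted; against a 540 s pre-test the session scores a +12.2% preference
shift.

Schedules render to pulse-event CSV (`write_pulse_events`), TTL event lists
(`write_ttl_events`), and normalized 0/1 square-wave PCM files
(`render_wave` + `write_wave_file`). A thin command-line dispatcher over the
same functions is installed at `inst/cli/optopattern`
(subcommands `classify`, `burstscan`, `generate`, `render`, `simulate`,
`playback`, `score`, `run`), and `run_pipeline()` wires all stages from one
JSON configuration with a checksum manifest.

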