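---
title: "Designing biomimetic optogenetic stimulation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing biomimetic optogenetic stimulation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optopattern)
```

## The problem this package addresses

Tonic optogenetic stimulation delivers light pulses at fixed, regular
intervals. That is a faithful proxy for neurons that fire tonically, but
many populations — fast-firing GABAergic neurons of the ventral tegmental
area among them — fire irregularly, and the temporal arrangement of their
spikes may itself carry information that a rate-matched tonic train
destroys. The biomimetic alternative is to record a single unit in the
behavioral state of interest, convert each action potential into a laser
pulse at the same time offset, and play the resulting file back through the
opsin-expressing population. Distinguishing temporal coding from rate
coding then requires a family of matched controls: a surrogate with the same
interspike-interval (ISI) multiset in permuted order, a tonic train at the
same mean rate, and an unpulsed continuous duty cycle.

`optopattern` implements that whole design space as data types and pure
functions: spike trains and waveforms in, pulse schedules out, plus a
simulator of the closed-loop delivery rule used in real-time place
preference (RT-PP) and seeded generators for all of its inputs.

## Unit classification

Putative GABAergic VTA units are identified from two features of the
baseline recording, with defaults held in `classification_criteria()`:

* **peak-to-trough time** of the mean waveform, at most **0.3 ms**, and
* **baseline firing rate**, at least **15 spikes/s**,

both boundaries inclusive. Rates are spike count over the full fixed-length
segment, not the first-to-last-spike span: condition segments have a known
recording length, and count-over-length is the convention the thresholds
were defined under. Peak-to-trough is the sample-grid distance between the
global maximum and the following global minimum, with **no sub-sample
interpolation**: at the 30 kHz acquisition rate the grid step is 0.033 ms,
an order of magnitude below the criterion, so interpolation would add
machinery without changing any label. A waveform whose trough precedes its
peak raises an error advising a polarity flip rather than guessing the
recording convention. Units that fail the rule are labeled `"other"`, not
"dopaminergic": the criteria are one-sided and say nothing quantitative
about any other cell class.

```{r classify}
wf <- simulate_waveform(0.0002, sample_rate = 30000)
tr <- simulate_train(16.7, duration = 900, seed = 1, condition = "baseline")
classify(tr, wf)
```

## Burst detection

`detect_bursts()` implements the four-parameter interval algorithm with the
conventional defaults: maximum 10 ms between spikes within a burst, minimum
4 spikes per burst, minimum 10 ms between bursts, minimum 20 ms burst
duration. Two aspects of the algorithm are under-determined by that list,
and the package pins them explicitly (they are design choices, not imported
facts):

* **Comparison senses.** The maximum/minimum wording is read literally and
  inclusively: intra-burst ISIs may equal 10 ms, a burst may have exactly
  4 spikes or span exactly 20 ms; runs are merged when their gap is
  *strictly below* the inter-burst minimum. The acceptance sweeps in the
  test suite pin each boundary.
* **Stage order.** The pipeline is segment → merge → filter: maximal
  sub-10 ms runs are formed first, near-neighbors merged (cascading left to
  right; merging only ever extends a run rightward, so a single pass
  reaches the fixpoint), and the count/duration filters are applied last.
  Merging before filtering means two short runs separated by a sub-threshold
  gap can jointly qualify as one burst even though neither qualifies alone.

The implementation is verified against a brute-force oracle that enumerates
every contiguous spike subsequence, keeps the maximal ones, merges to a
fixpoint, and filters — across a thousand random trains per run of the test
suite.

## The four stimulation modes

**Biomimetic** (`biomimetic_pattern`): one pulse `[t, t + w)` per spike at
`t`, default width `w` = 3 ms (chosen for fast channelrhodopsin variants
that follow high-frequency drive). When an ISI is below — or exactly at —
the pulse width, the overlapping squares merge into one light interval,
which is what a laser driven by OR-ed TTL triggers physically does; the
merge count is kept in the schedule annotation. Merging tolerates 1 ns of
floating-point noise in the comparison, three orders of magnitude below the
1 µs file precision.

**Shuffled** (`shuffle_isis` then `biomimetic_pattern`): the ISI sequence
after the first spike is replaced by a uniformly random permutation drawn
from an explicit integer seed (Mersenne-Twister, recorded in the
provenance attribute so any surrogate can be regenerated bit-exactly). The
first spike is anchored: the initial latency from segment start to first
spike is not an interspike interval, and anchoring it preserves exactly the
quantities the surrogate is supposed to preserve — spike count, first and
last spike time, total span, ISI multiset, and mean rate. Trains with fewer
than three spikes are rejected (no non-trivial permutation exists).

**Tonic** (`tonic_pattern`): `floor(rate × duration)` pulses at times
`k/rate`, starting at `t = 0` — phase carries no information in a
frequency-matched control, and a fixed phase makes the file deterministic.
Rates above `1/pulse_width` are refused rather than silently merged, since
a "tonic" file that is actually continuous light would be a different
experimental condition.

**Continuous** (`continuous_pattern`): repeating on/off phases from
`t = 0`, default 30 s on / 60 s off, clipped at the file end.

```{r modes}
train <- simulate_train(18.8, duration = 900, seed = 42, condition = "morphine")
biomimetic_pattern(train)
tonic_pattern(mean_rate(train), 900)
continuous_pattern(900)
```

## Gated session playback

RT-PP delivery pauses the stimulation file when the animal leaves the
paired compartment and resumes it on re-entry, so that no element of the
pattern is skipped. `gated_playback()` models this with a file clock that
advances only during paired-side dwell; a pulse whose file onset is reached
while the clock runs is emitted at the corresponding session time.
Consequences, each pinned by a test:

* emitted pulse count never exceeds the schedule's, with equality exactly
  when total paired dwell reaches the file length (up to the discreteness
  of pulse placement near the file end);
* relative file timing is preserved — the emitted file-onset differences are
  the schedule's onset differences;
* the file never rewinds or loops: a 15-min file in a 20-min session simply
  ends (stimulation files match the recording length; nothing in the
  delivery rule justifies wrapping around).

Two details the delivery rule leaves open are pinned as package decisions:
a pulse interrupted mid-width by an exit is truncated at the exit and not
replayed (the simplest causally consistent rule — the light was on until
the animal left; truncations are counted in the log), and the continuous
mode's 30/60 cycle lives on the file clock, not the wall clock, because the
continuous file is played and paused exactly like any pattern file.

Scores are paired-side dwell in seconds (`preference_score`), normalized
across days as percent change from the stimulation-free pre-test
(`percent_change`). Compartment assignment bookkeeping (pair
predicted-rewarding stimulation to the least-preferred side, and so on) is
provided by `assign_compartment()` as a pure helper.

## Synthetic data: what it emulates and what it does not

`simulate_train()` draws gamma-renewal ISIs — `refractory + Gamma(shape =
1/cv², scale)` scaled so the mean ISI is exactly `1/rate` — because a
two-parameter renewal family reproduces rate and irregularity
independently, which a Poisson process cannot, and irregular non-tonic
firing is the regime of interest. The default 2 ms absolute refractory
period is a conventional floor for fast-spiking units. Optional burst
injection overlays a Poisson process of dense spike runs (defaults 4–8
spikes at 4–8 ms ISIs, chosen to satisfy all four detection criteria with
margin); after overlay the refractory floor is re-imposed greedily.
`study_train_configs()` packages the three source-recording emulations: a
18.8 Hz morphine-condition train, a 22.2 Hz morphine-condition train with
sparse bursts (0.05 events/s — burst epochs were an occasional, not
dominant, feature of the corresponding recording), and a 16.7 Hz baseline
train, each 900 s.

These are renewal processes with stationary rate. Real recordings have
drifting rates, serial ISI correlations, and possibly the very higher-order
temporal structure whose behavioral relevance motivates the toolkit. A
passing rate-recovery or shuffle-conservation test therefore validates the
package's algebra — not any claim that the simulator reproduces a real
neuron's code. The simulator's tolerance targets (for example, mean rate
within 5% over 20 seeds at 900 s) are claims about the generator itself.

`simulate_waveform()` builds a biphasic template from two disjoint raised
cosine lobes so the noiseless peak-to-trough distance is exact on the
sample grid, giving a closed generator/analyzer loop; noise is added
afterwards. `simulate_occupancy()` is a two-state exponential renewal
process whose dwell means are proportional to `bias` and `1 − bias`; it is
the simplest process with a controllable long-run preference and makes no
behavioral claim.

## Numerical choices

* Timestamps and schedule edges are stored as decimal text with six
  fractional digits (1 µs), exceeding the 30 kHz acquisition resolution;
  file round trips are exact at that precision.
* Square-wave rendering uses half-open membership `[on, off)` so every edge
  maps to exactly one sample; `render_wave()` requires the sample rate to
  give every pulse at least two samples and names the minimum rate in its
  error. Rendering and decoding round-trip every edge within one sample
  period.
* Unsorted timestamp files are sorted with a warning rather than rejected
  (sorter exports vary); negative times and times past the declared segment
  length are hard errors.
* The wave file maps logical 1 to full-scale positive 16-bit PCM — the
  normalized form of a 0-to-1 V trigger signal; absolute voltage is a
  hardware volume setting outside the package's scope.
* Degenerate inputs are defined, not special-cased: empty trains yield
  empty schedules and empty burst lists; a zero-length continuous file has
  no cycles; a spike exactly at the segment end has no room for a pulse and
  is dropped from the biomimetic schedule.

## Problem sizes in the test suite

The suite exercises the oracle equivalences on 1,000 random trains per
property, shuffle conservation on 1,000 seeded permutations plus a
chi-square uniformity check over all 24 orderings of a 4-ISI train at
10,000 draws (α = 0.01), and rate recovery on 20 seeds per study preset at
the full 900 s segment length — sizes at which the Monte-Carlo error of
each check is far below its acceptance band while the whole suite stays
comfortably desk-scale.

## Known limitations

* Opsin kinetics are not modeled: the schedule is the commanded light, not
  the evoked spiking; fidelity of a given channelrhodopsin variant to a
  given pattern is the user's experimental question.
* Proprietary sorter formats (MClust, Spike2, NEX) are not parsed; the
  toolkit consumes plain-text timestamp exports.
* Which ISI features actually encode reward is an open scientific
  question; the package exposes seeds and provenance precisely so
  alternative surrogates can be generated and tested, and makes no claim
  beyond the algebra of the patterns themselves.
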