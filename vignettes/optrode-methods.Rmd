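---
title: "Quantifying optogenetic control of single units: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optogenetic control of single units: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optrode)
```

optrode quantifies how well light controls a single extracellularly
recorded neuron expressing an excitatory opsin (ChR2-class: brief blue
pulses evoke spikes) or an inhibitory opsin (NpHR-class: continuous green
light suppresses spiking). The measurement chain is: a voltage trace
sampled at 20 kHz and a TTL light-command channel come in; the trace is
band-pass filtered and thresholded into a spike train; spikes are aligned
to the light events; and per-pulse spike probability, first-spike latency,
peristimulus histograms, silencing/rebound metrics and an
autocorrelogram-based firing-pattern classification come out. Because
public single-unit datasets rarely ship with ground truth, the package
also contains a generator of synthetic sessions in which every spike's
provenance is known; all statistical guarantees quoted below are
established against that ground truth.

## The synthetic session model

The generator works event-first: spike times are drawn from point-process
models, a refractory floor of 2 ms is enforced (a physiological lower
bound for well-isolated units, and it makes ground truth unambiguous for
a detector), and only then is a voltage trace rendered as i.i.d. Gaussian
background noise plus one fixed biphasic template per spike.

**Template.** `spike_waveform()` builds a sharp half-sine lobe carrying the
full (negative, by extracellular convention) amplitude over half the
nominal width, followed by a broader opposite lobe of one third the
amplitude over 1.5 widths, rescaled so the sampled template integrates to
zero — the shape a tungsten microelectrode reports near a soma, reduced to
its two load-bearing properties (amplitude and compact biphasic support).
The template is inserted trough-aligned: a spike's ground-truth time marks
its extracellular extremum, which is exactly the feature an
amplitude-threshold detector time-stamps, so latency statistics carry no
systematic template-phase offset.

**Spontaneous firing.** Homogeneous Poisson at `spont_rate_hz`, or — for
"phasic" units whose network drive is rhythmic — an inhomogeneous Poisson
process with rate $r(t) = r_0\,(1 + m \sin 2\pi t / P)$, sampled by
thinning. The period default $P = 0.5$ s and depth default $m = 0.8$ are
package choices on the slow-oscillation timescale seen under anaesthesia;
nothing in the analysis depends on them being exact.

**Evoked spiking.** Each pulse evokes at least one spike with probability
`evoked_prob`; the latency is a truncated Gaussian on (0, inter-pulse
interval]. The configured `latency_mode_ms` names the modal *1 ms
histogram bin* — the resolution onset latencies are conventionally read
at — so the Gaussian is centred at `latency_mode_ms + 0.5` ms; centring it
exactly on the integer would park the density maximum on a bin edge and
make the modal bin an ill-posed coin flip. With probability `doublet_prob`
a second evoked spike follows 3–8 ms after the first. Doublets are the
mechanism by which mean spikes-per-pulse exceeds 1, the regime strongly
driven units show in repeated 20 Hz stimulation.

**Silencing and rebound.** Under continuous light, each would-be
spontaneous spike inside a light-on interval is deleted with probability
`silencing_efficacy`; survivors are breakthrough spikes. After each light
offset the rate is multiplied by
$1 + (g - 1)\,e^{-(t - t_\mathrm{off})/\tau}$ with `rebound_gain` $g$ and
`rebound_tau_s` $\tau$ (default 0.1 s, the ~100 ms timescale on which
post-inhibitory rebound excitability is expected, e.g. from
hyperpolarisation-activated inward current). The default efficacy 0.98
follows from the arithmetic of third-generation halorhodopsin silencing:
at ~1 Hz spontaneous rate over 10 s trials, the expected number of
escaping spikes is $10\,(1-\epsilon)$, and $\epsilon \approx 0.98$ puts
the per-trial breakthrough probability near
$1 - e^{-0.2} \approx 18\%$ — the "mostly complete, occasional
breakthrough" regime these experiments report.

What the generator deliberately does *not* model: biophysical photocurrent
kinetics, multi-unit waveform overlap or sorting ambiguity, electrode
drift, and non-stationary excitability. Tests passing on this generator
therefore certify the *analysis* (alignment, counting, binning,
estimation), not robustness to every pathology of real recordings.

## Filtering and detection

`bandpass()` applies a 4th-order Butterworth band-pass (two poles per
edge, 300–8000 Hz defaults) forward and backward (`signal::filtfilt`).
Zero-phase filtering matters here: a causal filter's group delay would
shift every detected spike and bias the latency mode. The squared
magnitude response leaves a 1 kHz tone within 1 dB and attenuates 50 Hz
by far more than 20 dB, which the tests verify empirically.

`estimate_noise_sd()` uses the median-based robust scale
$\hat\sigma = \mathrm{median}(|x|)/0.6745$, standard in extracellular work
because spikes occupy a small fraction of samples and barely move the
median, while they would inflate a naive SD badly.

`detect_spikes()` thresholds at $k\hat\sigma$ (negative-going by default),
emits one event per threshold excursion, time-stamps it at the waveform
extremum within the dead time (1 ms default), and enforces the dead time
between events. The choice of $k$ is a false-positive budget, not a
constant of nature: Gaussian noise crosses $4\sigma$ about
$3.2\times10^{-5}$ per sample one-sided, i.e. ~0.6 crossings *per second*
at 20 kHz. The default `threshold_k = 4` reflects common practice for
short, visually supervised snippets; for minute-scale unsupervised runs
the package's own analyses use $k = 5$, where the expected count of noise
crossings over $2\times10^6$ samples drops below one and measured
precision and recall both exceed 0.99 at signal-to-noise 10. Users should
scale $k$ with $\sqrt{2\ln N}$ in mind, where $N$ is the sample count of
their record.

## Alignment statistics

**Response window.** The per-pulse spike count uses the full inter-pulse
interval $[t_\mathrm{on}, t_\mathrm{on} + \mathrm{IPI})$ as the response
window (the last pulse of a train reuses the same width). A short fixed
window with an at-most-one count could never produce the above-1 spike
probabilities that strongly driven units show; counting every spike in
the interval is the only convention consistent with them.

**Mean probability and its SEM.** The headline mean is taken over pulse
positions 1..P (each position first averaged across trains); its SEM is
computed across positions by default, matching the "probability in
response to each of the P pulses" framing, with SEM across trains exposed
as an option since both populations are defensible.

**Latency mode.** First-spike latencies are binned at 1 ms into half-open
bins $[k, k+1)$ anchored at zero; the mode is the centre of the fullest
bin, ties broken toward the shorter latency (earlier activation is the
conservative claim). Binning uses a $10^{-9}$ relative guard so that
decimal times sitting on a binary-representation edge (e.g. a latency of
exactly 20 ms stored as 0.019999999999999997 s) land in the bin their
decimal value names.

**Silencing.** Per trial, rates are computed over
$[t_\mathrm{on} - 5\,\mathrm{s}, t_\mathrm{on})$, the light-on interval,
and $[t_\mathrm{off}, t_\mathrm{off} + 5\,\mathrm{s})$ (5 s matching the
baseline convention of the emulated protocols; both windows are
configurable and are truncated with a warning when trials crowd closer
than the requested windows). A trial is a breakthrough trial iff at least
one spike falls in the light-on interval — an exact set-membership count,
which is why the reported fraction must (and does, in tests) equal the
generator's logged ground truth exactly. The rebound index is the
post/pre rate ratio; `rebound_profile()` gives the 100-ms-resolution time
course. No significance test is attached: at five-trial scale a rebound
claim is descriptive, and the package declines to dress it up.

## Autocorrelogram and phasic classification

`autocorrelogram()` counts *all* ordered pairs $(i < j)$ with
$t_j - t_i \le$ 2 s — consecutive and non-consecutive — into 20 ms
half-open bins over positive lags. An interval histogram restricted to
consecutive pairs would lose the slow periodicity that distinguishes
phasic units; the all-pairs count is what makes rhythm visible as peaks
at multiples of the period. The implementation accumulates order-$k$
differences of the sorted times until they exceed the maximum lag, which
is $O(n \cdot r \cdot \mathrm{maxlag})$ rather than $O(n^2)$, and is
tested for exact equality against the brute-force all-pairs count.

For classification, the flat-baseline expectation of an unmodulated train
is estimated as the mean count over the upper half of the lag range, and
a unit is phasic when any bin at lag ≥ 2 bins exceeds baseline plus
$z\sqrt{\mathrm{baseline}}$ — Poisson counting noise, *not* the empirical
SD of the tail bins. The distinction is load-bearing: a coherently
rhythmic train modulates its ACH at all lags, so the tail SD of a truly
phasic unit contains the full oscillation amplitude and an
empirical-spread test would be blind to exactly the units it is meant to
find. The default $z$ is Bonferroni-corrected over the ~98 tested bins at
family-wise level $\alpha = 0.01$ ($z \approx 3.7$); an uncorrected
$z = 3$ across ~100 bins would miscall roughly one in eight Poisson
units. Under these defaults, measured specificity and sensitivity on
10,000-spike trains (depth 0.9, period 0.5 s for the phasic regime) are
both above 95% over 100 seeds. Reported peak lags are the maxima of
contiguous significant runs, excluding the run adjoining the lowest
testable lag — that run is the shoulder of the central zero-lag peak, not
evidence of rhythmicity at its own lag. Histograms with fewer than 100
pairs are declared unclassifiable rather than guessed at.

## Numerical and interface conventions

- Time is seconds from record start; all windows are half-open
  $[\mathrm{start}, \mathrm{end})$; TTL onset is the time of the first
  high sample.
- Voltage is microvolts throughout; the session container stores 32-bit
  floats (round trips are exact after the first quantisation).
- Determinism: a `synth_config` seed fixes trace, TTL and ground truth
  bit-for-bit; the YAML manifest written next to every simulated session
  regenerates it exactly.
- Degenerate inputs are contracts, not surprises: empty TTL gives an
  empty schedule, zero detections is a valid result, an all-zero trace
  has noise SD 0, fewer than two spikes give an all-zero ACH.

## Problem sizes used in the shipped analyses

The package's own validation runs (test suite and `scripts/acceptance.R`)
use sessions sized so each statistic is measured where its guarantees
bind while remaining comfortable to re-run: 100 s of 20 kHz trace
(~1000 spikes) for detection accuracy; 10 trains × 100 pulses per
fidelity regime; 20 trains × 100 pulses (2000 latencies) for the latency
mode; 30 × 10 s trials for silencing; 10,000-spike, 1000 s trains and 100
seeds per class for the classifier's error rates. The full two-hour,
61-train protocol is exercised at the schedule level (6100 pulses) with
event-level generation, which is exact for every alignment statistic.

## Known limitations

- Single-unit world: no sorting, no overlap resolution; on multi-unit
  records the detector returns the superposition.
- The classifier targets coherent rhythmicity; burst-only units (central
  ACH peak, no recurring peaks) are reported phasic by the
  any-significant-bin rule even though their peak list is empty —
  inspect `peak_lags_s` when the distinction matters.
- Rebound modelling is phenomenological (an exponential rate multiplier),
  adequate for testing the metric, silent on mechanism.
- Imported timestamp tables are trusted as-is apart from sorting and
  deduplication; no re-detection is attempted when only timestamps are
  deposited, and probabilities computed from them inherit whatever
  detection rule produced them.
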