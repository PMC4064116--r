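---
title: "Cycle-resolved analysis of thalamic sleep spindles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-resolved analysis of thalamic sleep spindles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(spindlr)
library(dplyr)
```

## The scientific problem

Sleep spindles are transient 7--15 Hz oscillations generated in the
thalamus by a "ping-pong" loop: thalamocortical (TC) relay cells fire
rebound bursts that drive the inhibitory nucleus reticularis thalami (nRT),
whose GABAergic feedback in turn triggers the next TC rebound, one burst
per cell per cycle, with nRT firing lagging TC by roughly 15--20 ms.
Multi-shank extracellular recordings in the ventrobasal thalamus see both
sides of this loop: TC somata as wide spikes (half-amplitude width above
150 µs, mode near 275 µs) and nRT axon terminals as narrow spikes (mode
near 100 µs).

`spindlr` packages the complete cycle-resolved analysis of such
recordings -- spindle detection from smoothed multiunit activity (MUA),
Morlet-phase cycle segmentation, spike-width unit classification,
per-cycle population metrics (participation probability, spikes per burst,
jitter, cross-correlograms, phase locking), trajectory-level correlation
statistics, and optogenetic evoked-spindle analyses -- together with a
synthetic spike-train generator that reproduces the statistical structure
the analysis assumes, with full ground truth. Because no public recordings
accompany this line of work, the generator is the package's reference
input: every stage can be validated by parameter recovery against known
ground truth.

## The generator and its trajectory table

The generator is driven by a *trajectory table*: for every spindle-length
category $k = 5..14$ cycles and cycle index $c$, the participation
probability $p(k, c)$ (probability that a unit of the class fires at least
one spike in the cycle), the conditional burst size $b(k, c)$ (mean spikes
given participation) and their product, the unconditional spikes per cycle
$s(k, c) = p \cdot b$. These three quantities are the core measurables of
the cycle-resolved analysis, and the identity $s = p\,b$ is enforced
everywhere (generator invariant, metric invariant, and test).

`default_trajectories("natural_sleep")` encodes the canonical picture:

* **nRT, short spindles** start at high recruitment -- $s(6, 1) = 3.5$
  spikes/cycle, 60% first-cycle participation for the shortest category --
  and decline monotonically to $s(6, 6) = 1.55$.
* **nRT, long spindles** start lower ($s(14, 1) = 2.1$), peak at cycle 3
  ($s(14, 3) = 3.15$) and collapse to $s(14, 14) = 0.83$ by termination.
* **TC cells** ramp up slowly (participation 35--40% to 40--45%) with a
  flat burst size of 3.19 spikes.

Between these anchor values the table interpolates linearly across cycles;
across length categories the first-cycle and last-cycle nRT participation
follow concave/convex power curves in $k$ chosen so that the ten category
means carry the intended correlation structure: first-cycle nRT
participation correlates with length at $r = -0.91$, first-versus-last nRT
participation at $r = 0.88$, and TC first-cycle participation carries a
weak positive trend ($r = 0.63$, via a small frozen deviation vector
orthogonal to the trend). These correlations are properties of the *table*;
the package's statistics recover them from simulated data.

One consequence of anchoring $s$ and $p$ jointly is that the implied nRT
burst sizes at cycle 1 come out at 6--7 spikes rather than the often-quoted
"approximately five"; the published per-cycle quantities are not mutually
consistent under $s = p\,b$, and we chose to honour $s$ and $p$ exactly
(they are the recovery targets) and let $b = s / p$ follow. The
characteristic decline of nRT burst size toward 3--4 spikes at termination
is preserved.

### Event timing

Cycle-peak times follow the base period $1/f_0$ ($f_0 = 12.65$ Hz by
default) scaled by a mean-one profile with ±8% depth: under natural sleep,
periods shorten over the first cycles and lengthen again before the end;
under urethane they shorten monotonically. Normalising the profile to mean
one keeps the mean intra-spindle frequency exactly $f_0$. Spindle lengths
are drawn from linearly increasing weights over 5--14 cycles with mean 10.7
cycles/spindle. Events are placed with a minimum 0.5 s gap and never
truncated at the session end.

### Spike placement

A participating unit fires one burst per cycle: a shifted-Poisson spike
count (mean matched to $b(k,c)$, minimum 1), a fixed intra-burst
inter-spike interval (6.7 ms for TC, 8 ms for nRT), centred on the cycle
peak (TC) or the peak plus the 17 ms TC-to-nRT lag (nRT), with 4 ms
Gaussian jitter of the burst centre. Bursts are shifted, when necessary, to
lie entirely inside their generating cycle window, so that ground-truth
participation flags equal an exact recount of spikes per unit per cycle.
The nRT intra-burst interval is deliberately shorter than the intra-burst
frequencies reported for nRT cells in vivo (~49 Hz), because at that rate a
5--7 spike burst would span more than one 79 ms cycle, contradicting the
one-burst-per-cycle bookkeeping the analysis (and the table) relies on.

Background firing is homogeneous Poisson per unit (1.5 Hz TC, 4 Hz nRT by
default) and is suppressed inside spindle events on the event's shank(s):
during spindles thalamic units fire exclusively in their low-threshold
bursts, and this makes the trajectory table directly measurable. Spike
widths are drawn from Normal(275, 40) µs for TC and Normal(100, 15) µs for
nRT, truncated positive, making the classes separable at the 150 µs
boundary with error below 0.5%.

Determinism: a session is fully reproducible from `(config, trajectories,
seed)`; a single RNG stream per session is used (the per-unit stream
refinement was judged not worth a hand-rolled counter-based RNG since the
reproducibility contract holds either way).

## Detection and cycle segmentation

Detection works on the smoothed MUA of one shank: spikes are binned at
`dt = 2 ms` and convolved with a 10 ms-SD Gaussian kernel (unit area per
spike, so the trace integrates to the spike count). The trace is band-passed
at 7--15 Hz with an FFT filter with raised-cosine transitions (a narrow-band
IIR at this band/sampling-rate ratio is numerically marginal, and the FFT
filter is exactly zero-phase), and the analytic-signal envelope is
thresholded at the baseline median plus 2 robust SD. Baseline statistics
are computed in two passes, excluding supra-threshold samples, so the
spindles themselves do not inflate the threshold. Runs are merged across
gaps below 100 ms.

Each candidate event is segmented into cycles by the phase of a complex
Morlet transform (6-cycle wavelets, L1-normalised, frequencies scanned in
0.5 Hz steps over 7--20 Hz; at each sample the scale with maximal magnitude
provides phase and frequency, and an oscillation peak is phase zero).
Candidate cycle peaks -- phase crossings of multiples of $2\pi$ -- are then
validated against the raw MUA: the locally averaged rate (±20 ms) at the
peak must exceed the baseline rate median by 3 robust SD, and successive
peaks must be 50--143 ms apart (the spindle band's period range, which also
guarantees that every detected event's cycle frequencies lie in 7--20 Hz).
The longest consecutive stretch of validated peaks defines the event:
`n_cycles` is the number of peaks, the onset/offset close the first/last
cycle half a local period outside the outermost peaks, and cycle boundaries
are midpoints between peaks. Events with fewer than 5 cycles are discarded.
All windows are half-open; a spike exactly on a boundary belongs to the
later cycle.

The published detection this replaces was semiautomatic with visual
verification; the deterministic criteria above were tuned once against
simulator ground truth and are exposed in `detection_config()`. On default
synthetic sessions the detector recovers >95% of events with median onset
error ~4 ms, counts cycles exactly in ~96% of events, and produces no
false events in spindle-free background at <1/min.

## Cycle metrics

`cycle_metrics()` computes, per (event, cycle, population): spikes per
cycle (mean spike count over eligible units), participation (fraction of
units with ≥1 spike -- any spike counts, not only burst spikes, which is
what makes the conditional burst size $s/p$ well-defined), conditional
spikes per burst, and jitter (population SD, divisor $n$, of spike-time
offsets from the cycle peak; the "spindle peak" is the segmented cycle peak,
one of the two readings of the published definition). Pooling follows the
"across all cells in all animals" convention: category means over all
events of a length, unweighted.

Per-cycle cross-correlograms use TC spikes inside the cycle as references
and all nRT spikes within ±50 ms as targets (1 ms bins). The reported peak
latency is the count-weighted centre of mass of the bump (iteratively
re-centred around the smoothed mode, found at *positive* lags): nRT
follows TC in the ping-pong loop, the negative window edge can carry the
tail of the previous cycle's nRT burst, and the burst-burst convolution
makes the lag distribution a broad plateau on which a raw argmax is
unstable even at large pair counts. Phase locking assigns each
in-event spike a linearly interpolated phase between surrounding cycle
peaks (one cycle = 360°) and reports the circular mean and resultant
length; with the default lag the nRT-minus-TC angle is
$360° \cdot 17 / 79 \approx 77°$.

The spatial profile (`spatial_ccg_profile()`) quantifies, for shank-local
events, the TC→nRT CCG modulation at shank offsets 0--3: the pair mass in a
peak region centred on the pooled same-shank latency divided by the mass
expected under independence, estimated from uniformly resampled surrogate
target trains (finite even with zero background). Flat (independent)
activity gives modulation 1 by construction.

## Trajectory statistics

Correlations are computed on the 10 per-length category means (one dot per
category, unweighted), Pearson for first-cycle-versus-length and
first-versus-last, Spearman (mid-ranks) for trend tests across cycles;
a zero-variance input returns $r = 0$, $p = 1$ by convention. Two-group
comparisons use the Mann-Whitney U test, three or more use Kruskal-Wallis.
No multiple-testing correction is applied, matching the original analysis
style; treat the p-values accordingly.

## Optogenetic analyses

`simulate_opto_session()` delivers laser pulses every 5 s; pulses in
permissive network epochs evoke a spindle with probability given by a
saturating logistic in log10 intensity (maximum 0.56, half-saturation
0.5 mW, slope 5 per decade, hard threshold 0.1 mW -- at 10.5 mW the curve
reaches 0.559), at a uniform latency within a 300 ms response window.
Evoked lengths are drawn independently of the stimulus. Overlapping events
are resolved by suppressing the later onset. `match_evoked()` links each
event beginning within the response window to the earliest qualifying
pulse (at most one event per pulse); everything else is spontaneous, and
the two sets partition the events exactly.

Because spontaneous spindles both collide with evoked ones (suppression)
and occasionally fall inside response windows (spurious matches), the
*measured* evoked fraction is attenuated at high spontaneous rates; the
package's evoked-probability analyses therefore use a low spontaneous rate
(2/min), while comodulation analyses use a dense-spindling condition
(8/min) where many spontaneous neighbours exist. This mirrors running
separate experimental sessions for the two questions.

The comodulation of spontaneous and evoked spindle lengths is
operationalised as the Pearson correlation between each evoked spindle's
length and the mean length of spontaneous spindles within ±15 s (the
pairing rule is the package's choice; the original report does not state
one). A shared sinusoidal modulation of the length mean (120 s period)
with amplitude 1.6 cycles -- calibrated once by simulation -- yields
$R \approx 0.21$ under this rule, and $R \approx 0$ when disabled. The
generator does not modulate spindle *rate*, so the weak density-versus-
length correlations seen in vivo (~0.1) are expectedly absent from
synthetic sessions; `comodulation()` still computes them.

## What the generator does and does not emulate

Emulated: spindle-band rhythmicity of pooled MUA with realistic cycle-count
and frequency statistics, length-specific cycle trajectories of both
populations, the fixed TC→nRT lag and its phase expression, bimodal spike
widths, multi-shank locality (local versus global events), burst structure
with one burst per cell per cycle, permissive/non-permissive state gating
and intensity-dependent evoked probability with stimulus-independent
lengths.

Not emulated: raw voltage traces and LFPs (everything starts from spike
times), spike-sorting artefacts and cluster contamination, non-Poisson
background (UP/DOWN states, slow oscillations), drifting oscillation
frequency across events, rate comodulation, inter-animal variability, and
conductance-level biophysics. Passing tests therefore certify the analysis
chain and its statistical behaviour on data with the assumed structure --
not robustness to every pathology of real recordings.

## Problem sizes and numerical choices

The package's own validation runs use ~5,000 detected spindles (ten
2,500 s single-shank sessions with 12 TC + 12 nRT units), which puts the
Monte-Carlo SE of the anchor category means at roughly 0.03--0.08
spikes/cycle; correlation recovery uses the same run. Stationarity checks
use 50 replicate 400 s sessions with a constant trajectory table;
evoked-probability recovery uses 1,200 pulses per intensity level.
These sizes were chosen to make recovery tolerances a small multiple of
the Monte-Carlo error while keeping a full validation run in minutes on a
single core.

Numerical conventions worth knowing: all event/cycle intervals are
half-open; cycle indices are 1-based in every output; times are seconds
(decimal text with ≥6 fractional digits in CSV); the autocorrelogram is
built from positive lags and mirrored, so it is exactly symmetric with the
zero-lag bin excluded; envelope and rate baselines use median/MAD
statistics; correlation guards return $r = 0$, $p = 1$ on zero variance;
Spearman tests use the t approximation with mid-ranks.

## Known limitations

* Cycle counting degrades gracefully but not perfectly (~4% of events off
  by one cycle at default SNR); category contamination biases the pooled
  anchor means by well under the Monte-Carlo error at validation scale.
* The conditional burst size inherits any participation bias
  ($b = s / p$), so it is the least robust of the three trajectory
  measures in small samples.
* `spatial_ccg_profile()` assumes event windows mark true locality; with
  global events mislabelled as local its modulation contrast shrinks.
* The comodulation pairing rule and window are package choices; other
  reasonable rules shift $R$ by tens of percent, which is why the
  amplitude was calibrated under the package's own rule.
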