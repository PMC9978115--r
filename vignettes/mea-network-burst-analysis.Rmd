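---
title: "Burst and network-burst analysis of MEA spike trains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst and network-burst analysis of MEA spike trains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## The problem

Cultured neuronal networks on microelectrode arrays (MEAs) develop, over
weeks in vitro, from sparse uncorrelated firing to a regime dominated by
*network bursts*: brief episodes in which many electrodes fire densely and
near-simultaneously, separated by quiescent intervals. Quantifying that
development — and how it responds to perturbations such as chemogenetic
silencing of excitatory transmission — requires (i) detecting bursts on
single electrodes, (ii) detecting network bursts on the pooled spike train
of the whole well, (iii) summarizing each recording with a small vector of
activity and synchrony metrics, and (iv) comparing experimental groups with
statistics appropriate for 5–6 networks per group. `meaburst` implements
that pipeline, together with a synthetic-recording generator with planted
ground truth, so that every stage can be validated with known answers.

The package starts from spike times. Spike detection from raw voltage is
performed upstream by the acquisition system and is out of scope, as is
spike sorting.

## Detection model

**Per-electrode bursts.** A burst is a maximal run of at least 4 spikes on
one electrode whose every inter-spike interval (ISI) is strictly below
100 ms. Both values are the classical fixed-threshold settings and are
exposed via `burst_params()`. Burst boundaries are the first and last
member spikes, so a burst's duration contains no padding. "Strictly below"
matters only for ties at exactly the threshold; we resolve them by
exclusion, consistent with a rule phrased as "lower than a threshold".

**Network bursts.** On the flattened train (all electrodes pooled and
time-sorted, `flatten_recording()`), we compute the span of every 6
consecutive spikes, `ISI6(i) = t[i+5] - t[i]`. We take the *span* (5 gaps)
as the ISI_N convention; the clamp bounds of 12–300 ms are dimensionally
sensible for a span, not for a mean gap. In a bursting culture the
log-histogram of ISI6 is bimodal: an intra-burst mode (sub-millisecond to a
few ms) and a background mode (hundreds of ms). The detection threshold is
the midpoint of the two modes on the log scale — the geometric mean of the
peak locations — clamped to [12, 300] ms. Spikes covered by any ISI6
window below the threshold are in-burst; maximal unions of *overlapping*
marked windows form candidates, and candidates with at least 6 spikes are
reported with their electrode participation. Overlapping (not merely
adjacent) is deliberate: two planted events separated by a quiet gap share
no spike and must never merge, which we verify by construction in tests.

Numerical choices in the threshold adaptation, none of which are canonical
in the literature and all of which are exposed in `nb_params()`:

| parameter | default | role |
|---|---|---|
| `bins_per_decade` | 10 | log10 histogram resolution |
| `smoothing_width` | 3 bins | centred moving average before peak finding |
| `min_prominence` | 5% of max | ignores ripple peaks |
| `fallback_threshold` | 100 ms | used when < 2 peaks exist, flagged |

Peaks are local maxima of the smoothed counts (`>` on the left, `>=` on the
right, so a flat-topped peak registers at its left edge — at 10 bins per
decade this biases a peak location by at most one bin, a factor of
10^0.1). The lowest-span peak is taken as the intra-burst mode and paired
with the *tallest* peak at strictly larger span; zero spans (exact
cross-electrode ties) have no logarithm and are dropped from the histogram
only — they still mark spikes during detection. When the histogram is
unimodal (very quiet or very regular recordings) the fixed 100 ms fallback
is used rather than failing the recording, and the diagnostics object
records `fallback_used`.

Per-electrode bursts are detected on each electrode's own train; network
bursts on the flattened train. Where a summary table of detection
parameters could be read as applying the 100 ms rule to the cumulative
train instead, we expose both routes (`detect_bursts()` accepts either a
recording or a bare numeric train) and use per-electrode as the default
for burst statistics. ISI6 is computed at every spike index (overlapping
windows), not at disjoint strides.

## Metrics

* **Recording spike frequency** per channel: `f = (spikes - 1) / dt`, with
  `dt` the time from first to last spike on the channel. The recording's
  mean firing rate averages `f` over *active* electrodes.
* **Active electrodes**: at least 0.1 Hz overall (6 spikes/min),
  configurable. The count `n` of active electrodes is fixed per recording
  and used as the denominator for every window.
* **Instantaneous spike frequency**: `f_window = spikes / (n * width)` on a
  1 s window stepped by 0.1 s, windows starting at 0 up to
  `duration - width` inclusive, membership half-open `[start, start+width)`.
* **Burstiness index**: spike counts per window; `f15` is the share of
  total windowed activity in the `ceiling(0.15 W)` highest-count windows
  (ties broken toward earlier windows). Because the top 15% of windows
  always carry at least their proportional share, `f15` is bounded in
  [0.15, 1]; we report the rescaled `BI = (f15 - 0.15) / 0.85` in [0, 1]
  as the headline value and keep raw `f15` alongside, matching the
  normalization used in the burstiness-index literature.
* **Coherence index**: population standard deviation of the `f_window`
  series divided by its mean. Population, not sample: the series is a
  complete description of one recording, not a sample from it (at ~10^4
  windows the distinction is negligible anyway).
* **Composition**: mean burst duration; mean IBI (the gap from one burst's
  end to the next burst's start, averaged *within* each electrode with at
  least two bursts and then across electrodes, so burst-rich electrodes do
  not dominate); mean NIBI analogously on network bursts; fractions of
  spikes inside burst / network-burst intervals; spikes-per-burst
  occurrence histograms. Undefined quantities (one burst, no bursts) are
  `NA`, never 0.

A note on time shifts: metrics defined through spikes alone (rates, ISIs,
burst statistics, fractions, the adaptive threshold) are invariant under a
common time offset. The windowed metrics are not, and should not be: a
recording that begins with dead time genuinely has more quiet windows, and
the burstiness and coherence indices see that.

## Group statistics

For one metric at one timepoint, all groups pass through a Shapiro–Wilk
gate: the family is treated as normal only if *every* group has p >= 0.05
(the conservative reading of "assessed for normality"; groups with n < 3 or
constant values force the non-normal route). Normal families use Welch's
unequal-variance t-test per pair; non-normal families use the Conover–Iman
pairwise rank test: joint midranks, the tie-corrected Kruskal–Wallis
statistic `H`, pooled rank variance `S2`, and

```
t_ij = (Rbar_i - Rbar_j) / sqrt( S2 * (N - 1 - H)/(N - k) * (1/n_i + 1/n_j) )
```

referred to Student's t with `N - k` degrees of freedom, two-sided. No
continuity corrections are added: with 5–6 networks per group the standard
definitions are used as-is. Raw p-values are Bonferroni-corrected over the
family of all `choose(k, 2)` pairs within one metric-timepoint — the
minimal family consistent with reporting per-day pairwise p-values. Whether
correction should also span timepoints is a study-design question; the
family is therefore an explicit argument of the workflow, not a hidden
constant. `type_i_calibration()` measures the family-wise error of the
whole gate-plus-test-plus-correction procedure under a simulated null; with
three groups of six it sits visibly below the nominal 5% (Bonferroni is
conservative, and the gate switches between two exact-null tests).

The Conover–Iman implementation is validated in the test suite against a
label-permutation null of its own statistic (10,000 shuffles); the
agreement tolerance of 0.03 covers ~3 Monte-Carlo standard errors plus a
small allowance for the t-approximation at n = 8 per group.

## The synthetic generator

`simulate_recording()` superimposes, per electrode, homogeneous-Poisson
background firing and planted network bursts: onsets form a Poisson process
thinned to a minimum spacing of two expected burst spans (so planted events
never merge ambiguously); each onset recruits
`ceiling(participation * n_electrodes)` electrodes uniformly without
replacement; each recruited electrode emits `max(1, Poisson(mean))` spikes
with exponential intra-burst ISIs truncated below at a 1 ms refractory
floor, starting at the onset plus Gaussian jitter. Inhibition can be
modelled two ways: as a rate multiplier inside an interval at generation
time (optionally ramping back to 1 over a recovery interval), or as
post-hoc spike thinning (`apply_inhibition()`), the operational effect of
chemogenetic silencing on recorded activity. Randomness is hierarchical —
every electrode and every event draws from a child stream of the single
seed — so identical seeds give byte-identical recordings and enlarging the
array leaves existing trains untouched.

Defaults describe one 20-min recording of a mature 64-electrode culture
(background 0.5 Hz/electrode, 0.05 network bursts/s, 60% participation,
12 spikes per electrode per burst, 4 ms intra-burst ISIs, 5 ms onset
jitter). Three presets span the developmental ladder — `asynchronous-tonic`
(no events, 2 Hz tonic firing), `mature-bursting` (the defaults), and
`hypersynchronous` (0.15 events/s, 95% participation, tighter jitter) —
with participation and event rate strictly increasing along the ladder, so
the burstiness and coherence indices must increase along it too, which the
tests assert over repeated seeds.

What the generator does *not* emulate: refractory structure of background
spikes, burst-internal rate envelopes (accelerando/decelerando), electrode
heterogeneity, slow nonstationarity, or any biophysics of the
excitatory/inhibitory balance. Passing tests therefore demonstrate that the
detectors and metrics recover what they are defined to recover, not that
they are optimal on real recordings.

Two inherent behaviours of the detection rule are worth knowing. First, a
*coincidence floor*: with pooled background rate `r`, the probability that
6 background spikes fall within the 12 ms clamp floor is
`P(Gamma(5, r) < 0.012)` per spike; at 64 electrodes times 0.5 Hz this
yields on the order of one spurious 6-spike event per 10 minutes, which is
material when false-discovery budgets are tight. Second, *fragmentation*:
planted events with exponential ISI tails occasionally detach a straggler
clump from the dense core, which interval-based matching then counts as an
unmatched detection. Both effects are visible in the validation numbers and
are properties of the rule, not bugs in its implementation.

## Problem sizes

The validation suite chooses sizes that exercise each property at
meaningful scale: detector-oracle equivalence on 1000 random trains of up
to 200 spikes; planted-event recovery on ten 600 s, 64-electrode
recordings; burstiness calibration on twenty 600 s Poisson recordings;
preset ordering on ten 120 s recordings per preset; statistical calibration
on 2000 simulated families; the orchestration checks on 8-electrode, 60 s
recordings where only bookkeeping (not signal quality) is under test.

## Workflow

```{r, eval = FALSE}
# simulate a study-shaped experiment: 6 DCZ, 5 PBS, 6 CTRL networks
res <- run_experiment(study_manifest(), seed = 1)
summarize_metrics(res$metrics)
res$comparisons

# or analyse a single recording from a spike table
rec <- read_spike_table("spikes.csv", duration = 1200)
met <- compute_metrics(rec)
met$network_bursts
```

Phases are first-class analysis units: passing
`phase_plan = treatment_phase_plan()` to `run_experiment()` splits each
recording into three 20-min phases, and the adaptive ISI6 threshold is
re-estimated per phase, since the appropriate threshold changes with the
activity state.

## Known limitations

* Only the two detection rules above are implemented; MaxInterval,
  Poisson-surprise and related burst detectors are out of scope.
* No spectral or cross-correlation synchrony measures.
* No repeated-measures or mixed-effects modelling across days in vitro;
  every metric-timepoint family is tested independently.
* The pipeline implements no network-exclusion logic; what goes into the
  manifest is what is analysed.
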