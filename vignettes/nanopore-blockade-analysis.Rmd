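---
title: "Nanopore blockade analysis: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanopore blockade analysis: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreblock)
```

## The measurement

A single alpha-hemolysin pore in a lipid bilayer under a +100 mV holding
potential passes a steady open-pore ionic current of order +100 pA. When a
protein such as alpha-synuclein encounters the pore it blocks part of that
current for a while: each encounter is a *blockade event* with an amplitude
*I* (a negative deflection, pA) and a dwell time *T* (ms). Three kinds of
encounter are distinguishable in (I, T) space:

* **translocation** — the chain threads the pore: deep blockade
  (about -85 pA for full-length alpha-synuclein) and long dwell
  (characteristic time about 0.5 ms);
* **bumping** — the chain collides with the pore mouth and diffuses away:
  shallow blockade (about -30 pA) and short dwell (about 0.05 ms);
* **intercalation** — the chain lodges in the vestibule and retreats:
  intermediate blockade.

A drug that binds and folds the protein shifts events from the
translocation peak into the bumping peak; which end of the protein it grips
is read off a panel of domain constructs (N-terminus, C-terminus, and the
NAC-deletion mutant). N-terminal-only binding leaves the aggregation-prone
NAC region exposed (a "knot"); binding that bridges both termini shields it
(a "loop"). `poreblock` implements this whole chain of reasoning as a
tested pipeline: event detection, population and dwell-time fitting,
replicate statistics, and binding-mode inference, plus a ground-truthed
simulator so every stage is testable without instrument data.

## The synthetic generator

`condition_model()` bundles per-class generative parameters
(`class_model()`: mixture weight, amplitude mean and SD, exponential dwell
scale) with acquisition parameters. The defaults are the study conditions
used throughout the package's validation:

| parameter | default | why |
|---|---|---|
| classes (full-length protein alone) | translocation 66 : bumping 24 (renormalized), -85 / -30 pA, 0.52 / 0.05 ms | published triplicate measurements of alpha-synuclein on alpha-hemolysin |
| baseline current | +100 pA | typical alpha-hemolysin open-pore magnitude at +100 mV; blockades are negative deflections |
| sampling rate | 100 kHz | 10x oversampling of the filter so 0.05 ms bumps span ~5 samples |
| filter | Gaussian kernel, -3 dB at 10 kHz | recording bandwidth; simple, monotone step response |
| noise | white Gaussian, SD 1.5 pA before filtering | SNR >= 15 for the shallowest (-30 pA) class |
| event rate, duration | 25 /s, 80 s | ~1900 events per replicate, so each replicate alone supports population and dwell fits; a bumping subpopulation of ~500 events resolves its 0.05 ms time scale |
| dead time | 1 ms between events | recordings are analyzed as well-separated events; overlap handling is out of scope |
| intercalation dwell scale (presets) | 0.2 ms | intermediate between bumping and translocation; not a measured value |

Event arrivals are Poisson with the dead time enforced; dwell times are
exponential; amplitudes Gaussian (resampled in the rare case a draw is
non-negative). Rendering places each event as a rectangle with
fractional-sample edge weighting, adds the noise, and applies the Gaussian
filter, whose standard deviation is `sqrt(ln 2) / (2 pi bandwidth)`.
A master seed derives independent per-replicate streams (`derive_seed()`),
so triplicate experiments are individually reproducible.

What the generator deliberately does **not** emulate: baseline drift and
1/f noise, pore gating and clogging, voltage-dependent capture, multi-level
substructure within events, overlapping events, and between-replicate
biological variability beyond counting statistics (real triplicate SEMs of
population percentages are often several points; simulated ones are
binomial, i.e. about one point at ~2000 events). Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to every pathology of real recordings.

## Event detection and feature extraction

The baseline is an iterated sigma-clipped median with a scaled-MAD noise
estimate — blockades are one-sided outliers, so the estimate tolerates
roughly 30% blocked time. Detection uses threshold crossing with
hysteresis: an event opens below `level - 5 sigma` and closes above
`level - 2.5 sigma`; runs shorter than 3 samples are discarded. The 5-sigma
default keeps false positives below about one per million samples; pulses
whose intervening trace never recovers above the release level merge into
one event, by construction. Detection is invariant to a constant offset of
the whole trace.

Feature extraction must contend with the recording filter: a 10 kHz
Gaussian filter has a rise time comparable to a bumping event, so naive
averaging underestimates short events' depth and threshold crossings
overestimate their width. Two estimators are used, routed by run length:

* **Long events** (run >= ~10 filter sigmas): boundaries are refined to the
  half-amplitude crossings with linear interpolation (for a filtered
  rectangle these sit exactly at the true edges), and the amplitude is the
  interior mean (3 edge samples excluded per side) divided by the
  analytically known attenuation factor of the averaging window.
* **Short events**: a rectangle of amplitude A and duration d keeps its
  area `A d` under linear filtering while its peak is
  `A erf(d / (2 sqrt(2) sigma_t))`; the area/peak ratio therefore
  determines d independent of A, and A follows as area/d. The peak is
  interpolated quadratically to reduce sampling bias.

Each event also carries a propagated amplitude standard error
(`amp_se_pA`). Events much shorter than the filter rise are detectable but
not measurable — their amplitude uncertainty is tens of pA — and the SE
makes that explicit instead of letting it masquerade as signal.

Dwell-time fits in the trace pipeline apply a missed-events correction:
the exponential MLE on left-truncated data, `tau = mean(d | d >= c) - c`.
The truncation point is the analytic detection limit of the class
(`detection_limit_ms()`) with a 3-sigma margin: at the bare threshold,
detection is a coin flip decided by noise, which thins and distorts the
short-dwell tail; above the margin detection is essentially certain and
the memoryless property makes the estimator unbiased even under dwell
measurement noise. Without this correction the bumping characteristic time
is biased upward by roughly 10%.

## Population profiles

`fit_population_model()` fits 1-3 Gaussian components to the blockade
amplitudes, by mixture maximum likelihood on raw amplitudes (default;
BIC selects k when `k = "auto"`) or by least squares of a sum of Gaussians
to the 2 pA-binned histogram, which mirrors how published profiles are
fitted; the two agree closely on clean data and both are exposed. The
mixture is fitted on well-measured events only (`amp_se_pA <= 3` pA and
SE below 25% of the amplitude): short-event amplitude noise otherwise
surfaces as a spurious broad component that BIC happily accepts.

Components are labelled by peak depth — deepest is translocation,
shallowest bumping, a middle component intercalation. A lone component is
labelled by absolute depth (<= -60 pA translocation, >= -40 pA bumping,
else intercalation), since a single peak carries no ordering information;
this matters for constructs like the N-terminal fragment whose histogram
is a single bumping peak. A known limitation: with exactly two shallow
peaks (e.g. a bumping/intercalation pair and no translocations) the
depth-order rule calls the deeper one "translocation"; population *changes*
are still detected correctly, so binding calls are unaffected.

Every event is then assigned to the component whose peak lies within 2.5
sigmas, where the z denominator inflates by the event's own amplitude SE;
nearest z wins, exact ties go to the deeper component. A component's
population is the percentage of **all** detected events in its window, so
populations need not sum to 100 — published tables show the same behaviour
(66% + 24% for the protein alone) — and the remainder is reported as
unclassified. Per-replicate profiles are kept for SEM reporting;
`pool_replicates()` concatenates tables for display histograms.

## Replicate statistics

`one_way_anova()` computes the classical fixed-effects F from per-group
(mean, SD, n) — raw vectors reduce to these, and published tables that
report only mean ± SEM with n = 3 can be compared directly via
`SD = SEM sqrt(n)`; the two modes agree to machine precision because the
sums of squares depend on the data only through those statistics.
`snk_posthoc()` implements the stepwise Student-Newman-Keuls procedure on
the studentized range: means are rank-ordered, a pair r steps apart is
referred to the range distribution with `nmeans = r`, unequal group sizes
use the harmonic mean n of the pair, and each pair's reported p is the
maximum over all ranges enclosing it — precisely the rule that an enclosed
comparison can never be significant inside a non-significant range.
Labels follow the strict ladder `* < 0.05`, `** < 0.01`, `*** < 0.001`.
The test suite checks the accept/reject pattern against an oracle that
integrates the studentized-range distribution numerically, independent of
`ptukey`.

## Binding calls and the knot/loop mode

For the full-length protein the folding signature is directional:
`call_binding(rule = "folding")` declares binding when the translocation
population falls significantly or the bumping population rises
significantly (p < 0.05 by the two-group comparison across replicates);
both together make the call "strong", one alone "weak". For domain
fragments the relevant question is whether the construct's profile changed
at all, so `rule = "any-change"` accepts a significant population change
of either sign and also the appearance of an intercalation component
(>= 10% population where the control had none) — new intermediate peaks
are binding evidence in their own right.

Two gates temper pure significance. A qualifying change must exceed 5
percentage points: with triplicate designs at ~2000 events, the
between-replicate noise is about one point, so each of the four constructs
would otherwise carry the full 5% type-I risk and a null drug would show
spurious "binding" somewhere in the panel roughly one run in five; every
published change called significant in this system is 13 points or more,
so the gate cannot mask a real effect of that scale. Peak-current shifts
(e.g. -85 to -89 pA under CPA) are recorded as supporting evidence but
never gate the call, since no magnitude threshold for them is established.

`infer_binding_mode()` then reads the panel: N-terminus bound with the
C-terminus free is a knot; both termini bound is a loop; C-terminal-only
or NAC-only evidence is indeterminate; and the mode is "none" exactly when
no construct binds. The NAC-deletion construct is reported in the
rationale but does not decide the mode — the termini do. Calls are
deterministic in their inputs and invariant to the order in which panel
constructs are supplied.

## Numerical choices and degenerate inputs

* Histogram bin width defaults to 2 pA; halving it must not change event
  counts (conservation is tested).
* Mixture fits refuse fewer than 50 events; dwell fits refuse fewer
  than 20; both errors state the count.
* A noiseless trace has no relative threshold — detection then requires an
  explicit absolute threshold and errors otherwise.
* Zero within-group variance with unequal means yields `F = Inf, p = 0`
  with a degeneracy flag rather than NaN.
* Two mixture components sharing a peak is a degenerate fit and an error.
* The binary trace format stores float64 samples so write/read round trips
  are exact; the text format is portable and accurate to 1e-6 pA.
* Sub-sample boundary interpolation means an event's `dwell_ms` matches its
  integer sample window only to about one sample — the continuous estimate
  is the one used by all fits.

## Problem sizes used in validation

The packaged checks run three simulated replicates of the default
condition (~1900 events each) for precision reporting; 50 independent
seeds of the full simulate-detect-profile chain for parameter recovery
(class weights within ±5 points, peaks within ±1 pA, dwell scales within
±10%); 100 random small-group datasets against the studentized-range
oracle plus 10,000 null datasets for the ANOVA's empirical size; and 20
seeds of each three-drug domain-panel configuration for the endpoint
logic. These sizes were chosen so each check's sampling noise is small
against the tolerance it tests.

## Limitations

Kinetic on/off rates, affinity constants, multi-exponential dwell
mixtures, voltage dependence, and 2D (I, T) joint clustering are out of
scope. The simulator's fidelity limits what green tests prove about real
traces (see above); supplied recordings enter the same pipeline via
`read_trace()` / `detect_events()`, but instrument-specific artifacts are
the user's to assess. ABF files should be converted to the text trace
format with an external reader (e.g. pyabf) first.
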