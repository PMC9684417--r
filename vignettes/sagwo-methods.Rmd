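---
title: "Fetal ECG extraction by sequential analysis with grey wolf optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal ECG extraction by sequential analysis with grey wolf optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagwo)
```

## The problem

Non-invasive fetal electrocardiography records electrical potentials from
electrodes on the maternal abdomen. Each abdominal channel is a mixture of
the maternal ECG (mECG), a much smaller and faster fetal ECG (fECG),
baseline wander from respiration and electrode drift, powerline
interference, and broadband noise. The maternal component dominates by
roughly a factor of three or more and overlaps the fetal component in both
time and frequency, so the central task is to remove the maternal beats
precisely enough that the fetal R-peaks can be detected from what remains.

`sagwo` implements a template-subtraction extraction in which each maternal
beat is modelled as independently scaled P-wave, QRS-complex and T-wave
sections of an averaged template, with the per-beat scaling vector found by
a Grey Wolf Optimizer (GWO).

## The beat model

Around every detected maternal R-peak a 0.70 s window is laid out:

* QRS: from 0.05 s before to 0.05 s after the R-peak,
* P: the 0.20 s ending where the QRS window begins,
* T: the 0.40 s starting where the QRS window ends.

The section boundaries follow from the requirement that the three sections
tile the stated 0.70 s total; all indices are 0-based and windows are
half-open, one convention everywhere so no module is off by one sample.
The non-truncated windows are averaged per section into templates
$\mu_P, \mu_{QRS}, \mu_T$, stacked into a block matrix

$$
M = \begin{pmatrix} \mu_P & 0 & 0 \\ 0 & \mu_{QRS} & 0 \\ 0 & 0 & \mu_T \end{pmatrix},
$$

so a cycle is approximated as $\hat m = M a$ with the scaling vector
$a = (a_P, a_{QRS}, a_T)$. Because the blocks are disjoint, $M^\top M$ is
diagonal and the least-squares solution
$a = (M^\top M)^{-1} M^\top m$ reduces to per-section projections
$\langle \mu_s, m_s\rangle / \lVert \mu_s\rVert^2$; the package computes the
normal-equations form and the tests assert both formulations agree to
$10^{-10}$ relative. The per-beat objective handed to the optimizer is the
mean squared error $J(a) = \mathrm{MSE}(m - M a)$ (the sum-of-squares form
differs only by a constant factor and has the same argmin; MSE is reported
because it is the labelled form of the objective).

Two boundary rules needed a decision the beat model itself does not make:

* **Record edges.** Beats whose full window would run past either record
  edge are flagged truncated and excluded from template averaging, but are
  still cancelled over their available span.
* **Overlapping beats** (RR < 0.70 s, routine at labour heart rates). The
  T window is truncated where the next beat's P window begins, so no sample
  is claimed by two templates. Truncated beats are likewise excluded from
  averaging but cancelled with the truncated template. Sections that are
  entirely absent from a truncated window are held at unit scaling — their
  template rows are zero, so the value is irrelevant to the fit.

Averaging is global (all non-truncated beats of the record) with per-beat
refitting via the scaling vector, rather than a sliding local average:
scaling-per-section is exactly the mechanism meant to absorb slow
morphology change, and a global template keeps the basis well conditioned
on short records.

## The Grey Wolf Optimizer

GWO is a population metaheuristic: the three best solutions found so far
(alpha, beta, delta) steer every agent. For each leader $L$ an agent at $X$
draws random coefficient vectors $A \in [-2a, 2a]$ and $C \in [0, 2]$
per dimension, forms $D_L = |C \cdot X_L - X|$ and the candidate
$X_L - A \cdot D_L$, and moves to the mean of the three candidates, clipped
to the search box. The exploration coefficient $a$ decays linearly from 2
to 0 over the iterations; the first move explores at $a = 2$.

Implementation decisions, in each case following the canonical published
algorithm where the prose description is ambiguous:

* **Leaders persist.** Alpha/beta/delta are the three best solutions *ever
  seen*, improved in place (ties go to the earlier-evaluated agent). An
  earlier variant that re-ranked leaders from the current pack each
  iteration let the leaders regress and measurably stalled on weakly
  curved dimensions; the persistent form matches the reference
  implementation and was cross-checked against an independent
  re-implementation on a fixed quadratic.
* Randoms are drawn per dimension, per leader, per agent, per iteration.
* Out-of-box positions are clipped componentwise.
* The reported history is the alpha fitness after each iteration, hence
  monotone non-increasing; the best-ever alpha is returned even if the pack
  later wanders.
* Omega-class wolves are not modelled separately: every non-leader agent
  follows the same update.

For per-beat scaling the search box is $[-2, 2]^3$: it contains the unit
vector, allows sign flips, and physiological per-cycle scaling rarely
exceeds a factor two. The default budget is 10 agents and 10 iterations,
the published operating point; with 10 agents and 50 iterations the
optimizer reaches the closed-form least-squares optimum within 5 % MSE for
the large majority of beats. GWO retains an intrinsic few-percent chance of
stalling on the weakly curved P dimension at small budgets — the per-beat
results store the GWO and least-squares fitness side by side so this gap is
always observable, and the invariant GWO $\ge$ LS is asserted on every run.
A `warm_start` flag can pin one initial agent at $(1,1,1)$; it is off by
default to match random initialisation.

Seeding: one master seed is expanded deterministically per (channel, beat),
so a whole extraction is bit-reproducible while every beat still gets an
independent optimizer stream.

## The pipeline

`extract_fecg()` runs, in order: (1) per-channel preprocessing; (2) PCA
across channels, first principal component taken as the maternal reference
(the maternal component dominates abdominal mixtures); (3) maternal R-peak
detection on that component; (4) per abdominal channel, template
construction and per-beat GWO scaling at the shared maternal R-peaks,
followed by subtraction; (5) PCA across the residual channels and selection
of the most kurtotic component as the enhanced fetal signal; (6) fetal
R-peak detection. Cancellation runs on every channel (not only the first
component) because the fetal content of each electrode would otherwise be
discarded before the residual PCA can concentrate it.

**Preprocessing.** The artifacts are named but no filters are prescribed,
so the package uses standard ECG practice: a zero-phase 4th-order
Butterworth high-pass at 1 Hz (preserves P/T morphology, removes drift) and
a zero-phase second-order IIR notch at 50 Hz with Q = 30 (the data this
method targets originate from a 50 Hz-mains country; the frequency is
configurable for 60 Hz grids). Forward-backward filtering uses
odd-reflection padding long enough for the slowest filter pole to settle
below $10^{-6}$ relative, so records do not inherit edge transients.

**QRS detection.** No detector algorithm is prescribed either; the package
implements the Pan–Tompkins energy chain (band-pass, derivative, squaring,
moving-window integration, adaptive median-based threshold, refractory
resolution in favour of the stronger peak, search-back over overlong RR
gaps at a relaxed threshold, refinement to the band-passed extremum).
Maternal defaults: 5–15 Hz band, 0.35 s refractory, 0.15 s integration.
Fetal defaults: 10–30 Hz band for the narrower complex, 0.25 s refractory
(caps rates at 240 bpm), 0.08 s integration, ±12 ms refinement, a lower
threshold (0.3 of the median peak level) and aggressive search-back —
fetal complexes that coincide with a maternal beat are partially absorbed
by the template fit, and the fetal stage must pick up those weakened peaks.

**Fetal component selection.** The residual component with the highest
kurtosis is selected (spiky, sparse fetal QRS trains are strongly
leptokurtic). The kurtosis is computed after winsorizing the component at
the 0.999 quantile of its absolute values: a single badly cancelled
maternal beat can put one enormous spike into a minor component and give it
a freak raw kurtosis, while a genuine fetal spike train owes its kurtosis
to hundreds of spikes and is barely affected by the clipping. Setting
`winsor_quantile = 1` restores the raw sample kurtosis.

## Evaluation protocols

* **Detection statistics.** Detections are matched one-to-one to reference
  annotations within ±50 ms, greedily in reference order with the nearest
  unmatched detection (ties to the earlier detection). The bookkeeping
  identities TP + FN = |reference| and TP + FP = |detected| hold by
  construction, and on realistically spaced peaks (spacing beyond twice the
  tolerance) the greedy matching attains the optimal one-to-one count,
  which the tests verify against a brute-force matcher. ACC, SE, PPV and F1
  follow the standard formulas, computed unrounded and displayed at two
  decimals.
* **Clinical features.** The beat-to-beat heart rate trace is
  $60 f_s / \Delta \mathrm{RR}$ smoothed by a centred 30-beat moving
  average (shrinking symmetrically at the edges; the "30 samples" of the
  smoother are beats of the rate series, which is what the trace is indexed
  by). The baseline rate is the mean over at most 10 minutes after
  iteratively excluding 1-minute segments deviating more than 25 bpm — the
  only quantitative criterion in the NICHD definition — with optional
  rounding to the nearest 5 bpm, exposed as a flag and off by default
  because published estimated baselines are not in fact multiples of five.
  Variability is the median over non-overlapping 1-minute windows of the
  peak-to-trough amplitude of the detrended smoothed trace (the median
  makes a single disturbed minute harmless; published usage does not state
  whether one whole-record number or a windowed statistic is intended).
* **Quality indices.** kSQI and sSQI are the population fourth and third
  standardized moments, Pearson convention (Gaussian kurtosis = 3), so the
  usual "kSQI above 5 means high quality" reading applies.

## The synthetic generator

`generate_record()` builds records whose structure is exactly what the
extraction assumes, with full ground truth: maternal and fetal R-peak
indices, the per-cycle scaling triples, the clean sources and the base-beat
section basis.

* Beat morphology is a sum of five Gaussians (P, Q, R, S, T) evaluated on
  the analysis window. Sections of the base beat are multiplied per cycle
  by scaling triples drawn uniformly from [0.8, 1.2] — multiplying the
  *sections* rather than the waves makes each noiseless cycle exactly
  $M_{\mathrm{base}} \, a$ on its window, which is what enables the exact
  recovery oracle below.
* Defaults describe a typical term recording: 500 Hz sampling, four
  channels, maternal 80 bpm with 3 % RR jitter (multiplicative Gaussian,
  truncated at ±3σ), fetal 140 bpm with 5 % jitter, fetal/maternal peak
  ratio 0.3, a 0.25 Hz baseline sinusoid of amplitude 0.3, a 50 Hz mains
  sinusoid of amplitude 0.1, and white noise at 20 dB SNR per channel
  relative to the clean mixture. The mixing matrix gives every electrode
  O(1) maternal weight and varied fetal weight, loosely mimicking electrode
  geometry.
* Reproducibility: the whole record and truth are a pure function of the
  seed.

Because the per-cycle truths are defined relative to the *base* beat,
projecting noiseless cycles onto the base-section basis recovers every
fully observed cycle's triple to machine precision; projecting onto the
record-averaged basis recovers them only up to the per-section mean of the
drawn scalings (the average template is itself scaled). The exact-recovery
check therefore uses the base basis from the ground truth.

What the generator does *not* emulate: fetal movement and changing fetal
position, electrode-contact artifacts, uterine EMG, morphology change
beyond per-section scaling, and the dispersion that distorts abdominal
fetal morphology relative to scalp-electrode recordings. Passing the
synthetic suite therefore demonstrates correctness of the mechanics under
the model's own assumptions, not clinical performance; the published
clinical benchmark enters only through its printed per-record TP/FP/FN
counts (`benchmark_detection_counts()`), from which the package reproduces
the reported per-record metrics and dataset averages exactly.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by choice, at desk scale:
120 s records for end-to-end extraction (about 160 maternal and 280 fetal
beats), 75 s for optimizer-versus-closed-form comparisons (100 beats, each
with a 10-seed sweep at 10 agents × 50 iterations, mirroring the published
10-run repeatability protocol), 60 s for exact-recovery checks. Moment-law
checks for the quality indices use $2 \times 10^5$–$10^6$ Gaussian,
Laplace and exponential draws.

Degenerate inputs are errors, not silent results: empty records, zero
sections, zero-norm template columns (rank-deficient $M$), zero-variance
signals for the SQIs, undefined SE/PPV at zero denominators (surfaced as
`NA` only in the bundled report), records too short for threshold
statistics (2 s) or extraction (10 s).

## Known limitations

* At the published 10 × 10 budget a few percent of beats retain a visible
  GWO–LS gap; downstream robustness (winsorized selection kurtosis,
  search-back detection) absorbs the resulting residual spikes, but the
  per-beat gap itself is inherent to the small budget.
* Template subtraction partially absorbs fetal complexes that coincide
  with a maternal QRS; the fetal detector recovers most but not all such
  beats. This is a structural property of single-template subtraction, not
  of the optimizer.
* The WFDB loader covers single-segment format-16 records, which is what
  the targeted public collections use; other storage formats are out of
  scope.
* Real-data benchmarks require the clinical recordings themselves, which
  the package deliberately does not depend on.
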