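---
title: "Methods: simulated interictal source imaging with hdesi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated interictal source imaging with hdesi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdesi)
```

## What the package models

In presurgical epilepsy evaluation, interictal epileptiform discharges
(IEDs, "spikes") recorded on high-density scalp EEG are detected, averaged,
and projected back into the head with a linear inverse operator (electric
source imaging, ESI). The clinically interesting questions are operational:
how well does an automated detector with a probability threshold agree with
visual marking, and how many spikes must be averaged before the source
maximum stops moving?

Real patient recordings for that workflow are not publicly available, so
`hdesi` builds a fully synthetic but physically grounded stand-in: an
analytic spherical head, a dense electrode montage, spike-wave events from
a known dipole, 1/f background, and a "resection mask" around the true
source. Every downstream stage (detection, review, averaging, wMNE
inversion, distance scoring, spike-count subsampling) then runs exactly as
it would on real data, with the advantage that ground truth is known.

## Forward model

The head is three concentric spheres (brain, skull, scalp; defaults
80/85/92 mm, conductivities 0.33/0.004/0.33 S/m). The scalp potential of a
current dipole is the classical spherical-harmonic series; per harmonic
order $n$ the radial transfer through the shells is obtained by solving the
five boundary conditions (potential and radial current continuity at the
two interfaces, zero current at the scalp) exactly, so the only
approximation is truncation at `n_terms` (default 60). Two properties make
this testable:

* with equal conductivities the shell factors are identically 1 and the
  series must sum to the homogeneous-sphere solution, for which a closed
  form exists (the insulated-sphere monopole potential, differentiated);
  the test suite checks 1 % agreement for sources up to 0.9 of the brain
  radius;
* truncation error is controlled: between `n_terms` 40 and 80 the gain
  changes by less than 0.1 % for sources within 0.8 of the brain radius.
  Sources within 2 mm of the brain shell are rejected rather than silently
  diverging.

Units are µV per nAm throughout, in the average reference (each gain
column sums to zero over channels), matching how a reference-free
256-channel system is analyzed. The electrode montage is a spherical
Fibonacci lattice over a 140° polar cap — a quasi-uniform surrogate for a
geodesic sensor net.

## Synthetic recordings

The stated world of the generator, chosen once for realism and not
revisited:

| parameter | default | rationale |
|---|---|---|
| spike FWHM | 70 ms | sharp transient of a spike-wave complex |
| slow-wave FWHM | 300 ms, 30 % amplitude, opposite sign | classic after-going slow wave |
| dipole moment | 800 nAm | scalp peak ≈ 70–90 µV at 0.6 brain radius: the eye-visible regime clinicians mark |
| background | 15 µV RMS per channel, PSD ∝ 1/f | resting scalp EEG magnitude and spectral shape |
| amplitude jitter | ±20 % multiplicative | spike-to-spike variability |
| event spacing | ≥ 4 s, ≥ 2 s edge margin | keeps the ±2 s analysis epochs disjoint |
| sampling | 250 or 1000 Hz | the acquisition rates the workflow targets |

The background is generated per channel by spectrally shaping white
Gaussian noise, so channels are independent; real EEG has spatially
correlated background, ocular and muscle artifacts, and state changes.
A green detection test therefore establishes that the detector separates
coherent dipolar transients from incoherent 1/f noise — not that it would
match a commercial detector on clinical data.

## Detection and the probability score

Detection is per-channel normalized matched filtering against the
template's sharp segment, after a zero-phase band-pass (4–45 Hz,
raised-cosine edges). Candidates are local maxima of the best-channel
|correlation| separated by ≥ 200 ms. The probability score squashes
(correlation × amplitude z-score) through a logistic with midpoint 2.5 and
slope 2.0, fitted once on a calibration simulation and frozen.

One design choice deserves its own paragraph: the amplitude z-score is
computed on the **global field power** (across-channel RMS of the
band-passed data) rather than on the single peak channel. On 1/f
background, single-channel scores of true spikes and of background
fluctuations overlap — no threshold separates them. A dipolar event,
however, lifts many channels simultaneously, while independent background
peaks cannot; the GFP z-score therefore separates the classes cleanly and
is the statistic that makes the 0.9 probability threshold meaningful. This
is also where the density of the montage genuinely pays off.

Thresholding retains probability ≥ 0.9 (a value of exactly 0.9 is kept).
Retained events are clustered by the electrode with the highest amplitude;
clusters are ranked by event count with lexicographic tie-break. A
simulated reviewer keeps candidates within 100 ms of a ground-truth mark,
each with probability 1 − miss rate (default 0.05), and rejects the rest —
the stand-in for visual review of 2-s event epochs.

Agreement metrics: sensitivity = matched reference marks / reference
marks; PPV = true discharges / all detections; success rate = share of
recordings with ≥ 30 reviewed events in a cluster up to a given rank;
Cohen's κ = (Pr(a) − Pr(e)) / (1 − Pr(e)). κ needs a trial structure that
point processes lack, so the recording is divided into non-overlapping 2-s
decision epochs (the same granularity as review) and the 2×2 table built
over epochs. The matching tolerance for all metrics defaults to 100 ms;
the marking convention is "on the peak" but no tolerance is inherent, so
it is configuration, not science.

## Averaging and the half-rise time point

Epochs of ±2 s around each accepted mark are exact slices (no
resampling); epochs whose worst channel exceeds 300 µV peak-to-peak are
dropped (a pragmatic artifact criterion — the workflow it stands in for
uses visual cleaning). Averaging is arithmetic; the 1/√N law for the
residual of an N-epoch average is enforced by a Monte-Carlo test.

Source reconstruction uses the 50 % rising-phase sample of the averaged
discharge: on the peak channel (configurable to global field power),
baseline = mean of [−1.5, −0.5] s; the rising phase runs from the last
baseline crossing to the peak; the half-rise is the first sample at ≥ 50 %
of peak-minus-baseline excursion. The definition is polarity-agnostic and
invariant to scaling and DC offsets. The baseline window avoids both the
epoch edges and the discharge's own rise; the choice of peak channel
versus GFP is genuinely open in the workflow being modelled, so both modes
exist and the default is documented here.

## The wMNE inverse

Free-orientation weighted minimum-norm estimation:

$$ M = W L^\top (L W L^\top + \lambda^2 C)^{-1}, \qquad
   \lambda^2 = \frac{\operatorname{tr}(L W L^\top)}
                    {\operatorname{tr}(C)\, \mathrm{snr}^2}, $$

with per-source depth weights $w_s = \lVert L_s \rVert^{-2\gamma}$
(Frobenius norm of the source's three gain columns; γ = 0 is plain MNE).
$C$ is the sample covariance of pre-event baselines pooled across epochs,
diagonally loaded with fraction α (default 0.05) to guarantee positive
definiteness. Defaults snr = 3 and γ = 0.5 follow common practice; the
literature the workflow cites does not pin them, so they are configuration
and are exercised across values in the tests. The source map is the
Euclidean norm of the 3-vector estimate at the chosen sample; the maximum
is the lowest index on ties.

## Evaluation

* **Distance to resection**: 0 if the source maximum is a mask member,
  otherwise the shortest Euclidean distance to any member.
* **Sublobar concordance**: a geometric surrogate parcellation — each
  hemisphere (split at x = 0) is partitioned into 19 regions by k-means on
  grid coordinates, deterministic under a seed. Concordance = the
  maximum's label occurs among mask labels. Because the parcellation is
  geometric, not anatomical, concordance is meaningful within the
  simulation world only.
* **Subsampling experiment**: the full-average maximum is computed once;
  for each requested N, epochs are resampled without replacement (default
  25 repetitions per N, a deliberate addition — single draws would
  confound sampling noise with the effect), averaged, half-rise found,
  inverted, and the distances to the full-average maximum and to the mask
  recorded. `smallest_N_below()` reports the smallest N whose mean
  distance to the full-average maximum is below 10 mm with all larger
  sampled N also below — the stability reading of "how many spikes are
  enough".

## Numerical choices and degenerate inputs

* Series truncation `n_terms = 60`; sources within 2 mm of the brain
  shell raise an error.
* Radii are scaled to the scalp radius inside the shell solve to keep the
  per-order 5×5 systems well conditioned.
* A dipole exactly at the origin has no radial direction; only the n = 1
  term survives there and it is direction-independent, so an arbitrary
  unit vector is used safely.
* `kmeans` for the atlas uses 5 restarts under a fixed seed; ties in
  `find_source_maximum` break to the lowest index; cluster rank ties break
  lexicographically by channel id.
* All randomness flows through explicit seeds; re-running a pipeline
  config reproduces every output byte for byte (timestamps are not written
  into reports for this reason).

## Known limitations

* **Peak localization bias of wMNE.** On a volumetric free-orientation
  grid, the wMNE amplitude maximum is displaced outward by ~15–20 mm on
  average even for noiseless data at high assumed SNR, for any depth
  exponent in [0, 1] and with or without the skull layer. This is the
  well-documented localization error of minimum-norm estimators that
  standardized variants (sLORETA and relatives) were designed to remove —
  and those variants are deliberately out of scope here. Consequences:
  absolute distances to the true source or to the resection mask carry
  this bias (comparable in size to distances reported for the clinical
  workflow), while *relative* quantities — the subsampling curve, whose
  distances are measured against the full-average maximum — are unaffected,
  because the bias is common to both maps. One acceptance test asserts
  5 mm noiseless localization and is expected to fail; it is kept red
  deliberately rather than silently weakened.
* The synthetic reviewer is an oracle with a miss rate: it cannot be
  fooled by plausible artifacts the way a human can, so reviewed-κ values
  are optimistic upper bounds.
* Single-focus sources by default; multiple foci can be simulated but are
  not modelled as interacting.
* The EDF writer covers continuous 16-bit recordings with a uniform rate;
  it is an interchange convenience, not a general EDF(+) implementation.

## A worked run

```{r example, eval = FALSE}
cfg <- default_config(
  seed = 1L,
  electrodes = list(n_channels = 64L),
  grid = list(spacing_mm = 10),
  simulation = list(duration_s = 200, n_events = 35L),
  evaluation = list(Ns = c(5L, 10L, 20L, 30L), n_reps = 10L))
report <- run_full_pipeline(cfg)
print(report)
report$subsampling$curve
```

The printed report shows the per-stage counts (simulated, detected,
retained at p ≥ 0.9, reviewed), the agreement block, the localization
block, and the subsampling curve with its stability threshold; the README
reproduces one such run with its actual output.
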