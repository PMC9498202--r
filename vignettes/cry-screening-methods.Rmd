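---
title: "Methods: entropy-based cry screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based cry screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryentropy)
```

This vignette is the package's account of its own science: the models and
procedures it implements, the parameters that matter and why their defaults
are what they are, what the synthetic corpus does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The screening problem

Neonatal sepsis alters crying: clinical red-flag descriptions note a lower
tone, and spectral analyses of septic cries report lower spectral entropy
(a peakier, less uniform energy distribution) than healthy cries. The
package classifies *single cry units* — expiratory (EXP) or voiced
inspiratory (INSV) vocalizations delimited by hand — as healthy or septic.
Treating each unit as one sample maximises the usable sample count from
scarce clinical recordings, at the price of correlated samples from the
same infant; the package does not attempt per-infant aggregation.

## Front end

Cry signals are nonstationary; short-window analysis makes each frame
locally stationary. The geometry is fixed at 10 ms Hamming-windowed frames
with 30 % overlap. At the nominal 44.1 kHz this gives 441-sample frames
advancing by `round(0.7 * 441) = 309` samples; both counts are resolved by
rounding so the geometry recomputes cleanly at other rates. Two consecutive
windows therefore span 750 samples ≈ 17 ms, and the admission rule — a
unit must span more than two consecutive windows to be analyzable —
becomes "at least two whole frames". Trailing samples that do not fill a
frame are dropped rather than padded, consistent with whole-frame
admission. Silent (all-zero) units are rejected at admission, since every
downstream quantity (log energies, spectral mass functions, centroids) is
undefined on them.

Pre-emphasis `H(z) = 1 − a z⁻¹` with `a = 0.97` is applied to the whole
waveform before framing — it is a property of the signal, not of a frame.
Each frame is zero-padded to `nfft = 512` (the next power of two above
441; the frame length, not the transform length, sets the spectral
resolution) and the one-sided magnitude spectrum retained.

## The three cepstral feature sets

All three extractors share the 13-filter triangular mel bank. Filter edges
are equally spaced on the mel axis `M(f) = 1125 ln(1 + f/700)` between 0 Hz
and Nyquist, mapped back to hertz, and snapped to FFT bins; 13 filters is
the low end of the conventional 13–24 range and matches the 13 cepstral
coefficients kept. The decorrelating transform in all three is the
*orthonormal type-II DCT* (`T·Tᵀ = I`), so coefficient 0 is always
`(profile sum)/√13` and energy is preserved across the transform.

**MFCC (39).** Per frame: mel band energies → log → DCT → keep 13.
The log uses a floor of `1e-10 ×` the segment's maximum band energy
(absolute floor `1e-30`): relative, so loud segments are untouched, and
sufficient to keep silent frames finite. Delta and delta-delta tracks use
the standard regression window with half-width Θ = 2 and replicated edge
frames; a linear coefficient ramp has its slope recovered exactly at
interior frames. Static, delta and delta-delta blocks concatenate to 39.

**SENCC (13).** The spectrum of each frame is mapped onto the 13 mel
bands, normalised to a mass function `xᵢ = Xᵢ/ΣXᵢ`, and each band
contributes its entropy term `hᵢ = −xᵢ log₂ xᵢ`; the frame's spectral
entropy is `H = Σhᵢ ≤ log₂ 13`. The DCT of the 13-term entropy *profile*
gives the 13 coefficients. This is the only construction that yields 13
coefficients from a quantity "computed from the mel spectrum": a scalar
entropy cannot produce 13 decorrelated values, while the per-band profile
carries the *position* of peakiness across the spectrum and recovers the
scalar as `√13 ×` coefficient 0. A silent frame is assigned the uniform
mass function (maximal entropy — silence is maximally uninformative about
where energy concentrates).

**SCCC (5).** Eq-style spectral centroids are computed *within* each mel
band — the weighted mean frequency of the triangle-weighted magnitudes —
giving a 13-point subband-centroid profile per frame; a band with no
energy falls back to its center frequency (the symmetric prior). The
profile is divided by the Nyquist frequency so coefficients are comparable
across sample rates, DCT-transformed, and the first five coefficients
kept. This is the standard spectral-subband-centroid construction; its
coefficient 0 degrades gracefully to (a scaled) global centroid.

Each set is reduced to one vector per segment by the mean over frames.
The mean-over-time reduction is applied uniformly to all three sets so a
segment always maps to one fixed-length vector — the per-segment
classification requires it, and the printed set sizes (39/13/5, 52, 57 for
the concatenations) only add up under uniform reduction.

One caveat worth stating: the full-band magnitude centroid of a *windowed*
tone is biased above the tone frequency, because the Hamming window's
sidelobe mass is small per bin but spread over thousands of high-frequency
bins. The tests therefore check point-mass centroid identities on exact
point spectra, dominant-bin recovery on synthesized tones, and the
*ordering* of class centroids — not absolute centroid values of windowed
signals.

## Fuzzy-entropy feature selection

Each feature column is clustered into `c = 2` fuzzy subsets by
one-dimensional fuzzy c-means (fuzzifier `m = 2`, Euclidean distance on
scalars). The matching degree of cluster `i` with class `c`,
`D_c = Σ_{k∈c} uᵢ(k) / Σ_k uᵢ(k)`, is the share of the cluster's
membership mass carried by that class; the feature's fuzzy entropy is
`FE = −D_H log₂ D_H − D_S log₂ D_S` after assigning clusters to classes.
A cleanly separating feature drives both matching degrees to 1 and FE to
0; a noise feature splits mass evenly and lands near the two-class
maximum. Features with FE *strictly below* the mean FE are retained.

Open choices, resolved as follows:

* **Initialisation** — centers start at the 10th and 90th percentiles:
  deterministic (no RNG in the selector), affine-equivariant, and robust
  to outliers at the extremes. The convergence tolerance (1e-5) is
  *relative to the data range*, which makes the whole iteration
  affine-equivariant: rescaling a feature column cannot change its FE.
* **Cluster→class assignment** — the bijection maximising `D_H + D_S`.
  Any fixed assignment could invert the statistic's meaning on a feature
  whose low cluster happens to align with the other class.
* **Log base** — base 2 throughout, consistent with the spectral entropy;
  base only scales all FE values equally and can never change which side
  of the mean a feature falls on.
* **Degenerate (constant) features** — assigned the maximal observed FE,
  guaranteeing removal: a constant carries no class information.
* **Ties and empty selections** — `FE == threshold` is excluded (the rule
  is "strictly lower"); if the strict rule selects nothing (all FE equal),
  all features are kept with a warning rather than emitting an empty
  table.
* **Where selection runs** — by default inside each training fold, so the
  held-out fold never influences which features survive. Whole-table
  selection before CV (`paper_mode`-style) is available for comparability
  with reports that tuned on the full table.

## Classification and tuning

**KNN** is a brute-force implementation (exact, no approximate index) with
the nine-distance menu: Minkowski (exponent fixed at p = 3 — p = 1 and
p = 2 appear separately as Manhattan and Euclidean), Chebyshev, Euclidean,
standardised Euclidean (training-fold standard deviations), cosine,
Jaccard, Manhattan, Hamming and correlation. Hamming on continuous vectors
is the fraction of unequal coordinates and Jaccard the unequal fraction
among coordinates where either value is nonzero — the only self-consistent
reading for real vectors. Distance ties at the k-th neighbour include all
co-distant points; a tied vote falls back to the single nearest
neighbour's label, so prediction is deterministic without an RNG.

**SVM** is the soft-margin Gaussian-kernel machine
`K(x,z) = exp(−‖x−z‖²/σ²)` with kernel scale σ and box constraint C, both
free continuous hyperparameters; the dual is solved by libsvm via `e1071`.

**Bayesian tuning.** Hyperparameters are found by minimising a
cross-validated misclassification rate with a Gaussian-process surrogate
(squared-exponential kernel on the unit-cube encoding — log-scaled
continuous ranges, one-hot categorical metric — lengthscale picked from a
small grid by marginal likelihood each update) and expected-improvement
acquisition maximised over 512 random candidates per iteration. The
budget, 30 evaluations including an 8-point Latin-hypercube initial
design, follows the premise that a surrogate-guided search needs far fewer
evaluations than grid or random search. Non-finite objective values are
recorded with a large penalty and the search continues.

**Cross-validation.** Outer folds are stratified and *keyed by a seeded
hash of segment ids*, so fold membership is invariant to row order.
Tuning by default uses an inner stratified 3-fold split of each outer
training fold — the held-out fold never reaches the tuner. The
`paper_mode = TRUE` flag instead tunes one configuration directly on the
outer-CV objective shared across folds, reproducing the common (leakier)
single-configuration-per-experiment reporting style. Features are z-scored
on training-fold statistics inside every split: both the distance menu and
the Gaussian kernel are scale-sensitive.

**Metrics.** Accuracy, recall, precision, specificity, F1 and MCC, septic
positive. Zero-denominator rates are reported as undefined (`NA`) and
excluded from fold aggregation with a warning; MCC with a zero marginal is
defined as 0 (random-equivalent), flagged. Aggregation is mean ± sample
standard deviation (n−1) over folds. All computation is in fractions;
percentages are formatting.

## The synthetic corpus

Clinical cry corpora are proprietary, so the pipeline is exercised on
seeded harmonic-plus-noise surrogates. Each segment is a stack of up to 12
harmonics at a per-segment fundamental drawn from the class register, with
amplitudes rolled off by the class spectral tilt (dB/octave), white noise
at the class noise floor (dB relative to harmonic RMS), 5 ms raised-cosine
fades, and peak normalisation. Durations are lognormal with means 0.72 s
(EXP) and 0.21 s (INSV), floored at 17 ms; `sdlog = 0.35` keeps the floor
essentially inactive (hit by far less than 1 % of draws) while giving the
right-skewed shape typical of vocalization lengths.

Class presets (chosen once, as the package's model of the documented
contrasts, and not revisited):

| parameter | healthy | septic (well-separated) | septic (overlapping) |
|---|---|---|---|
| f0 mean ± sd (Hz) | 450 ± 40 | 340 ± 40 | 445 ± 40 |
| spectral tilt (dB/oct) | −3 | −12 | −3.5 |
| noise floor (dB) | −25 | −40 | −26 |

The septic register sits ~110 Hz below healthy (lower tone); the steeper
tilt concentrates energy in the low harmonics (lower centroid, peakier
spectrum) and the lower noise floor removes broadband mass (lower
entropy). At 30 segments per class the septic-minus-healthy differences
are ≈ −0.2 bits of frame entropy and ≈ −800 Hz of centroid, both
significant at rank-sum p < 0.01. The *overlapping* preset moves the
septic parameters nearly onto the healthy ones, as a difficulty knob for
sanity checks: accuracy must fall strictly below the well-separated
preset's.

What the generator does *not* emulate — and therefore what passing tests
do not show about clinical data: formant structure and glottal source
dynamics, inter-infant variability and repeated units from one infant,
NICU noise scenes (chatter, beeps, other cries), recording-channel
variation, and any physiological model of sepsis. The generator's job is
to produce a corpus in which the documented class orderings hold with
realistic segment geometry, so the pipeline's machinery can be verified
end to end; clinical performance claims require clinical data.

## Problem sizes and determinism

The shipped checks use 200 segments per class for the end-to-end
classification surrogate (with a permuted-label control required to land
at chance), 30 per class for the contrast tests, 100 seeded repetitions
for the selector's noise-removal rate, and 100 seeded runs for the
optimiser's convex-recovery check — sizes at which the stochastic
assertions are stable across seeds while a full run stays in the
tens-of-seconds range. Every stochastic step (generation, folds, tuner)
derives from explicit integer seeds; regenerating with the same seed
reproduces waveforms bit-exactly and metrics exactly.

## Known limitations

* Single-unit decisions; no per-infant or per-recording aggregation.
* The SENCC/SCCC multi-band constructions are one principled reading of a
  design described only loosely in the literature they come from; the
  scalar-profile alternatives are recoverable from coefficient 0.
* The mel-subband centroid axis is physical hertz; bin-index weighting
  would differ by a constant factor per band.
* Fuzzy c-means is run per feature in one dimension only; multivariate
  selection (interactions between features) is out of scope.
* The GP tuner uses a fixed small lengthscale grid rather than full
  hyperparameter marginalisation — adequate for 2–3 search dimensions and
  a 30-evaluation budget.
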