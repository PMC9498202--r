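# cryentropy

Entropy-based acoustic screening of newborn cries.

Neonatal sepsis is a leading, largely treatable cause of newborn mortality,
and it is hardest to catch where clinicians are scarcest. A newborn's cry is
produced by the coordinated action of the respiratory and nervous systems,
so systemic illness leaves measurable traces in its acoustics: septic cries
sit at a lower tone and have a less uniform (peakier) spectral energy
distribution than healthy ones. `cryentropy` implements a complete,
deliberately simple cry-screening pipeline that turns segmented cry
recordings into a healthy-vs-septic decision using classical signal
processing and conventional machine learning — no specialised hardware, no
deep models.

The pipeline, stage by stage:

* **Front end** — mono PCM WAV cry units (expiratory `EXP` or voiced
  inspiratory `INSV`) are pre-emphasised with `H(z) = 1 − 0.97 z⁻¹`, sliced
  into 10 ms Hamming-windowed frames with 30 % overlap, and admitted only if
  they span at least two consecutive windows (17 ms). The magnitude
  spectrum of each frame feeds three cepstral feature sets.
* **Features** — per segment, means over frames of:
  * **MFCC** (39): 13 mel-frequency cepstral coefficients from a 13-filter
    triangular mel bank (`M(f) = 1125 ln(1 + f/700)`), plus delta and
    delta-delta tracks;
  * **SENCC** (13): the DCT of the 13-band spectral-entropy profile
    `hᵢ = −xᵢ log₂ xᵢ` of the mel spectrum, where
    `xᵢ = Xᵢ / ΣXᵢ` (frame entropy `H = Σhᵢ`);
  * **SCCC** (5): the DCT of the 13 mel-subband spectral centroids
    `C = Σ fₖ|X(k)| / Σ|X(k)|`, Nyquist-normalised, first five kept.
  Any concatenation is supported (MFCC+SENCC = 52, all three = 57).
* **Fuzzy-entropy feature selection** — each feature is clustered by 1-D
  fuzzy c-means; the matching degree `D_c` between cluster mass and class
  gives `FE = −D_H log₂ D_H − D_S log₂ D_S`, and only features with FE
  below the mean FE are retained (low FE = informative).
* **Classifiers** — K-nearest neighbours with a nine-distance menu
  (Minkowski, Chebyshev, Euclidean, standardised Euclidean, cosine,
  Jaccard, Manhattan, Hamming, correlation) and a Gaussian-kernel SVM
  (`K(x,z) = exp(−‖x−z‖²/σ²)`), both tuned by Bayesian hyperparameter
  optimisation (Gaussian-process surrogate, expected improvement, 30
  evaluations) under stratified five-fold cross-validation.
* **Evaluation** — accuracy, recall, precision, specificity, F1 and the
  Matthews correlation coefficient
  `MCC = (TP·TN − FP·FN)/√((TP+FN)(TN+FP)(TP+FP)(TN+FN))`, with septic as
  the positive class, reported per fold and as mean ± sd.
* **Synthetic corpus** — clinical cry corpora are proprietary, so the
  package ships a seeded generator of harmonic-plus-noise cry surrogates
  whose septic class has a lower fundamental, steeper spectral tilt and
  lower noise floor — hence lower spectral entropy and centroid, the
  documented septic signatures — with lognormal durations averaging 0.72 s
  (EXP) and 0.21 s (INSV).

## Worked example

```r
library(cryentropy)

ds  <- generate_dataset(30, "EXP", synthesis_config("well_separated"),
                        seed = 11)          # 60 labeled cry surrogates
tab <- extract_features(ds$segments)        # 60 x 57 feature table

select_features(tab)
#> <fe_selection: kept 27/57 features, threshold 0.6045>

rep <- cross_validate(tab, "SVM", folds = 5, seed = 11,
                      select_fe = TRUE, bhpo_budget = 15)
rep
#> <cv_report: SVM, 5-fold, seed 11, FE selection>
#>   accuracy      98.33 +/- 3.73 %
#>   recall        96.67 +/- 7.45 %
#>   precision    100.00 +/- 0.00 %
#>   specificity  100.00 +/- 0.00 %
#>   f1            98.18 +/- 4.07 %
#>   mcc            0.97 +/- 0.07

rep$tuned[[1]]
#> $kernel_scale
#> [1] 2.172438
#> $box_constraint
#> [1] 0.4002448
```

The fuzzy-entropy screen discards about half of the 57 concatenated
features (the mean-FE threshold 0.60 separates the class-informative
columns from noise-like ones), and the tuned SVM then recovers the
synthetic healthy/septic contrast almost perfectly: 98.3 % mean accuracy
over the five held-out folds with an MCC of 0.97 (1 = perfect, 0 =
chance). Recall (96.7 %) is the fraction of septic segments caught —
the clinically critical number.

## Command line

A thin CLI over the same functions is installed at
`exec/cryscreen` inside the package:

```sh
cryscreen=$(Rscript -e 'cat(system.file("exec","cryscreen",package="cryentropy"))')
Rscript $cryscreen simulate --n-per-class 30 --dataset EXP --seed 3 --out audio/
Rscript $cryscreen train --manifest audio/manifest.csv \
    --features mfcc,sencc --classifier svm --fe-selection \
    --folds 5 --bhpo-iters 30 --seed 3 --out run/
```

Subcommands: `simulate`, `extract`, `select`, `train`, `evaluate`,
`sweep` (the seven-feature-set grid: MFCC, SENCC, SCCC and all their
concatenations).

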