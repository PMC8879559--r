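# emgmpca

Multiscale PCA denoising and feature classification for multi-channel
surface electromyography (sEMG).

## The problem

Surface EMG recordings of hand gestures are a superposition of motor-unit
action-potential trains (MUAPTs) contaminated by instrumentation noise,
power-line interference, crosstalk between nearby muscles and a
low-frequency (roughly 0–19 Hz) component caused by unstable motor-unit
firing. Gesture classifiers are trained on compact per-trial features, and
a practical question for anyone building such a pipeline is whether a
cross-channel denoising step helps or hurts each feature family.

`emgmpca` implements the full pipeline needed to answer that question:

1. **MPCA denoising.** Each channel is decomposed with an orthogonal DWT
   (symlet `sym4`, periodized, depth *L*); the coefficients of every scale
   form a coefficient × channel matrix that is filtered by PCA
   (project onto the components whose eigenvalue exceeds 0.05 · Σλ, and
   back). A detail scale *l* is kept only when its relevance factor
   μ\_l = 1, decided by two process-monitoring statistics exceeding their
   control limits for more than a small fraction of coefficient rows:

   - Hotelling **T²** = Σ\_{j≤k} t\_j²/λ\_j with limit
     T\_α = k(m−1)(m+1)/(m(m−k)) · F\_{k,m−k,α},
   - **SPE** (Q statistic) = ‖(I − P\_k P\_kᵀ)x‖² with the
     Jackson–Mudholkar normal-theory limit from the residual eigenvalue
     moments θ\_n = Σ\_{j>k} λ\_j^n.

   The denoised signal is the inverse DWT of A\_L + Σ μ\_l D\_l.
2. **Decomposition operators.** Orthogonal DWT/IDWT (hand-rolled filter
   banks, exact Parseval), an L1-normalized CWT diagnostic (white-noise
   power ∝ 1/scale), and one-unit deflation **FastICA** (Newton step
   w′ = E{z g(wᵀz)} − E{g′(wᵀz)}w with g = tanh, unit-norm and
   Gram–Schmidt decorrelation).
3. **Three 10-dimensional feature families.**
   `arcoeff` — order-10 AR coefficients via Yule–Walker/Levinson–Durbin;
   `DWTF` — level-9 DWT scale energies [E(ca9), E(cd9), …, E(cd1)];
   `ICAF` — FastICA component weights from the trial segmented into
   pseudo-channels.
4. **Classification.** KNN (k ∈ {1, 4, 7, 10}, deterministic tie-breaks)
   and Gaussian naive Bayes under stratified 10-fold cross-validation;
   the correction rate is R = N\_tp/N\_t × 100 with full confusion
   matrices.
5. **Synthetic data.** A seeded MUAPT simulator (renewal discharge trains
   convolved with unit-energy biphasic templates, crosstalk mixing, white
   noise, 50 Hz line, band-limited baseline instability) generates
   labelled 6-class trial sets so the whole pipeline is testable without
   recordings. A reader for the UCI two-channel hand-grasp MAT-v5 layout
   supports real-data runs.

## Worked example

```r
library(emgmpca)

cfg <- synth_config(duration_s = 6, seed = 7)          # 2 ch @ 500 Hz
ts  <- generate_trialset(cfg, n_classes = 6, n_trials_per_class = 30)
ts
#> emg_trialset: 180 trials, subject 'synthetic', fs 500 Hz
#>   classes: 1 (n=30), 2 (n=30), 3 (n=30), 4 (n=30), 5 (n=30), 6 (n=30)

mpca_denoise(ts$trials[[1]])
#> mpca_result
#>   wavelet: sym4  level: 5
#>   scale relevance mu (fine -> coarse): 1 1 1 0 0

feats <- extract_all(ts, seed = 7)
feats$DWTF
#> feature_table (DWTF): 180 trials x 10 features, 6 classes

cross_validate(feats$DWTF, "knn", k = 1, n_folds = 10, seed = 7)
#> cv_result: knn (k = 1), 10-fold
#>   correction rate: 67.22% (121/180)
```

The μ flags say which detail scales the monitoring statistics considered
signal-bearing for this trial (here the three finest scales); the
correction rate is the cross-validated percentage of trials assigned
their true class. `run_experiment(experiment_config(seed = 1))` executes
the full raw-vs-denoised grid (3 features × {KNN k grid, naive Bayes} ×
2 arms) and returns the accuracy table and confusion matrices;
`channel_correlation_report()` and `detail_correlation_report()` provide
the correlation diagnostics.

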