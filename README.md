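# hrstress

Can a day-long stream of wrist-wearable heart-rate readings tell whether
the wearer had a stressful day? `hrstress` is an R package for exactly
this question: it turns irregular, adaptively sampled heart-rate streams
into fixed-length day vectors, extracts time- and frequency-domain
feature modalities, evaluates imbalance-aware classifiers under repeated
stratified cross-validation, and compares modalities with a
rank-based statistical framework. Because real cohorts of this kind are
typically confidential, the package ships a synthetic wearable-stream
generator with the same statistical structure, so every stage is testable
end to end.

It is aimed at researchers in digital phenotyping / mobile health who
have per-day binary self-reports (e.g. "Was today stressful?") and
passively collected heart-rate readings, and want a reproducible,
leakage-free analysis pipeline rather than an ad-hoc notebook.

## The pipeline

1. **Ingest & filter.** Readings (`participant_id,timestamp,bpm`) and
   daily labels (`participant_id,date,stressful`) are assembled into
   participant-days. A *valid day* has a label and readings in more than
   21 of 24 clock hours (an hour counts if it contains at least one
   reading).
2. **Regularize.** Per minute, the *maximum* bpm is kept (surges should
   stand out, not average away); empty minutes are filled by
   carry-forward, with the first reading propagated back to midnight;
   the 1440-slot series is then downsampled by window maximum to a
   480-point day vector *hr*₀…*hr*₄₇₉ (3-minute granularity).
3. **Featurize.** Three modality families per day vector:
   - `org`: the raw 480-point vector;
   - `fft`: the DFT half-spectrum magnitudes |HR₀…HR₂₃₉|, where
     HRₖ = Σₙ hrₙ·e^(−i2πkn/N) (conjugate symmetry of real signals makes
     the upper half redundant);
   - `wave50/150/250`: modulus of a continuous Morlet-wavelet transform
     ψ(t) = π^(−1/4)·e^(iω₀t)·e^(−t²/2) on integer scales 1…J
     (J = 10/30/50), compressed by a *per-day* PCA (scales as
     observations) to 5 components → 5·J features.
4. **Evaluate.** Six classifiers (ridge logistic regression, linear /
   polynomial / RBF SVM, random forest, gradient boosting) × four
   settings (balanced class weights or SMOTE, each with or without PCA),
   under 10×10 repeated stratified cross-validation. All preprocessing
   (scaling, SMOTE, PCA) is fitted strictly inside each training fold.
5. **Compare.** Majority baseline, Kruskal–Wallis across the per-modality
   best fold accuracies, Dunn's post-hoc z-tests with Bonferroni
   correction, and per-modality one-sample t-tests against the baseline.

## Worked example

```r
library(hrstress)

cfg <- sim_config(n_participants = 1, n_days = 200,
                  stress_lf_amp = 8, stress_burst_multiplier = 1.8,
                  seed = 42)
cohort <- simulate_cohort(cfg)

days  <- group_by_day(cohort$readings, cohort$labels)
valid <- filter_valid_days(days)          # label + >21 covered hours
nrow(valid)
#> [1] 164

day_tbl <- regularize_days(valid)         # 164 x 480 day vectors
fft_fs  <- build_features(day_tbl, "fft") # 164 x 240 magnitudes

res <- run_setting(fft_fs, setting_spec("bcw"),
                   classifier_spec("svm_poly"), cv_config(seed = 1))
res
#> <cv_result> fft | BCW | svm_poly: train 100.0%, test 85.3 +/- 7.9%, balanced 75.9 +/- 11.8%

majority_baseline(fft_fs$labels)
#> [1] 71.95
```

A mean balanced test accuracy of ~0.76 against a 0.5 chance level shows
the classifier recovering the injected stress signature (elevated
low-frequency amplitude and burst rate); on a generator with all stress
effects zeroed the same configuration sits at chance. The full grid
(`run_grid()`) and statistical report (`build_report()`) follow the same
pattern; see the methods vignette (`vignettes/heart-rate-stress-pipeline.Rmd`)
for the model, assumptions, and design choices.

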