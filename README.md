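# memdecode

Time-resolved multivariate decoding and representational similarity analysis
of epoched MEG data, built around a question from visual cognition: does the
*memorability* of an image — the stimulus-intrinsic tendency to be remembered
across observers — leave a detectable trace during early perceptual
encoding, before any deliberate memory process?

The package is for researchers who work with epoched multichannel
neural time series (MEG/EEG, or source-localized ROI time courses) and want
a tested, fully scriptable implementation of the standard analysis chain:

* **epochs container** — HDF5 layout for `trials × channels × times` data
  with per-trial image/condition labels and per-channel group labels;
* **preprocessing** — baseline mean removal, zero-phase 20 Hz low-pass,
  amplitude-based bad-trial rejection, PCA blink-artifact projection;
* **decoding** — pseudo-trial sub-averaging (random groups of *g* = 5),
  leave-one-out cross-validated linear-SVM accuracy for every image pair at
  every time point, averaged over repetitions into a time-resolved
  representational dissimilarity matrix (RDM) series; ROI decoding is the
  same code on a channel subset; temporal generalization (train at *t*, test
  at *t'*) reuses the diagonal's classifiers;
* **RSA** — hypothesis model RDMs (categorical vs dispersion geometry),
  per-subject Spearman ρ time courses, classical MDS for visualization;
* **inference** — cluster-size permutation tests (1-D time courses and 2-D
  generalization matrices, sign-flip maximum-cluster null), bootstrap
  peak-latency confidence intervals, exact Wilcoxon signed-rank, and
  signal-detection d′;
* **synthetic cohorts** — a generator with controlled representational
  geometry (an early image-identity signal shared by both conditions plus a
  dispersion difference confined to a known latency window) providing ground
  truth for recovery and calibration studies.

## The statistic at the core

At each time point *t* the pairwise decoding accuracy
*a<sub>ij</sub>(t)* of a linear SVM (C = 1, leave-one-out over *N* = 6
pseudo-trials per image) defines the dissimilarity entry of a *K* × *K* RDM.
Two hypothesis geometries are compared against the measured series by
Spearman rank correlation: a **categorical** model (between-condition pairs
1, within 0: conditions linearly separable) and a **dispersion** model
(within-high 1, between 0.5, within-low 0: high-memorability exemplars
spread out around the *same* centroid as the tightly clustered
low-memorability exemplars). Because the dispersion hypothesis predicts no
between-condition separability, the condition-level summary is the average
of within-high vs within-low RDM entries and their difference, tested
against 0 with a cluster-size permutation test: one-sample *t* per time
point thresholded at *p* < 0.05, maximal supra-threshold runs scored by
size, null distribution = maximum cluster size under whole-series sign
flips per subject, *p* = (1 + #{perm max ≥ size}) / (n<sub>perm</sub> + 1).

## Worked example

Simulate a small cohort with the default geometry (dispersion effect
confined to 149–228 ms), preprocess, decode, and test where the high−low
difference and the dispersion-model correlation are significant:

```r
library(memdecode)

cfg <- synth_config(n_subjects = 12, n_high = 4, n_low = 4,
                    n_trials_per_image = 20, n_channels = 64,
                    sampling_rate = 100, seed = 7)
cohort <- simulate_cohort(cfg)

rdms <- lapply(cohort$subjects, function(ep) {
  clean <- preprocess_epochs(ep)$epochs
  build_rdm_series(clean, decode_params(group_size = 5, repetitions = 2, seed = 7))
})
print(rdms[[1]])
#> <rdm_series> subject sub-01: K = 8 images, 61 time points (-100..500 ms)

tc <- lapply(rdms, condition_mean_timecourses)
diffs <- do.call(rbind, lapply(tc, function(x) x$difference$accuracy))
cluster_test_1d(diffs, chance = 0,
                params = stat_params(n_perm = 1000, seed = 7),
                times = rdms[[1]]$times)
#> <cluster_result> 3 cluster(s); n_perm = 1000, cdt = 0.05, alpha = 0.05, tail = greater
#>   cluster 1: size 1 (50..50 ms), p = 0.8202
#>   cluster 2: size 6 (160..210 ms), p = 0.01698 *
#>   cluster 3: size 1 (500..500 ms), p = 0.8202

rho <- do.call(rbind, lapply(rdms, function(r)
  rsa_correlate(r, dispersion_model(r$condition_of))$accuracy))
cluster_test_1d(rho, 0, stat_params(n_perm = 1000, seed = 7), rdms[[1]]$times)
#> <cluster_result> 3 cluster(s); n_perm = 1000, cdt = 0.05, alpha = 0.05, tail = greater
#>   cluster 1: size 1 (50..50 ms), p = 0.8362
#>   cluster 2: size 6 (160..210 ms), p = 0.01299 *
#>   cluster 3: size 2 (490..500 ms), p = 0.4875
```

The high−low decoding difference and the dispersion-model correlation are
both significant in a cluster spanning 160–210 ms — recovering the injected
149–228 ms window (onset detection lags the injected onset by one sample at
this SNR and 100 Hz grid) — while isolated single-point excursions elsewhere
are correctly assigned large p-values. The categorical model, run the same
way, yields no significant cluster.

## The analysis workflow

`analysis/` holds numbered drivers that run the whole study on a
desk-scale synthetic cohort (15 subjects, 5+5 images, 64 channels @ 100 Hz)
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R                # epochs + ground truth
Rscript analysis/02_preprocess.R              # cleaning + loss report
Rscript analysis/03_decode_rdms.R             # per-subject RDM series
Rscript analysis/04_condition_timecourses.R   # condition means + clusters + peaks
Rscript analysis/05_rsa_models.R              # model RDM correlations + MDS
Rscript analysis/06_temporal_generalization.R # 2-D generalization + clusters
Rscript analysis/07_behavioral_sensitivity.R  # d' + signed-rank on synthetic counts
```

A run of this workflow prints, among other things: within-high vs
within-low prototype distance ratio 12.4; grand-mean pairwise decoding
53–59% per subject; a high−low difference cluster 160–220 ms
(p ≈ 0.01) with peak 200 ms, CI [170, 200]; a dispersion-model cluster
160–220 ms with the categorical model silent; an MDS spread ratio of
29.7 vs 10.7 in the effect window; and a temporal-generalization
difference cluster covering train/test 140–230 ms. `run_pipeline()` exposes
the same chain as one configurable call (YAML-driven via
`read_pipeline_config()`).

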