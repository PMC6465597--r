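---
title: "Time-resolved decoding and representational geometry of image memorability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding and representational geometry of image memorability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question and the analysis it demands

Some images are reliably remembered by most observers and others reliably
forgotten; this stimulus-intrinsic property is called *memorability*. A
central question in visual cognition is whether memorability already leaves a
trace during early perceptual encoding — before any deliberate memory
process — detectable as a transient difference in how strongly individual
exemplars are represented in neural population activity.

The analysis strategy this package implements answers that question with
time-resolved multivariate pattern analysis of epoched MEG data under a
rapid serial visual presentation design:

1. **Pairwise decoding into RDMs.** At every time point $t$, a linear
   support-vector machine is trained to discriminate each pair of stimulus
   exemplars $(i, j)$ from the channel pattern vectors, with leave-one-out
   cross-validation over pseudo-trials. Accuracy (in %) populates a
   $K \times K$ representational dissimilarity matrix $\mathrm{RDM}_t$:
   decodability *is* the dissimilarity measure.
2. **Representational similarity analysis.** The measured
   $\mathrm{RDM}_t$ series is rank-correlated (Spearman's $\rho$) with
   hypothesis model RDMs: a *categorical* geometry in which high- and
   low-memorability exemplars form linearly separable clusters, and a
   *dispersion* geometry in which high-memorability exemplars are spread far
   apart while low-memorability exemplars cluster tightly around the same
   centroid.
3. **Condition-mean time courses.** Because the dispersion hypothesis
   predicts no between-condition separability, the informative summary is
   the average of the RDM entries *within* each condition:
   $\bar a_{\mathrm{high}}(t)$, $\bar a_{\mathrm{low}}(t)$, and their
   difference.
4. **Temporal generalization.** Classifiers trained at $t$ are tested at
   every $t'$; a diagonal-dominated matrix indicates a representation
   evolving through successive processing stages, a square matrix a
   sustained one.
5. **Nonparametric group inference.** Cluster-size permutation tests
   (one-sample $t$ thresholding, whole-series sign flips per subject,
   maximum-cluster-size null) control the family-wise error rate over time
   (1-D) and over train × test time (2-D, 4-connected components); peak
   latencies get bootstrap confidence intervals; behavioral sensitivity is
   summarized as $d' = z(\mathrm{HR}) - z(\mathrm{FAR})$ with exact Wilcoxon
   signed-rank tests at the group level.

No public recording accompanies the design, so the package is driven by a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes, with known ground truth for recovery testing.

## The synthetic cohort generator

Each trial of exemplar $i$ for one subject is

$$ x(t) \;=\; g \,\bigl[\, e(t)\, u_i \;+\; w(t)\, v_i \,\bigr] \;+\; \varepsilon(t), $$

with

* $u_i \sim \mathcal N(0, \sigma_{\mathrm{id}}^2 I_S)$ an **identity
  prototype**, independent of condition, switched on by an envelope $e(t)$
  that rises at $t_{\mathrm{early}} = 70$ ms and persists — it makes every
  exemplar decodable from every other without any condition difference,
  emulating the early identity information seen in time-resolved decoding;
* $v_i = c + r_i$ a **window prototype** active only inside the effect
  window $[149, 228]$ ms, where the centroid $c$ is shared by both
  conditions and $r_i \sim \mathcal N(0, \sigma_{\mathrm{cond}}^2 I_S)$ with
  $\sigma_{\mathrm{high}} = 1.0 > \sigma_{\mathrm{low}} = 0.3$. The shared
  centroid is the load-bearing design choice: within-high pair distances
  grow (expected squared distance $2 S \sigma_{\mathrm{high}}^2$) while the
  conditions remain linearly inseparable in expectation, so the categorical
  model RDM stays uncorrelated with the true geometry while the dispersion
  model matches it;
* $\varepsilon$ AR(1)-smoothed Gaussian noise with marginal SD
  $\sigma_n$ and coefficient $0.9$ at 1 kHz, rescaled as
  $0.9^{1000/f_s}$ so the autocorrelation time is sampling-rate invariant —
  white noise would make decoding unrealistically easy at high sampling
  rates;
* $g$ a per-subject log-normal gain (SD 0.1 on the log scale), making
  subjects exchangeable but not identical;
* raised-cosine ramps (5 ms) at the envelope edges to avoid ringing through
  the low-pass filter (a boxcar envelope is available).

Defaults mirror the emulated study design: 15 subjects, 15 high + 15 low
exemplars, 30 trials per exemplar, epoch −100..500 ms. Channel count and
sampling rate default to desk scale (64 channels, 250 Hz; 306 / 1000 Hz are
configuration choices away).

### Calibration of the default signal-to-noise ratio

The absolute scale of $(\sigma_{\mathrm{id}}, \sigma_{\mathrm{high}},
\sigma_{\mathrm{low}})$ relative to $\sigma_n$ is not identified by the
emulated design, so it was calibrated once: with
$\sigma_n = 1$ the default prototypes saturate pairwise decoding at 100%
from the identity onset onward, which destroys the analysis — a ceiling RDM
has no variance, so neither the dispersion contrast nor the condition
difference can be expressed. The default is therefore $\sigma_n = 10$,
which lands pairwise decoding in the 50–70% range that time-resolved MEG
decoding studies report, keeps the pre-stimulus baseline at chance, and
lets the injected window express itself as a 10–20 point within-high
advantage. These defaults are declared study conditions of the synthetic
cohort, not estimates of any real recording's SNR; recovery results below
are statements about this generative model only.

What the generator deliberately does **not** emulate: MEG forward physics
and sensor geometry, head movement, realistic blink waveforms (a fixed
spatial transient is injectable for testing the artifact projection),
heteroscedastic channel noise, and any stimulus-feature confound. Passing
recovery tests therefore show that the pipeline detects the geometry it is
designed for at realistic SNR — not that real data contain that geometry.

## Preprocessing choices

The epoch-domain chain is baseline mean removal (window −100..0 ms), a
zero-phase 20 Hz low-pass, rejection of trials whose absolute amplitude
exceeds 6000 units (per channel group when thresholds differ, e.g.
magnetometers in fT vs gradiometers in fT/cm), and blink removal by
orthogonal projection of the leading spatial principal components of
peri-event segments, with events detected as frontal-channel RMS $z$-score
peaks ($z > 4$), capped at 2 components or 90% of segment variance.

The low-pass is realized in the frequency domain with the squared magnitude
response of a 4th-order Butterworth — exactly the response a forward–backward
IIR application would have — applied with reflection padding and vectorized
across all trials and channels. The contract is behavioral: passband
(≤ half the cutoff) preserved within 5%, stopband (≥ 3× the cutoff)
attenuated by ≥ 20 dB, zero phase; the tests enforce those bounds with
sinusoid-fit measurements rather than assuming any particular realization.

## Decoding choices

* Pattern vectors are raw baseline-corrected, filtered channel values at one
  time point. No z-scoring or dimensionality reduction is applied — any
  scaling would be an undocumented addition to the procedure being modelled.
* Sub-averaging: trials of each exemplar are randomly partitioned into
  $\lfloor n/g \rfloor$ groups of exactly $g = 5$; remainder trials are
  discarded at random, and repeating the whole cycle $R$ times (default 100)
  marginalizes the loss. 30 trials yield $N = 6$ pseudo-trials.
* Cross-validation: fold $k$ holds out pseudo-trial $k$ of *each* exemplar,
  keeping every training set balanced at $2(N-1)$ vectors.
* The SVM is a linear C-SVM with $C = 1$, solved by a compiled SMO dual
  solver on a precomputed Gram matrix; the solver is cross-checked against
  libsvm (via e1071) for weight vectors, biases and whole leave-one-out
  accuracy curves. Decision ties ($w^\top x + b = 0$) resolve to the first
  class deterministically; this matters only on degenerate toys.
* Temporal generalization reuses the diagonal's trained classifiers rather
  than retraining per $(t, t')$, which guarantees that the matrix diagonal
  is bit-identical to the 1-D time course under shared seeds; the choice is
  recorded in the output metadata.
* ROI decoding is the same code path restricted to a channel group — no
  separate implementation.

## Model RDMs and their coding

The categorical model codes between-condition pairs 1 and within-condition
pairs 0. The dispersion model codes within-high 1, within-low 0 and
between-condition pairs 0.5 — under a shared centroid the expected
between-pair distance lies between the two within-pair distances. Because
the comparison is rank-based, results are invariant to the specific values
so long as this ordering holds; an option to mask between pairs out of the
comparison entirely is provided. Spearman's $\rho$ is computed per subject
and tested at the group level with the same cluster machinery (no Fisher
transform — the statistic is rank-based and the test nonparametric).
Classical (Torgerson) MDS of the window-averaged group RDM is provided for
visualization only; it feeds no statistic.

## Inference choices

* Cluster-defining statistic: one-sample $t$ against chance at each point,
  thresholded at the one-sided $p < 0.05$ quantile ($p < 0.025$ per sign
  when two-sided). The sign-flip null (whole series flipped per subject)
  makes no distributional assumption; $t$-thresholding is the standard
  realization of cluster-size inference. A pointwise permutation-quantile
  threshold variant is deliberately not claimed equivalent and not provided.
* Cluster mass is the **count** of supra-threshold points (cluster-size
  inference), not the summed statistic.
* Permutation p-values carry the $+1$ correction,
  $p = (1 + \#\{\max_\pi \ge s\})/(n_{\mathrm{perm}} + 1)$, so finite
  permutation counts cannot produce $p = 0$. When $2^{n}$ does not exceed
  `n_perm`, the test switches to exhaustive sign flips with a warning and
  exact enumeration p-values.
* Chance levels: 50% for accuracy curves, 0 for difference and $\rho$
  curves, one-sided in the direction the hypothesis specifies.
* $d'$ clips hit and false-alarm rates to $[1/2n,\, 1 - 1/2n]$ per response
  class before the inverse-normal transform (the log-linear alternative was
  rejected because clipping preserves representability of negative $d'$).
* The signed-rank test drops zero differences, uses average ranks for ties,
  and computes the exact null for $n \le 25$ by a generating-function
  recursion over doubled ranks (ties make the classical integer-rank
  recursion inapplicable; doubling restores integrality). Beyond $n = 25$ a
  normal approximation with tie correction takes over.
* Peak latencies: subjects resampled with replacement 1000 times; each
  resample contributes the argmax of its group mean; the CI is the 2.5/97.5
  percentile of that distribution. Flat maxima resolve to the earliest
  maximum and are flagged.

## Numerical and degenerate-input policy

Validation rejects epochs with non-finite values, non-uniform time axes, or
an exemplar appearing in both conditions, naming the violated invariant.
Zero-variance RDM vectors at a time point yield $\rho = 0$ with a flagged
count instead of `NA` propagation. All randomness flows through explicit
seeds derived hierarchically (global → subject → repetition → permutation),
so any stage re-runs in isolation reproducibly, and two runs of the full
pipeline with one configuration produce byte-identical summaries.

## Problem sizes used by the shipped studies

The test suite and the acceptance studies run the full pipeline at reduced
problem sizes chosen once: recovery cohorts use 15 subjects, 5 + 5 images,
20 trials per image, 64 channels at 100 Hz with 2 decoding repetitions;
the false-positive-rate study uses 200 null cohorts of 15 subjects × 150
time points with 500 permutations; chance calibration uses one signal-free
subject with 6 images × 30 trials and 20 repetitions. The `analysis/`
drivers use the same cohort with 5 repetitions and 1000 permutations.
Scaling the generator to 306 channels / 1 kHz and $R = 100$ changes compute
time, not code paths.

## Known limitations

* The generator's geometry is stationary within the effect window; it does
  not model drifting or rotating representations, so temporal-generalization
  recovery shows a square-within-window pattern rather than the
  diagonal-chain structure real perceptual cascades produce.
* The dispersion effect enters through exemplar prototypes only; trial-level
  representational variability is isotropic noise.
* Cluster-size inference controls the family-wise error rate weakly (under
  the global null); onset/offset of significant clusters are descriptive,
  not error-controlled boundaries, which is why the recovery contract is
  stated as overlap plus an onset tolerance rather than boundary equality.
* The sign-flip null assumes symmetric subject deviations under the null;
  with strong global effects the null distribution is conservative for
  cluster size.
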