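---
title: "Classifying breast tissue from fingerprint-region Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying breast tissue from fingerprint-region Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanBreast)
```

# The problem and the data model

A hand-held Raman probe interrogates ~0.5-mm spots of excised breast
tissue at 785 nm and records, per probed point, N repeat spectra
(accumulations) plus laser-off dark frames, on a fingerprint axis of
roughly 600–1800 cm⁻¹ at ~1.8 cm⁻¹ resolution. Each measurement is
co-registered with histology, which reports the percentage of cancer,
normal and adipose cells inside a 3-mm circle around the probed point.
The scientific question is whether a small number of interpretable
spectral bands suffices to classify each measurement as cancer, normal
or fat.

The package models a measured spectrum as

\[
  y(\nu) \;=\; \big[\,s_c(\nu)\, e_p(\nu)\, m(\nu) + b(\nu)\,\big]\,
               r(\nu)\, t \;+\; d\,t \;+\; \varepsilon(\nu),
\]

where \(s_c\) is the class band profile (a sum of Gaussian lines at the
registry bands), \(e_p\) a per-patient and \(m\) a per-measurement
log-normal band-amplitude effect, \(b\) a smooth autofluorescence
baseline one order of magnitude larger than the bands, \(r\) the
wavelength-dependent instrument response, \(t\) the exposure, \(d\) the
dark rate and \(\varepsilon\) i.i.d. Gaussian detector noise per pixel
and repeat. Every preprocessing step inverts one factor of this model:
averaging suppresses \(\varepsilon\), dark subtraction removes \(d\,t\),
division by the measured/certified standard ratio removes \(r\),
polycarbonate calibration fixes the \(\nu\) axis, BubbleFill removes
\(b\), and SNV removes the remaining multiplicative scale (including
\(t\)). Because SNV is the terminal step, the pipeline is exactly
equivariant to positive rescaling of the raw input.

# What the generator emulates — and what it does not

The default `cohortSpec()` encodes the study conditions the package is
exercised under: 20 patients, 388 measurements, N = 10 accumulations of
1 s (admissible range 0.1–4 s), and planted failures sized to the
canonical exclusion arithmetic — 58 noise-swamped acquisitions, 58
compositions meeting no labeling threshold, and 34 label mismatches
(28 fat-signature spectra under cancer/normal compositions, 6
protein-signature spectra under fat compositions), leaving 238 retained
measurements split 87 cancer / 58 normal / 93 fat. Class band
amplitudes follow the qualitative contrasts the classifier is expected
to find: cancer strongest at 1004 cm⁻¹ (phenylalanine), fat exactly
zero there and dominant at the 1129 and 1301–1304 cm⁻¹ lipid bands,
normal dominant at the 940 cm⁻¹ collagen band.

The generator's defaults — noise 30 counts/pixel/repeat, baseline scale
5000 counts/s against a band amplitude scale of 500 counts/s, patient
effect SD 0.15 and measurement jitter SD 0.10 (log scale) — were chosen
once as a plausible tissue-spectroscopy regime. What the generator does
**not** emulate: cosmic-ray spikes, ambient-light and substrate
artifacts, detector nonlinearity and saturation, spatial registration
error as a *process* (mismatches are planted directly), and any real
biochemical covariance between bands. Green tests therefore demonstrate
that the *pipeline machinery* is correct and self-consistent under the
stated statistical structure; they cannot certify performance on real
patient spectra.

# Numerical and design choices

**BubbleFill.** The published description of the baseline algorithm is
not reproduced in the sources available here, so the implementation is
a documented reconstruction of the idea: in square-normalized
coordinates, circles are grown from below each span and lifted until
they touch the spectrum; the touch point splits the span and recursion
continues while spans are at least `minBubbleWidth` (default 50 cm⁻¹,
well above the band widths) wide; the baseline is the upper envelope of
the arcs, smoothed by a moving average of width `minBubbleWidth/4`.
Three reconstruction details matter numerically: (i) the linear trend
through the endpoints is removed first and restored afterwards, which
makes straight-line baselines exact; (ii) spans touching a spectrum
boundary grow edge-aligned bubbles (apex at the boundary, radius equal
to the span width) and the envelope outside the outermost touch points
is replaced by the chord to the endpoints, which are treated as
background anchors — without this the arcs droop at the edges; (iii)
under heavy noise the envelope would hug the *lower envelope* of the
noise, leaving smooth scallops, so the pipeline grows bubbles against a
lightly pre-smoothed copy of the spectrum (`baselinePreSmooth = TRUE`
in `pipelineConfig()`); the returned decomposition is still exact,
`baseline + raman = input`. For noise-free inputs pre-smoothing is
unnecessary and `bubbleFill()`'s own default leaves it off.

**No resampling after calibration.** All spectra of a cohort share one
calibration model, so the mapped axis is already common to every
spectrum; the default therefore keeps the calibrated native axis.
Resampling to a finer regular grid (available via `resampleSpacing`)
would correlate adjacent noise samples, which matters because the
quality factor reads sub-smoother-scale variance as noise: interpolated
noise looks smooth and would let genuinely noise-swamped spectra pass
the gate.

**Quality factor.** The published metric's exact form is likewise not
available, so the package uses the smoothing-residual energy form
`qf = 1 − ‖x − smooth(x)‖²/‖x − mean(x)‖²` with a Savitzky–Golay
smoother (window 9 samples, order 3), clipped to [0, 1]. White noise
scores ≈ 0.44 (the fraction of noise variance a cubic 9-point fit
reproduces), smooth band-dominated spectra score near 1, and the metric
is monotone in signal-to-noise ratio — the properties the 0.6 gate
needs. The boundary is read strictly: `qf < 0.6` excludes, equality
keeps.

**Labeling and the exclusion ledger.** The 80/80/70 thresholds are
inclusive (≥). Rules are checked cancer → normal → fat; the order is
irrelevant when percentages sum to 100 but is fixed for degenerate
synthetic inputs. Exclusions are staged quality → category → signature
mismatch, and the ledger satisfies `initial = final + excluded` on
every run. The suspected-mislabeling exclusion is operationalized
entirely through the fat-consistency screen: a fat-vs-rest weighted SVM
trained on the post-gate labeled measurements flags every record whose
predicted fat status contradicts its composition label. This works
because fat vs protein-rich tissue is the most separable contrast in
the data (presence vs absence of the 1004 cm⁻¹ band), so a moderate
fraction of label noise does not move the decision boundary.

**Sparse band selection.** No installed library provides an
L1-penalized SVM, so the package implements one: squared hinge loss
with a lasso penalty, solved by FISTA (proximal gradient with Nesterov
acceleration, step size from the spectral norm of the design), warm
starts along a 30-point logarithmic penalty path. The penalty is chosen
by stratified five-fold cross-validated balanced accuracy with a
0.5-standard-error preference for sparsity; at the chosen penalty,
nonzero features below 0.2× the largest absolute weight are discarded
and at most nine features are retained, ranked by |weight| with ties
broken toward the lower wavenumber. The weight floor implements the
"discard less important bands" step and suppresses chance entries of
uninformative bands; the sparsity preference guards against the
winner's-curse of picking the densest penalty.

**Classification.** The weighted linear SVM itself is delegated to
libsvm (`e1071`), with inverse-class-frequency baseline weights and the
minority class further multiplied by γ (grid {1, 2, 5, 10}); C uses 7
logarithmic points on [10⁻³, 1]. Posteriors come from a Platt-style
sigmoid fitted on the training decision values with regularized targets
(finite on separable sets, slope constrained so the map is monotone
increasing). Grid points are scored by mean held-out fold AUC under
patient-grouped five-fold CV — patients, not measurements, are
partitioned, so no patient ever appears on both sides of a split — and
the pooled held-out posteriors of the winning grid point form one ROC
per model (per-fold AUCs are also reported). The ROC sweeps every
distinct posterior (plus 0 and 1) with the rule *positive iff
p ≥ λ*; trapezoidal AUC equals pairwise concordance with ties counted
one half. The operating point minimizes the distance to the (0, 1)
corner, ties resolved toward higher sensitivity (missing a positive
margin is the costlier error).

**Reduced-accumulation study.** Cohort membership is decided once at
the largest N and the same retained measurements are re-preprocessed at
each smaller N, isolating the effect of reduced signal averaging from
cohort-composition churn; at the reference N the run is bit-identical
to the default analysis. The high-noise stress condition used in the
tests (noise 300 counts, 10 patients × 80 measurements, quality gate
disabled for the study because at that noise the gate would empty the
reference cohort) was fixed as a regime where single-accumulation
spectra are genuinely SNR-limited, so that mean AUC decreases from
N = 10 through N = 1.

**Dosimetry.** Only the continuous-wave, >10 s skin MPE branch is
implemented (`0.2 · C_A` with `C_A = 10^{2(λ−700)/1000}`, λ in nm,
valid 700–1050 nm); shorter exposures follow a different rule and are
rejected rather than guessed.

# Problem sizes

The test suite exercises reduced cohorts (typically 5–10 patients,
30–96 measurements) for unit behavior, the full 388-measurement default
configuration for the exclusion accounting and the end-to-end
performance floor (10 seeded runs), 20-seed replicates for the
planted-band recovery and the accumulation study, and analytic or
brute-force oracles (pairwise concordance, closed-form means, planted
shifts) wherever one exists. `scripts/acceptance.R` reruns the default
configuration end to end and the accumulation study at 5 seeds.

# Known limitations

- BubbleFill and the quality factor are reconstructions of cited but
  unavailable algorithm descriptions; both are flagged as such above.
- The synthetic cohort's class contrasts are generous; absolute
  AUC/accuracy values on it say nothing quantitative about patient
  data.
- The fat screen assumes fat-vs-rest is nearly separable; with heavily
  corrupted labels or weak lipid contrast it would both miss mislabels
  and flag genuine records.
- Exact support recovery by any lasso-path selector is statistical, not
  deterministic: with small effect sizes correlated or chance features
  can enter, which is why the selection rule combines cross-validation,
  a sparsity preference and a weight floor.
- Multiclass classification, nonlinear kernels, cosmic-ray removal and
  vendor file formats are out of scope.
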