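---
title: "Models and methods behind cinephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cinephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cinephys` implements a complete multimodal psychophysiology pipeline for
film-viewing experiments: a synthetic cohort generator with known ground
truth, feature extraction for EEG, cardiac, facial-EMG and electrodermal
streams, the classical genre/correlation statistics, and a
leave-one-film-out rating-prediction protocol. This vignette explains the
models, the parameter choices, and what the package's tests do and do not
demonstrate.

## The experimental design being emulated

The reference design is a cohort of 21 subjects who each watch 8 short
films (4 comedies, 4 dramas, 261–445 s long) and rate each film on an
integer 1–10 scale, yielding 168 subject × film trials. Recorded streams
per trial: 18-channel EEG (10–20 montage, 1000 Hz), one vertical EOG
channel, a photoplethysmogram, surface EMG over *zygomaticus major* and
*corrugator supercilii*, and skin conductance; each trial is preceded by
a 60-s rest segment used as its baseline.

Because no public recording of this kind is available, the package's
first-class component is a generator that produces the whole cohort
synthetically, with configurable planted effects, so that every
downstream stage can be verified against ground truth.

## The synthetic cohort model

**Ratings.** For subject $s$ and film $f$,
$R^*_{sf} = \mu_s + \beta_e z^{(e)}_{sf} + \beta_v z^{(v)}_{sf} +
\varepsilon_{sf}$, rounded and clipped to $1..10$. Here $z^{(e)}, z^{(v)}$
are standard-normal latent engagement and valence levels,
$\mu_s \sim N(6.2, 1)$ subject means, and the coefficients are solved in
closed form: $\beta_e = r_e \sigma_{tot}$, $\beta_v = r_v \sigma_{tot}$,
with the residual variance chosen so the total pre-rounding SD equals
$\sigma_{tot}$ (default 2.4). With these defaults the within-subject
median split separates halves by roughly 3.5 rating points and the
trialwise latent–rating correlations hit the configured targets (default
$r_e = 0.4$, $r_v = 0.25$) up to a small rounding/clipping attenuation.
The rating noise level is a free parameter of the design; 2.4 was chosen
once so that the rating spread and split-half means sit in the range
typical of 1–10 film-rating scales, and is not revisited.

**EEG.** Channels are sums of band-limited Gaussian processes (theta
4–8, alpha 8–12, beta 12–30 Hz; raised-cosine band edges) plus a $1/f$
pink background, drawn directly in the frequency domain — which is
distributionally identical to band-filtering white noise — and normalised
to a 100 µV² background variance. Latent engagement modulates the beta
band weight ($w_\beta = 1 + 0.25\, z^{(e)}$), so extracted engagement
indices correlate with the latent level; latent valence asymmetrically
scales frontal alpha (F4 up, F3 down), driving the valence index. Blinks
are a fixed 400-ms biphasic template at Poisson times, strongest
frontally and copied (×2.5) into the EOG, enabling regression-based
correction tests. The EEG is generated at 1000 Hz and passed through the
same decimation path as real data would be.

**Cardiac.** RR intervals follow a stationary AR(1),
$RR_i = \mu + \phi (RR_{i-1} - \mu) + \epsilon_i$, with innovation
variance scaled so the stationary SD equals the configured SDNN (default
50 ms, $\phi = 0.8$, subject-specific $\mu \sim N(820, 60)$ ms). The PPG
places a fixed two-bump pulse template, maximum exactly at each beat
time, at 100 Hz.

**EMG.** A 10–350 Hz noise carrier (unit SD) is modulated by a constant
baseline envelope plus smooth Gaussian bursts at Poisson times. The
genre effect is planted *additively on the deterministic baseline
envelope*: subject $s$ carries a contrast
$\delta_s \sim N(d\,\sigma_\delta, \sigma_\delta)$ (default
$\sigma_\delta = 1.2$ µV) applied with opposite signs to comedies vs
dramas (zygomaticus high for comedies, corrugator high for dramas).
Because the rectified mean is linear in the envelope, the realized
paired Cohen's d of the extracted feature equals the configured `d` up
to the small Poisson burst noise — planting on burst amplitudes instead
would dilute `d` through burst-count variance.

**EDA.** A slow tonic level (drift + very-low-frequency wander) plus
skin conductance responses at Poisson times, each a Bateman kernel
$A(e^{-t/\tau_d} - e^{-t/\tau_r})$ with $\tau_r = 1$ s, $\tau_d = 4$ s.
Event times and amplitudes are returned as ground truth.

**Seeds.** All randomness flows from one master seed: a single seeded
stream draws a per-(subject, film, stream) seed table, so any single
trial is regenerable in isolation. `generate_cohort()` therefore returns
the manifest, ground-truth table and config, and materialises trial
waveforms lazily — a fully materialised default cohort would occupy
roughly 10 GB of memory, while the lazy design keeps extraction at
constant memory.

## Feature extraction

**EEG preprocessing** mirrors the standard reduction chain: decimation
1000 → 125 Hz, band-pass 0.05–30 Hz, bad-channel replacement, ocular
correction, artifact masking. All routine filtering uses zero-phase
frequency-domain (frequency-sampling FIR) filters with raised-cosine
edges: exactly linear-phase, deterministic, and far cheaper at 1000 Hz
than long time-domain kernels. Decimation keeps only the retained
spectral bins, which is simultaneously the anti-alias filter and the
rate change. FFT lengths are padded to 5-smooth integers (mixed-radix
FFTs degrade badly on large prime factors).

Bad channels — total power more than 10× above or 0.1× below the montage
median — are replaced by the mean of their neighbours in a fixed montage
adjacency list (a deterministic, testable stand-in for interpolation
methods that resample channel subsets). Ocular contamination is removed
by least-squares regression of each channel on the filtered EOG; on
short synthetic records this is stable and seed-insensitive, which
decomposition-based blink removal is not. Samples where any channel's
within-trial z-score exceeds 10 are masked, dilated by ±0.5 s so no
spectral window straddles an artifact.

**Band powers** are Welch estimates: 1-s (125-sample) Hann windows, 50 %
overlap, per-window mean spectral density in each band, then the
*median* across windows (windows overlapping masked samples are
dropped). Band membership uses half-open intervals [4, 8), [8, 12),
[12, 30). From trial and rest tables the package computes per channel
the three pair ratios θ/α, θ/β, α/β and the engagement indices
β/(α+θ) and β/α, plus the frontal arousal index
(β~F3~+β~F4~)/(α~F3~+α~F4~) and valence index
(α~F4~/β~F4~) − (α~F3~/β~F3~). "Ratios of the three bands" is read as
the three unordered pair ratios; the alternative (six ordered ratios)
would only duplicate reciprocals. Baseline correction subtracts the
rest-segment *index* value from the trial index value — the index is the
variable carried forward — rather than correcting band powers before
forming ratios; indices with a zero denominator are flagged missing,
never fabricated.

**Complexity measures** (11 per channel, computed on the cleaned,
unmasked 125 Hz film segment) follow their defining formulas: Petrosian,
Katz and Sevcik fractal dimensions; permutation entropy (order 3, delay
1, normalised by ln 3!, ties broken by order of occurrence); histogram
Shannon entropy with ⌈√N⌉ bins; spectral entropy over the normalised
Welch PSD; SVD entropy and Fisher information over the normalised
singular values of the delay-embedding matrix (m = 3, delay 1); Hjorth
complexity; relative roughness 2(1 − ρ₁); and the Gaussian closed form
of differential entropy ½ln(2πe σ²) on the broadband signal. Embedding
order 3/delay 1 and the binning rule are the conventional defaults of
complexity toolkits; population variance (denominator N) is used
throughout the module for internal consistency. Constant inputs return
fractal dimension 1 by convention and missing for variance-based
measures.

**Cardiac features.** Beats are local maxima of the 0.5–8 Hz band-passed
pulse wave above an adaptive threshold (2-s rolling mean + 0.5 × rolling
SD) with a 300-ms refractory period. The RR series is cleaned by a
Hampel filter (window 3 + 3, threshold 3 × 1.4826 × MAD, outliers
replaced by the window median and flagged). Ten summary statistics are
computed: HR, SDNN, RMSSD, SDSD, pNN20, pNN50 (strict inequalities),
MAD, Poincaré SD1, SD2 and SD1/SD2. SD1 uses the uncentred mean square
of successive differences, so SD1 = RMSSD/√2 *exactly* and
SD1² + SD2² = 2·SDNN² holds to machine precision with population
variance — the only convention under which both identities hold
simultaneously for arbitrary series. The rest baseline runs through the
same path with the minimum-interval requirement relaxed to 10 (a 60-s
rest holds only ~70 beats).

**EMG** is band-passed 10–350 Hz at the native 1000 Hz (the band demands
it), full-wave rectified and averaged; **EDA** subtracts an 8-s
moving-median tonic estimate, detects SCR peaks on the (lightly
smoothed) phasic residual with a 0.01 µS minimum amplitude, and reports
the sum of peak amplitudes divided by epoch duration. The moving median
is a deterministic replacement for convex tonic–phasic decompositions
and is adequate for the amplitude-per-time statistic, with one caveat
worked through in the tests: an 8-s window partially absorbs the ~15-s
Bateman kernel, so recovered amplitudes are attenuated by a
kernel-dependent factor (the closed-form oracle is verified with a long
tonic window, and the default window is verified to detect the event
with attenuated amplitude). All three features are baseline-corrected
as trial − rest.

## Statistics

Genre contrasts use the paired t-test on per-subject genre means with
the paired effect size d = mean(Δ)/SD(Δ) — the only convention
consistent with t/√n at n = 21. Feature–rating correlations are Pearson
coefficients pooled over all 168 trials (ignoring within-subject
dependence, replicating the reference analysis; a subject-aggregate
variant would be the conservative alternative). Benjamini–Hochberg
correction is applied within each channel across that channel's index
family; a global scope is a flag. The within-subject median split ranks
a subject's films and labels the lower half "low"; boundary ties are
resolved by a seeded jitter smaller than the integer rating resolution,
so distinct ratings are never reordered.

## Prediction protocol

The feature matrix holds one row per trial: identifiers, rating, and
357 baseline-corrected features (8 band/index + 11 complexity features
× 18 channels, 2 frontal scalars, 10 HRV, 2 EMG, 1 EDA). Identifier
columns are never imputed and never eligible as predictors — using film
or subject identity to predict a held-out film's ratings would be
target leakage.

Within each leave-one-film-out fold, strictly on the training rows:
column outlier thresholds (mean ± 3 SD, statistics computed once),
chained-equation imputation (median initialisation, then 10 sweeps of
per-column least squares on the 10 most-correlated feature columns — the
full 350-column regression is singular at 147 training rows; the
predictor-subset strategy mirrors standard MICE practice), selection of
the 15 features with the highest random-forest impurity importance, and
model fitting. Held-out rows are completed by applying the *fitted*
training imputation models. Leakage is asserted in tests by corrupting
the held-out film and checking training-fold bit-identity.

Models: gradient-boosted trees and RBF support-vector regression for
the continuous task; logistic regression, k-nearest neighbours, a
single decision tree, gradient-boosted trees and an RBF SVC for the
binary task (fixed documented hyperparameters: depth 3 / 150 rounds /
learning rate 0.1 for boosting; k ≈ √n for kNN). Metrics: MAPE
(observed rating in the denominator), MAE, accuracy, F1 (positive
class = high), and AUC from continuous scores (signed margins for the
SVC). Binary labels come from the within-subject split over *all* films
by default — the held-out film's rating participates in defining its own
label, replicating the reference convention; `fold_safe_labels = TRUE`
recomputes test labels against the training-film median instead.
Feature selection runs inside each fold by default; a
`global_selection` flag reproduces the leakier select-once variant for
comparison. Chance level is established by re-running the pipeline with
labels permuted within subject: across many permutations the mean AUC
sits at 0.5 (slightly below on finite folds, a known property of
cross-validated null data).

## What the synthetic cohort does and does not show

The generator reproduces the *statistical skeleton* of the design:
sampling rates, durations, baselines, band structure, beat-to-beat
dynamics, burst-like EMG, Bateman-shaped SCRs, and planted effect sizes
with known ground truth. It does not attempt biophysically realistic
EEG source mixing, PPG morphology beyond peak detectability,
respiration coupling, or movement artifacts beyond stereotyped blinks
and gross spikes. Passing tests therefore demonstrate that the
*pipeline* is correct (formulas, baselines, fold hygiene, calibration of
planted vs recovered effects), not that real recordings would yield the
reference study's effect sizes.

## Problem sizes and numerical choices

Property tests run at the full study design (21 × 8, planted d = 0.7,
50 seeds) but with films shortened to 30–32 s and rests of 15–35 s;
shortening only adds extraction noise and so works against detection.
Prediction-pipeline null/signal properties run on matrix-level cohorts
(generator latents + noise features) — signal content is then controlled
exactly, and the full signal path is covered separately by
extraction-level tests. Tie-breaks, degenerate inputs and zero-variance
guards are handled as described above; all stochastic steps draw from
explicit seeds, and the package restores the caller's RNG state after
every seeded operation.
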