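---
title: "Recognising stuttering disfluencies with PCA residual distances: models and methods"
author: "stutterPCA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising stuttering disfluencies with PCA residual distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stutterPCA)
```

## The problem

Stuttering interrupts fluent speech with events such as blocks (silent
stops before words, typically before plosives), syllable repetitions and
sound-initial prolongations.  Human assessment of these disfluencies is
subjective and inconsistent, which motivates automatic recognition.  The
package implements a recognition chain for 4-second mono utterances at
22,050 Hz that distinguishes the three disfluency types from fluent
speech:

1. an auditory front-end (512-point FFT frames, A-weighting, 21
   one-third-octave bands, 100–10,000 Hz) producing a 171 × 21 matrix of
   band levels per utterance;
2. a per-utterance principal component analysis of the band correlation
   matrix, whose *reconstruction residual distance* per frame is the
   classification feature;
3. a 5 × 5 Kohonen self-organising map as the baseline feature
   extractor for comparison; and
4. a 171-8-4 multilayer perceptron trained with BFGS under categorical
   cross-entropy.

The guiding idea of the feature model is deliberately inverted from most
spectral front-ends: it is not the fitted model but the *difference*
between the model and the data that carries the information.  A
per-utterance PCA is dominated by the utterance's most common frames —
silence and low-energy material — so the residual distance of a frame
measures how far it stands from that baseline, which preserves the
utterance's syllabic time structure in a single number per frame.

## The feature model

Let $X$ be the $d \times m$ matrix of band levels ($d = 171$ frames,
$m = 21$ bands).  Each column is standardized,
$z_{ij} = (x_{ij} - \bar{x}_j)/\sigma_j$, with the sample standard
deviation (divisor $d - 1$; this convention makes the variance of the
$i$-th component score exactly $\lambda_i$).  The correlation matrix
$S = Z^\top Z/(d-1)$ is decomposed as $S = E \Lambda E^\top$; scores are
$G = Z E_l$ and the rank-$l$ reconstruction is $Y = G E_l^\top$ (the
standardized mean is zero, so no offset is added).  The residual
distance of frame $i$ is

$$ d_i \;=\; \sqrt{\frac{\sum_{j=1}^{m} (z_{ij} - y_{ij})^2}{m - l}}, $$

an RMS residual per unexplained degree of freedom, in the family of the
Q/SPE statistics of process monitoring.  A frame lying in the span of
the retained components has $d_i = 0$ exactly.

Two diagnostics aid interpretation.  Factor loadings
$a_{jk} = \sqrt{\lambda_k}\, e_{jk}$ are, for a correlation-matrix PCA,
the correlations between band $j$ and score $k$ — the package enforces
this identity in its tests rather than treating the $\sqrt{\lambda}$
scaling as a convention.  The per-band contribution
$S_j = 1 - \mathrm{var}(z_j - y_j)/\mathrm{var}(z_j)$ measures how fully
a band is used by the model (1 = fully reconstructed, 0 = ignored).

### Component selection

The retained count $l$ is chosen by the joint Kaiser–Guttman /
cumulative-variance rule: $l = \max(n_K, l_V)$ with $n_K$ the number of
eigenvalues above unity (at least 1) and $l_V$ the smallest count
explaining at least 75% of total variance.  On speech-like material the
selected count varies from utterance to utterance (roughly 4–7), so the
default pipeline fixes `lOverride = 4` — the count the joint rule
settles on for the corpus-level analysis — while per-sample selection
remains available (`lOverride = NULL`) and is exercised by the
parameter-recovery tests.  A cross-validated selector was considered
and rejected: it adds a free parameter (the fold count) without a
defensible default for 171-frame samples, and the Kaiser/variance rule
is the selector the recognition results are defined with.

### Numerical choices

* Eigenvectors get a deterministic sign (largest-magnitude entry
  positive) so loadings are reproducible across platforms.
* `residualDistances()` requires $l < m$; at $l = m$ the statistic has
  no remaining degrees of freedom and the chain refuses to continue
  rather than return zeros.
* `standardizeLevels()` raises an error naming any zero-variance
  column, since a constant band cannot be standardized.
* Eigenvalues are clamped at zero below `-1e-10`; anything more
  negative is treated as a numerical failure, not noise.

## The auditory front-end

Frames are consecutive, non-overlapping, rectangular 512-sample windows
(23.2 ms at 22,050 Hz), matching a hop-equals-frame reading of a "23 ms
resolution" analysis; a 4-second signal provides 172 complete frames
and the final one is dropped to give exactly 171.  Per frame, the
one-sided FFT power spectrum is A-weighted (IEC 61672 analytic curve,
unity gain at 1 kHz) and aggregated into 21 base-ten third-octave bands
(centres 100–10,000 Hz, edge ratio $10^{1/10}$).

Band aggregation shares each FFT bin's power across bands in proportion
to the overlap of the bin's frequency span (bin centre ± half the
43.07 Hz bin spacing) with each band.  A simpler centre-frequency
assignment was rejected for a concrete reason: the 100 Hz band is only
23 Hz wide, narrower than the bin spacing, so it would contain no bin
at all, making its column constant and breaking standardization for
every utterance.  Overlap weighting keeps the bands an exact partition
of the analysis range (the Parseval-style test in the suite checks that
summed band powers equal total in-range spectral power) while
populating every band.

Levels are stored in dB with an additive power floor of `1e-12`, so
silence maps to a finite −120 dB rather than −Inf; scaling a waveform
by 2 raises all above-floor levels by 6.02 dB.  Whether the original
analysis stored linear power, dB or a sone-like loudness is not
recoverable; dB is the package's choice, consistent with the
loudness-like intent of the representation.

## The SOM baseline

The comparison extractor maps each 21-dimensional frame to the index of
its best-matching unit on a 5 × 5 Kohonen map trained online for 100
epochs with constant learning rate 0.1 and a bubble neighbourhood whose
radius falls linearly from 3 to 0 (Chebyshev grid distance; all units
within the radius move by `lr * (x - w)`).  Unit indices are row-major
and 0-based.  Two choices are the package's own, since neither scaling
nor neighbourhood shape is prescribed by the method description: frames
are standardized per band before training (unstandardized dB bands have
wildly unequal variances, which would dominate the Euclidean BMU
distance), and the bubble neighbourhood is the simplest scheme
consistent with an integer radius falling to zero.  Winner sequences
are fed to the classifier as raw indices; the classifier's own input
z-scoring handles their scale.

## The classifier

A single hidden layer of 8 tanh units and a 4-way softmax output,
trained under mean categorical cross-entropy by full-batch BFGS
(`stats::optim`) for at most 100 iterations from seeded uniform
[−0.1, 0.1] initial weights.  Inputs are z-scored with training-set
statistics.  When a validation partition is supplied, the weights with
the lowest validation loss seen during optimisation are retained — the
early-stopping reading of training "for 100 epochs" against a
validation set.  A learning rate and momentum are meaningless under
BFGS; a momentum-SGD fallback (`optimizer = "sgd"`) accepts them for
comparison runs.  The hidden activation is tanh and the output softmax,
the standard pairing that makes the outputs interpretable as
class-membership probabilities; the per-case maximum probability is
reported as the classification certainty.

The corpus split is stratified: per class, train/validation/test counts
37/9/9 (blocks), 36/5/5 (repetitions), 42/5/12 (prolongations) and
25/10/3 (fluent), i.e. 140/29/29 of 198.  For other corpus sizes the
pipeline falls back to a proportional ~70/15/15 plan.

## The synthetic-speech generator

No clinical corpus is distributable, so `generateUtterance()` emulates
the four classes from filtered-noise and harmonic building blocks:

* **block** — ≥ 1 s of near-silence, a 120 ms broadband plosive-like
  burst, then ordinary syllables;
* **repetition** — five 120–180 ms voiced bursts at 400 ms spacing with
  silent gaps, then continuous voicing;
* **prolongation** — ~2 s of band-limited noise confined to
  3,150–9,500 Hz (sibilant-like; its spectral centroid sits well above
  3,150 Hz), then ordinary syllables;
* **fluent** — syllables of 260 ms at 350 ms spacing (pauses < 150 ms)
  throughout.

All classes share the same syllable material (f0 ≈ 125 Hz, formants
near 450 and 1,400 Hz): classes should differ by their disfluency
*event*, not by speaker- or phoneme-like spectral markers, which real
corpora do not provide either — early designs that gave repetitions
their own f0/formant set made every frame class-diagnostic and the
comparison between feature arms degenerate.  Each utterance draws a
random onset shift (uniform in [0, 0.3] s in easy mode) because real
4-second excerpts of running speech do not start at a deterministic
point; per-syllable f0, amplitude and timing jitter are applied on top.
The `difficulty` knob scales contrast: `"hard"` adds background noise
(amplitude 0.02), wider jitter and onset shifts up to 0.5 s, and moves
the prolongation band down to 2,200 Hz where it overlaps voiced
harmonics.  Amplitudes are clipped to [−0.99, 0.99] before 16-bit WAV
quantisation to avoid wrap-around.

What the generator does **not** emulate: phonetic content, coarticulation,
speaker identity, age or gender, recording-channel effects, or the
within-class heterogeneity of real stuttering events.  Tests passing on
this material show that the chain recovers the designed spectral and
temporal class signatures; they do not certify clinical performance.

The companion fixture `generateLowRankFilterbank()` builds
`171 × 21` matrices as `rank` smooth cosine spectral profiles with
random time-varying weights (weight standard deviations tapering from 3
to 1.5) plus i.i.d. noise (sd 0.3).  These defaults place the first
four correlation eigenvalues clearly above unity and the remainder well
below, so recovering `rank = 4` with the selection rule is a meaningful
end-to-end check of the standardize → eigendecompose → select chain,
not a tautology: with noise present the selector could plausibly return
3 or 5.

## Problem sizes and reproducibility

Every stochastic entry point takes an integer seed and restores the
caller's RNG state; the pipeline derives per-stage sub-seeds from the
master seed, so a run is a pure function of its configuration.  The
test suite exercises the full 198-utterance corpus composition over
seeds 0–4 for the end-to-end study, 50 seeded replicates for
component-count recovery, and 100 random matrices for the SVD-oracle
equivalence of the eigendecomposition; unit tests use reduced corpora
(8 utterances per class) and shortened SOM/MLP schedules, sizes chosen
so the suite gives stable statistics while remaining quick to run on a
single CPU.

## Known limitations

* The residual-distance feature is computed per utterance, so feature
  values are not commensurable across utterances in the way pooled-model
  residuals would be; a pooled mode (`extractFeatures(..., model = )`)
  exists but is not the default, matching the per-sample variability
  the method description reports.
* The selection rule's 75% threshold and the Kaiser criterion are
  heuristics; on data whose eigenvalue spectrum decays smoothly the
  selected count is sensitive to noise level.
* BFGS with 1,412 parameters and 140 training cases can overfit;
  validation retention mitigates but does not remove this.
* On synthetic material the SOM baseline is competitive with, and often
  better than, the residual-distance features: its codebook is shared
  across the corpus, so winner indices are absolute frame-type labels,
  and synthetic classes separable in their band profiles are exactly the
  regime where frame-type labels suffice.  The residual distance is
  relative to each utterance's own model, which is its strength on
  heterogeneous clinical speech and its weakness here.  Conclusions
  about the ordering of the two extractors therefore do not transfer
  from this generator to real recordings.
* The WAV reader handles only the format the chain consumes (RIFF PCM,
  16-bit, mono); it is not a general audio loader.
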