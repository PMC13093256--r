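---
title: "Bag-of-waves EEG classification: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bag-of-waves EEG classification: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowaves)
```

## The problem and the model

Long-term single-channel EEG from freely behaving animals contains
rhythmic oscillations and transient waveforms whose occurrence rates can
differ between genotypes. `bowaves` turns such recordings into
interpretable count features and classifies individuals from them.

The generative assumption is extreme sparsity: within a short window
$\tilde{x} \in \mathbb{R}^L$ (2 s at 256 Hz by default), at most one
canonical waveform $c_k \in \mathbb{R}^P$ ($P < L$) is dominant, appearing
at some shift $\tau$ and non-negative scale $\alpha$:

$$\tilde{x} \approx \alpha\, S_\tau(c_k) + \text{noise},$$

where $S_\tau$ zero-pads a $P$-vector into length $L$ at offset $\tau$
(the adjoint of the windowing operator $W_\tau$). Under this assumption,
dictionary learning reduces to a clustering problem solved by
**shift-invariant k-means**:

1. *Assignment*: each window is matched to the waveform and shift
   maximizing the cosine similarity
   $\mathrm{sim}(W_\tau(\tilde{x}_i), c_k)$ over
   $k \in \{1..K\}$, $\tau \in \{0..L-P\}$.
2. *Update*: each waveform becomes the plain average of the aligned
   sub-windows $W_{\tau_i}(\tilde{x}_i)$ assigned to it.

Cosine assignment makes matching amplitude-free; the update keeps
centroids unnormalized so their shapes stay in physical units. Note the
cosine argmax does not always minimize the squared reconstruction error
(it ignores sub-window norms); the algorithm is used as stated because in
simulation it recovers planted waveforms at least as well as
error-minimizing assignment, and `reconstruction_objective()` reports the
true scaled-and-shifted squared error independently of the assignment
path.

A **bag-of-waves** (BOW) for a segment is the vector of per-waveform
assignment counts over the segment's non-overlapping $L$-windows,
concatenated across the per-genotype dictionaries. Counts are
TFIDF-weighted, $w_k = \log\frac{1+N_\text{train}}{1+N_k} + 1$, and
$\ell_2$-normalized, which makes the feature invariant to the count/rate
distinction. Classification is $\ell_2$-regularized (multinomial)
logistic regression; individuals are scored by pooling counts over all of
their segments before the transform. A factorized variant predicts
background strain first and disease genotype conditionally per strain.

Two baseline featurizations share all of this infrastructure: **BOS**
clusters unit-norm root spectra of the same windows with ordinary
k-means, and **SCW** slides mean-removed, $\ell_1$-normalized waveforms
over every sample offset, accumulating the winning inner products into
dense soft counts (standardized rather than TFIDF-transformed, and
mean-pooled per subject).

## Evaluation protocol

Subjects are split into two folds. Dictionaries are learned per genotype
from windows drawn from the *first half* of each dictionary-fold
subject's recording; encoding segments are drawn (possibly overlapping)
from *second halves*, so dictionary-fold subjects contribute only unseen
data at encoding time. Every subject outside the dictionary fold is then
scored leave-one-out: the inverse-regularization value `C` is chosen by
stratified-group 3-fold CV over the non-dictionary training subjects
(pooled per-subject accuracy, ties broken by segment-wise accuracy, then
by the strongest regularization), the model is refit on everything except
the held-out subject (TFIDF refit included), and the held-out subject is
predicted from its pooled counts. Fold roles then swap, so each subject
is predicted exactly once per split; splits are repeated with re-drawn
fold assignments and summarized with the corrected resampled t interval,
which inflates the naive variance by $1/n_\text{splits} +
n_\text{te}/n_\text{tr}$ to account for overlapping training sets.

Interpretation uses linear-model Shapley values
$\varphi_k = \beta_k (x_k - \bar{x}_k)$ on the pooled features, averaged
across a fold's leave-one-out models with sign $\pm 1$ by class
membership (ACSSV). Waveforms with positive mean coefficient are ranked
by ACSSV and reported with their Welch spectra (two 95%-length
Hann-tapered sub-windows at 90% overlap, zero-padded to 1024 bins) and
occurrence rates in counts/minute.

## Tunable parameters

| Parameter | Default (`full` profile) | Meaning |
|---|---|---|
| `L` | 512 samples (2 s) | analysis window |
| `P` | 256 samples (1 s) | waveform length |
| `K` | 200 | waveforms per genotype dictionary |
| `windows_per_dict` | 40 000 | training windows per dictionary |
| `segment_len` | 3600 s | encoding segment |
| `segments_per_subject` | 120 | hourly segments per subject |
| `grid` | $15$ points, $10^{-1}..10^{4}$ | inverse regularization `C` |
| `K_CV` | 3 | internal CV folds |
| `n_splits` | 5 | repeated fold assignments |
| `tol_factor` | $10^{-4}$ | k-means stop, × pooled window variance |
| `max_iter` | 300 | k-means iteration cap |

The `desk` profile (`run_config("desk")`) keeps the same pipeline at
minutes-scale sizes: `K = 16`, `P = 128` (0.5 s), `L = 256` (1 s),
2000 training windows, six 10-minute segments per subject.

The hyperparameter `C` is treated as *inverse* regularization strength
(larger = weaker penalty), the convention of every mainstream logistic
solver and the only direction compatible with a $10^{-1}..10^{4}$ grid of
useful model capacities; the penalty weight on the mean-log-loss scale is
$\lambda = 1/(2\,C\,N_\text{train})$. TFIDF uses the natural logarithm
(the smooth-IDF convention this weighting mirrors). BOW windows are
non-overlapping by default; the stride-$(L-P+1)$ alternative is exposed
via `segment_to_windows()` composition but not used by the pipeline.

## Numerical choices and degenerate inputs

* Sample indices and shifts are 0-based with half-open intervals
  `[start, start + len)`, matching the mathematical operator definitions
  and removing off-by-one ambiguity; "first/second half" splits at
  `floor(length/2)`.
* Assignment argmax ties break by lowest waveform index, then lowest
  shift. SCW offset ties break by lowest waveform index.
* Cross-correlations run through an FFT path when `P >= 64` and direct
  BLAS products otherwise; the two paths agree to `1e-8` relative
  similarity and identical argmaxes (tested).
* Zero-norm sub-windows or centroids have cosine similarity defined as 0.
  Windows whose best similarity is negative are still assigned (the
  assignment formula has no clamp); their scale $\alpha$ is clamped to 0
  only for reconstruction purposes.
* Empty clusters re-seed from the first `P` samples of a uniformly drawn
  training window using the fit's seeded RNG stream, the same recipe as
  initialization.
* The k-means stopping tolerance multiplies the *pooled scalar variance*
  of all training-window samples, the simplest reading of a "pointwise
  variance" of a window collection.
* All-zero pooled bags yield a zero feature vector with a warning rather
  than an error; downstream models see the origin, i.e. the most neutral
  point of the normalized feature space.
* Balanced window quotas use ceiling division (`ceiling(total/n)` per
  subject, no trimming), so a cohort of 3 subjects asked for 40 000
  windows contributes 13 334 each — every subject meets or exceeds the
  even share, and totals may slightly exceed the request.
* Window and segment draws avoid exclusion intervals by rejection
  sampling capped at 10 000 attempts before reporting the subject.
* Stratified group folds deal the subjects of each class (rarest class
  first, shuffled under the seed) to the fold currently lightest in that
  class; a multi-subject validation fold containing a single class
  triggers regeneration under a new seed, with a logged message.
  Single-subject folds are exempt — they can never be multi-class.
* BOS assignment is Euclidean nearest-centroid; on unit-norm spectra the
  Euclidean and cosine orderings coincide.
* Five repeated splits draw fold assignments with seeds `0..4`, each
  subject landing in either fold with equal odds; draws are repeated
  until every genotype appears in both folds, since a genotype absent
  from a fold would have no dictionary in that fold role.

## What the synthetic cohorts emulate

`make_waveform_bank()` + `simulate_cohort()` generate the data the BOW
model assumes: unit-norm canonical shapes — Hann-windowed sinusoidal
rhythms and Gabor-like transients — planted at Poisson rates
(events/minute) with log-normal amplitudes, placed without mutual
overlap, over Gaussian or 1/f-shaped background noise. Banks are
resampled until all pairwise shift-maximal |cosine| similarities are at
most 0.8, so "recovering a planted waveform" is well-defined. SNR is
defined as planted-event RMS over noise standard deviation within the
event support.

The validation cohorts were fixed as follows, with power arithmetic done
up front:

* **Recovery**: 4 subjects, 2 h at 256 Hz, three waveforms at 10/min
  each, white noise at SNR ≈ 9, dictionary `K` = planted + 2 from 1500
  windows. Dense planting keeps roughly a fifth of training windows
  event-bearing, the regime in which averaging-based clustering can
  align events.
* **Rate-separated classification**: two genotypes share two 6/min
  rhythms and differ only in one transient's rate, 1.0 vs 0.1 events/min;
  6 subjects per class, 4 h recordings, twelve 10-minute segments pooled
  per subject (120 min). The pooled planted-count difference is then
  ≈ 108 events against a Poisson-scale spread of ≈ 15, a ≈ 7σ margin.
  Background noise is 1/f (exponent 1), as in real EEG; this also keeps
  featureless noise windows matched to smooth low-frequency centroids
  instead of inflating the transient waveform's count floor. The
  dictionary uses `K = 32` from 2000 windows per genotype, matching the
  cluster-size regime of the full-scale configuration (tens of
  event-bearing windows against clusters of a few hundred).
* **Null**: identical rate vectors in both classes; accuracy is checked
  against a two-sided 99% binomial band around chance.

Passing these tests shows the pipeline recovers planted morphology and
rate differences under its own generative assumptions. It does *not*
show robustness to what the generator omits: sleep/wake architecture,
movement artifacts, non-stationary background spectra, amplitude drift,
or waveforms that overlap in time.

## Known limitations

* One waveform per window: windows spanning two events credit only one.
* Cosine assignment can mis-rank candidates when sub-window norms vary
  strongly within a window.
* Leave-one-out with small cohorts carries the usual anti-bias: under
  strong regularization a held-out subject's class is always the training
  minority, so weak-signal accuracies can dip below chance.
* The EDF reader/writer covers continuous 16-bit single-rate files only —
  enough for fixtures and interchange, not a general EDF+ implementation.
* The per-mouse seizure-event bookkeeping of the source cohort is not
  modeled; exclusion masks are applied only when event lists are
  supplied.
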