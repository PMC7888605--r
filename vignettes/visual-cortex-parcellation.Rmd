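---
title: "Decoding and parcellating mouse visual areas from calcium activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and parcellating mouse visual areas from calcium activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 5, fig.height = 4)
library(visparc)
```

## The scientific question

Mouse visual cortex contains at least six retinotopically defined areas —
primary visual cortex (V1) and the higher areas LM, AL, RL, AM and PM.
Retinotopy tells us *where* each area sits, but not whether the areas are
functionally distinct processing stages. visparc asks the question the
other way around: if we hide the retinotopic map and look only at calcium
activity (dF/F time series from wide-field pixels or two-photon neurons),
can the area that a pixel or neuron belongs to be decoded from its
activity alone? If yes, each area's circuitry imposes a recognizable
statistical signature on its responses.

Three analyses address this:

1. **Supervised classification.** Units are reduced to a low-dimensional
   feature space (PCA followed by LDA) and four standard classifiers are
   trained on a small labeled subset (5% of pixels in wide-field data,
   50% of neurons in two-photon data) to predict area membership of the
   rest.
2. **Semi-supervised parcellation.** Supervision is reduced to a single
   labeled grid cell at the interior of each area; the rest of the sheet
   is parcellated by region growing driven by a universal background
   model (UBM), MAP adaptation and a likelihood-gain merge score.
3. **Correlation and duration analyses.** Intra- versus inter-area
   correlations quantify the signature the classifiers exploit; duration
   sweeps compare trial-averaged, single-trial and resting-state inputs.

## The generative model behind the synthetic data

The original recordings (a wide-field dataset and the Allen Brain
Observatory two-photon resource) are not bundled. Instead, a first-class
synthetic generator produces data with the second-order structure the
analyses rely on. Each unit $i$ in area $k$ evolves as

$$
x_i(t) = \sigma_g\, g(t) \;+\; \sigma_a\, a_k(t) \;+\;
         h_{k,s}(t - t_{\mathrm{on}}) \;+\; \sigma_n\, \varepsilon_i(t),
$$

where $g$ is a global fluctuation shared by every unit, $a_k$ an
area-specific latent signal, $h_{k,s}$ a fixed response kernel of area
$k$ to stimulus $s$ (active inside trial windows only), and
$\varepsilon_i$ per-unit noise. All latent processes are unit-variance
Gaussian and white in time. In wide-field mode the noise field is
spatially Gaussian-smoothed (radius `spatial_smooth_px`, default 1 px) to
mimic optical blurring, and units live on a 2D raster whose areas come
from a budgeted region-growing layout in which V1 receives twice the
pixel budget of each other area — preserving the size imbalance that
makes the size-biased chance level interesting. Background pixels
(label 0) receive only global signal and noise and are excluded from all
analyses.

Because the latents are white, the resting-state correlations have closed
forms: intra-area $(\sigma_a^2+\sigma_g^2)/(\sigma_a^2+\sigma_g^2+\sigma_n^2)$
and inter-area $\sigma_g^2/(\sigma_a^2+\sigma_g^2+\sigma_n^2)$ (no
smoothing). The test suite verifies both at $T = 20{,}000$ frames.

What the generator deliberately does **not** model: hemodynamic and
optical gain fields, calcium indicator kinetics, eye movements and
behavioral state, retinotopic fine structure within areas, and
inter-area correlations of the stimulus kernels (each $(k, s)$ kernel is
drawn independently). Passing tests therefore demonstrate correctness of
the *pipeline* under the assumed covariance structure, not performance
on real recordings.

### Default study conditions

The reference simulation is a 64 × 64 sheet at 10 Hz with 8 stimuli
presented 10 times each in a block design (2 s stimulus, 2 s blank, a
fresh random stimulus permutation per block) and a 120 s resting tail,
with $\sigma_a = \sigma_g = \sigma_n = \sigma_{\mathrm{stim}} = 1$.
Frame rate and stimulus count are scaled down from typical wide-field
experiments (20 Hz, dozens of stimuli) to keep the whole pipeline fast
on one CPU; all problem sizes are parameters of `sim_params()`.

```{r map, fig.alt = "Synthetic six-area map"}
am <- generate_area_map(64, 64, seed = 7)
plot(am)
table(am$labels)
```

## The feature front end

Units are samples, timepoints are variables. The analysis matrix is
either the trial average (per stimulus, mean over its repetitions,
blocks concatenated in ascending stimulus order) or an untrialed
resting-state window. Each unit is z-scored across time before PCA; the
data carry no documented normalization convention, and z-scoring removes
trivially classifiable brightness offsets so that classification
reflects response *shape*.

* **PCA** uses the $1/n$ (expectation-form) covariance. The number of
  retained components defaults to the smallest $K$ explaining 95% of the
  variance, capped at 50 — enough to keep LDA well-posed while retaining
  the signal subspace. When there are more timepoints than units the
  spectrum is computed through the unit-space Gram matrix.
* **LDA** maximizes the ratio of the between-area scatter (the
  unweighted $1/C$ average of squared class-mean offsets) to the *total*
  covariance of the features, keeping at most $C-1 = 5$ directions. A
  ridge of $10^{-6}\,\mathrm{tr}(\Sigma)/K$ is added when the total
  covariance is ill-conditioned (condition number above $10^8$).
* Eigenvectors and discriminant directions are sign-fixed (largest
  absolute entry positive) so repeated fits are bit-identical.

In evaluation protocols both transforms are fitted on the training units
only and applied to the held-out units, so no test information leaks
into the representation.

## The four classifiers

All four share one contract: fit on features plus area codes, predict
area codes; every argmax tie breaks to the lowest area code.

| model | form | implementation |
|---|---|---|
| Bayes | one Gaussian per area, equal priors, ML rule | authored here (1/n MLE, floored covariance) |
| GMM | M = 4 full-covariance mixture per area | authored here (EM, k-means start, monotone log-likelihood, rel. tol. $10^{-6}$) |
| SVM | soft margin, RBF kernel, one-against-one vote | libsvm via e1071 (the decomposition is libsvm's native multiclass scheme) |
| ANN | 1 hidden layer × 30 units, softmax, cross-entropy | nnet |

Choices where the method descriptions leave room: the GMM mixture count
(described only as estimated empirically) defaults to 4 and is capped by
the smallest per-area training count; SVM uses C = 1 and
$\gamma = 1/(d\,\mathrm{var})$; the network trains by quasi-Newton
(BFGS) rather than mini-batch gradient descent — with a single hidden
layer both optimize the same cross-entropy surface, and BFGS needs no
learning-rate tuning. Covariance estimates are floored by
$\tau I$ with $\tau = 10^{-6} \times$ the mean eigenvalue, supplemented
by a floor shared across a model's components
($10^{-8} \times$ the mean training variance) so that, on noise-free
data, density comparisons between collapsed components are decided by
mixture weights rather than by numerical accidents of the collapse.

```{r supervised}
rec <- simulate_widefield(am, sim_params(seed = 3))
run_supervised(rec, "gmm",
               spec = split_spec(train_fraction = 0.05, n_repeats = 5,
                                 seed = 1))
```

The label-shuffle control (training labels permuted, test labels intact)
should land near the unbiased chance level of 16.67%:

```{r shuffle}
run_supervised(rec, "gmm",
               spec = split_spec(mode = "shuffle", train_fraction = 0.05,
                                 n_repeats = 5, seed = 1))
```

## Semi-supervised parcellation

The semi-supervised pipeline reduces supervision to six labeled grid
cells:

1. PCA features of every in-map pixel (labels unused).
2. A **UBM** — one diagonal-covariance GMM with `M_ubm = 64` components
   — is trained on all pixels. It plays the role reference models play
   in speaker verification: a population-wide density against which
   subset-specific models are expressed.
3. The sheet is tiled into 8 × 8-px cells (edge scraps under a quarter
   cell are merged into a neighbor).
4. The cell containing each area's **interior pole** — the distance
   transform argmax, chosen over the centroid because centroids of
   concave areas can fall outside them — is seeded with that area's
   label.
5. Cell models arise by **relevance-MAP adaptation** of the UBM:
   responsibilities give soft counts $n_k$ and data means $E_k$, and
   $\hat\mu_k = \alpha_k E_k + (1-\alpha_k)\mu_k$,
   $\hat w_k \propto \alpha_k n_k/n + (1-\alpha_k) w_k$, with
   $\alpha_k = n_k/(n_k + r)$ and relevance $r = 16$ (the standard value
   in the UBM literature; the method description does not fix it).
6. Each (labeled cell, unlabeled 4-neighbor) pair is scored by the
   likelihood gain of joint versus separate modeling,
   $S_{a,b} = \log p(D \mid \lambda) - \log p(D_a \mid \lambda_a)
   - \log p(D_b \mid \lambda_b)$ — a modified BIC whose penalty term is
   replaced by the adaptive threshold below. Computed from additive
   sufficient statistics, the score is exactly symmetric, and exactly
   zero when $r \to \infty$.
7. Scores are sorted and the top $x\%$ merged, $x$ falling linearly from
   80 to 20 as the labeled cell fraction grows; a cell contested within
   an iteration joins the higher-scoring region (ties to the lower area
   code). At least one merge per iteration guarantees termination.
8. A GMM classifier trained on a 20% sample of each final cluster
   re-predicts every pixel, smoothing the blocky cell boundaries.

**Why weights are adapted, not just means.** Adapting only the means (a
common reading of relevance-MAP) makes the merge score useless here:
data from two *different* areas adapt disjoint UBM components without
interacting, so the joint model fits exactly as well as the two separate
ones ($S \approx 0$), while two cells from the *same* area pay a small
mean-compromise cost — the score then prefers heterogeneous merges. With
weight adaptation, a subset from one area concentrates its weight budget
on that area's components; the joint model of a heterogeneous pair must
split the budget, costing every point log-likelihood. On the reference
simulation this flips the same-versus-cross pair ordering from 13% to
91% correct and lifts parcellation accuracy from roughly two-thirds to
the 90%+ range.

```{r semisup}
parc <- parcellate(rec, seed = 1)
parc
plot(parc)
```

Accuracy sits below the supervised result but far above the size-biased
chance level — supervision down to six cells degrades the boundaries
gracefully rather than catastrophically. Different UBM initializations
give slightly different accuracies but highly overlapping label maps
(`ubm_seed` varies only the UBM).

## Chance levels, correlations, durations

Two reference levels calibrate all accuracies: the fair-die level
$100/C$ (16.67% for six areas, rounded to two decimals) and the
size-biased level $100\sum_i p_i^2$ for class proportions $p_i$
(*truncated* to one decimal — the layer-4 session census
{AL 106, LM 267, RL 1023, AM 115, PM 234, V1 149} gives 33.988… which
prints as 33.9).

```{r chance}
chance_unbiased(6)
chance_biased(c(AL = 106, LM = 267, RL = 1023, AM = 115, PM = 234,
                V1 = 149))
```

`correlation_analysis()` averages Pearson correlations over all unique
unit pairs, split into same-area and different-area pairs. On raw
responses intra exceeds inter whenever $\sigma_a > 0$ — this is the
signature the classifiers read. A caveat discovered while building the
discriminant-domain version of this analysis
(`lda_correlation_ratio()`): for *centered* features the count-weighted
class means sum to zero, which forces the count-weighted sum of
inter-class mean dot products to be negative; with well-separated
classes the mean inter-area correlation of LDA features is therefore
negative, and the intra/inter *ratio* in the discriminant domain is
flagged undefined rather than reported as a misleading negative number.
Real recordings, whose representations retain shared non-discriminative
structure, can behave differently; on the synthetic conditions the
directional statements (intra > inter in both domains) are the robust
ones.

`duration_sweep()` truncates the feature time base and re-runs the
protocol for trial-averaged, single-trial and resting inputs. Because
the stimulus kernels are fixed per (area, stimulus), averaging across
trials raises SNR exactly as a trial-repeatable response should:
trial-averaged accuracy is never materially below single-trial accuracy
at matched duration, and resting accuracy grows with window length.

## Numerical and design notes

* All randomness flows through explicit seeds (`withr::with_seed`);
  fits, simulations and the CLI are bit-reproducible.
* Degenerate inputs fail loudly with classed conditions
  (`visparc_*_error`): zero-variance PCA input, classes with fewer than
  two samples, mixtures with more components than samples, trial windows
  outside the recording, under-length resting segments.
* EM reduces its component count (with a warning) when the data contain
  fewer distinct rows than requested components — the noise-free
  simulations exercise this path.
* The recording container is a plain-text directory (TSV matrices at 17
  significant digits, which round-trips IEEE doubles exactly, plus a
  JSON metadata file); every exported result embeds the seed and a
  configuration fingerprint.
* Known limitations: the parcellation assumes the six-area layout with
  one seeded cell per area (no automatic model selection for `M_ubm` or
  the relevance factor); fully unsupervised clustering is out of scope;
  the synthetic generator's independence assumptions make the supervised
  problem easier than real data, where accuracy is driven down by
  correlated noise and shared stimulus drive.
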