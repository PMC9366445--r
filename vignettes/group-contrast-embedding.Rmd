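---
title: "Embedded group-contrast learning for morphological species discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedded group-contrast learning for morphological species discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(morphocontrast)
library(dplyr)
```

## The problem

Cryptic species complexes -- most famously the whitefly *Bemisia tabaci* --
contain genetically distinct lineages whose morphology is so similar that
expert taxonomists cannot separate them by eye.  The taxonomically
informative life stage is the puparium, photographed as a low-resolution
grayscale photomicrograph.  Sample sizes in such studies are tiny by
machine-learning standards (tens of specimens per group), far too small to
train an image classifier in the usual one-image-one-label way.

`morphocontrast` implements the *embedded group-contrast* alternative: the
training unit is not a labelled image but a **pair** of images labelled
*same group* / *different group*.  A set of $n$ specimens yields $n(n-1)/2$
unordered pairs (or $n(n-1)$ ordered ones), so even 386 specimens provide
on the order of $10^5$ training items.  A small convolutional network maps
each image to a $k$-dimensional embedding (here $k = 2$), and training
shapes that space so that within-group distances shrink and between-group
distances grow.  Specimens are then identified by **nearest group
centroid** in the trained space, and the strength of group separation is
quantified by one-way MANOVA statistics (Wilks' $\lambda$, Pillai's trace)
with permutation-based significance.

## The model

### Network

The network is the classic small LeNet-5 layout for $28\times28$ grayscale
input:

| layer | output shape |
|-------|--------------|
| input | $1\times28\times28$ |
| convolution, 10 filters $4\times4$, stride 1, valid | $10\times25\times25$ |
| ramp (rectifier) | $10\times25\times25$ |
| pooling $2\times2$, stride 2 | $10\times12\times12$ |
| convolution, 20 filters $4\times4$ | $20\times9\times9$ |
| ramp | $20\times9\times9$ |
| pooling $2\times2$, stride 2 | $20\times4\times4$ |
| flatten | $320$ |
| linear | $k$ (2 default, 15 optional) |

The kernel size $4\times4$ is forced by the shape algebra ($28-25+1 = 4$,
$12-9+1 = 4$).  With $k = 2$ the network has 4,032 trainable parameters --
verifiable by enumerating `init_weights()`.  The pooling operator is max
pooling by default (the usual companion of rectifier activations in modern
LeNet variants); mean pooling is selectable via `network_spec(pool =
"mean")`.

### Loss and optimisation

Both images of a pair pass through one shared-weight network (a Siamese
arrangement).  With embedding distance $d$, same-group pairs contribute
$d^2$ and different-group pairs $\max(0, m_c - d)^2$ -- the margin-based
contrastive loss, with margin $m_c = 1$ by default.  This is the canonical
functional realisation of "maximise between-group, minimise within-group
distance"; any loss with that monotone structure would serve, and the
margin only sets the scale of the embedding.

Optimisation is Adam with step size $\eta = 10^{-3}$ by default (plain SGD
is selectable).  Weights are initialised with a seeded uniform fan-in
scheme; biases start at zero.  There is no early stopping -- the budget is
entirely config-driven (`n_rounds`, `pairs_per_round`, `batch_size`), so
the full-study regime (10 rounds of 1863 batches of 64) and desk-scale
regimes are both expressible.  Because same-group pairs are a small
minority of all pairs, each round by default draws a seeded, class-balanced
sample of pairs (equal same/different); set `balanced = FALSE` to present
every unordered pair exactly once per round, shuffled between rounds.

Two seeds (`init_seed`, `shuffle_seed`) drive all randomness through
independent substreams; identical seeds, configuration and data reproduce
bit-identical weights and logs.

### Ordered versus unordered pairs

The loss is symmetric in the pair, so unordered pairs are the default
training unit.  Counting utilities (`enumerate_contrasts(ordered = TRUE)`)
support the ordered convention as well, under which 386 and 366 specimens
give 148,610 and 133,590 contrasts.  The batch bookkeeping utilities
reproduce the reference regime of 1863 batches of 64 per round and
1,192,320 presentations over ten rounds from 119,232 contrasts.

## Image preparation

Raw photomicrographs pass through a fixed chain:

1. **Grayscale via Von Kries chromatic adaptation** (RGB inputs only):
   sRGB is linearised, mapped to XYZ and then to cone responses
   (Hunt--Pointer--Estevez), rescaled by the adopted white point's cone
   response relative to D65, and the luminance channel is gamma-encoded.
   With the default D65 white the transform is exactly neutral for
   achromatic pixels.
2. **Percentile exposure normalisation** (defaults: 1st and 99th
   percentiles to 0 and 1).  Manual brightness/contrast editing is not
   reproducible; a percentile stretch is the automated surrogate.
   Constant images are passed through with a warning.
3. **Crop and white frame**: the tight bounding box of pixels darker than
   0.98 of full white, centred on a square pure-white frame whose side is
   the larger box dimension.
4. **Step-down to 28 x 28** by exact area-average resampling, which maps
   constants to constants and preserves the image mean to machine
   precision.  Bilinear interpolation is selectable; the resampling kernel
   used by any particular framework's "step-down" is generally unstated,
   and area averaging is the deterministic, parameter-free choice.

"Stepping down" is implemented as plain downsampling, not a learned
autoencoder: it is a resolution standardisation step, and a deterministic
kernel keeps the whole chain parameter-free and reproducible.  The chain is
order-fixed; running `prep_images()` on an already prepared set is a no-op
(prepared inputs are detected by their target geometry), which makes
preparation idempotent.

## The synthetic image generator

Real puparium image sets cannot ship with a package, so every stage is
exercised against a seeded generator that emulates their statistical
structure rather than their photographic appearance.  Each specimen is an
8-bit grayscale rendering of:

* an elongate **superellipse outline** (aspect ratio ~1.55--1.67,
  exponent 2.4),
* a posterior interior **Gaussian blob** (a vasiform-orifice analogue),
* faint transverse **segmentation bands**, and
* a sinusoidal **margin crenulation**,

on a pure-white background.  Group identity shifts the six shape
parameters by $\delta \cdot u_g \cdot s$, where $u_g$ is a unit-norm
direction drawn once per group from a seeded stream and $s$ a fixed
per-parameter scale vector; $\delta$ is therefore a single interpretable
between-group effect size.  Specimen identity adds jitter (rotation
$\sigma = 3^\circ$, scale $\sigma = 3\%$, brightness $\sigma = 0.03$,
inside-the-outline pixel noise $\sigma = 0.01$), and a two-level
*substrate* factor (hairy vs. glabrous rearing leaf) applies one fixed
aspect-ratio and margin-amplitude shift to every group, mirroring the
ecophenotypic effect of leaf hairiness on puparial form.

Two properties anchor the generator's honesty:

* $\delta = 0$ makes group labels carry **no** information (tested by a
  permutation test on within- vs between-group image distances, and by
  chance-level held-out classification), and
* between-group image distance is non-decreasing in $\delta$.

The default jitter magnitudes are not estimates of biological variation --
no quantitative within-group image variance is available for real
specimens.  They were chosen once so that $\delta \approx 1$ yields
near-perfect separability and $\delta = 0$ chance behaviour, which is
exactly the regime the discrimination experiments need.  Consequently,
passing tests demonstrate that the *pipeline* recovers group structure at
a given effect size; they say nothing about the effect size real puparia
exhibit.  The generator also omits features of real data -- focus-stacking
artifacts, staining, moulting sutures, parasitised specimens, non-white
debris -- so real-data performance must be established on real images.

## Evaluation

`post_hoc_identify()` embeds the training set and assigns each specimen to
the nearest group centroid (ties broken to the lexicographically first
label and flagged); results are tabulated in a confusion matrix with raw
accuracy and the **multiclass Matthews correlation coefficient** in the
covariance (Gorodkin) form, which reduces exactly to the classic binary
formula on $2\times2$ tables (tested).  A degenerate marginal (every
specimen assigned to one class) makes the MCC denominator vanish; the
conventional value 0 is returned with a warning.

`jackknife()` implements the sequester-and-retrain stability check for
small samples: each of `n_holdout` randomly selected specimens is removed
in turn, the network is **retrained from scratch** on the remainder under
an identical configuration, and the holdout is classified in the retrained
space.  Holdouts whose removal empties their group are flagged rather than
scored.  The per-iteration retraining budget is configurable because a
full-budget retraining per holdout is a workstation-scale computation.

## Feature-space statistics

`manova_stats()` computes Wilks' $\lambda = |E|/|E+H|$ and Pillai's trace
$V = \mathrm{tr}\,[H(H+E)^{-1}]$ from the between- and within-group scatter
matrices, with Rao's $F$ approximation for $\lambda$ and the standard
Pillai $F$ (dof $s(2m+s+1)$, $s(2n+s+1)$).  For $p = 2$, $g = 15$,
$N = 386$ these degrees of freedom are 28 and 740 (Wilks) / 742 (Pillai) --
an algebraic consequence of the formulas, reproduced exactly in the tests.
An eigenvalue route ($\lambda = \prod (1+\theta_i)^{-1}$,
$V = \sum \theta_i/(1+\theta_i)$ for eigenvalues $\theta_i$ of $E^{-1}H$)
serves as an independent oracle, and `stats::manova` as a cross-check; the
implementation itself never calls either.  A singular within-group scatter
(possible with tiny groups in 2-D) falls back to a ridge pseudo-inverse
with a warning, or errors if `fallback = FALSE`.

"Bootstrapped" significance is implemented as a **label-permutation test**
-- the natural nonparametric test of group separation, with exact level
under exchangeability -- using the add-one estimator
$p = (1 + \#\text{extreme})/(n_{\mathrm{perm}} + 1)$ so $p = 0$ is
impossible ($\lambda$ counts smaller values as extreme, $V$ larger).  A
true within-group resampling bootstrap is available behind
`method = "bootstrap"` and reports percentile intervals instead of
p-values.

`tsne_ordination()` is an exact-gradient t-SNE (perplexity calibration by
bisection, early exaggeration, momentum switch at iteration 250, adaptive
gains), run over a grid of perplexity and iteration settings because
apparent t-SNE clustering can be an artifact of a single setting.  The
iteration grid is produced by snapshotting one seeded descent, so grid
cells are mutually consistent and individually reproducible.  Exact
gradients are appropriate at the problem sizes involved (a few hundred
specimens); no tree approximation is provided.

## Numerical and design choices

* **Tie-break** in nearest-centroid assignment: lexicographically first
  group label, flagged in the output.
* **Divergent training** (non-finite loss) aborts with the offending batch
  named.
* **Degenerate inputs**: single-group training sets, empty images after
  background removal, upscaling requests, constant images and singular
  scatter matrices all have explicit contracts (error or warning) rather
  than silent behaviour.
* **Weight serialisation** is a single JSON container with full-precision
  numbers (spec, seeds, config digest, tensors) -- portable and diffable.
* **Desk-scale budgets**: the worked examples and tests train 4 rounds of
  64-contrast batches on a few thousand balanced pairs with
  $\eta = 3\times10^{-3}$, which reaches zero training error on separable
  synthetic sets (300 specimens, $\delta = 2$) in a few minutes on one
  CPU.  The package default remains $\eta = 10^{-3}$, which is the safer
  setting for longer, full-budget runs.
* The per-batch training log records the contrastive loss; the
  nearest-centroid training error is evaluated at the end of each round
  (the exact error metric displayed during training is an implementation
  choice; misassignment rate is ours).

## Known limitations

* The generator's shape family is closed-form and grayscale by design; it
  is a statistical stand-in, not a photorealistic puparium model.
* MANOVA $F$ approximations assume multivariate normality within groups;
  on trained feature spaces (which are anything but normal) only the
  permutation p-values should be interpreted.
* t-SNE coordinates are not metrically meaningful across grid cells; the
  grid is for qualitative robustness, not quantitative comparison.
* Real-data values of $\lambda$ and $F$ from the original study depend on
  the original images and trained weights and are not reproducible from
  this package alone; only their degrees of freedom and attainable bounds
  are.

## A complete desk-scale run

```{r example, eval = FALSE}
syn <- synthetic_config(n_groups = 15, per_group = 20, delta = 2, seed = 42)
images <- generate_image_set(syn) |> prep_images()

cfg <- train_config(n_rounds = 4, pairs_per_round = 4096,
                    learning_rate = 3e-3, init_seed = 43, shuffle_seed = 44)
model <- train_contrast_cnn(images, cfg)
glance(model)

posthoc <- post_hoc_identify(model, images)
posthoc$mcc                      # 1 on this separable set

manova_stats(model$scores)
permutation_test(model$scores, n_perm = 999, seed = 45)

autoplot(model$scores)           # the trained 2-D feature space
```
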