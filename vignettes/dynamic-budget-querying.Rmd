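---
title: "Dynamic-budget superpixel querying: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-budget superpixel querying: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albudget)
```

## The problem

Labeling images for semantic segmentation is expensive, and in
background-dominant domains — the motivating case is UAV imagery of crop
fields, where soil dominates and the rare weed class is what actually
needs labels — most of that expense is wasted on easy pixels.  Regional
active learning addresses this by labeling only high-impact *regions*
of high-impact images.  The established regional schemes use a *static*
budget: a fixed fraction `q` of regions is queried in every selected
image.  But the number of genuinely informative regions varies from
image to image, so a static budget over-labels easy images and
under-labels hard ones.

This package implements a *dynamic-budget* alternative: each selected
image's superpixel uncertainty scores are split into a high and a low
cluster by two-class Jenks natural breaks, and exactly the high cluster
is queried.  The number of labeled regions per image then adapts to the
image content at no extra asymptotic cost.

## The querying model

**Uncertainty.** The learner provides, per image, `T` stochastic
forward passes (e.g. MC-Dropout), giving class distributions
$P_{t,c}(u,v)$ at pixel $(u,v)$.  The pixel score is the BALD
(Bayesian Active Learning by Disagreement) acquisition, implemented as
the sum of the mean sample entropy and the entropy of the mean sample:

$$U(u,v) \;=\; \frac1T \sum_{t=1}^{T} E\big(P_{t,\cdot}(u,v)\big)
\;+\; E\Big(\frac1T \sum_{t=1}^{T} P_{t,\cdot}(u,v)\Big),
\qquad E(P) = -\sum_c P_c \log P_c .$$

A note on the sign: the classical BALD mutual information is the
*difference* of these two terms (entropy of the mean minus mean
entropy).  The sum form is what this querying scheme specifies, and
since both terms are large exactly where predictions are uncertain
and/or disagree, the sum is a perfectly serviceable ranking score; the
canonical difference form is available as
`bald_map(stack, mode = "mutual_information")`.  Entropies are in nats
(the log base only rescales scores and cannot change any ranking, so
nothing downstream depends on this choice), with $0\log 0 = 0$ by
continuity.

**Aggregation.** The image score $U^{(i)}$ is the mean of its pixel
scores; the superpixel score $U^{(s)}$ is the mean over member pixels.
Ranking is two-stage: one sort of the $n$ pool images, then a sort of
the $m$ superpixel scores in each of the $b$ selected images — cost
$n\log n + b\,m\log m$, never the $nm\log(nm)$ of a pooled region sort.
`instrument_ranking()` counts touched scores and actual sort
comparisons so the contract is checkable, not just asserted.

**The split.** For two classes, Jenks natural breaks reduces to the
single split of the sorted scores minimizing the total within-class sum
of squared deviations.  `jenks_split_2()` scans all distinct-value
split points with prefix sums ($O(n\log n)$, exact); a cluster count of
two is hard-coded — a harsher three-cluster split was considered and
rejected upstream of this design because it under-labels.  Conventions
for degenerate inputs, chosen once: all-equal scores query *nothing*
(equal uncertainty carries no ranking signal, and being conservative
with the budget is the point of the method); a single eligible score
queries that one segment (an image worth selecting should yield at
least one region); values exactly equal to the break stay in the low
class.

**Partial labels.** Queried superpixels receive their ground-truth
labels from the (simulated) oracle; everything else in the image is set
to an ignore value, 255 by convention, which both the learner's loss
and the IoU evaluation skip.

**Budget accounting.** The ledger records integer counts — labeled
superpixels and total eligible superpixels per queried image — and the
average labeled fraction is always recomputed as
$\sum \text{labeled} / \sum \text{total}$ from the raw counts, never
updated incrementally, so it is exact.  This average is the labeling
cost proxy: a static-budget run is *budget-matched* to a dynamic run by
setting `q_fraction` to the dynamic run's recorded average, which
reproduces the dynamic total up to per-image rounding (at most one
superpixel per image, since the static count is
`round(q * m_eligible)` with a floor of one).

**Foreground mode.** In background-dominant imagery a model learns the
background class almost immediately, after which background pixels have
near-zero uncertainty and the Jenks split degenerates to
foreground-vs-background — querying essentially all vegetation, which
defeats the purpose.  Foreground mode therefore (a) masks background
pixels out of the image score, (b) multiplies the image score by the
image's foreground fraction so vegetation-free tiles sink in the
ranking, (c) excludes background-flagged superpixels (zero foreground
pixels) from both selectors, and (d) counts only foreground superpixels
in the ledger totals.  The foreground mask comes from the model's own
background prediction (`mask_from_prediction`, the mode the loop uses)
or from thresholding the CIVE vegetation index
($0.441R - 0.811G + 0.385B + 18.78745$, lower = more vegetative;
`mask_from_cive`, useful for bootstrapping before any model exists,
with Otsu's method choosing the threshold when none is given).
Whether ranking should use the masked mean, the fraction scaling, or
both was genuinely open; the implementation composes both (mask, then
scale), since they address different failure modes — the mask keeps
easy background pixels from diluting the foreground signal, the scaling
keeps near-empty tiles from winning on a handful of uncertain pixels.

## Superpixels

`slic_segment()` implements SLIC: localized k-means in the joint
CIELab + position space, centers seeded on a regular grid, each center
competing only within a `2S × 2S` window.  Compactness defaults to 10
(the common default for Lab-space SLIC; exposed in configuration), and
the realized segment count may differ slightly from the request (empty
clusters are dropped; labels are relabeled to the contiguous range
`1..m`).  Segmentation is deterministic for fixed inputs.  Connectivity
enforcement is deliberately omitted: stray single-pixel assignments are
rare at the compactness used, and scoring/selection operate on label
sets, not contours.

## The synthetic data and what it does (and does not) show

`make_field_dataset()` emulates the statistics that make the motivating
field data hard: ~85% soil background in every tile, a crop class
(~13% of pixels, present in ~87% of tiles), a rare weed class (~2% of
pixels, present in ~22% of tiles), and entirely vegetation-free tiles.
Plants are elliptical blobs; soil is far from both plant colors, while
crop and weed are close in hue — separating the two vegetation classes
is the hard part, as in the real data.  Crop blobs are a uniform
cultivar; weed blobs get a wide per-blob brightness factor
(0.65–1.45), so a classifier needs labels across many weed blobs
before its boundary settles.  That is the mechanism that gives the
learning curve its sample-size dependence and gives targeted querying
something to be better *at*.  Generated scenes are pure functions of
the seed.

`make_prob_stack()` plants high-disagreement regions aligned to chosen
superpixels: outside them every Monte-Carlo sample is peaked on the
true class (jitter `low_noise = 0.01`); inside, each sample commits to
a randomly drawn class (`high_noise = 1` mixes the disagreement
component), which drives the entropy-of-mean term toward $\log C$.  At
these defaults the mean BALD inside planted regions exceeds the outside
mean several-fold, so recovery tests measure the selector, not the
generator.

`tiny_learner()` is a multinomial logistic regression over six local
color features (RGB plus 3×3 neighborhood means), trained on a seeded
subsample of at most 20,000 labeled pixels, with Monte-Carlo samples
drawn by input-feature dropout (rate 0.5, inverted scaling).  It
honors the ignore class, trains in under a second on CPU, and is
deterministic given its seeds — which makes whole active learning runs
reproducible end to end.

What passing tests on this synthetic world do *not* show: anything
about deep segmentation networks (texture, spatial context, training
instability), about real vegetation indices on real soil, or about
absolute mIoU levels on any real dataset.  The synthetic studies
validate the *querying machinery* — that dynamic budgets adapt where
static ones cannot, at matched labeling cost.

## Problem sizes used in the shipped studies

The package's own experiments (tests and `scripts/acceptance.R`) use
64×64 tiles with 64 superpixels per tile — the same tile-to-superpixel
ratio as coarse superpixels on the 256×256 field tiles the design
targets — pools of 50–200 images, `T = 8` Monte-Carlo samples, and
active learning runs of 20 initialization images plus four steps of 10
images.  These sizes were chosen so a full study is a desk-scale
computation while every pipeline stage still operates in its intended
regime (background-dominant tiles, rare-class blobs, budget fractions
comparable to the ~31% labeled-foreground-superpixel averages the
method reports at full scale).

## Numerical and API conventions

* Coordinates are (row, col), 0-origin top-left; segment ids are
  `1..m` (contiguous, every id occupied) — the natural R convention.
* Class ids are `0..C-1`; 255 is the ignore value (8-bit convention).
* Probability vectors must sum to 1 within `1e-6`; violations are
  errors, not warnings.
* All ties break toward the lowest id (argmax ties, ranking ties,
  static-selection cutoff ties) for determinism.
* A foreground-masked image score over an empty mask is 0 with a
  warning, not an error: vegetation-free tiles are valid inputs that
  should simply lose the ranking.
* mIoU averages over classes present in truth or prediction
  (non-ignored); classes absent from both are excluded rather than
  scored.
* Labels and masks round-trip losslessly as 8-bit PNG; segment maps as
  16-bit single-channel TIFF (no installed PNG writer emits 16-bit).

## A worked example

```{r example, eval = FALSE}
scenes <- make_field_dataset(60, seed = 1)
test   <- make_field_dataset(20, seed = 2)

cfg <- al_config(init_count = 10, b = 5, steps = 3, T = 8,
                 n_segments = 64, mode = "dynamic", seed = 1)
run <- run_active_learning(lapply(scenes, `[[`, "image"),
                           lapply(scenes, `[[`, "label"),
                           cfg, tiny_learner(3),
                           lapply(test, `[[`, "image"),
                           lapply(test, `[[`, "label"), n_classes = 3)
run$records
labeled_fraction(run$ledger)   # the static baseline's matched q
```

## Known limitations

* The learner contract is intentionally minimal; warm-starting is the
  learner's concern and `tiny_learner` refits from scratch (its fits
  are cheap enough that warm starts would only add state).
* Superpixel connectivity is not enforced (see above).
* Pool images are re-scored every step (the procedure's definition);
  per-image probability stacks are not cached across steps, though
  segmentations are.
* Once queried, an image leaves the pool: re-querying partially
  labeled images in later steps is not supported.
* The static selector defines its budget as a fraction of *eligible*
  segments per image (not a fixed count), which is the natural reading
  when realized segment counts differ between images.
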