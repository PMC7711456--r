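---
title: "Histogram-based bag-of-tiles classification of whole-slide images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-based bag-of-tiles classification of whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A whole-slide image (WSI) is a gigapixel scan of a stained tissue section.
Slide-level diagnosis — here the three-way distinction between squamous
mucosa, non-dysplastic Barrett's esophagus (NDBE) and dysplastic BE — is
driven by texture that lives at the scale of small tissue patches, while
most of a diseased slide is benign tissue or glass. `histobag` treats every
slide $X_i$ as a bag of fixed-size tissue tiles $\{x_1, \dots, x_{n_i}\}$
and compares three families of tile representations under one shared
aggregation and inference protocol:

* **fully supervised (FS)** — a tile classifier trained on tiles labeled
  from pixel-wise annotation masks;
* **weakly supervised (MIL, EM)** — a tile classifier trained on tiles that
  inherit their slide's label, optionally refined by an
  expectation–maximization loop that keeps only *discriminative* tiles;
* **unsupervised (KM, GMM)** — an autoencoder embeds tiles, a clustering of
  the embeddings defines a visual vocabulary (codebook), and tiles are
  assigned to codeblocks hard (k-means) or soft (Gaussian-mixture
  posteriors).

Each route induces a mapping from a tile to a probability vector over a
concept vocabulary $V = \{c_1, \dots, c_K\}$. The slide encoding is the
same everywhere — the normalized concept frequency

$$h_k = \frac{1}{|X_i|} \sum_{x \in X_i} p(c_k \mid f_\psi(x)),$$

with the hard variant counting nearest-codeblock assignments. A
decision-fusion classifier (RBF SVM or 500-tree random forest) predicts the
slide label from the histogram, evaluated with patient-grouped 10-fold
cross-validation; crossing the five representation routes with the two
classifiers yields the ten-model comparison grid (FS-RF … GMM-SVM).

The GMM posterior is the standard mixture responsibility

$$p(c_m \mid v) = \frac{\pi_m \, \mathcal N(v \mid \mu_m, \Sigma_m)}
{\sum_k \pi_k \, \mathcal N(v \mid \mu_k, \Sigma_k)},$$

computed in log space; covariances are diagonal with a variance floor of
$10^{-6}$ (small-sample stability at large $K$), and EM is initialized from
a seeded k-means run so the whole fit is reproducible. The package's own
EM implementation is cross-checked in the test suite against an independent
mixture fitter on a separated-blob fixture, and the posterior against a
naive density-ratio oracle.

## The synthetic study cohort

The clinical cohort this design mirrors is not distributable, so the
package ships a generator that reproduces its *statistical* structure
rather than its biology — what matters for every algorithm above is that
slides are bags, that diseased bags contain only a minority of
class-discriminative instances, and that slides arrive in patient groups.

* Each class texture is an oriented sinusoid grating with class-specific
  spatial frequency (4, 7.2, 13 cycles/tile), orientation (0°, 60°, 120°)
  and mean intensity (0.62, 0.53, 0.44 — the diseased texture darkest,
  echoing nuclear hyperchromasia). Amplitude, phase and a small mean jitter
  vary per tile.
* A dysplastic slide carries exactly `round(lesion_fraction * n_tissue)`
  lesion-texture tiles (default 30%), planted as one **contiguous** lattice
  region grown by randomized breadth-first search; the remaining tissue is
  NDBE filler. Real lesions are spatially coherent regions — and spatial
  coherence is precisely what Gaussian-smoothed EM selection exploits, so a
  scattered planting would make that stage untestable by construction.
* `background_fraction` (default 20%) of cells are near-white glass;
  the tissue filter must remove them.
* All of a patient's slides share one diagnosis, making patient-grouped
  folds the only leakage-safe design.
* `texture_noise` is the single separability knob: it scales additive pixel
  noise *and* per-tile jitter of orientation (sd $0.6\sigma$ rad) and
  log-frequency (sd $0.8\sigma$). At the default 0.08 the classes are
  cleanly separable; at 0.4 they begin to overlap; by 1.2 a
  nearest-centroid tile classifier is close to chance. The suite checks
  this degradation is monotone.
* Optional RGB mode multiplies the optical density $(1-\text{gray})$ by a
  random per-slide 3-vector whose luminance-weighted mean is 1, so
  grayscale conversion cancels the stain almost exactly (dark pixels can
  clip); this emulates stain variability and justifies the
  grayscale-first preprocessing.

Default scale: 30 patients with 2–4 slides each (≈ 90 slides), an 8×8 tile
lattice at 64 px per tile (≈ 4,700 tissue tiles). These sizes keep a full
pipeline run at a few minutes on one core while leaving every estimate far
from its small-sample breakdown; `tile_size` accepts up to 128 px, the
operating point of scanner-resolution tiles.

What passing on this cohort does **not** show: robustness to the
morphological variance, staining artifacts, annotation noise and
magnification structure of real H&E slides. The generator makes the
pipeline's *logic* testable; it does not make its clinical performance
claims transferable.

## The tile backbone

No claim in this package depends on a particular neural architecture, so
the default ("desk") backbone is chosen for determinism and speed rather
than capacity. The feature stage is a fixed oriented band-pass filter bank
realized in the Fourier domain: the tile's power spectrum is pooled into 8
log-spaced radial frequency bands × 6 orientation bins, log-transformed,
and joined by the tile mean and standard deviation (50 features). On top of
this sit the trainable parts:

* **Tile classifier** — dense ReLU layer (64 units) with dropout
  $p = 0.5$ and a softmax head, trained with seeded Adam on cross-entropy
  (60 epochs, batch 64, lr $5\times10^{-3}$, weight decay $10^{-4}$).
* **Autoencoder** — dense tanh bottleneck of $E = 32$ units (the
  embedding) and a linear decoder to a 4×-pooled raster, upsampled back to
  tile shape; MSE loss. Because nearest-neighbour upsampling is linear and
  the within-block variance does not depend on the parameters, training
  against the pooled target optimizes exactly the full-tile MSE.

Two properties of this stage are load-bearing. First, the spectral features
are invariant to grating phase, so same-class tiles embed tightly — which
is what lets a clustering of embeddings recover texture classes. Second,
the dihedral augmentation group (horizontal flip × 90° rotations) acts on
the descriptor as a *permutation of orientation bins*, so training-time
augmentation is applied exactly in feature space at zero cost; the
pixel-level `augment_tile()` operation carries the same group structure and
is tested for closure (four rotations = identity, two flips = identity,
intensity multiset preserved).

Scanner-scale residual backbones occupy the same interface (tiles in,
probabilities or embeddings out) and the pipeline is agnostic to the swap;
they are deliberately not the default because nothing downstream becomes
more testable by making the backbone heavier. Training is bit-reproducible
given `(seed, data order)`: every stochastic choice — initialization,
shuffling, dropout masks, augmentation draws — comes from one locally
scoped RNG stream.

## Tiling and preprocessing

Tiles are extracted by a sliding window, row-major from the top-left,
stride = tile size by default (the window stride is configurable; partial
edge windows are dropped). A pixel is *tissue* iff its grayscale intensity
falls below 0.9 — near-white is glass — and tiles with less than 50% tissue
are discarded; both thresholds are exposed because "tissue section" has no
canonical computational definition. Grayscale conversion uses the standard
luminance weights $0.299R + 0.587G + 0.114B$. An optional per-tile
intensity standardization (subtract mean, divide by sd, re-clip to
$[0,1]$) exists but is off by default; on this cohort the luminance-neutral
stain model makes grayscale conversion alone sufficient.

## EM discriminative-patch selection

Iteration 0 marks every retained tile discriminative ($z = 1$). Each
M-step retrains the tile classifier on the selected tiles under MIL labels;
each E-step lays the classifier's own-class probability onto the slide
lattice, smooths it with a Gaussian kernel (sd 1 lattice unit, truncated at
$3\sigma$, weights renormalized over present cells so filtered cells
neither leak mass nor acquire values), and re-selects tiles whose smoothed
value exceeds the threshold. The loop stops when fewer than 1% of
indicators change, or after 10 iterations. If a slide would end up with an
empty bag, its single maximum-value tile is kept.

Two defaults deserve their rationale:

* **Selection threshold 0.5, not $1/K$.** The benign filler texture occurs
  in NDBE slides (labeled NDBE) *and* in dysplastic slides (labeled
  dysplastic), so a well-fitted MIL classifier assigns filler tiles a
  dysplastic probability equal to their label mixture — about 0.41 under
  the default composition. Any threshold at or below $1/3$ therefore keeps
  essentially every tile forever and the EM loop degenerates to MIL. At
  0.5 a tile is kept only when its slide's class outranks all alternatives
  combined; filler tiles fall away after the first E-step, subsequent
  M-steps train on nearly pure lesion bags, and the selection stabilizes on
  the planted region (Jaccard ≈ 0.84 against generator truth).
* **Smoothing sd 1 lattice unit.** Large enough to consolidate a
  contiguous lesion region against single-tile noise, small enough not to
  erase a region occupying ~30% of the tissue; kernel parameters are
  config-exposed.

With `max_iters = 1` and threshold 0 the loop provably reduces to plain
MIL training (same tileset, same seed, same weights bit-for-bit), and the
suite asserts exactly that.

## Slide inference and evaluation

* **Folds.** Patients are shuffled once per seed and split into k groups
  whose sizes differ by at most one; slides inherit their patient's fold.
* **SVM.** One RBF machine per class (one-vs-rest), slides scored by
  signed decision values; AUC is rank-based so no calibration is needed.
  The kernel bandwidth is the variance-scaled heuristic
  $\gamma = 1/(p \cdot \overline{\mathrm{Var}})$: histogram entries scale
  like $1/K$, and a fixed $1/p$ bandwidth would flatten the kernel exactly
  when the vocabulary grows.
* **RF.** 500 trees, seeded.
* **Metrics.** Per class, one-vs-rest: binarized accuracy, AUC from the
  class score, precision (0 when nothing is predicted positive), recall,
  F1. The support-weighted average is reported per fold; *weighted
  accuracy* is the overall multiclass accuracy, which coincides with
  support-weighted recall — under this reading a label-permuted control
  sits at $1/K$, whereas a weighted one-vs-rest accuracy would sit near
  $5/9$ for three classes and could never serve as a chance reference.
* **Confidence intervals.** Fold means with
  $\pm t_{0.975, m-1}\, s/\sqrt{m}$ over the $m$ folds where the metric is
  defined, clipped to $[0, 1]$. A fold that lacks a class has no AUC for
  that class; such folds are dropped from that class's mean with a warning.
  Fold metrics are averaged, not pooled.
* **Grid.** All ten models share one fold assignment. Tile-level models
  may be trained on a disjoint cohort (the `train_cohort` option), which is
  the protocol the analysis scripts follow; codebooks are fit on the
  unsupervised embeddings once, not per fold — they see no labels, so no
  label leakage arises, and this matches the two-step protocol of learning
  the vocabulary on a training pool before cross-validating the fusion
  classifier.

## Interpretability

FS/MIL/EM heatmaps are direct: the cell value of a retained tile is its
predicted class-C probability. The unsupervised route has no class-aligned
concepts, so class relevance is recovered in two steps: permutation
importance of each codeblock for class C at the slide level, propagated
onto tiles through their posteriors,

$$I_x^C = \sum_{m=1}^{K} p(c_m \mid f_\psi(x))\, I_{c_m}^C .$$

The error functional behind the importance is the one-vs-rest **Brier
score** of the class-C score (logistic link applied to SVM decision
values). A 0/1 misclassification functional is available
(`error = "zero_one"`) but degenerates here: with 150 codeblocks the
per-class evidence is spread over dozens of partially redundant columns,
shuffling any single column almost never flips a hard label, and every
importance collapses to exactly zero — no heatmap survives. The graded
functional measures the same "increase in prediction error when the feature
is shuffled" while remaining sensitive under redundancy; a constant column
still gets importance exactly 0 under both. Shuffling permutes a column
across slides, 10 repeats by default, seeded.

Rendering normalizes each map per slide and class to $[0,1]$ (an all-equal
map renders at uniform mid-scale), colors it blue→red with red = high
attention, makes filtered cells transparent, and expands cells to tile-size
blocks so the overlay matches the slide raster.

## Numerical and degenerate-input choices

* Mixture responsibilities and likelihoods in log space
  (`log-sum-exp`); diagonal covariance floor $10^{-6}$; component weights
  floored at $10^{-10}$ and renormalized.
* k-means: Hartigan–Wong, 5 starts, centroids sorted lexicographically so
  component order (and hence the GMM initialized from it) is reproducible.
* Nearest-centroid ties resolve to the lowest index; heatmap top-1
  fallback takes the first maximum.
* Empty bags error at encoding time (`|X_i| = 0` has no histogram);
  slides never reach that state inside EM because of the top-1 fallback.
* Gaussian smoothing renormalizes kernel mass over present cells, so a
  constant map is exactly invariant and boundaries are unbiased.
* All long-running stages (cohort rendering, network training, EM, GMM)
  are pure functions of their seeds; R's 32-bit integer seed space is
  respected when deriving sub-seeds.

## Known limitations

* The backbone is a filter-bank-plus-dense network: appropriate for
  oriented-texture discrimination, not a substitute for learned
  convolutional features on real histology.
* Codebooks are learned once on the full embedding pool rather than inside
  each CV fold; with labeled-data leakage impossible this is a variance,
  not a bias, concern — but it is a protocol difference from fully nested
  resampling.
* Per-class "accuracy" in the one-vs-rest sense is reported alongside the
  multiclass reading; the two diverge in exactly the situations where
  class imbalance matters.
* The stain model is a single multiplicative optical-density vector per
  slide; real stain variation is nonlinear and spatially heterogeneous.
* Lesions are planted as one connected region per slide; multifocal
  disease would stress the smoothing bandwidth in ways this cohort does
  not test.
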