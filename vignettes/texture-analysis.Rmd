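---
title: "Higher-order cooccurrence texture analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order cooccurrence texture analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotex)
```

## The problem

Malignant tissue in B-mode ultrasound differs from visually similar benign
tissue mainly in its *texture*: malignant regions are chaotic and
heterogeneous, benign and pre-malignant regions more regular.  Classical
second-order grey-level cooccurrence matrices (GLCMs) summarize pairwise
spatial statistics of the grey levels; this package implements their
generalization to orders 3 and 5, the analogous cooccurrence statistics of
*edge orientations* (EOCM, orders 2 and 3), and the full pipeline that turns
them into a tissue classifier: feature computation on rectangular regions of
interest (ROIs), correlation-based feature selection with a genetic search,
information-gain ranking, construction of a per-class "textural model", and
stratified cross-validated evaluation.

## The order-n cooccurrence matrix

For an image $f(x, y)$ and an ordered set of displacement vectors
$\vec d = ((d_{x_1}, d_{y_1}), \dots, (d_{x_{n-1}}, d_{y_{n-1}}))$, the
order-$n$ cooccurrence matrix counts pixel $n$-tuples

$$C_D(g_1,\dots,g_n) = \#\{((x_1,y_1),\dots,(x_n,y_n)) :
  f(x_i,y_i) = g_i,\;
  |x_{i+1}-x_1| = |d_{x_i}|,\; |y_{i+1}-y_1| = |d_{y_i}|,$$
$$\operatorname{sgn}((x_{i+1}-x_1)(y_{i+1}-y_1)) =
  \operatorname{sgn}(d_{x_i} d_{y_i})\}.$$

The first pixel is the *anchor*, sitting in the central position of the
configuration.  Matching is by absolute coordinate difference with a sign
constraint on the product, so each displacement vector contributes both its
$+\vec d$ and $-\vec d$ placement; at order 2 this reproduces the classical
symmetric Haralick counting.  A tuple is counted only when *every* neighbor
is in bounds (and mask-valid); there is no partial counting.  Dividing by
the total count gives the probability matrix $p(g_1,\dots,g_n)$.

Direction geometries follow the method's protocol:

* order 2: single vectors at 0°, 45°, 90°, 135° (magnitude 1 by default —
  the classical usage; the magnitude is configurable);
* order 3: the four collinear pairs (0°,180°), (90°,270°), (45°,225°),
  (135°,315°) and the eight right-angle pairs (0°,90°), (90°,180°),
  (180°,270°), (0°,270°), (45°,135°), (135°,225°), (225°,315°), (45°,315°),
  with components in $\{0, \pm 2\}$;
* order 5: the two groups (0°,180°,90°,270°) and (45°,225°,135°,315°),
  also with components in $\{0, \pm 2\}$.

Angles use the image convention ($y$ down): a direction $\theta$ maps to the
offset $(m \cdot \operatorname{round}(\cos\theta),
-m \cdot \operatorname{round}(\sin\theta))$ — the unit direction is rounded
*before* scaling, so diagonal directions at magnitude 2 give components
$\pm 2$, not $\pm 1$.

**Storage.** A dense order-5 array over 256 grey levels would need $256^5$
cells; the engine instead encodes each observed tuple as a single integer
code ($g_1 + g_2 L + \dots + g_n L^{n-1}$, exact in doubles up to
$256^5 < 2^{53}$) and aggregates codes by radix sort and run-length
encoding.  Distinct tuples are bounded by the pixel count, so sparse
counting is exact and fast even at $L = 256$, order 5.

## Extended Haralick features

The classical order-2 statistics are generalized through the pairwise mean
squared level difference
$D_2(t) = \frac{2}{n(n-1)} \sum_{i<j} (g_i - g_j)^2$ and the positional
marginal moments $\mu_i, \sigma_i$ of each tuple slot:

* energy $\sum_t p(t)^2$, entropy $-\sum_t p(t) \ln p(t)$ (natural log
  throughout the package),
* contrast $\sum_t p(t) D_2(t)$, local homogeneity
  $\sum_t p(t) / (1 + D_2(t))$,
* variance $\sum_t p(t) \frac1n \sum_i (g_i - \mu)^2$ with $\mu$ the
  probability-weighted mean level,
* correlation $\sum_t p(t) \prod_i (g_i - \mu_i) \big/ \prod_i \sigma_i$,
  reported 0 when any $\sigma_i = 0$ (constant texture),
* maximum probability $\max_t p(t)$ — high for regular textures whose grey
  patterns repeat, low for chaotic ones.

At $n = 2$ every formula reduces algebraically to its classical Haralick
counterpart on a symmetric GLCM; the test suite verifies this against an
independent dense-matrix implementation to $10^{-9}$.  The generalization
itself (pairwise differences, positional marginals) is this package's
definition: it is the natural symmetric extension that preserves the
order-2 reduction, which the tests anchor.

## Edge orientations

Gradients come from the standard 3×3 Sobel kernels with edge replication.
Orientation is $\operatorname{round}(\operatorname{atan2}(G_y, G_x))$ in
degrees folded into $[0°, 180°)$ — edges are undirected, so the 180°
ambiguity is physical.  A pixel is an edge pixel when its gradient magnitude
strictly exceeds a threshold (default 0: any nonzero gradient).  The EOCM
reuses the cooccurrence engine with the edge mask as validity mask; a tuple
counts only if all $n$ pixels are edges.  Orientations are kept at 1°
resolution by default (configurable bin width; reported dominant values
like 0°, 45°, 90° would also survive coarser binning).

**Edge-orientation variability** summarizes orientation dispersion.  No
closed formula is inherited, so the package uses the standard treatment for
axial data: double the angles, compute the mean resultant length $\bar R$,
and report the angular deviation $\sqrt{2(1-\bar R)}$ (radians, shown in
degrees).  It is 0 iff all edge orientations coincide and reaches
$\sqrt 2\,\text{rad} \approx 81.03°$ for a fully dispersed distribution;
unlike $\sqrt{-2\ln \bar R}$ it stays bounded, which keeps the feature
usable when orientations are exactly balanced.  Alongside it, the "old"
edge statistics are the gradient-magnitude mean and standard deviation and
the edge density (edge pixels / total pixels).

## Classic features

* **Mean grey level** of the (denoised) ROI.
* **Laws microstructure statistics**: the image is convolved with the
  separable 5×5 kernels built from the level/edge/spot/wave/ripple vectors.
  Each class's energy map is the mean absolute response of its symmetric
  kernel pair ($v \otimes L5$, $L5 \otimes v$), normalized pixelwise by the
  $L5 \otimes L5$ response so detection is contrast-relative (the level
  class uses the raw $L5 \otimes L5$ energy).  A pixel is a detected
  microstructure when its energy strictly exceeds mean $+ k \cdot$ sd of
  its map ($k = 1$ by default); frequency is the hit count and density the
  hit fraction.  The detection rule is this package's choice — only the
  kernels themselves are canonical.  Note the thresholds are per-map
  relative, so densities compare response *shape*: a broadband impulse
  excites the wave/ripple kernels on more cells than the spot kernel, while
  a kernel-scale blob is spot-dominated.
* **Haar wavelet subband entropies**: a two-level 2-D Haar transform (the
  second level applied to each first-level subband) gives $4 + 16 = 20$
  subbands; each contributes the Shannon entropy of its normalized
  squared-coefficient distribution ($p_i = c_i^2 / \sum c^2$).  Computing
  the entropy on coefficient *energies* rather than raw coefficients makes
  the feature sign-invariant and zero for empty subbands.

Features are computed on multiple directions and averaged *at the feature
level* (not by averaging matrices), per family: e.g. `glcm2_avg_entropy` is
the mean entropy over the four order-2 directions, while
`glcm3_0_270_entropy` is the entropy of the single (0°, 270°) combination.
Degenerate sub-features (EOCM statistics of an edge-free ROI) are recorded
as missing, never fatal, so the feature schema is identical across ROIs.

## Preprocessing

ROIs (default 50×50 px) are cut from 8-bit greyscale images (PNG/TIFF/BMP;
RGB collapsed to luminance) and denoised with a 3×3 averaging filter — the
smallest kernel that suppresses pixel noise without destroying texture at
the 50×50 scale; the size is configurable since no canonical value exists.
Grey levels are quantized uniformly, `label = floor(value * L / 256)`, with
$L = 256$ by default: sparse counting makes full resolution affordable, and
reported raw grey values (e.g. 57) suggest no coarser quantization was
used.  $L$ is configurable down to 32 for speed.

## Feature selection

Features are discretized with Fayyad–Irani MDL-stopped entropy splitting
(the default inside the reference toolkit's selectors; features with no
accepted cut collapse to a single bin and carry zero information; missing
values form their own bin).  Correlations are measured by symmetrical
uncertainty $SU = 2(H(a) + H(b) - H(a,b)) / (H(a) + H(b))$, defined 0 when
both entropies vanish.  The CFS merit of a subset $S$ with $k$ features is

$$\text{Merit}_S = \frac{k\,\overline{r_{cf}}}
 {\sqrt{k + k(k-1)\,\overline{r_{ff}}}},$$

with $\overline{r_{cf}}$ the mean feature–class SU and
$\overline{r_{ff}}$ the mean pairwise feature–feature SU.  The merit is
maximized by a genetic search over bitstring chromosomes: population 20,
20 generations, single-point crossover probability 0.6, per-bit mutation
probability 0.033, seed 1 — the method's standard settings — plus elitism
of one (unstated in the protocol; it stabilizes the best-ever contract).
Information gain $IG = H(C) - H(C \mid A)$ ranks features individually.
The final relevant set is the *union* of the CFS subset and the top-$k$ IG
features; the ranker cutoff is not canonical, so it defaults to 10 with an
optional IG > 0 filter, and the union is floored at the single best IG
feature so it can never be empty.

## Textural model and evaluation

The textural model stores, per selected feature and class: the relevance
(how many selectors retained it, 0–2), the class-conditional mean and
standard deviation, and a normalized 16-bin histogram over the pooled
feature range.  Evaluation uses stratified 5-fold cross-validation (each
class dealt round-robin after a seeded shuffle, so fold proportions match
within one instance; 80%/20% train/test per iteration).  Features are
z-scored on the training folds only (with train-mean imputation of missing
values) — unstated in the protocol but required for SVM/MLP stability.
Classifiers:

* SVM with polynomial kernel of degree 3 (via e1071);
* a single-hidden-layer softmax MLP, hidden units = rounded mean of the
  feature and class counts, learning rate 0.2, momentum 0.8.  Training is
  full-batch gradient descent with momentum for 500 epochs (seeded): the
  batch variant was chosen over per-instance updates because it vectorizes
  cleanly and converges reliably at these problem sizes; the epoch count
  and stopping rule have no canonical value;
* AdaBoost.M1 with 10 boosting iterations wrapping either base learner,
  using weighted resampling (the standard device for base learners without
  native instance weights).

Reported metrics: recognition rate (correctly classified %), TP rate
(sensitivity of the positive class), TN rate (specificity), and AUC by the
Mann–Whitney rank statistic on held-out scores (average ranks for ties, so
the value is invariant under monotone score transforms; macro one-vs-rest
beyond two classes), all from the pooled cross-validation confusion
matrix.  Model-building wall time is reported but is informational only.

## Synthetic textures

No imaging data ships with the package; a seeded generator provides
study-scale inputs.  A recipe controls echogenicity (mean grey level),
granularity (correlation length), regularity (`periodic` grating /
`smooth` correlated field / `chaotic` i.i.d. noise with bright and dark
spots), noise level, and an optional multiplicative log-normal
speckle-like factor.  Two reference conditions are frozen in
`standard_recipes()`:

* `"contrast"` — the two-class discrimination setting used by the
  end-to-end experiment: a regular hypoechogenic class (periodic, mean 90,
  correlation length 5, noise sd 8) versus a chaotic hyperechogenic class
  (mean 150, noise sd 30, 12 spots per 1000 px), both with speckle.  The
  classes differ in echogenicity, granularity *and* regularity, emulating
  clearly distinct tissues.
* `"equal_mean"` — regularity isolated at equal echogenicity (both classes
  mean 120, speckle off): a near-noiseless periodic class (noise sd 3)
  against i.i.d. noise (sd 25).  The low intra-texture noise of the regular
  class makes its grey tuples genuinely repeat, which is what
  tissue-scale maximum probabilities of order 0.05 (order 2) / 0.01
  (order 3) imply; at heavy within-class noise and $L = 256$ the
  order-3/5 maxima of *any* texture collapse toward $1/\text{total}$ and
  the regular/chaotic ordering washes out.

What the generator does *not* emulate: physical point-spread functions,
attenuation, depth-dependent gain, anatomical context.  Passing tests
therefore show the pipeline's statistical machinery is correct and
discriminates textures that differ the way the tissue classes are
described — not that clinical accuracy figures transfer.

## Numerical choices and degenerate inputs

* Natural logarithm for all entropies; MDL bookkeeping internally in bits.
* Normalized tensors sum to 1 within $10^{-12}$; a zero-count direction
  set raises a degenerate-input error that the feature assembler converts
  to a missing feature.
* Correlation is reported 0 when any positional sd is below $10^{-12}$.
* Quantization is monotone by construction; ties in IG ranking break
  alphabetically for determinism; `max.col` ties break on the first level.
* Problem sizes in the package's own experiments: 100 ROIs per class at
  50×50 px for the end-to-end run, 50 image pairs for the equal-mean
  ordering, brute-force cross-checks on maps up to 12×12 with $L \le 8$ —
  sizes at which exhaustive oracles remain exact.

## Known limitations

* The appendix-level definitions of the extended Haralick features and the
  "autocorrelation index" are not inherited; the generalization here is
  anchored by its exact order-2 reduction instead.
* AdaBoost with resampling and the batch-trained MLP are faithful in
  protocol parameters but not bit-compatible with other toolkits'
  implementations.
* Multi-class AUC is a macro one-vs-rest average; the study design is
  two-class.
* BMP support covers uncompressed 8-bit palette and 24-bit files only.

## A worked run

```{r example, eval = FALSE}
man <- generate_dataset(standard_recipes("contrast"), n_per_class = 25)
cfg <- default_config(classifiers = c("svm_poly3", "mlp"))
tab <- run_extract(man, cfg, quiet = TRUE)
sel <- run_select(tab, cfg)
res <- run_evaluate(tab, sel, cfg)
res$summary
model <- build_textural_model(tab, sel)
model
```
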