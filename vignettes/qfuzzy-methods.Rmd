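---
title: "Quantum-behaved swarm feature selection with fuzzy k-NN: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-behaved swarm feature selection with fuzzy k-NN: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfuzzy)
```

## The problem

Screening Pap-smear slides means classifying single cervical cells into
normal types (superficial squamous, intermediate squamous, columnar) and
dysplastic grades (light, moderate, severe, carcinoma in situ). The
morphological signature of dysplasia is well established: the nucleus
enlarges, chromatin darkens and coarsens, the boundary grows irregular and
the nucleus/cytoplasm (N/C) area ratio rises. Automated pipelines extract
many quantitative descriptors of these changes and feed them to a
classifier — but not every descriptor helps, and irrelevant ones actively
hurt a distance-based classifier because they dilute the metric. `qfuzzy`
implements a *wrapper* feature selector: candidate feature subsets are
scored directly by the cross-validated performance of the downstream
classifier, and a stochastic combinatorial optimizer searches the subset
lattice.

The package has three layers:

1. **Feature extraction** (`extract_features`): 17 features — 54 vector
   entries — from a grayscale image plus a background/cytoplasm/nucleus
   label mask.
2. **Classification** (`fknn`): a fuzzy k-nearest-neighbour classifier
   returning class memberships rather than hard votes.
3. **Selection** (`qfuzzy`): a binary quantum-behaved particle swarm
   (QPSO) maximizing the cross-validated macro-F1 of the fuzzy k-NN
   restricted to the selected entries, with a standard binary PSO
   (`optimizer = "pso"`) and an all-features baseline
   (`all_features_baseline`) for comparison.

## The feature vector

The 54 entries comprise 16 scalars and a 38-entry texture descriptor:

* **Nucleus geometry** — area $A_n$ (pixel count), major/minor axis
  lengths $L_n, D_n$ of the moments-equivalent ellipse, bounding-box
  aspect ratio $R_n = W_n/H_n$, perimeter $P_n$, roundness
  $A_n / (\tfrac{\pi}{4} L_n^2)$.
* **Nucleus intensity** — counts of strict local maxima/minima over the
  8-neighbourhood, GLCM homogeneity
  $H_n = \sum_{i,j} p(i,j)/(1+|i-j|)$, mean brightness $B_n$.
* **Cytoplasm** — local extrema counts and mean brightness.
* **Whole cell** — area $A_{cell}$, compactness $P_{cell}^2/A_{cell}$,
  N/C ratio $R_{cell} = A_{nucleus}/A_{cytoplasm}$.
* **Texture** — rotation-invariant LBP histogram-Fourier features
  (38 entries) over the whole-cell region.

Conventions the definitions above leave open were fixed as follows, and
each is either configurable or isolated in one small function so it can be
swapped:

* **Axis lengths.** "The ellipse enclosing the region" is realised as the
  *moments-equivalent* ellipse (the ellipse with the region's second
  central moments — the convention of every regionprops implementation).
  A literal minimal enclosing ellipse is ill-conditioned on rasters: one
  protruding pixel changes it discontinuously. For a filled ellipse with
  semi-axes $(a, b)$ the estimate converges to $(2a, 2b)$; tests check
  this within 5% and against an independent moment computation.
* **Perimeter.** Base definition: the count of region pixels with at
  least one background 4-neighbour. A staircase boundary under-measures
  Euclidean length: for rasterized disks the raw count converges to
  $2\sqrt{2}/\pi \approx 0.90$ of $2\pi r$, so disk compactness converges
  to $32/\pi$ rather than $4\pi$. The default therefore multiplies the
  count by the isotropic correction $\pi/(2\sqrt{2}) \approx 1.11$, which
  brings disk compactness within a few percent of $4\pi$ (tested at radii
  10–40 with a 15% tolerance); `region_perimeter(..., correct = FALSE)`
  gives the raw count.
* **Local extrema.** Strict inequality against all *available*
  8-neighbours, where available means inside both the image and the
  region; plateaus count zero. This makes the count well defined at
  region borders without inventing padding values.
* **GLCM.** 8 gray levels by uniform quantization of 0–255, single offset
  $(0, 1)$, symmetric accumulation, pairs restricted to the region. Levels
  and offset are arguments. Homogeneity is 1 exactly for a
  quantization-constant region.
* **LBP.** 8 neighbours, radius 1, bit set when neighbour $\ge$ centre.
  Only $P = 8$ yields the 38-entry layout: 7 rotation orbits (1–7 set
  bits) × 5 unique DFT magnitudes, plus the all-zeros, all-ones and
  non-uniform bins. Histograms are normalized by the number of coded
  pixels before the transform. Neighbour samples are taken at the 8
  discrete raster neighbours rather than by circular interpolation, which
  makes invariance under 90° rotations *exact* (tested to 1e−6) at the
  cost of only approximate invariance at intermediate angles.
* **Colour.** RGB input collapses to ITU-R BT.601 luma before any
  intensity feature; brightness is the only colour-derived feature.

All features are invariant to translating the cell within its frame
(tested as exact equality under pad-and-shift).

## Fuzzy k-NN

Training features are min–max normalized to $[0,1]$ per column with
training-fold statistics (constant columns map to 0; queries are clipped).
Training memberships are crisp one-hot rows — the literature also fuzzifies
them by neighbourhood composition, and `init_memberships` keeps the hook,
but crisp initialization is the default and the only scheme used for the
results here. A query $x$ receives memberships

$$u(x, c_i) = \frac{\sum_{k=1}^{K} u(x_k, c_i)\, d(x, x_k)^{-2/(m-1)}}
                   {\sum_{k=1}^{K} d(x, x_k)^{-2/(m-1)}}$$

over its $K$ nearest training rows under Euclidean distance, with weight
exponent $m > 1$; the predicted class is the argmax, ties resolved to the
lowest class index. Defaults: $k = 4$, $m = 2$ (the conventional fuzzy
k-NN exponent). Two degenerate cases are fixed explicitly: a query at zero
distance inherits the mean membership row of its exact matches (the limit
of the formula), and neighbour ties at the $k$-th rank are broken by
training-row order, which keeps predictions deterministic. Memberships are
row-stochastic whenever the training memberships are, and invariant to a
global rescaling of distances (the weights are homogeneous and the
normalization cancels the constant).

## The optimizers

Both optimizers search over real-valued particle positions
$X_i \in \mathbb{R}^d$, one dimension per feature-vector entry, and
convert a position to a selection mask stochastically through
$\mathrm{bit}_j = 1$ iff $\sigma(x_{ij}) > U(0,1)$ with the logistic
$\sigma$. The fitness of a mask is the cross-validated macro-F1 described
below; the all-zero mask scores 0.

**QPSO.** Velocity-free: each iteration computes the swarm mean-best
position $m = \tfrac{1}{S}\sum_i P_i$, a per-particle attractor
$p = \phi P_i + (1-\phi) G$ ($\phi \sim U(0,1)$ per dimension, $G$ the
global best), and samples

$$X_i' = p \pm \alpha\,|m - X_i|\,\ln(1/u), \qquad u \sim U(0,1),$$

taking the minus branch when an auxiliary uniform draw $s \ge 0.5$ and the
plus branch otherwise. The two sign branches are what gives the sampled
position a symmetric double-exponential spread around the attractor; a
single-signed version collapses the distribution to one side and is
treated here as a typographical artefact of some write-ups. The
contraction–expansion coefficient $\alpha$ decays linearly 1.0 → 0.5 over
the run (the common QPSO schedule; a constant $\alpha$ is accepted too).
The per-particle search scope $Q = 2\alpha|m - X_i|$ is recorded as a
diagnostic only — the update uses the expressions above directly.

**PSO baseline.** Classic velocity update
$v' = wv + c_1 r_1 (P_i - X) + c_2 r_2 (G - X)$ with $w$ decaying
0.9 → 0.4, $c_1 = c_2 = 2$, velocities clamped to $\pm 4$ — standard
binary-PSO settings, since the comparison experiment specifies only that
swarm size and iteration count match. The same sigmoid binarization is
shared.

Personal bests move only on *strict* fitness improvement, so the
global-best trace is monotone non-decreasing by construction. Positions
initialize from $U(-1,1)$ (bit probabilities near 0.5); swarm size 20 and
200 iterations are the defaults. Each run consumes a single seeded RNG
stream, so results are exactly reproducible; because the fitness is a pure
function of the mask, `qfuzzy()` memoizes it per mask.

On 12-bit planted-mask surfaces — where the optimum is verifiable by
exhaustively enumerating all 4096 masks — QPSO at the default budget finds
the global optimum in ≥95% of seeded runs and the PSO baseline in ≥90%
(checked over 100 runs in the test suite and recomputed by
`scripts/acceptance.R`).

## The wrapper fitness

`subset_fitness` scores a mask by stratified 5-fold cross-validation:
per fold, a fuzzy k-NN is fit on the training rows restricted to the
selected entries and evaluated on the held-out rows; the mean across folds
of the macro-averaged F1 (unweighted over classes, degenerate classes
scoring 0 rather than NaN) is returned. Folds derive deterministically
from a seed, making the fitness a pure function of the mask — a
requirement for the monotone-trace guarantee to be meaningful. Full-data
cross-validation rather than an inner train/test split was chosen because
the datasets here are small and a single split at these sizes is noisy
enough to destabilise the search. The *reported* metrics of a fitted model
(per-class precision/recall/F1, macro averages, Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$) are computed separately from pooled-fold
confusion counts, which avoids averaging ratios over folds.

Macro (unweighted) averaging is used for all overall figures; whether
published overall benchmark figures are macro- or micro-averaged is not
always stated, so agreement there is directional, not numeric.

## The synthetic generator

Real Herlev-style data is an external download, so the package ships a
generator with the statistical structure the method assumes — it defines
the package's study conditions and is itself tested code.

**Cell images** (`generate_cell`, `generate_cells`): per class, a
cytoplasm blob and a nucleus (an ellipse-like boundary with sinusoidal
radial perturbation) fully inside it, with class-specific nucleus radius,
brightness, boundary irregularity and texture grain. Along the
superficial → carcinoma axis the defaults encode the standard progression:
nucleus radius ranges rise from 3–5 px to 14–17 px, N/C ratio rises
accordingly, nucleus brightness falls 180 → 95 (hyperchromasia), boundary
irregularity rises 0.04 → 0.28 and texture correlation length 1 → 4 px.
These defaults are package choices that reproduce the qualitative
ordering; they are not measurements. One deliberate simplification: mild
dysplasia is sometimes described as transiently *brighter* before the
darkening of later grades; a monotone axis cannot encode both, so
brightness decreases monotonically. The renderer is also not
photorealistic (no staining variation, no overlapping cells, no
segmentation error), so passing tests demonstrate the pipeline's
correctness and discriminative behaviour on cells whose class signal is
real but cleaner than microscopy; they do not certify benchmark-level
accuracy on real slides.

**Feature tables** (`generate_feature_table`): `d_informative` columns
carry class signal, `d_noise` columns are pure standard Gaussian noise,
and the planted index set is returned as ground truth. `effect_size` is
defined as the separation of adjacent class centroids *across the whole
informative block*, in noise-sd units: each informative column contributes
spacing `effect_size/sqrt(d_informative)` (a random permutation of class
ranks per column, so columns are complementary rather than redundant).
This block-wise definition matters: if each single column separated the
classes by the full effect size, the cross-validated F1 would saturate at
1.0 for almost any mask containing a couple of informative columns and
"recovering the planted set" would be meaningless. Under the block
definition, at the recovery experiment's conditions (n = 300, 5 + 25
columns, effect 3, 3 classes) the true 5-column mask scores ≈ 0.93,
3-of-5 masks ≈ 0.86 and the all-features mask ≈ 0.84 — every planted
column carries needed signal.

## Problem sizes and numerical choices

The shipped experiments use sizes chosen to make the full suite a
desk-scale computation: the optimizer-oracle study uses d = 12 bits
(S = 20, T = 200, 100 seeded runs, exhaustive 4096-mask enumeration as the
independent oracle); the recovery study uses S = 20, T = 25 with fitness
memoization (100 runs in the tests, 50 in the acceptance script); the
end-to-end image study simulates 140 cells (20 per class, 100×100 px) and
selects over the full 54 entries with S = 20, T = 30. Swarm budgets for
the wrapper studies are smaller than the package defaults because the
fitness there costs a full cross-validated fit per new mask; the studies'
conclusions (recovery rate, selection-vs-baseline direction) are stable in
these budgets.

Other numerical details: feature extraction is exactly deterministic;
fitness evaluation never sees NaN (non-finite fitness aborts the run with
a diagnostic); degenerate evaluation denominators score 0 and are defined,
not silently dropped; $p_e = 1$ in Cohen's kappa (both raters constant and
identical) is reported as $\kappa = 1$; stratified folding spreads classes
with fewer members than folds as evenly as possible instead of failing.

## Known limitations

* The LBP radius is fixed at 1 by default; only the neighbour count
  ($P = 8$) is pinned by the 38-entry layout, and other radii are
  plausible.
* Crisp training memberships are the only implemented initialization for
  the fuzzy k-NN.
* The generator does not model segmentation error, stain variation or
  overlapping cells; benchmark figures on real data (precision/recall of
  ~0.85 at $k = 4$ on the 917-cell Herlev set) are shipped as reference
  numbers (`reference_scores()`) for the F1-consistency worked example,
  not reproduced computationally.
* Filter-style selectors (Relief, sequential forward selection) and other
  classifiers (SVM, random forest, naive Bayes) that appear in published
  comparisons are out of scope; the package's claim is about the
  QPSO + fuzzy k-NN wrapper against its own PSO and all-features
  baselines.
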