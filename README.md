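# qfuzzy

Wrapper feature selection for single-cell Pap-smear classification:
a binary **quantum-behaved particle swarm optimizer (QPSO)** searches over
subsets of 54 cell-image feature entries, scoring each candidate subset by
the cross-validated macro-F1 of a **fuzzy k-nearest-neighbour** classifier.
The package is aimed at researchers in quantitative cytology and
biological image analysis who have segmented single-cell images (intensity
image + background/cytoplasm/nucleus mask) or precomputed feature tables
and want a reproducible selection-plus-classification pipeline with
standard-PSO and all-features baselines.

## The method

**Features.** From each segmented cell, 17 features (54 vector entries)
are extracted: nucleus area, moments-equivalent ellipse axes, bounding-box
aspect ratio, perimeter, roundness; counts of strict 8-neighbourhood local
maxima/minima and mean brightness of nucleus and cytoplasm; GLCM
homogeneity of the nucleus; whole-cell area, compactness and the
nucleus/cytoplasm area ratio; and a 38-entry rotation-invariant LBP
histogram-Fourier texture descriptor.

**Classifier.** Fuzzy k-NN assigns a query class memberships

    u(x, c_i) = sum_k u(x_k, c_i) d(x, x_k)^(-2/(m-1)) / sum_k d(x, x_k)^(-2/(m-1))

over its k nearest training samples on min–max-normalized features
(defaults k = 4, m = 2); the predicted class is the membership argmax.

**Selector.** Particles carry real positions, one dimension per feature
entry, binarized by `bit = 1 iff sigmoid(x) > U(0,1)`. QPSO samples new
positions around a per-particle attractor `p = phi*pbest + (1-phi)*gbest`:

    X' = p ± alpha * |mbest - X| * ln(1/u),    mbest = mean of personal bests,

with the contraction–expansion coefficient `alpha` decaying 1.0 → 0.5. The
fitness of a mask is the stratified 5-fold cross-validated macro-F1 of the
fuzzy k-NN restricted to the selected entries. Fitted models report
pooled-fold precision/recall/F1 per class and Cohen's kappa.

## Worked example

Simulate 105 segmented cells (15 per class), extract features, and run the
Q-Fuzzy selector against the all-features baseline:

```r
library(qfuzzy)
cells <- generate_cells(counts = setNames(rep(15L, 7),
                                          names(cell_class_specs())),
                        seed = 42)
tab <- extract_feature_table(cells$cells, labels = cells$labels,
                             ids = cells$ids)
fit <- qfuzzy(tab[, feature_names()], tab$class, k = 4,
              control = swarm_control(S = 15, T = 20, seed = 7))
summary(fit)
```

```
Q-Fuzzy wrapper feature selection (QPSO optimizer)
  28 of 54 feature entries selected; CV macro-F1 = 0.8914
  fuzzy k-NN: k = 4, m = 2; 5-fold CV on 105 samples, 7 classes

Pooled-fold evaluation of the selected subset:
               class tp fp fn precision recall    f1
   carcinoma_in_situ 13  1  2     0.929  0.867 0.897
            columnar 13  2  2     0.867  0.867 0.867
        intermediate 12  0  3     1.000  0.800 0.889
    light_dysplastic 13  2  2     0.867  0.867 0.867
 moderate_dysplastic 14  0  1     1.000  0.933 0.966
   severe_dysplastic 14  3  1     0.824  0.933 0.875
         superficial 15  3  0     0.833  1.000 0.909

Macro: precision 0.903, recall 0.895, F1 0.895; Cohen's kappa 0.878
```

The selector kept 28 of 54 entries (morphometry such as nucleus area,
perimeter and N/C ratio, brightness, and a subset of the texture entries)
and reaches a cross-validated macro-F1 of 0.89 with kappa 0.88. The same
data classified with *all* 54 entries:

```r
base <- all_features_baseline(tab[, feature_names()], tab$class, k = 4,
                              seed = fit$fold_seed)
# CV macro-F1 0.7439, kappa 0.711
```

so pruning the feature vector lifts macro-F1 by ~0.15 here — noisy or
redundant entries dilute the k-NN distance metric. `plot(fit)` draws the
monotone global-best fitness trace, `coef(fit)` returns the 0/1 selection
mask, and `predict(fit, newdata)` classifies new feature rows.

A command-line pipeline over the same functions is installed as
`exec/qfuzzy`, with subcommands `simulate`, `extract`, `select`,
`classify`, `evaluate` operating on PNG image pairs, CSV feature tables
and JSON results.

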