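# dixonmuscle

Automated quantification of intramuscular fat in whole-body Dixon
(chemical-shift) MRI for muscular dystrophy studies, with the clinical-trial
statistics stage built on top — exercisable end to end on synthetic data.

## The problem

In *FKRP*-related limb-girdle muscular dystrophy (LGMD2I), muscle is
progressively replaced by fat. Two-point Dixon MRI yields four co-registered
channels per voxel — in-phase (W + F), opposed-phase (|W − F|), water and
fat — from which tissue can be classified automatically. The biomarker of
interest is the **intramuscular fat fraction** over the thigh:

    FF = 100 · n(fat-infiltrated muscle) / (n(healthy muscle) + n(fat-infiltrated muscle))

with bone and subcutaneous fat excluded from numerator and denominator, so
that subjects with more subcutaneous fat do not appear more infiltrated at
identical muscle pathology.

The classifier is a patch-based 2-D CNN over per-voxel **tissue
signatures** — the ordered intensity 4-vector (IP, OP, W, F) in its 5 × 5
in-plane neighborhood: four 3 × 3 convolutions (128/64/32/16 filters), each
with batch normalization and ReLU, 2 × 2 stride-2 max pooling after the
first two, a fully connected layer and softmax; trained with Adam
(lr 0.001, β₁ 0.9, β₂ 0.999, ε 1e−8, minibatch 1024, cross-entropy). The
network and its training loop are implemented in R on BLAS matrix products
and are deterministic given a seed.

Because no clinical images ship with the package, a phantom generator
renders thigh cross-sections (bone rim + marrow, muscle annulus with a
controllable infiltrated fraction, subcutaneous rind, air) under the Dixon
forward model with Rician-like noise at a chosen SNR, and a cohort generator
emulates the two-visit, two-day outcome structure of a trial lead-in
(thirteen outcomes scaled to published adult LGMD2I reference ranges, severity-driven
associations, heteroscedastic test–retest noise). The statistics stage
implements Bland–Altman limits of agreement, Spearman repeatability with
exact permutation p-values (n ≤ 9), Shapiro–Wilk-gated paired t /
exact-Wilcoxon longitudinal comparisons (exact under ties for n ≤ 25),
a Bonferroni-adjusted mixed Pearson/Spearman correlation matrix, and the
largest-standardized-residual outlier sensitivity analysis.

## Worked example

Train on ten phantom realizations spanning infiltration fractions 0.1–0.9
at SNR 20, then segment a held-out phantom:

```r
library(dixonmuscle)

phantoms <- lapply(1:10, function(i)
  generate_phantom(desk_phantom_params(i / 11, seed = 1000 + i)))
patches  <- build_training_set(phantoms, per_class = 5000, seed = 11)
model    <- train_cnn(build_model(4, 4, cnn_config(epochs = 10, seed = 5)), patches)

held <- generate_phantom(desk_phantom_params(0.5, seed = 777))
pred <- segment_volume(model, held$volume)

round(sapply(1:3, function(k) dice_coefficient(pred, held$labels, k)), 4)
#> [1] 1.0000 0.9844 0.9999
round(intramuscular_fat_fraction(pred), 2)
#> [1] 50.01
round(100 * held$truth$realized_infiltration_fraction, 2)   # generator truth
#> [1] 50
```

The Dice coefficients score voxel overlap with the generator's ground-truth
labels for healthy muscle, subcutaneous fat and fat-infiltrated muscle; the
estimated fat fraction recovers the generator's target to a fraction of a
percentage point at this noise level.

The cohort/statistics stage runs the same way:

```r
cohort <- generate_cohort(19, seed = 300)
summ   <- summarize_cohort(cohort)     # trial-style per-outcome table
cm     <- correlation_matrix(cohort)   # Bonferroni-adjusted pairwise cells
```

`run_pipeline(default_demo_config(seed = 1), "out/")` chains
simulate → train → segment → quantify → stats from one configuration and
writes every output with an MD5-checksummed manifest. The numbered scripts
under `analysis/` run the same stages as a narrated workflow writing under
`results/run/`.

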