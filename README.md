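# hippseg

Hippocampal subfield segmentation is hard: the subfields (dentate gyrus,
CA1–CA3, subiculum) are small, rater protocols disagree about which of them to
draw and where, and their volumes change non-linearly across the lifespan.
`hippseg` is a desk-scale, fully testable R implementation of an end-to-end
segmentation-and-analysis factory for this problem, aimed at methodologists
who want every stage of such a pipeline to be exercisable without any imaging
data download:

* **Synthetic phantoms.** A parametric curved-tube hippocampus (DG core,
  CA1/CA2/CA3/SUB angular sectors, optional undifferentiated HEAD/TAIL caps)
  with class-dependent intensities, multiplicative bias field, additive noise,
  bilateral embedding into a "head" scene at known affine poses with a paired
  template/atlas, and cohort tables following growth–stability–decay volume
  trajectories with sex offsets.
* **ROI localization.** Template-to-native affine registration (built-in
  multi-resolution mean-squared-error optimizer), atlas back-projection of the
  bilateral hippocampus boxes with a 16-voxel safety margin, Z-normalization,
  and padding to multiples of 8.
* **Segmentation model.** A 3D residual U-Net with attention-gated skip
  connections and switchable normalization, trained with a protocol-aware
  focal Tversky loss
  `L = (1 - TP / (TP + 0.7 FN + 0.3 FP))^0.75`
  that merges classes (e.g. CA2+CA3) per observation and scores subfield
  predictions inside undifferentiated head/tail regions as hippocampus rather
  than penalizing them. Training uses bootstrap bagging, AdamW, a one-cycle
  learning-rate schedule and stochastic weight averaging; magnitude pruning
  (default 70%) produces efficient variants. The network, its reverse-mode
  autodiff and the optimizer are implemented in this package (R + Rcpp/BLAS).
* **Inference.** Test-time augmentation (flips, affine, elastic; 21 versions
  by default), voxel-wise plurality voting across ensemble × augmentation
  predictions realigned to native space, and a vote-entropy uncertainty map
  `H = -Σ p̂_m log p̂_m`.
* **Evaluation.** Dice coefficient, symmetric Hausdorff distance and
  volumetric similarity per label, validated against brute-force oracles.
* **Lifespan analytics.** Per-sex natural cubic spline volume trajectories
  with AIC-selected degrees of freedom, knee-point (kneedle) inflection
  detection, per-period OLS of `volume ~ age * sex` with Benjamini–Hochberg
  correction, and normalized anteroposterior subfield composition profiles.

## Worked example

```r
library(hippseg)

# a phantom cohort and a two-member bagged ensemble
train <- phantom_cohort(20, seed = 101)
dataset <- lapply(train, function(p)
  list(image = z_normalize(p$volume)$data, target = p$labels$data,
       protocol = protocol_spec()))
ens <- train_ensemble(dataset,
                      model_config(depth = 3, base_channels = 8, n_classes = 6),
                      train_cfg = train_config(n_models = 2, epochs = 40,
                                               seed = 11))

# segment a held-out phantom with TTA fusion and evaluate
test <- phantom_cohort(1, seed = 909)[[1]]
out <- segment_crop(z_normalize(test$volume)$data, ens,
                    tta_config(n_versions = 5, seed = 34))
evaluate_pair(out$labels, test$labels, labels = 1:5)
#>   label        DC HD        VS n_ref n_pred
#> 1     1 0.9688525  1 0.9770492   596    624
#> 2     2 0.9679529  1 0.9928058   770    759
#> 3     3 0.9695387  1 0.9991297   574    575
#> 4     4 0.9668386  1 0.9992631   678    679
#> 5     5 0.9667440  1 0.9976798   648    645
```

Labels 1–5 are DG, CA1, CA2, CA3 and SUB: Dice above 0.96 per subfield on
this held-out phantom with a one-voxel Hausdorff distance; the uncertainty map
concentrates on subfield boundaries (boundary vote entropy exceeds the
interior's). A lifespan run looks like:

```r
tab <- make_lifespan_cohort(lifespan_spec(seed = 7))   # n = 1000 per sex
df <- select_df_aic(tab, "DG", "F")
fit <- fit_ncs(tab, "DG", "F", df)
detect_inflections(fit)
#> [1] 23.13996 72.13996
```

The generating cohort bends at ages 22 (growth end) and 70 (decay onset); the
detected knees land within the expected recovery tolerance of both.

A thin command-line front end is included at `inst/cli/factory.R`
(`phantom`, `extract`, `evaluate`, `lifespan` subcommands).

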