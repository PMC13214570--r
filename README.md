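# datmap

Normative mapping of dopamine-transporter (DaT) binding from multispectral
MRI voxel signatures.

## What it does

Striatal DaT density, the molecular target of PET/SPECT dopamine imaging,
declines early in Parkinson's disease (PD) — first and most strongly in the
putamen.  `datmap` asks how far that molecular readout can be predicted
noninvasively: given, for every voxel in a common space, a vector of
quantitative MRI values (diffusion, susceptibility, saturation-transfer,
anatomical channels), it learns a mapping onto a healthy-reference DaT
atlas and reads group differences as deviations from that normative
prediction.

The pipeline has two learned stages plus classical preprocessing and
statistics:

1. **Preprocessing** — per subject and channel, a degree-4 polynomial in
   the voxel coordinates is fit and subtracted (35-term monomial basis;
   removes smooth B0/B1-like trends), residuals are z-scored per subject,
   and the atlas target is standardized.
2. **Contrastive embedder** — an MLP encoder produces L2-normalized 16-D
   voxel embeddings trained with InfoNCE (temperature 0.07) over two
   augmented views of each voxel (global intensity shifts, smooth low-rank
   channel gains, monotone gamma-like warps, noise, feature dropout).
   Adversarial coordinate and subject classifiers attached through a
   gradient-reversal layer force the embedding to hide voxel location and
   subject identity:
   `L = L_InfoNCE + 20 * L_coordinate + 20 * L_subject`.
3. **Regressor** — a feed-forward network (architecture shared with the
   adversarial heads) maps frozen embeddings to the standardized atlas
   value by MSE, with AdamW and cosine annealing.
4. **Validation & statistics** — leave-one-healthy-control-out
   cross-validation (patients never train), fold aggregation (mean and
   median), ROI summaries (putamen, caudate, striatum, control), Welch's
   t with Benjamini-Hochberg FDR, Hedges' g with bootstrap 95% CI, and
   flipped ROC with the Youden operating point on the binding-potential
   scale.

Because no public cohort pairs co-registered multispectral voxel
signatures with a DaT reference, the package ships a seeded synthetic
cohort generator (`generate_cohort()`) whose voxels carry the structure
the pipeline assumes — atlas-linked tissue signal, removable polynomial
bias fields, residual subject-specific bias, per-channel gains, noise, and
a plantable putaminal attenuation in PD subjects — so every stage is
testable end to end.  The compute core (dense blocks, InfoNCE gradient,
fused AdamW training step) is implemented in RcppArmadillo with pure-R
reference implementations pinned to it in the tests.

## Worked example

```r
library(datmap)

## synthetic cohort: 8 HC, 4 PD, 700 voxels/subject, 40 channels,
## 30% putaminal attenuation of the atlas-linked signal in PD
cohort <- generate_cohort(cohort_config(disease_attenuation = 0.3,
                                        n_voxels_per_subject = 700,
                                        seed = 9))

embed_cfg <- embedder_config(input_dim = 40, hidden = c(64, 64),
                             head_hidden = c(128, 128, 128),
                             steps = 250, batch_size = 160,
                             coord_bins = 8, lr = 1e-3, seed = 9)
reg_cfg <- regressor_config(input_dim = 16, hidden = c(128, 128, 128),
                            epochs = 35, batch_size = 512, seed = 9)

run   <- run_loho(cohort, embed_cfg, reg_cfg, seed = 9)
summ  <- summarize_roi(run, cohort$voxels)
stats <- group_stats(summ, rois = c("putamen", "caudate", "striatum",
                                    "control"), seed = 9)
print(stats)
#>       roi     t       p       q   df hedges_g g_ci_low g_ci_high n_hc n_pd
#>   putamen  4.54 0.00231 0.00925 7.39    2.390   1.5300     4.740    8    4
#>   caudate -1.49 0.19700 0.19700 5.10   -0.903  -2.8000     0.188    8    4
#>  striatum  1.88 0.12700 0.17000 4.37    1.230   0.1470     3.590    8    4
#>   control  1.77 0.10900 0.17000 9.36    0.746  -0.0212     1.950    8    4

sel <- subset(summ, roi == "putamen" & aggregation == "mean")
roc_analysis(sel$summary_mean[sel$group == "HC"],
             sel$summary_mean[sel$group == "PD"])
#> ROC (flipped: low binding = PD-like): AUC 0.969 | Youden threshold 1.270 (binding potential)
#>   sensitivity 1.000, specificity 0.875, balanced accuracy 0.938
```

The putamen shows a significant reduction in predicted binding for PD
(q < 0.05, large Hedges' g) while the control region does not; the ROC is
computed on negated summaries so that lower predicted binding counts as
PD-like, and the Youden threshold is reported on the original
binding-potential scale.  (Exact numbers vary with the seed; these are the
values printed by this example.)

Ablations reuse the same folds:

```r
run_ablation(cohort, "raw", embed_cfg, reg_cfg, seed = 9)            # no embedder
run_ablation(cohort, "no_adversarial", embed_cfg, reg_cfg, seed = 9) # w_c = w_s = 0
```

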