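# petthresh

Adaptive, machine-learned SUV thresholding for PET-based tumour
delineation.

## What problem this solves

Radiotherapy planning for lung cancer increasingly uses FDG-PET to help
define the gross tumour volume (GTV). The common automatic approach
contours the region of voxels whose standardized uptake value (SUV) meets
or exceeds a threshold — but a single threshold per study is too rigid: the
optimal threshold varies from slice to slice as the tumour cross-section
and partial-volume dilution change. `petthresh` implements a learning
approach to this problem: each axial PET slice is summarized by six
uptake-distribution attributes — the area and mean SUV inside the
superlevel-set contours at 0.10, 0.15 and 0.20 × SUV₇₀, where SUV₇₀ is the
mean SUV inside the 70%-of-SUV₍max₎ 3D contour — and a ν-support-vector
regressor with Gaussian kernel is trained to predict, per slice, the SUV
threshold whose contour best matches the reference GTV.

Reference labels are built reproducibly: for tumour slices, the threshold
maximizing the Jaccard overlap J = |R∩A|/|R∪A| with the GTV cross-section
(found exactly by searching all distinct superlevel sets of the slice);
for the eight adjacent tumour-free slices, the slice maximum SUV.
Performance is evaluated over five repeated random 75/25 train/test
splits by (i) the Pearson correlation between reference and predicted
thresholds and (ii) the pooled Jaccard index between reference-contoured
and predicted-contoured test regions, alongside a classical
contrast-oriented baseline threshold (mean background SUV + 0.15 × SUV₇₀).

Since no patient data ship with the package, a synthetic thorax phantom
generator provides studies with known ground truth: ellipsoidal tumours
with radially decaying uptake on a low-uptake background, scanner PSF
blur, additive noise, and gated versus free-breathing (respiratory-motion
averaged) acquisition modes.

Intended users: researchers in PET image analysis and radiotherapy
planning who want a reproducible reference implementation of per-slice
adaptive thresholding, with a fully synthetic test bed.

## Worked example

```r
library(petthresh)

suite   <- default_patient_suite(seed = 1)   # 2 tumours x 2 modes
study   <- suite$patient2_gated
records <- build_labelled_instances(study)   # features + reference labels
head(records[, c("slice_index", "is_tumour", "area_015", "mean_015",
                 "reference_threshold")])

report <- evaluate_study(study, learner_config(seed = 1),
                         n_repeats = 5, seed = 1, records = records)
report
```

```
Study 'patient2_gated' (gated): 41 slices (33 tumour), 5 random splits
  correlation (ref vs svm):   0.940
  Jaccard     (ref vs svm):   0.970
  Jaccard     (ref vs baseline): 0.943
```

Reading this: the study has 33 tumour-bearing slices plus 8 tumour-free
neighbours. Averaged over five random 75/25 splits, the predicted
thresholds correlate r ≈ 0.94 with the per-slice reference thresholds, and
the regions they contour overlap the reference regions with a pooled
Jaccard index of ≈ 0.97 — higher than the ≈ 0.94 achieved by the constant
contrast-oriented baseline threshold, which cannot follow slice-to-slice
variation.

Individual pieces are exposed too: `global_uptake_stats()`,
`slice_attributes()`, `best_threshold()`, `train_threshold_model()` /
`predict_threshold()`, `jaccard()`, and NIfTI/CSV/JSON I/O via
`read_suv_volume()`, `write_feature_table()`, `write_report()`. A thin
command-line front end lives at `inst/cli/petthresh.R`
(`phantom` / `label` / `evaluate` subcommands).

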