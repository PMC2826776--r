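---
title: "Adaptive SUV thresholding for PET tumour delineation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive SUV thresholding for PET tumour delineation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petthresh)
```

## The problem

Threshold-based delineation of hypermetabolic tumours in FDG-PET contours
the region of voxels whose standardized uptake value (SUV) meets or exceeds
a threshold. Classical rules pick one threshold per study — a fixed SUV, a
fixed percentage of SUV~max~, or a contrast-oriented rule such as

$$t_{\mathrm{co}} = \overline{\mathrm{SUV}}_{\mathrm{bg}} + 0.15 \times \mathrm{SUV}_{70},$$

where SUV~70~ is the mean SUV of all voxels at or above 70% of SUV~max~ and
$\overline{\mathrm{SUV}}_{\mathrm{bg}}$ is the mean background uptake. But
the threshold that best reproduces a clinician's gross tumour volume (GTV)
varies from slice to slice: partial-volume effects depress the apparent
uptake of small cross-sections, so thin tumour ends need lower thresholds
than hot central slices. `petthresh` treats the per-slice optimal threshold
as a *regression target*: each axial slice is summarized by six
uptake-distribution attributes, and a Gaussian-kernel ν-support-vector
regressor learns the mapping from attributes to threshold within a study.

## The per-slice attributes

For a study with statistics SUV~max~ and SUV~70~, each slice is described by
the area (mm²) and mean SUV inside the superlevel-set regions at thresholds
$f \times \mathrm{SUV}_{70}$ for $f \in \{0.10, 0.15, 0.20\}$ — six numbers
capturing the interplay between uptake level and cross-section size at three
nested contour levels (roughly: tumour plus surroundings, the tumour, and
the hottest core). Regions are plain superlevel sets with an inclusive
comparator (voxels exactly at the threshold belong to the region) and no
connected-component filtering — a region may legitimately consist of several
disjoint contours. The mean of an empty region is reported as 0 so that
tumour-free slices far from the tumour still yield a complete attribute
vector.

## Reference labels

Clinical reference thresholds would be assigned by radiation oncologists.
The package substitutes the purely geometric optimum, the only criterion
that can be stated operationally: for each tumour slice, the threshold
maximizing the Jaccard index $J = |R \cap A| / |R \cup A|$ between the
thresholded region and the GTV cross-section. Searching the sorted unique
positive voxel values of the slice visits every distinct superlevel set, so
this optimum is global; ties break toward the smallest (most inclusive)
threshold, and the achieved Jaccard is kept as a diagnostic. Tumour-free
slices are labelled with their maximum SUV — the threshold that most nearly
empties the slice under the inclusive comparator.

## The learner

The regressor is a ν-SVR with Gaussian kernel. Hyperparameters are selected
by 5-fold cross-validated mean squared error on a logarithmic grid
(defaults: cost $2^{-3}\ldots2^{9}$ and kernel width $2^{-11}\ldots2^{3}$
stepping by powers of 4, ν ∈ {0.25, 0.5, 0.75}); folds are seeded and
stratified by the tumour flag so every fold sees tumour-free labels, and
ties break toward smaller cost, then width, then ν. Attributes are
standardized to zero mean and unit spread on the training set.

Two clamps guard prediction, both motivated by the geometry of kernel
regression rather than by the application alone:

* **Attribute clamp.** A Gaussian-kernel machine queried far from its
  training data reverts to its intercept, which is an arbitrary threshold.
  This is not hypothetical: the 0.10×SUV~70~ contour can cover essentially
  the whole slice on every training slice, leaving that area attribute with
  a tiny spread; a test slice a few voxels different then lands tens of
  standard deviations away after scaling. Scaled attributes are therefore
  clamped into the training range, so the model is never evaluated outside
  the attribute regime it was fitted on.
* **Output clamp.** Raw predictions are clamped first into the training
  label range (a threshold below every label seen in training is an
  extrapolation artefact — and a threshold below the background uptake
  contours the entire slice), then into $[0, \mathrm{SUV}_{\max}^{\mathrm{slice}}]$.

Degenerate inputs are handled explicitly: a constant label vector returns a
flagged constant predictor; a constant attribute receives unit spread and a
warning.

## Evaluation harness

Within a study, the labelled slices are split at random into 75% training
and 25% test (training size $\lfloor 0.75N \rfloor$), the model is trained,
and test slices are contoured at their predicted, reference, and
contrast-oriented baseline thresholds. The split is repeated 5 times
(per-repeat seeds derive from the master seed as `seed + split_id`) and
metrics are averaged. Two metrics are reported per split: the Pearson
correlation between reference and predicted thresholds, and the Jaccard
index between pooled regions — the test slices' reference regions stacked
into one 3D voxel set against the corresponding predicted (or baseline)
set. Pooling weights each slice by its area, which is the natural
volumetric reading; the per-slice mean Jaccard is also recorded as a
secondary metric. Empty-region conventions: two empty regions count as
perfect agreement (J = 1) — a tumour-free slice where both thresholds
exceed all voxels is a success — and exactly one empty region counts as
total disagreement (J = 0). Tumour-free test slices are included by
default and can be excluded with a flag. A test set with constant reference
thresholds has no defined correlation; such splits are recorded as `NA`,
excluded from the average, and warned about rather than silently zeroed.

The baseline threshold is computed once per study from SUV~70~ and the mean
SUV over the background mask. Its constancy across slices, against the
per-slice variation of the reference thresholds, is the structural contrast
that motivates the learned approach.

## The phantom generator

Because no public PET/GTV data accompany the method, every stage is
exercised on synthetic studies with known ground truth. The defaults
emulate a single-bed thorax acquisition: a 64 × 64 × 48 grid of 4 mm
isotropic voxels, background uptake 1 SUV, one ellipsoidal tumour peaking
at 10 SUV, a 7 mm FWHM isotropic Gaussian PSF, and additive Gaussian noise
with SD 0.05 SUV clipped at zero. The four-study default suite pairs two
tumour geometries (axially elongated ellipsoids spanning 24 and 33 slices —
the smaller tumour yields 32 selected slices, the larger 41, each tumour
count plus eight adjacent tumour-free slices, four inferior and four
superior) with both acquisition modes.

Design choices that were genuinely open:

* **Tumour profile.** Uptake decays radially from the peak as
  $1 - (1 - e)\rho^{p}$ in the normalized ellipsoidal radius ρ (default
  exponent $p = 2$), reaching not the background but an elevated rim at
  `edge_fraction` $e = 0.3$ of the peak-to-background contrast. A profile
  fading to exactly background makes the GTV rim invisible — no threshold
  can recover a boundary with zero contrast, reference labels on thin end
  slices collapse into the noise floor, and the delineation problem becomes
  ill-posed for *any* method. Clinically, FDG-avid tumours present a
  contrast step at their boundary; the elevated rim preserves that while
  the radial decay plus partial-volume blur still makes the per-slice
  optimal threshold vary with cross-section, which is the phenomenon the
  learner exists to handle.
* **GTV defined pre-blur.** The mask rasterizes the geometric ellipsoids
  (voxel-centre inclusion), not their blurred image: the anatomic tumour is
  the clinical target, and this forces nontrivial optimal thresholds.
* **Respiratory motion.** Free-breathing mode averages copies of the
  activity displaced axially before blurring. Displacements are sampled
  sinusoidally over the respiratory cycle as $(A/2)(1 - \cos\phi)$, i.e.
  one-sided in $[0, A]$ (default amplitude 8 mm) *from the end-exhale
  reference position* — the phase a gated acquisition selects and the
  phase the GTV describes. This matters: breathing does not displace a
  tumour symmetrically about its planning position, and a zero-mean
  symmetric smear in fact *narrows* the per-slice threshold distribution
  (end slices borrow hotter neighbouring cross-sections), whereas the
  one-sided smear reproduces the broadened free-breathing threshold
  histogram alongside a diluted SUV~max~.
* **Background mask.** A peritumoral shell at city-block distance 2–4
  voxels outside the GTV: deterministic, close enough to be the relevant
  background, far enough (≥ 8 mm) that PSF spill-in is negligible at the
  default blur.
* **Noise.** Gaussian on the blurred activity, clipped at zero, rather
  than a full Poisson sinogram simulation — adequate fidelity for
  threshold statistics at this scale.

What the phantom does *not* emulate: heterogeneous background anatomy
(mediastinum, chest wall), necrotic cores, scatter/randoms/reconstruction
artefacts, non-rigid motion, and inter-patient variability. Passing tests
on phantoms therefore demonstrates the internal consistency and statistical
behaviour of the method under controlled conditions, not clinical
performance.

## Worked example

```{r example, eval = FALSE}
suite <- default_patient_suite(seed = 1)
st <- suite$patient2_gated
records <- build_labelled_instances(st)
report <- evaluate_study(st, learner_config(seed = 1),
                         n_repeats = 5, seed = 1, records = records)
report
```

On this study the five-split averages are a correlation near 0.94 and
pooled Jaccard near 0.97 for the learned method against roughly 0.94 for
the contrast-oriented baseline; the smaller-tumour studies score lower,
consistent with their smaller training sets. Exact values for any seed are
reproduced by `scripts/acceptance.R`.

## Numerical and scale choices

Problem sizes throughout (64 × 64 × 48 grids, 168-point hyperparameter
grid, 5 folds, 5 splits, 20-seed property checks) were chosen so a full
study evaluation takes seconds and the complete statistical test battery
minutes on a single core, while leaving the per-study slice counts at the
scale the method is designed for (tens of labelled instances). Determinism
is end-to-end: all randomness (noise draws, fold assignment, splits) flows
from explicit integer seeds through a private RNG stream that restores the
caller's state.

## Known limitations

* Reference labels are the geometric Jaccard optimum; clinicians also use
  anatomic context, which is not modelled.
* The learner is strictly intra-study: a model trained on one study has no
  claim to transfer to another patient or scanner.
* Areas are computed by voxel counting; no sub-voxel contour interpolation.
* SUV values are assumed already normalized; computing SUVs from raw
  activity, weight and dose is out of scope, as are DICOM ingestion and
  PET–CT registration.
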