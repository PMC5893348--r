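---
title: "Region distance profiling: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region distance profiling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiodist)
```

## The model

`regiodist` treats a brain as a *set of regional gray-level distributions*
and disease as a multidirectional departure of those distributions from a
healthy baseline. The pipeline assumes its inputs are skull-stripped,
gain-corrected volumes already registered (affinely) into the atlas space;
registration, bias correction and segmentation are out of scope. Residual
registration error is tolerated deliberately: the unit of analysis is the
distribution of intensities *within* a region, which is insensitive to small
boundary displacements — the package only emits a Dice-overlap QC warning
(default threshold 0.90) between each subject's brain mask and the atlas
mask.

Each region's intensity sample becomes a fixed-bin histogram, normalized to
unit mass, and shifted so that its center of mass lies on the central bin.
The shift removes constant intensity offsets (scanner gain, background
level); what remains is distribution *shape*, which is where tissue
composition expresses itself. Histograms are compared with the Earth Mover's
Distance with unit cost $|i-j|$ between bins. For equal-mass 1-D histograms
the transportation linear program's optimum equals
$\sum_k |\mathrm{CDF}_S(k) - \mathrm{CDF}_C(k)|$, so the closed form is the
production path; `emd_lp()` implements the LP itself (a transportation
simplex with a north-west-corner start and MODI optimality verification) as
the exact reference and for inspecting transport plans.

Subjects are compared by $\delta(a,b) = \sum_r \mathrm{EMD}(a_r, b_r)$, the
unweighted sum over regions. The healthy reference is the *medoid* of the
control group under $\delta$ — a real subject, not a synthetic average, so
its regional histograms are guaranteed to be realizable distributions. Every
subject is then reduced to its vector of per-region EMDs to the medoid's
corresponding regions: the feature matrix.

Classification uses RUSBoost: AdaBoost over single-region threshold stumps,
with the majority class randomly undersampled to the minority size before
each round. The stump is the natural weak learner here because each feature
is already a calibrated "distance from normal" for one region, and the
ensemble's per-region summed stump weights directly yield an importance
ranking. Evaluation is a leave-one-out ROC over pooled out-of-fold scores,
with AUC by the trapezoid rule and the equal error rate read off the
crossing of the ROC with the anti-diagonal.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bins` | 64 | histogram bins | enough resolution for bimodal tissue mixtures without starving regions of counts; smaller regions (~200 voxels) still average ~3 counts per bin |
| `intensity_range` | per-subject [0.5th, 99.5th] percentile of labeled voxels | intensity | robust to skull-strip holes and hot spots; shared across one subject's regions so regional histograms stay comparable; configurable to a fixed global range |
| `aggregate` | `"sum"` | — | how per-region EMDs combine into $\delta$; `mean` and `max` available for sensitivity analysis |
| `rounds` | 100 | boosting rounds | saturates the toy and phantom problems well before 100; more rounds only re-pick established stumps |
| `dice_warn` | 0.90 | Dice | registration QC warning threshold; well-registered cohorts sit near or above 0.97 |
| `seed` | — | — | master seed; every random draw (undersampling, folds, phantoms) derives from it deterministically |

## Numerical choices

* **Equal-mass precondition.** EMD requires equal totals; after unit-mass
  normalization the check tolerance is 1e-9 (relative).
* **Center-of-mass shift** is by an *integer* number of bins
  (`round(central_bin - com)`). A fractional, interpolated shift would smear
  mass across bins and change the distribution being measured; an integer
  shift is lossless except at the ends, where shifted-out mass is clipped
  and the histogram renormalized. Clipping above 5% of the mass logs a
  warning. Circular wrapping was rejected: intensity has no cyclic topology,
  and wrapping would teleport mass across the axis.
* **Central bin of an even-length histogram** is index $m/2$ (0-based). Any
  single fixed choice works; this one keeps the shift integral.
* **Normalization order**: histograms are renormalized *after* shifting, so
  clipped mass never breaks the equal-integral precondition of the EMD.
* **Stump threshold candidates** are the midpoints between consecutive
  distinct sorted feature values; a constant feature gets one below-range
  candidate, making the stump an explicit, flagged majority-class voter.
  Ties break to the lowest region index, then the lowest threshold, then
  positive polarity, so training is exactly reproducible.
* **Weighted error** of each stump is evaluated on the full weighted sample,
  not the undersampled subset, so ensemble weights (alpha) stay meaningful
  for the whole cohort; epsilon is clamped to [1e-10, 0.5 − 1e-10].
* **Weak rounds.** A round whose full-sample error reaches 0.5 contributes
  nothing: its stump is discarded and the next round draws a fresh
  undersample. A hard stop at the first weak round was tried and rejected —
  with a 30:12 imbalance one unlucky resample would truncate the ensemble to
  one or two stumps and collapse the out-of-fold score to two levels.
* **Pooled LOOCV scores are alpha-normalized.** Each fold trains its own
  ensemble with its own total stump weight, so raw score sums are not
  comparable across folds; each out-of-fold score is divided by its
  ensemble's summed alpha, putting all scores on the common margin scale
  $[-1, 1]$ before one ROC is built.
* **Missing regions** (empty in the atlas or in a subject) yield `NA`
  features. Stumps abstain (vote 0) on `NA` at prediction time and count
  `NA` samples as misclassified during fitting, so a region missing in many
  subjects is naturally avoided by training.
* **Medoid ties** break to the lexicographically smallest subject id.
* **Probabilistic atlases** are reduced to maximum-probability label maps at
  load time, ties to the lowest label id.

## The phantom generator

`phantom_spec()` defines the synthetic study conditions: a spherical "brain"
on a 24³ grid, partitioned into 20 contiguous regions by a seeded k-means
tessellation of voxel coordinates, each region's intensities drawn from a
two-component Gaussian mixture — "dense" tissue (mean 70, sd 8) and
"rarefied" tissue (mean 40, sd 8) mixed at a dense fraction of 0.60. This is
the minimal model in which a regional histogram is a probability statement
about tissue composition.

Biological variability and disease are expressed entirely through the dense
fraction:

* every subject-region jitters the dense fraction with sd 0.05 (healthy
  between-subject variability);
* a patient *expresses* each affected region independently with probability
  0.75; an expressed region loses `effect_size` (default 0.3, a strong
  neuronal-loss analogue) times Unif(0.8, 1.2) of dense fraction, an
  unexpressed one only up to 20% of that.

The expression model is the point: disease involvement is heterogeneous
across patients, so no single region carries every patient and the
classifier must combine regions — the regime the method is designed for. The
default cohort is 30 controls and 12 patients, imbalanced like real
case-control cohorts (a 66:20 preset mirrors the classical
controls-vs-dementia ratio).

What the phantom does **not** emulate: anatomy (regions are Voronoi cells,
not structures), registration error fields, MR physics (bias fields, partial
voluming, noise correlation), and longitudinal change. Passing phantom tests
therefore demonstrates the *pipeline's* correctness and sensitivity under
known ground truth — not clinical performance on real scanners.

With these defaults, sizes were chosen so the full 10-seed phantom study
(effect and null conditions, leave-one-out over 42 subjects, 100 boosting
rounds) completes in roughly two minutes on one CPU; the per-region
closed-form EMD is what makes this cheap.

## Known limitations

* **Redundancy suppresses correlated regions.** Boosting assigns weight to
  regions that *add* discriminative value. When two planted regions catch
  the same patients, the second is redundant and can earn little or zero
  importance — with only 12 patients this happens in roughly half of the
  phantom cohorts, where one of the three planted regions contributes no
  unique information. The importance table ranks *non-redundant evidence*,
  not ground-truth involvement; interpreting low importance as "region
  unaffected" is a misreading the package cannot prevent.
* The subject distance $\delta$ weighs all regions equally regardless of
  size; a weighted aggregation is a one-line configuration change but no
  principled default weighting is established.
* Zero-intensity voxels inside labeled regions (skull-strip holes) are kept,
  on the argument that center-of-mass alignment absorbs constant background;
  cohorts with large holes may prefer to mask them upstream.
* The per-subject percentile intensity range makes histograms robust to gain
  differences but means two subjects' bins are not strictly the same
  physical intensities; the center-of-mass alignment is what makes the
  comparison meaningful. A fixed global range is available when acquisitions
  are calibrated.
* `apply` transfers a trained model across cohorts only when the histogram
  configuration hashes match; it cannot detect deeper distribution shift
  (different field strengths, sequences) — inspect the transfer ROC before
  trusting it.
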