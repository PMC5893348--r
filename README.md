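# regiodist

Regional intensity-distribution distances for group analysis of brain MR
volumes.

## The problem

Neurodegenerative disease does not move every brain in the same direction:
different patients depart from the healthy baseline in different regions. A
single global deformation or volumetric score therefore misses much of the
signal. `regiodist` characterizes each subject by *how far every anatomical
region's gray-level distribution sits from a healthy reference*, and lets a
boosted classifier decide which regions carry discriminative information.

The pipeline, for skull-stripped volumes already registered to an atlas:

1. **Parcellation** — voxels are grouped by an integer label atlas
   (the bundled default table follows the Harvard–Oxford scheme:
   48 cortical areas × 2 hemispheres + 17 subcortical = 113 regions).
2. **Histograms** — each region becomes a fixed-bin (default 64) gray-level
   histogram, normalized to unit mass and shifted so its center of mass sits
   at the central bin, removing global intensity offsets.
3. **Earth Mover's Distance** — regions are compared with the EMD: the
   minimum cost of transporting histogram mass, with unit cost |i − j|
   between bins,

       EMD(S, C) = (1 / Σ x*_ij) Σ_ij |i − j| x*_ij ,

   where x\*_ij solves the transportation linear program
   min Σ p_ij x_ij s.t. Σ_j x_ij ≤ S_i, Σ_i x_ij ≥ C_j, x_ij ≥ 0.
   For equal-mass 1-D histograms this equals the Wasserstein-1 distance
   Σ_k |CDF_S(k) − CDF_C(k)|, the O(n) closed form used in production;
   the LP solver (`emd_lp`) is kept as the exact reference and for
   transport-plan inspection.
4. **Control medoid** — the reference subject is the medoid of the control
   group, medoid(A) = argmin_{x∈A} Σ_{y∈A} δ(x, y), with δ the sum of
   per-region EMDs. Every subject is then a feature vector of 113 distances
   to the medoid's regions.
5. **RUSBoost + LOOCV** — an AdaBoost ensemble of single-region threshold
   stumps, with the majority class randomly undersampled each round,
   classifies CN vs patients; leave-one-out out-of-fold scores pooled into
   one ROC give AUC and the equal error rate, and summed stump weights give
   a per-region importance table.

A synthetic phantom generator (`phantom_spec`, `simulate_cohort`) produces
labeled cohorts with planted regional effects so the whole pipeline is
testable without any imaging download.

## Worked example

The canonical transport example — two 3-bin histograms of total mass 3 where
one unit moves one bin:

```r
library(regiodist)
p <- c(1, 1, 1); q <- c(0, 2, 1)
emd_closed_form(p, q)   # 0.3333333  (= 1/3: one unit moved one bin, mass 3)
lp <- emd_lp(p, q)
lp$distance             # 0.3333333  (LP agrees with the closed form)
lp$plan$moves           # optimal flows:
#      [,1] [,2] [,3]
# [1,]    0    1    0
# [2,]    0    1    0
# [3,]    0    0    1
```

An end-to-end phantom study — 30 controls and 12 patients on a 20-region
phantom with 3 affected regions:

```r
res <- run_phantom_study(seed = 4)
sprintf("AUC %.3f | EER %.3f | medoid %s", res$auc, res$eer, res$medoid)
# "AUC 0.972 | EER 0.083 | medoid subj_019_CN"
head(res$importance, 6)
#     region importance
#  region_02  28.855427
#  region_01  16.322305
#  region_03  13.379462
#  region_18   5.198438
#  region_16   4.605390
#  region_15   4.198635
res$affected_regions
# "region_01" "region_02" "region_03"
```

The out-of-fold ROC has AUC 0.97 and an equal error rate of 0.08 (at the
crossing, false-positive and false-negative rates are both ~8%), and the
three planted regions top the importance ranking, together carrying ~59% of
the total relevance.

For real data, point the pipeline at a cohort manifest (TSV:
`subject_id`, `volume_path`, `group`), a label atlas NIfTI and a label table:

```sh
Rscript inst/cli/regiodist.R evaluate \
  --manifest cohort/manifest.tsv --atlas cohort/atlas.nii.gz \
  --labels cohort/labels.tsv --out results/ --bins 64 --seed 1
```

Stages (`extract`, `featurize`, `train`, `evaluate`, `rank`, `apply`,
`simulate`) write TSV/JSON artifacts plus a run manifest; `apply` transfers a
trained model and its serialized control-medoid reference to a new cohort and
refuses mismatched histogram configurations.

## Documentation

The methods vignette (`vignettes/region-distance-profiling.Rmd`) describes
the model, its assumptions, every tunable parameter, what the phantom
generator does and does not emulate, and known limitations.
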