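---
title: "Pooling acoustic surveys and citizen-science checklists for tropical bird distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling acoustic surveys and citizen-science checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structured acoustic surveys and semi-structured citizen-science checklists
are complementary sources of bird occurrence data. Autonomous recorders
placed along a habitat gradient sample evenly and intensively, but only
over a few square kilometers; citizen checklists cover whole regions but
concentrate where people go — in the lowland Amazon, along rivers and at
ecolodges, the low end of the floodplain–terra firme gradient that
structures the avifauna. `birdpool` implements a pooling workflow that
feeds both sources into common encounter-rate and occupancy models, so
that the acoustic data supply fine-grain information about positions on
the intact-forest gradient while the citizen data anchor predictions in
habitats (including disturbed and non-forest ones) the recorders never
see.

The workflow is organized as numbered drivers under `analysis/`
(simulate, calibrate, pool, encounter, occupancy), each a thin narrative
over package functions; every computational step lives in `R/` and is
unit-tested.

## Habitat model

The landscape is a gridded stack of elevation, a drainage (river) mask,
height above nearest drainage (HAND), categorical land cover and canopy
height. HAND — elevation minus the elevation of the Euclidean-nearest
drainage cell, floored at zero — is the flooding-intensity proxy that
separates floodplain forest from terra firme; hydrological flow-path HAND
is deliberately out of scope. Land cover follows HAND thresholds
(floodplain forest below t1, transition forest to t2, terra firme above),
with flooded-vegetation fringes along the channel and anthropogenic
patches (a "town" of crops/built area, a riverside "mining beach").
Habitat covariates for any survey point are buffer summaries: mean and SD
of continuous layers, percent cover per class, and edge density (meters
of class boundary per hectare) at two radii. Cell membership in a buffer
is by cell-center inclusion and edge segments on the buffer boundary are
not counted — landscape-metric tools differ here, so both conventions are
stated and the implementation is tested against a brute-force per-cell
oracle.

## Acoustic pipeline

Classifier detections carry confidence scores in (0, 1), logit-scaled
after clipping to [1e-6, 1 - 1e-6]. An annotation sample is drawn
stratified by 10 m elevation bands — up to 30 events per band across
scores 0.3–1 plus an independent up-to-30 per band at scores 0.8–1, so
the score region where false positives give way to true ones is always
represented. Three candidate calibration models are fitted to the labels:
an intercept-only null, a logistic regression on logit score, and a
logistic GAM adding a cubic-regression-spline smooth of site elevation
(classifier reliability can drift along the gradient as the acoustic
environment changes). Models are compared by
AICc = −2logLik + 2k + 2k(k+1)/(n−k−1), using the smoothing-corrected
model degrees of freedom for the GAM. The acceptance threshold is the
smallest value on a 0.001 grid of calibrated probability whose empirical
false-positive rate among accepted annotated events stays below 5%;
thresholding in probability space (rather than raw confidence) is the
default because the calibrated scale is comparable across seasons and
sites. Accepted detections are collapsed to at most one per species per
clock hour ("independent detections") and zero-filled against the
recording log; a filter can restrict events to a diel-schedule whitelist
per season.

## Pooling and rebalancing

Checklists pass the standard effort filters (complete; stationary or
traveling; duration < 5 h; distance < 1 km; fewer than 5 observers), and
"X" (present, uncounted) entries remove a checklist from that species'
dataset only. Citizen records are spatiotemporally subsampled — at most
one record per 600 m grid cell per ISO-8601 week per presence class, the
classes sampled separately — while acoustic records pass through, their
regular spacing already limiting spatial bias. Zero-filled acoustic hours
become pseudo-checklists (stationary, 1 observer, 1 h, 0 km) sharing the
checklist schema. Where a training table's presence fraction is below
25%, SMOTE adds synthetic presences interpolated between a presence and
one of its k = 5 nearest presence neighbors (distances on predictors
standardized by presence-class statistics; interpolation factor U(0, 1)),
adding exactly the count that first reaches the target. Non-citizen
tables are finally subsampled, class-proportionally, to the citizen
table's size so the three model classes compare at equal n.

## Encounter-rate models

Each bootstrap iteration subsamples, rebalances, splits 80/20 (stratified
by class and source; synthetic SMOTE rows are confined to the training
portion so evaluation always uses real observations), fits a
1000-tree probability random forest per model class, calibrates it, and
evaluates all three classes on the same test set containing both sources.
Two numerical choices deserve comment:

* **Calibration.** The monotone calibration is fit on *out-of-bag*
  training predictions (in-bag random-forest predictions are nearly
  memorized and would make any calibrator overconfident). The default map
  is a sigmoid recalibration on the logit of the raw prediction with the
  slope constrained non-negative — smooth and low-variance, which is the
  entire point of constrained calibration when the map must be estimated
  from training data. Fully nonparametric isotonic regression is
  available (`method = "isotonic"`), but its hard steps push the top of
  the SMOTE-inflated training range to probability ~1 and inflate weak
  models' confidence.
* **Decision threshold.** The binary metrics (kappa, MCC, sensitivity,
  specificity) use a fixed 0.5 threshold on the calibrated scale by
  default. An MCC-maximizing threshold is available (`threshold = NULL`),
  but when a model class has little signal the MCC surface is flat and
  the maximizer lands arbitrarily, usually liberally — the resulting
  sensitivity/specificity numbers then reflect threshold noise, not model
  quality.

Evaluation reports Cohen's kappa, MCC, MSE, sensitivity, specificity and
the step-integrated precision–recall AUC; all formulas are tested against
an independent confusion-matrix oracle. Predictor importance is the Gini
impurity decrease (computationally cheap; diluted under collinearity —
permutation importance would be the robust alternative at higher cost),
and importance contrasts across spatial scales, habitat-vs-effort
covariates and forest-characteristic indicators are estimated by linear
mixed models with species as a random intercept (fixed-effects fallback,
flagged, below 2 species).

## Occupancy models

Detection histories use 90-day closure periods. Citizen records group by
(location snapped to a grid, observer, period), keeping groups of 2–10
visits and sampling 10 when more; the snapping distance is a parameter
(`site_grouping_m`, default 1100 m — the metric analog of rounding
coordinates to two decimal degrees; the desk-scale analyses use 150 m
because the synthetic world is only 1.5 km wide). Acoustic histories
collapse each block of three consecutive recording days to one visit
(outcome: any detection; effort: recorded hours; hour covariate: first
detection hour, else the block's first recorded hour).

The sampler is Metropolis-within-Gibbs with explicit latent-state
augmentation: z is drawn from its closed-form conditional, and the
occupancy and per-source detection coefficient blocks by adaptive
random-walk Metropolis (scale tuned toward ~30% acceptance during
burn-in). Priors are N(0, 2.72) on every coefficient; predictors are
mean-centered and SD-scaled internally; "thinning rate 0.25" is read as
keeping every 4th post-burn-in draw. Defaults are desk-scale (3 chains x
4000 iterations, 1000 burn-in); the field-scale setting (3 x 28000,
burn-in 3000) is one argument away. Convergence is rank-normalized
split-chain R-hat < 1.1 on every parameter (zero-variance parameters
report 1.0), and the marginal likelihood underlying the sampler and WAIC
is tested against brute-force enumeration over all latent-state
configurations. The integrated fit shares one occupancy coefficient
vector across sources, with separate detection vectors; exactly
co-located sites (same site key) share a latent state. WAIC is computed
from stored per-site likelihood draws as −2(lppd − p_WAIC).

Predictor selection is staged: drop zero-variance predictors (the
published description's "non-zero variances" is an evident typo); cluster
predictors with |r| ≥ 0.7 (complete linkage on 1 − |r|; the published
"|r| < 0.7" is read the same way) keeping the member with the highest
encounter-model importance; univariate screening with linear + quadratic
terms, informative if any 95% credible interval excludes zero; then
backwards stepwise elimination by WAIC, with quadratic and linear terms
entering and leaving together (hierarchy principle). Evaluation sites
whose cumulative detectability 1 − prod(1 − p_it), computed from the
relevant source's fitted detection submodel, does not exceed 0.9 are
removed before bootstrapped evaluation (100 subsamples, each keeping all
acoustic sites plus an equal number of citizen sites at the citizen
presence/absence ratio).

## The synthetic study system

All tests run against a generator whose pieces mirror the statistical
structure the analysis assumes: occupancy logit-linear in HAND (and
optionally canopy); hour-scale acoustic sampling in which occupied sites
emit cues at a configurable rate and all sites emit false detections,
with logit-scale confidence scores drawn from label-conditional Gaussians
(equal class frequencies then give a logistic P(true | logit score) with
slope (mu_T − mu_F)/sd²), optionally drifting with elevation; and citizen
checklists whose locations decay exponentially in HAND with effort-
dependent logit-linear detection. All randomness flows from one integer
seed through a stage-keyed hierarchical scheme, so identical
configurations are byte-identical.

Two features model documented citizen-data pathologies rather than ideal
surveys: a configurable fraction of checklists snap their coordinates to
one of a few shared riverside "hotspot" locations while the species
outcome comes from a cell the observer actually roamed to within a trail
radius (`p_hotspot`, `hotspot_roam_m`) — so hotspot presences carry
lodge covariates that do not represent where the bird was found — and
configurable fractions of incomplete checklists and "X" entries exercise
the filters. The generator does not attempt audio waveforms, real
classifier behavior, phenology, or observer skill heterogeneity; passing
tests therefore demonstrate the pipeline's statistical correctness and
its behavior under the assumed biases, not performance on any real
dataset.

The directional experiments use a terra firme species on a steep HAND
response (logit psi = −6 + 6·HAND/10), strong river bias
(`checklist_bias` 5, 75% hotspot checklists roaming 450 m), sparse
acoustic detections (vocal rate 0.12 per occupied site-hour, matching
field detection rates of a few percent of recorded hours), 25 recorder
sites x 18 days x 5 h, and 900 checklists. Problem sizes elsewhere are
chosen so the full suite runs on a single desktop core: parameter
recovery at 400 sites x 4 visits x 20 replicates; selection studies at
200 sites; desk-scale MCMC settings throughout.

## Known limitations

* The pooling benefit is scale-dependent. At desk scale the integrated
  occupancy models' evaluation PR-AUC generally improves on citizen-only
  models, but the encounter-side sensitivity comparison is dominated by
  threshold placement and test-set composition: a citizen model with
  little signal can score high sensitivity simply by predicting presence
  broadly (at the cost of specificity), and hour-scale acoustic labels
  are so sparse that the pooled model's honest low probabilities are
  penalized. The acceptance suite runs this comparison at the frozen
  study conditions and reports whatever it measures; the corresponding
  field-scale result should not be expected to reproduce in miniature.
* HAND is Euclidean-nearest-drainage, not flow-path; buffers are
  cell-center unions, so very small radii relative to the cell size can
  hold few cells.
* The sampler is a general-purpose random-walk scheme; it is exact but
  less efficient per iteration than Pólya-Gamma augmentation, which the
  architecture leaves room for behind the same interface.
* Evaluation-time standardization of covariates uses the evaluation
  set's own statistics (the same convention as fitting); with very small
  evaluation sets this adds variance.
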