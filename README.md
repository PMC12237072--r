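# birdpool

Integrated species-distribution models for tropical rainforest birds,
pooling structured acoustic-survey detections with semi-structured
citizen-science checklists.

Citizen checklists in the lowland Amazon concentrate along rivers and at
ecolodges — the low end of the height-above-nearest-drainage (HAND)
gradient separating floodplain forest from terra firme — while autonomous
recorders sample the gradient evenly but only over a trail network.
`birdpool` implements the full pooling workflow that combines the two:

* **Score calibration** of classifier detections: an elevation-stratified
  annotation sample; candidate models (null, logistic in logit score,
  logistic GAM with an elevation smooth) compared by AICc; and the most
  permissive probability threshold keeping the false-positive rate below
  5%. Accepted detections collapse to at most one per species per hour
  and are zero-filled against the recording log.
* **Pooling**: checklist effort filters (complete, < 5 h, < 1 km, < 5
  observers, "X" recoding), 600 m x weekly spatiotemporal subsampling by
  presence class, acoustic hours recast as stationary 1-h
  pseudo-checklists, SMOTE rebalancing to ~25% presences, and
  sample-size equalization across model classes.
* **Covariates**: HAND from a DEM and drainage mask, land-cover merging,
  and multi-scale circular-buffer summaries (mean/SD, percent cover,
  edge density) tested against brute-force oracles.
* **Encounter-rate models**: bootstrapped calibrated probability random
  forests for citizen-only, acoustic-only and pooled data, evaluated on
  shared mixed-source test sets (kappa, MCC, MSE, sensitivity,
  specificity, PR-AUC) with Gini importances and mixed-effects
  importance contrasts.
* **Occupancy models**: detection histories in 90-day closure periods
  (2–10 citizen repeat visits; 3-day acoustic blocks), single-source and
  integrated fits by Metropolis-within-Gibbs MCMC with N(0, 2.72)
  priors, rank-normalized split-chain R-hat, WAIC, staged predictor
  selection, cumulative-detectability filtering (1 − prod(1 − p_it) >
  0.9) and bootstrapped evaluation.
* **Synthetic data**: a generator for landscapes, occupancy states,
  acoustic detections with label-conditional confidence scores, and
  river-biased checklists (including lodge "hotspot" coordinate
  mislocation), so the whole pipeline is testable without field data.

The model core is the standard single-season occupancy likelihood with
the latent state marginalized,

    L_i = psi_i * prod_t p_it^y_it (1 - p_it)^(1 - y_it)
          + (1 - psi_i) * 1[sum_t y_it = 0],

with logit-linear psi (shared across data sources in the integrated fit)
and logit-linear per-source detection p.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on the
synthetic study system (a terra firme species with strong river bias in
the citizen data):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_calibrate.R
Rscript analysis/03_pool.R
Rscript analysis/04_encounter.R
Rscript analysis/05_occupancy.R
```

Stage 2 prints, for example:

```
annotation sample: 157 events (95% true)
candidate AICc: null 65.2 | logistic 43.6 | logistic+elev 35.0 -> chose logistic_elev
threshold 0.066 accepts 156 annotated events at fpr 0.045
accepted 221 events -> 217 independent detections -> 9.64% of 2250 recorded hours
```

i.e., the elevation-smooth calibration wins the AICc comparison, the
selected probability threshold keeps the annotated false-positive rate at
4.5% (under the 5% bound), and after hourly collapse 9.64% of recorded
hours contain an independent detection. Stage 5 fits citizen-only,
integrated and null occupancy models, confirms the fitted models beat the
null on WAIC, applies the detectability filter (59 of 87 sites retained)
and reports bootstrapped evaluation metrics per model class; tables land
under `results/`.

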