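# icar — PD-1 ligand functionality scoring and clinical association

PD-L1 immunohistochemistry (the Combined Positive Score, CPS) counts ligand
that is *present*; it cannot say whether that ligand actually *engages*
PD-1. A reporter-cell blocking assay can: PD-1-overexpressing reporter
cells secrete murine IL-2 when their receptor is bound, and the drop in
signal caused by a blocking antibody (pembrolizumab for the receptor,
durvalumab for PD-L1, anti-CD273 for PD-L2) quantifies each interaction's
functional contribution in an FFPE tumor sample.

This package implements the complete computational pipeline around that
assay, for analysts evaluating functional PD-1 ligand biomarkers in
checkpoint-inhibitor cohorts (the motivating setting is head and neck
squamous cell carcinoma):

* **Scoring.** From raw 96-well plate measurements to per-patient PD-1 /
  PD-L1 / PD-L2 functionality scores,

  $$\text{score} = \frac{\bar S_{\text{no AB}} - \bar S_{\text{blocked}}}{\log_2(\text{coverage mm}^2)} \times \frac{\text{PC}_{\text{ref}}}{\text{PC}_{\text{plate}}},$$

  with optional 4PL standard-curve interpolation, blank subtraction, and
  positive-control normalization across plates.
* **CPS.** Combined Positive Score from cell counts, positivity calls and
  the conventional <1% / 1–20% / >20% bands.
* **Cohort analysis.** RECIST responder classification, stratification at
  a score cutoff (default 4, strict inequality), response-rate tables,
  Kaplan–Meier / log-rank survival comparisons, rank-sum /
  chi-squared / Fisher group comparisons, response-duration summaries and
  swimmer tables.
* **Predictive evaluation.** A single-boosting-round tree classifier on
  the three scores, stratified 3-fold cross-validated AUC, repeated over
  100 bootstrap cohorts at every size from 15 to 29.
* **Synthetic data.** A generator for both raw plates and clinical
  cohorts with returned latent truth, so the whole pipeline is testable
  without patient data. Wells invert the score formula exactly at zero
  noise.

## Worked example

The `analysis/` scripts run the full workflow on synthetic study-condition
data (29 patients, 5% well noise, scores carried from raw wells):

```sh
Rscript analysis/01_simulate.R   # plates.csv, cohort.csv, truth.csv
Rscript analysis/02_score.R      # scores.csv + recovery check
Rscript analysis/03_cohort.R     # stratified tables, survival, durations
Rscript analysis/04_predict.R    # cross-validated AUC sampling curve
```

Output of stages 2–4 on the committed seed:

```
scored 29 patients from 238 wells
  pd1   score vs latent: r = 0.996
  pdl1  score vs latent: r = 0.995
  pdl2  score vs latent: r = 0.973

response rates by PD-1 score stratum:
 stratum responders total percent
   pd1>4         10    13      77
  pd1<=4          1    16       6

study-condition cohort:
  mean test AUC across sizes: 0.890 (range 0.855-0.920)
strong-effect preset: min across sizes of mean AUC = 0.913
null preset: mean AUC = 0.531 (per-size range 0.497-0.552)
```

Reading it: the plate-to-score step recovers the latent functionality
scores nearly perfectly at 5% well noise; patients with a PD-1 score above
4 respond at 77% versus 6% below in this realization; and the three scores
predict response with a mean held-out AUC of 0.89 across cohort sizes
15–29, while a null cohort (labels independent of scores) sits at chance.

Equivalent single calls: `generate_cohort()` / `generate_plates()`,
`score_plates()`, `run_pipeline()`.

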