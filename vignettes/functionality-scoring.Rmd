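---
title: "Scoring PD-1 ligand functionality and evaluating its clinical association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring PD-1 ligand functionality and evaluating its clinical association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icar)
```

## The measurement and its model

PD-L1 immunohistochemistry (the Combined Positive Score, CPS) measures how
much ligand is *present* in a tumor; it does not measure whether that ligand
can *engage* PD-1. A reporter-cell blocking assay measures engagement
directly: reporter cells overexpressing PD-1 secrete murine IL-2 when their
receptor is bound, so co-culturing them with an FFPE tumor sample produces a
signal proportional to functional ligand binding. Adding a blocking antibody
(pembrolizumab against the receptor, durvalumab against PD-L1, anti-CD273
against PD-L2) removes the corresponding interaction, and the *drop* in
signal quantifies that interaction's functional contribution.

For one sample and one blocking condition the package computes

$$\text{score} \;=\; \frac{\Delta\,\text{response}}{\log_2(\text{coverage})}\times \text{PC ratio},
\qquad
\Delta\,\text{response} = \bar S_{\text{no AB}} - \bar S_{\text{blocked}},$$

where coverage is the tissue surface area in mm² occupied by the sample in
its well (more tissue, more signal — the log2 transform reflects the
saturating relation between tissue area and reporter output), and the PC
ratio harmonises plates run on different days: it is a configured reference
positive-control signal divided by the plate's own mean positive-control
signal. Three scores result per patient: PD-1 (receptor block, capturing
both ligands), PD-L1 and PD-L2.

Numerical conventions, chosen where the procedure leaves them open:

* **PC reference.** The cross-experiment reference signal defaults to the
  grand mean of all positive-control wells in the run, making a single run
  self-normalising; a fixed external reference can be supplied.
* **Negative deltas** (blocking *raised* the signal) are retained and
  flagged `negative_delta`, never clamped — clamping would hide blocking
  failures.
* **Replicates** are aggregated by arithmetic means of signal and coverage
  before the formula; SDs are kept for QC.
* **Coverage guard.** Coverage ≤ 1 mm² is a hard error: log2 would be zero
  or negative and flip or explode the score.
* **Blank wells**, when present, are subtracted (per-plate mean) from every
  measured well, positive controls included, before any other step.
* **Standard curve.** When the plate reports optical densities instead of
  interpolated concentrations, a four-parameter logistic is fit to the
  calibrators by least squares (`fit_standard_curve()`); interpolation is
  defined only strictly between the asymptotes.

## Clinical evaluation

Patients are classified by RECIST 1.1 best response: CR/PR are responders,
SD/PD non-responders. Cohorts are stratified at a score cutoff of 4 with a
strict inequality ("above 4" is score > 4; ties go to the low stratum).
Response-rate tables report `round(100 * responders / total)`; an empty
stratum reports an undefined (NA) percentage rather than zero.

Survival uses the standard product-limit estimator and the unweighted
log-rank test (1 df), with events preceding censorings at tied times.
Group comparisons follow a deterministic rule: continuous variables get a
Wilcoxon rank-sum test (exact when both groups have ≤ 10 observations
without ties, normal approximation otherwise); categorical variables get
Pearson's chi-squared test without continuity correction, falling back to
Fisher's exact test when a 2×2 table has an expected cell below 5. The
uncorrected chi-squared is deliberate: on the cohort's mortality table
(responders 6/14 dead vs non-responders 12/15) it reproduces the reported
p = 0.039, which neither the Yates-corrected test (0.094) nor Fisher's
exact test (0.060) does.

Response duration is (response end − response start), with ongoing
responses censored at last follow-up and *included* in stratum means —
excluding them would bias long responses out of the summary.

## The predictive protocol

The three scores feed a gradient-boosted tree classifier deliberately
limited to **one boosting round** (a single depth-3 tree) to avoid
overfitting at n ≈ 29. Evaluation is stratified 3-fold cross-validation;
out-of-fold risk scores are pooled across the three folds and a single
Mann–Whitney AUC is computed on the pooled predictions (stabler than
averaging three AUCs of ~5 test patients each). The whole evaluation is
repeated on 100 cohorts drawn from the source cohort at every size from 15
to 29, by *stratified bootstrap* — sampling with replacement is the only
reading under which a size-29 draw from 29 patients is not the identity.
The per-size summary is the mean (and minimum) test AUC over the 100
repeats, and the headline statistic is the minimum across cohort sizes of
the per-size mean.

Two hyperparameter choices matter at these sample sizes and are not
defaults of the underlying library:

* `min_child_weight = 0`. With logistic loss every sample contributes a
  hessian of ≈ 0.25, so the library default of 1 forbids any split that
  would leave a child with fewer than ~4 samples — on training folds of
  8–12 patients the "tree" silently degenerates to a constant.
* `lambda = 0`. Without L2 shrinkage the leaf values are pure functions of
  class proportions, so duplicating every training row leaves the fitted
  predictions unchanged — a property the test suite asserts.

At a single round with `eta = 1` the learning rate only rescales the risk
score and is irrelevant for ranking.

## What the synthetic generator emulates

No patient-level data accompany the study, so the generator produces both
layers the pipeline consumes, with a returned latent-truth table for
recovery tests.

**Cohort layer.** Latent PD-L1 and PD-L2 functionality scores are
log-normal (meanlog log 2 and log 1.2, sdlog 0.9); the latent PD-1 score is
their sum, since receptor blockade ablates both ligand interactions.
Response is Bernoulli with a logistic link on the PD-1 score; the default
intercept −5.5 and slope 1.3 were fixed by a one-time calibration
simulation (200 cohorts) so that a 29-patient cohort averages a 47%
responder fraction with response rates of roughly 84% above the cutoff-4
stratum and 13% below — the regime the study reports (14/29 responders,
12/13 vs 2/16 by stratum). Overall survival is exponential with mean 32
months for responders and 17 for non-responders (the reported group means),
right-censored uniformly on (0, 60] months; PFS is exponential at 70% of
the OS mean, constrained below OS. CPS positivity agrees with latent PD-L1
functionality > 4 with probability 0.7 — deliberately imperfect, producing
the CPS-negative responders that motivate a functional assay — and one
patient's CPS is missing, as in cohorts with an unevaluable stain. Line of
treatment is multinomial in the 10/17/2 first/second/third-line pattern.

**Plate layer.** Wells are constructed by inverting the score formula: a
shared no-antibody signal is set to a 5-unit blocked baseline plus
`latent × log2(coverage) / pc_ratio`, each blocking condition's wells sit
below it by their latent score's contribution, and per-plate
positive-control wells realize a drawn PC ratio (log-normal spread 0.15).
Coverage is uniform on 2–12 mm², two replicate wells per condition, ten
samples per plate. At zero noise, scoring the wells returns the latent
scores to machine precision *across plates* — the PC normalization cancels
the plate effect by construction. The default well noise is Gaussian with
SD 5% of signal, under which recovered scores correlate with latents at
r ≥ 0.95 over 200 patients. The 5-unit blocked baseline reflects that full
blockade reduces the reporter to near background; a large baseline would
make the PD-L2 delta a small difference of large noisy numbers.

**Presets.** `default` is the study condition. `strong-effect` makes the
scores nearly determine response: a steep logistic (slope 25) *plus* a
rejection-sampled gap of ±0.75 around the cutoff in the latent PD-1 score —
the gap is essential, because patients arbitrarily close to the cutoff are
coin flips under any finite slope, and bootstrap resampling amplifies a
single such patient into many repeats. `null` sets the slope to zero. Under
the strong-effect preset the minimum across sizes of the per-size mean test
AUC lands at 0.89–0.94; under the null preset, checks use a 200-patient
source cohort, because repeated draws from a single 29-patient null cohort
inherit that cohort's chance score–label separation (AUC SD ≈ 0.11) and
say nothing about the protocol itself.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: ELISA optics and plate spatial effects (edge
wells), real score distributions (only boxplot summaries exist to compare
against), correlation between CPS level and survival beyond the
concordance mechanism, non-exponential survival, and cohort selection
effects (the study cohort was deliberately enriched to balance responders).

## Problem sizes

The test suite and the acceptance script run the full protocol at its
stated size — sizes 15–29 × 100 repeats × 3 folds (4,500 single-tree fits,
about 10 s) — and the recovery checks at 29 and 200 patients. Simulation
power checks use 200 replicates against oracle values computed once at
4,000 replicates.

## Known limitations

* The per-well versus per-sample coverage aggregation is ambiguous in the
  source procedure; the package averages coverage over a sample's wells
  before the formula. With equal coverage across a sample's wells (the
  generator's case) the two readings coincide.
* The PC-ratio construction (reference over plate mean) is a declared
  convention; other positive-control schemes would rescale scores by a
  plate-constant factor without changing stratification at a rescaled
  cutoff.
* The cutoff of 4 is taken as given, not re-derived; no optimism
  correction for cutoff selection is attempted.
* `compare_groups` implements a two-test battery (rank-sum /
  chi-squared-with-Fisher-fallback); it does not cover ordered-categorical
  trend tests.
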