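---
title: "NTCP model-based selection for proton therapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NTCP model-based selection for proton therapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcpselect)
```

## The selection problem

Radiotherapy for head-and-neck cancer inevitably irradiates healthy
structures — salivary glands, the oral cavity, the swallowing muscles —
and the late toxicities that follow (dry mouth, dysphagia, tube feeding
dependence) are the dominant quality-of-life burden for survivors.
Protons can spare these organs-at-risk (OARs) more than photons, but
proton slots are scarce and expensive, so the Dutch system allocates
them by *model-based selection*: for each referred patient, predicted
complication probabilities are compared between the best photon plan and
a proton plan, and the patient qualifies when the predicted reduction
exceeds nationally agreed thresholds.

`ntcpselect` implements that decision chain as a tested engine: the
three normal tissue complication probability (NTCP) models, the
threshold flowchart, a validation/updating toolkit for the models
themselves, and a synthetic cohort generator so the whole pipeline can
be exercised without patient data.

## The NTCP models

Each model is a logistic regression on plan and patient features,

$$\mathrm{NTCP} = \frac{1}{1 + e^{-\mathrm{LP}}}, \qquad
\mathrm{LP} = \beta_0 + \sum_k \beta_k D_{\mathrm{mean},k}
            + \sum_l \gamma_l x_l,$$

where $D_{\mathrm{mean},k}$ is the mean physical dose in Gy to OAR $k$
(no EQD2 or fractionation conversion is applied) and $x_l$ are 0/1
clinical indicators. The three shipped endpoints, all assessed 6 months
after radiotherapy:

* **xerostomia** — patient-rated moderate-to-severe dry mouth, CTCAE
  grade 2. Predictors: contralateral parotid mean dose (0.052/Gy) and
  baseline xerostomia category (minor +0.525, moderate-severe +1.482);
  intercept −1.507.
* **dysphagia** — physician-rated grade II–IV swallowing dysfunction,
  CTCAE grade 2. Predictors: oral cavity and superior pharyngeal
  constrictor muscle (PCM) mean doses, both 0.024/Gy, and baseline
  dysphagia grade ≥ 2 (+0.967); intercept −3.303.
* **tube_feeding** — tube feeding dependence, CTCAE grade 3. Predictors:
  superior PCM (0.030/Gy), inferior PCM (0.013/Gy), contralateral
  parotid (0.022/Gy) and cricopharyngeal muscle (0.008/Gy) doses,
  advanced T-stage (T3–T4, +0.680), weight-loss category (+0.317 /
  +1.178) and systemic-treatment category (accelerated RT +0.198,
  chemoradiation +1.101, RT + cetuximab +1.716); intercept −6.849.

Two transcription choices deserve a note. The published tube-feeding
formula prints its parotid and cricopharyngeal multipliers twice
(a typesetting duplication); the engine applies each coefficient once,
consistent with the other dose terms. "Advanced T-stage" is read as
T3 or T4, the standard definition. The equal oral-cavity/superior-PCM
coefficients in the dysphagia model reflect a deliberate merged-variable
remedy for their collinearity; `refit_logistic(..., merge = )` exposes
the same option for re-derivations.

Coefficients live in a versioned JSON file
(`system.file("extdata", "models.json", package = "ntcpselect")`), not
in code, so revised coefficient sets load without a code change; a
transcription guard at load asserts every default dose coefficient is
positive and every clinical coefficient nonnegative. The CLI's
`--version` prints the file's MD5 so a clinical run is auditable
against the exact coefficient set used.

## The selection flowchart

1. **Eligibility gate** — pharynx/larynx/oral-cavity primary, no distant
   metastases, curative intent. Fails closed: no NTCP is computed.
2. **Pre-screen** — for each endpoint, the maximum achievable benefit
   $\Delta\mathrm{NTCP}_{\max} = 100\,[\mathrm{NTCP}(\text{photon
   doses}) - \mathrm{NTCP}(\text{all model doses} = 0)]$ percentage
   points, the value a proton plan could reach if it eliminated every
   dose term while clinical factors stay fixed. A plan comparison is
   only indicated when the thresholds below are reachable by these
   bounds (the summed rule is mirrored at this stage, since it too could
   potentially be met).
3. **Plan comparison** — $\Delta\mathrm{NTCP} = 100\,(\mathrm{NTCP}_{\rm
   photon} - \mathrm{NTCP}_{\rm proton})$ per endpoint.
4. **Qualification** — a patient qualifies when any single endpoint
   meets its grade's threshold (grade 2: ≥ 10 pp, grade 3: ≥ 5 pp,
   grade 4: ≥ 2 pp) or any two endpoints *of the same grade* sum to the
   summed threshold (≥ 15 / 7.5 / 3 pp). No summation across grades.

Numerical choices: comparisons are inclusive (≥) and made at full
floating precision — reports round percentages to one decimal, but
decisions never round first. Summed pairs use signed values, so an
endpoint where protons are *worse* (negative delta) reduces the pair
sum; this is the conservative reading of a case the protocol text does
not address. With the three default endpoints the grade-2 summed rule
has exactly one pair (xerostomia + dysphagia) and grade 3 none, but the
engine implements the generic any-same-grade-pair rule, and the policy
table carries grade-4 thresholds even though no shipped model uses
them, keeping the national table complete for future model additions.
Because all dose coefficients are positive and the logistic is strictly
increasing, $\Delta\mathrm{NTCP} \le \Delta\mathrm{NTCP}_{\max}$ for any
proton plan with nonnegative doses; the test suite checks this
dominance, and the implication chain *qualifies ⇒ comparison indicated
⇒ gate passed*, on randomized patient/plan pairs.

## Validation and model updating

External validation of a coefficient set on a new cohort reports:

* **AUC** — the probability that a random event outscores a random
  non-event, ties counted ½, computed by the Wilcoxon rank identity and
  tested against brute-force pair enumeration (and an independent ROC
  implementation).
* **Calibration** — slope = coefficient of the model's linear predictor
  (LP) in a logistic refit of outcome on LP; calibration-in-the-large
  intercept = intercept of a refit with LP as fixed offset. The sign
  convention is observed minus predicted log-odds: outcomes generated
  from LP + 0.5 yield an intercept near +0.5.

Validation is complete-case: rows missing any required predictor are
dropped and counted, and no imputation is attempted. The TRIPOD-style
stage-of-evaluation label on a report is user-declared, not computed.

**Closed-testing update.** When a model drifts on new data, the update
should be as simple as the data demand: keep the original, shift its
intercept, recalibrate (intercept + common slope on LP), or revise (full
refit). `closed_testing_update()` uses a step-down likelihood-ratio
scheme: first revision vs. original (if not rejected, keep the
original — this gate alone gives asymptotic type-I control at level
$\alpha$, since any update requires its rejection); given rejection,
revision vs. intercept-update; then revision vs. recalibration; the
selected level is the simplest one the full revision does not
significantly improve upon. Likelihoods are maximised with `glm`
(IRLS, relative tolerance 1e-10, at most 100 iterations); a refitted
|coefficient| above 15 flags probable separation; an aliased design is
an error. Degenerate edges behave as expected: $\alpha = 1$ always
revises, $\alpha \to 0$ always keeps the original, and selection is
monotone in $\alpha$. The traversal is a design choice — the protocol
literature describes the closed-testing idea without fixing every step —
and the sequence above was chosen because it is the standard
construction that both controls the family-wise error and can select
every level of the hierarchy.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the protocol
assumes, not any real referral population:

* photon OAR mean doses from a correlated multivariate normal, truncated
  to [0, 80] Gy; the oral-cavity/superior-PCM correlation is set high
  (0.85) because the two structures share a dose bath, others moderate
  (0.45–0.60);
* clinical factors drawn independently from configurable prevalences;
* proton doses as photon doses times a per-patient, per-OAR reduction
  factor (default mean 0.6, SD 0.15, truncated to [0, 1]), emulating
  consistent but variable proton sparing;
* outcomes Bernoulli from the true models' photon-plan NTCPs.

Default dose means and prevalences were fixed once so the latent event
fractions (≈ 0.55 / 0.26 / 0.07 for the three endpoints at n = 20,000)
are of the same order as the development-and-validation cohorts the
models came from; they are fixtures, not claims about case-mix. A single
seed drives all draws through fixed per-table substreams, so the same
`(config, seed)` always reproduces the same cohort and individual tables
are stable under partial regeneration.

What passing tests on this generator do show: coefficient recovery
(refitting each shipped model on 50,000 self-generated patients returns
every coefficient within 3 standard errors), closed-testing operating
characteristics (the null keeps the original model in ≈ 95% of 2,000-
patient replicates at $\alpha = 0.05$; a one-unit intercept shift is
essentially always detected), agreement of outcome-based AUC with the
model-implied concordance of the latent linear predictor, and the
monotonicity of the qualification rate in the proton reduction factor.
What they cannot show: performance on real dose distributions (which are
not multivariate normal, vary by subsite, and couple to the clinical
factors), on postoperative patients, or the published cohort-specific
discrimination values — those require the original patient data.

## Problem sizes and runtime

The test suite uses 1,000-iteration oracle comparisons per operation,
10,000 randomized pairs/profiles for the flowchart properties, one
50,000-patient cohort for recovery, and 500 + 200 closed-testing
replicates of 2,000 patients; the full suite runs in about three
minutes on one core, and `scripts/acceptance.R` in about one.

## Known limitations

* The engine consumes finished plan metrics; it does not extract DVH
  parameters from dose grids or steer plan optimisation.
* Only the three shipped endpoints are modelled; the policy supports
  grade-4 thresholds but no grade-4 model is provided.
* Coefficients were derived from photon-treated cohorts; applying them
  to proton dose distributions inherits that extrapolation.
* The closed test relies on asymptotic $\chi^2$ null distributions;
  with very few events per predictor its per-step error control
  degrades, and the separation flag should be heeded.
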