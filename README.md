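# ntcpselect

Model-based selection of head-and-neck cancer patients for proton
therapy, as operated nationally in the Netherlands: normal tissue
complication probability (NTCP) models predict each patient's risk of
late radiation toxicity under the best photon plan and under a proton
plan, and the patient qualifies for protons when the predicted risk
reduction (ΔNTCP) exceeds agreed thresholds. The package is for
radiotherapy physicists, clinical epidemiologists and methodologists
who need the decision chain as reproducible, testable code: the three
national logistic NTCP models, the threshold flowchart, an external
validation / closed-testing model-updating toolkit, and a synthetic
cohort generator.

## The models and the decision rule

Each endpoint is a logistic model

    NTCP = 1 / (1 + exp(-LP)),
    LP = β0 + Σk βk · D_mean,k + Σl γl · x_l

with `D_mean,k` the mean dose (Gy) to organ-at-risk *k* and `x_l`
binary clinical indicators. Shipped endpoints (6 months after
radiotherapy): moderate-to-severe xerostomia (CTCAE grade 2), grade
II–IV dysphagia (grade 2) and tube feeding dependence (grade 3), with
their published coefficient sets in a versioned JSON file.

For an eligible patient (pharyngeal/laryngeal/oral-cavity primary, M0,
curative intent), ΔNTCP_max = 100·[NTCP(photon doses) − NTCP(all model
doses = 0)] decides whether a plan comparison is worthwhile; with a
proton plan, ΔNTCP = 100·(NTCP_photon − NTCP_proton) per endpoint. The
patient qualifies when one endpoint reaches its grade's threshold
(grade 2 ≥ 10 pp, grade 3 ≥ 5 pp, grade 4 ≥ 2 pp) or two same-grade
endpoints sum to ≥ 15 / 7.5 / 3 pp. Comparisons are inclusive and
unrounded.

## Worked example

```r
library(ntcpselect)

decision <- select_patient(
  tumor_site = "pharynx", distant_metastases = FALSE, curative_intent = TRUE,
  photon_doses = oar_doses(parotid_contralateral_mean = 35, oral_cavity_mean = 45,
                           pcm_superior_mean = 55, pcm_inferior_mean = 30,
                           cricopharyngeal_mean = 25),
  proton_doses = oar_doses(20, 25, 35, 20, 15),
  clinical = clinical_factors(treatment = "chemoradiation"))
decision
#> <selection_decision>
#>   gate passed:               TRUE
#>   plan comparison indicated: TRUE
#>   qualifies for protons:     TRUE
#>   xerostomia     NTCP_photon  57.8%  delta  19.2 pp  delta_max  39.6 pp
#>   dysphagia      NTCP_photon  28.8%  delta  15.4 pp  delta_max  25.3 pp
#>   tube_feeding   NTCP_photon   6.1%  delta   4.0 pp  delta_max   5.8 pp
#>   triggered: single[grade2:xerostomia 19.2>=10];single[grade2:dysphagia 15.4>=10];summed[grade2:xerostomia+dysphagia 34.6>=15]
```

The photon plan predicts a 57.8% xerostomia risk; the proton plan cuts
it by 19.2 percentage points, past the 10-pp grade-2 threshold (the
dysphagia single rule and the grade-2 summed rule fire too), so the
patient qualifies. `screen_cohort()` runs the same flowchart over CSV
cohort tables, `validate_model()` / `closed_testing_update()` check and
update a coefficient set on a cohort with observed outcomes, and
`generate_cohort()` simulates referral cohorts with correlated OAR
doses. A command-line wrapper with subcommands `ntcp`, `select`,
`validate`, `update` and `simulate` is installed under
`system.file("scripts", "ntcpselect", package = "ntcpselect")`.

See the vignette (`vignettes/model-based-selection.Rmd`) for the model
and design details.

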