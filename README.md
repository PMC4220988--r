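# vpaggt

Population pharmacokinetic–pharmacodynamic (PK–PD) modelling of valproic
acid (VPA) exposure and serum γ-glutamyltransferase (γ-GT) elevation in
patients with epilepsy.

## What it does, and for whom

Pharmacometricians and pharmacogenetics researchers who want a fully
scriptable, testable R implementation of the classic two-stage
exposure–response analysis:

1. **Population PK.** Sparse steady-state VPA concentrations are fitted
   with a one-compartment oral model with absorption lag, parameterised by
   CL/F, Vd/F, Ka and ALAG, with exponential inter-individual variability
   and proportional residual error, by FOCE with interaction. The covariate
   model is CL/F ∝ (Dose/1000)^θ · f_female^[female] · f_CBZ^[CBZ] ·
   f_CLB^[CLB] · f_PB^[PB] · f_PHT^[PHT] · e^η, with a dose power on Vd/F.
2. **Exposure–response.** Each γ-GT measurement is binarised against an
   age/sex-stratified upper limit of normal, and the probability of
   elevation is modelled as

   logit(Pr) = BASE + θ_ID·[disability] + θ_SOD2·[Val/Val] + SLOPE·AUC + η,

   with AUC = daily dose / CL/F (g·h/L) fixed from the PK stage and one
   normal random effect per subject, fitted by the Laplace approximation.

Around that core: forward-inclusion/backward-elimination covariate
selection on objective-function changes (ΔOFV thresholds 3.84 / 5.99),
stratified nonparametric bootstrap, visual predictive checks, conditional
weighted residual diagnostics, a Monte-Carlo risk table of γ-GT elevation
percentages and odds ratios by dose × *SOD2* genotype × intellectual
disability, and a synthetic-cohort generator reproducing the published
cohort structure (237 PK subjects / ~827 concentrations; 169 PK–PD
subjects / ~472 binary observations) so the whole pipeline runs without
patient data.

## Worked example

```r
library(vpaggt)

# a synthetic study at the published generating values
st <- generate_study(generator_config(n_subjects = 120), seed = 1)
st$cohort
#> VPA cohort: 120 subjects, 409 concentration records, 334 gamma-GT records

# stage 1: population PK by FOCE-with-interaction
pk <- fit_pk_model(st$cohort)
round(coef(pk)[c("cl", "vd", "dose_cl", "pht")], 3)
#>      cl      vd dose_cl     pht
#>   0.564  16.787   0.583   1.554

# stage 2: individual AUCs frozen, then the gamma-GT logit model by Laplace
auc <- individual_auc(pk, st$cohort)      # g·h/L per subject
pd <- fit_pd_model(st$cohort, auc)
round(coef(pd), 2)
#>         base        slope coef_id_flag  coef_valval       omega2
#>        -7.71         2.43         3.18         1.54        13.19

# risk table at the published final estimates (bootstrap-median variance)
rt <- simulate_risk(dose_grid = 800, n = 1000, n_replicates = 50, seed = 2)
rt[, c("daily_dose", "disability", "sod2_group", "pct_elevated", "odds_ratio")]
#>   daily_dose disability       sod2_group pct_elevated odds_ratio
#> 1        800          - ValAla-or-AlaAla         6.59       1.00
#> 2        800          -           ValVal        21.47       3.90
#> 3        800          + ValAla-or-AlaAla        43.73      11.09
#> 4        800          +           ValVal        72.49      37.63
```

The PK coefficients are the typical apparent clearance (L/h) and volume
(L), the power of normalised daily dose on CL/F, and the multiplicative
phenytoin effect; at n = 120 subjects single-replicate estimates scatter
around the generating values (0.559, 21.4, 0.596, 1.43) with the spread the
recovery tests quantify. The PD coefficients are in logit units; the risk
table rows give the predicted percentage of subjects with γ-GT elevation in
each dose × genotype × disability cell and the marginal odds ratio against
the Ala-carrier/no-disability reference — the marginal odds ratios are
attenuated relative to the conditional e^coef, as discussed in the methods
vignette.

A full pipeline run (generate → QC/filter → fit PK → freeze AUCs → fit PD →
bootstrap → VPC → risk table), with every artifact and seed written to a
manifest:

```r
run_pipeline("runs/demo", seed = 1, config = generator_config(n_subjects = 169))
```

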