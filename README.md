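# mnbmd

Covariate benchmark-dose (BMD) modelling and margin-of-exposure (MOE)
analysis for continuous in vivo micronucleus data.

## What it does, and for whom

Quantitative genetic-toxicology risk assessment replaces the classical
positive/negative call of the rodent bone-marrow micronucleus assay with
a dose metric: fit a continuous dose-response model to MN-PCE%
(micronucleated polychromatic erythrocytes, percent), derive a benchmark
dose and its lower confidence bound (BMDL) as the point of departure
(PoD), scale it to a human-equivalent dose (HED), and compare it to
anticipated human exposure as a margin of exposure. `mnbmd` implements
that chain for toxicologists and biostatisticians, following the
covariate approach used by PROAST-style continuous BMD analysis:

* **Models.** Exponential `m(x) = a[c − (c−1)e^(−bx^d)]` and Hill
  `m(x) = a[1 + (c−1)x^d/(b^d + x^d)]`, with lognormal errors
  (log-responses normal around `log m(x)`).
* **Covariate approach.** Shape parameters `c` and `d` are shared across
  subgroups (sexes, studies); background `a`, potency `b` and residual
  variance become subgroup-specific only when a likelihood-ratio test
  accepts them (forward stepwise, 2·ΔLL > χ²₀.₀₅ per added parameter).
* **BMD at a critical effect size.** Default CES 50% (the in vivo
  micronucleus recommendation; 10% is the general default), closed-form
  BMD per family, and profile-likelihood BMDL/BMDU at a two-sided 90%
  level (profile drop χ²₀.₉₀,₁/2 = 1.3528, bisection on log-dose).
* **Combination and PoD.** Per subgroup, lowest BMDL and highest BMDU
  across families; the lowest combined BMDL is the PoD.
* **HED and MOE.** Rat mg/kg ÷ 6.2 → human mg/kg, × Km 37 → mg/m²; MOE =
  PoD(HED)/exposure with green (≥10), yellow (3–10) and red (<3) zones.
* **Synthetic data.** Generators emulating a 14-day two-sex
  low-through-high-response rat study (doses 0/1.14/11.36/57 mg/kg/day)
  and a 2-day medium-response-only study (0/14.3/28.5/57/114), plus
  parameter-recovery, CI-coverage and design-comparison harnesses. No
  animal-level data are bundled; files under `inst/extdata/` are
  synthetic (see filenames).

## Worked example

```r
library(mnbmd)

ds <- read_mn_dataset(system.file("extdata", "garriott_s1_synthetic.csv",
                                  package = "mnbmd"))
report <- run_pipeline(ds, mn_config(), exposure_range = c(35, 100))
report
```

```
<mn_report> covariate BMD analysis, CES 50%, 90% CI

Per-family estimates:
      family covariate_level    bmd  bmdl   bmdu ci_ratio
 exponential          female 10.502 8.307 15.348    1.847
 exponential            male  3.809 2.924  5.014    1.715
        hill          female 10.502 8.321 15.325    1.842
        hill            male  3.809 2.928  5.024    1.716

Combined (lowest BMDL / highest BMDU per level):
 covariate_level pod_bmdl pod_bmdu contributing_families ces ci_level
          female    8.307   15.348      exponential+hill 0.5      0.9
            male    2.924    5.024      exponential+hill 0.5      0.9

PoD: BMDL50 = 2.924 mg/kg (male)
<mn_hed> 2.92422 mg/kg (rat) / 6.2 = 0.4716 mg/kg HED; x Km 37 = 17.45 mg/m2
  at reporting precision: 0.47 mg/kg -> 17.4 mg/m2
<mn_moe_profile> worst-case zone: RED
  exposure       moe zone
1       35 0.4985996  red
2      100 0.1745099  red
```

Reading the output: the male and female curves share their shape; the
likelihood-ratio step kept background and potency sex-specific. The male
BMDL50 of 2.9 mg/kg is the PoD (the lower of the two sexes); divided by
the rat body-surface-area factor 6.2 and multiplied by the human Km 37
it corresponds to about 17 mg/m². Against a 35–100 mg/m² exposure range
the margins are below 1 — far under the 3- to 10-fold target range, so
both endpoints sit in the red zone.

`write_report_json()` / `write_report_md()` serialize the report;
`plot_dose_response()` and `plot_bmd_intervals()` draw the fits and the
BMDL–BMDU intervals. A thin command-line wrapper with `simulate`,
`report`, `hed` and `moe` subcommands is installed at
`inst/cli/mnbmd.R`.

## Vignette

`vignettes/covariate-bmd-methods.Rmd` documents the model and its
assumptions, the covariate likelihood-ratio procedure, the profile-CI
construction, every numerical choice (bounds, starts, tolerances,
degenerate cases), what the synthetic designs emulate and what they
deliberately do not.
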