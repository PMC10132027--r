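# ecrisk

Ten-year absolute risk prediction models for esophageal cancer (EC) in
Chinese adults, implemented as a complete, testable R pipeline: model
development, competing-risk absolute risk, recalibration, and the full
internal/external validation battery, exercised end to end on a synthetic
cohort generator that reproduces the structure of the development and
external validation cohorts (which are not publicly deposited).

The intended users are biostatisticians and epidemiologists who want to
study, extend or stress-test this class of risk models — nested predictor
tiers designed around what Chinese electronic health records actually
contain — without access to the original cohort data.

## The model

Both cause-specific hazards (EC incidence and all-cause mortality) are
flexible parametric models on the log cumulative hazard scale with age as
the timescale and delayed entry:

```
log H(t | x) = γ0 + γ · B(log t) + x'β
```

where `B` is a restricted cubic spline of log age with boundary knots at 30
and 90 years and internal knots at 60 and 70. Four nested EC tiers are
fitted (age-only; simple: + sex, regional risk level, education, family
history of cancer; intermediate: + smoking, alcohol, BMI; full: + physical
activity, tea temperature, fresh fruit). The 10-year absolute risk at age
`a` combines the two fitted hazards:

```
AR(a) = ∫ₐ^(a+10) h_EC(t|x) · exp(−[H_EC(t|x) − H_EC(a|x)]
                                  −[H_D(t|x_D) − H_D(a|x_D)]) dt
```

Validation follows the study design: AUC on horizon-settled participants
(DeLong intervals), Kaplan–Meier observed risk by decile of predicted risk,
continuous NRI and IDI between adjacent tiers, cutoff performance,
subgroups, 2/3–1/3 split plus 500-replicate bootstrap optimism internally,
and two-parameter recalibration (scale `k` on the cumulative-hazard scale,
slope `b` on the cloglog scale) externally. The methods vignette
(`vignettes/ec-absolute-risk-methods.Rmd`) documents the model, the
generator's study conditions, and every numerical choice.

## Worked example

```r
library(ecrisk)

## study conditions: development-profile cohort, published stratum
## incidences (132.2 / 20.2 per 100,000 person-years) as calibration targets
cfg    <- generator_config("ckb", tier = "simple", n = 60000, seed = 42)
cfg    <- calibrate_baseline(cfg, mode = "stratum", n_cal = 60000)
cohort <- generate_cohort(cfg)

ex <- apply_exclusions(cohort)
incidence_rate(ex$cohort)
#> 49.7   # per 100,000 person-years; median follow-up 11.1 years

## cause-specific fits: simple tier + all-cause mortality
fit_ec <- fit_fpm(ex$cohort, fpm_spec("simple"))
fit_d  <- fit_fpm(ex$cohort, fpm_spec("mortality"))
fit_ec
#> Flexible parametric model [simple tier, event: ec]
#>   n = 59684, events = 315, logLik = -2446.561, converged: TRUE
#>   hazard ratios:
#>                       term    hr  lower upper
#>                 sex.female 0.285 0.2237 0.363
#>           region_risk.high 6.920 5.4654 8.763
#>   education.middle_or_high 0.588 0.4457 0.775
#>          education.college 0.233 0.0724 0.747
#>  family_history_cancer.yes 1.444 1.1175 1.866
```

The fitted hazard ratios bracket the generator truth (the published simple
tier: female 0.31, high-risk area 6.31, family history 1.71) within this
cohort's Monte-Carlo error — 315 cases at n = 60,000; the acceptance script
runs the same recovery at 500,000 rows per replicate, where the estimates
tighten onto the published values.

```r
## ten-year absolute risk for a 55-year-old man in a high-risk area
## (primary education, no family history), competing mortality accounted
x   <- setNames(numeric(length(fit_ec$beta)), names(fit_ec$beta))
x["region_risk.high"] <- 1
x_d <- setNames(numeric(length(fit_d$beta)), names(fit_d$beta))
x_d["region_risk.high"] <- 1
absolute_risk(fit_ec, fit_d, x, x_d, age_a = 55)
#> 0.0288   # 2.88% ten-year absolute risk

## internal validation: 2/3 train, 1/3 holdout
rep <- internal_validation(ex$cohort,
         pipeline_config(tiers = c("age_only", "simple"),
                         bootstrap = 0, seed = 7))
rep$tiers$simple$auc[c("auc", "lower", "upper")]
#> 0.786 (0.736–0.836)
```

The per-decile calibration table in `rep$tiers$simple$calibration` pairs
mean predicted risk with Kaplan–Meier observed risk (for this run, decile
10: predicted 0.0246 vs observed 0.0191, interval 0.0137–0.0266).
`run_study()` orchestrates the whole workflow — exclusions, four-tier
development, internal and external validation with recalibration, and the
sensitivity variants — into one deterministic, JSON-serialisable report.

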