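# placomp

Compositional analysis of placental cell-type composition and prenatal
fine-particulate (PM2.5) exposure.

The placenta is a mixture of six major cell types — syncytiotrophoblasts,
trophoblasts, stromal, endothelial, Hofbauer cells and nucleated red blood
cells (nRBCs) — and their relative abundance can itself be an outcome of
prenatal exposures. `placomp` is for epidemiologists and epigenomics
analysts who have bulk placental DNA-methylation beta values, a cell-type
reference panel, and per-pregnancy exposure/covariate tables, and who want
to ask: *does trimester-average PM2.5 shift the placental cell-type
composition, and does the answer differ by infant sex?*

## What it computes

1. **Deconvolution** (`estimate_composition`): per-sample proportions `w`
   by constrained projection onto a reference panel `R`,

   ```
   min_w || b − R w ||²   s.t.  w ≥ 0,  Σ w ≤ 1,
   ```

   solved exactly as a quadratic program, then renormalized to the simplex;
   rounded zeros are replaced multiplicatively (`replace_zeros`, default
   δ = 1e-3) so log-ratios are defined.

2. **Compositional regression** (`fit_compositional`,
   `bootstrap_inference`): the six proportions are analysed jointly through
   an isometric log-ratio (ilr) transform, `z = clr(w) V`, regressed on the
   three IQR-standardized trimester exposures plus covariates. Effects are
   reported back on the proportion scale as
   `Δ = ilr⁻¹(η_ref + β_t) − ilr⁻¹(η_ref)` (change in each proportion per
   one IQR; Δ sums to zero), with case-bootstrap percentile CIs and an
   overall per-trimester p-value from a bootstrap-corrected median-F test
   (Wilks' Λ / Rao F).

3. **Beta regression** (`fit_beta_regression`, `wald_summary`): each cell
   type separately, Beta likelihood with logit mean link and constant
   precision, log-odds coefficients per IQR — the secondary,
   per-cell-type view of the same question.

4. **Study orchestration** (`run_analysis`): overall and sex-stratified
   models, complete-case filtering, Table-1-style descriptives, sensitivity
   rerun excluding preeclampsia/eclampsia, CSV outputs and a JSON run log.

5. **Synthetic data** (`generate_cohort`, `generate_reference_panel`,
   `mix_bulk`): a seeded generator emulating a 226-pair cohort's
   statistical structure (sex-specific baseline compositions, exposure
   means/SDs/correlation, covariate frequencies) with effects injected in
   ilr space, so every stage is testable against known truth.

The methods vignette
(`vignettes/placental-composition-methods.Rmd`) documents the model,
the bootstrap correction, all defaults and their rationale, and known
limitations.

## Worked example

Simulate a study-sized cohort in which one IQR of first-trimester PM2.5
shifts the *male* composition from syncytiotrophoblast toward trophoblasts
(females carry no effect), deconvolve the bulk methylation, and fit the
male stratum:

```r
library(placomp)
panel <- generate_reference_panel(seed = 1)
sim <- generate_cohort(226, effect_spec = list("pm25_t1:male" = c(-0.2, 0.12, 0, 0, 0)),
                       seed = 1)
bulk <- mix_bulk(panel, sim$truth)
comp <- replace_zeros(estimate_composition(bulk, panel))
male <- sim$cohort$sex == "male"
bootstrap_inference(comp$values[male, ], sim$cohort[male, ],
                    covariates = c("maternal_age", "gestational_age"),
                    B = 1000, seed = 1)
#> Compositional regression (ilr) fit
#>   samples: 131  predictors: 6  parts: 6
#>   composition-scale effects per one IQR of exposure:
#>    syncytiotrophoblast trophoblasts stromal endothelial hofbauer    nrbc
#> t1             -0.0637       0.0278  0.0100      0.0162   0.0016  0.0081
#> t2              0.0179      -0.0081 -0.0063     -0.0003  -0.0001 -0.0031
#> t3              0.0026      -0.0024  0.0041     -0.0029  -0.0007 -0.0006
#>   overall bootstrap-corrected p-values (B = 1000 ):
#>     t1     t2     t3
#> 0.0000 0.2289 0.4448
```

Reading this: in the male stratum the first trimester shows a clear overall
compositional signal (p ≈ 0), driven by a 0.064 drop in the
syncytiotrophoblast proportion per IQR with compensating increases
elsewhere (each row of effects sums to zero); second and third trimesters —
which carry no injected effect — are null. The per-cell-type beta
regression agrees:

```r
w <- wald_summary(fit_beta_regression(comp$values[male, "trophoblasts"],
       sim$cohort[male, ], covariates = c("maternal_age", "gestational_age")))
w[w$term == "pm25_t1", ]
#>      term estimate     se ci_lower ci_upper    z        p
#> 2 pm25_t1    0.302 0.0488    0.206    0.398 6.19 6.01e-10
```

i.e. trophoblast log-odds rise by 0.30 per IQR of first-trimester PM2.5 in
males.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R                  # cohort, panel, bulk -> results/data/
Rscript analysis/02_deconvolve.R                # composition + descriptives
Rscript analysis/03_compositional_regression.R  # overall/female/male, B = 1000
Rscript analysis/04_beta_regression.R           # per-cell-type log-odds
Rscript analysis/05_sensitivity.R               # excluding preeclampsia/eclampsia
```

`run_analysis(config)` performs the same pipeline programmatically (or from
a YAML config).

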