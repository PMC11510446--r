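# glp1ivivc

Quantitative translation of in vitro GLP-1 receptor potency to clinically
efficacious exposure, for DMPK and quantitative-pharmacology scientists
benchmarking GLP-1 receptor agonists (and new entities with the same
target) against approved drugs.

Cell-based cAMP potency assays report EC50 values that vary by orders of
magnitude with the assay format — cell system (receptor-over-expressing
CHO vs endogenous-density EndoC-betaH1) and albumin supplement (none,
0.1% BSA, 0.1% ovalbumin, 4.4% HSA). This package implements the pipeline
that decides which format translates to the clinic:

1. **Steady-state PK** (`pk_model()`, `simulate_steady_state()`,
   `simulate_exposures()`): one-/two-compartment linear kinetics with
   first-order absorption; steady state by closed-form dose superposition
   (each exponential term scaled by `1/(1 - exp(-lambda*tau))`), with a
   numeric ODE path as cross-check; Cavg, Cmax, Cmin and peak-to-trough
   per drug x regimen, in pM.
2. **Potency normalisation** (`normalize_ec50()`, `fold_nec50()`):
   `nEC50 = EC50,drug / EC50,GLP-1(7-36)NH2` per format, then the potency
   multiple `fold = Cp,free / (nEC50 * funb,assay)` with the
   free-fraction correction the format requires —
   `funb(diluted SA) = DF*funb,p / (1 + (DF-1)*funb,p)`, `DF = 4.4/0.1 = 44`
   for 0.1%-albumin buffers, no in vitro correction for the no-albumin and
   ovalbumin formats, total:total at physiological 4.4% HSA.
3. **Format ranking** (`correlate_formats()`, `rank_assays()`): Spearman
   correlation of potency multiples against treatment effects (HbA1c
   %point and body-weight % change vs placebo), pooling drugs and dose
   levels; inclusion for regression requires |r| > 0.75 on at least one
   endpoint with p < 0.01.
4. **Exposure-response regression** (`fit_effect_model()`,
   `compare_models()`): weighted least squares of linear `a*x`, power
   `a*x^b` and sigmoid `a + (b-a)*x^c/(x^c+d^c)` effect models, weights
   1/(dose levels per drug); selection by AICc among fits whose parameter
   CIs exclude sign changes (the four-parameter sigmoid typically fails
   this precision criterion on power-like data — the over-fitting
   signature).
5. **Inverse prediction** (`predict_bounds()`, `invert_at_response()`):
   delta-method 95% functional bounds on the fitted curve, inverted at
   target responses (default -1.5 %point HbA1c, -5% body weight) to give
   the efficacious potency multiple with its interval; an upper bound the
   lower bound-curve cannot support is reported as not determinable.

`run_pipeline()` chains the stages; `generate_study()` creates a fully
synthetic study (drug panel, regimens, distorted per-format potencies,
power-law treatment effects) with known ground truth so the whole pipeline
is testable without external data. The measured potency table for the five
approved drugs ships as `approved_glp1ra_potency()`. Fitted models support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(glp1ivivc)
study  <- generate_study(generator_config(seed = 42L))
result <- run_pipeline(study)
result
#> In vitro -> in vivo translation result
#>   30 drug x regimen exposures, 900 translation rows
#>   format ranking (by max |r| across endpoints):
#>     CHO 0% SA        cavg  |r| = 0.998  [included]
#>     CHO 0.1% OA      cavg  |r| = 0.976  [included]
#>     CHO 0% SA        cmax  |r| = 0.967  [included]
#>     CHO 0.1% OA      cmax  |r| = 0.952  [included]
#>     CHO 4.4% HSA     cmax  |r| = 0.948  [included]
#>   inverse predictions:
#>     CHO 0% SA, bodyweight_pct at -5: multiple 293 [249, 346]
#>     CHO 0% SA, hba1c_pctpoint at -1.5: multiple 106 [86, 131]
#>     ...
```

The no-albumin format translates best (|r| = 0.998 on Cavg); the formats
with heavy drug-specific distortion (physiological HSA, endogenous
receptor) rank lower and mistranslate the efficacious multiple. Inverting
the selected power fit for the no-albumin format says a ~106-fold multiple
of normalised potency gives a -1.5 %point HbA1c reduction and ~293-fold a
-5% body-weight reduction — against the generator's true values of 115.6
and 280.7, i.e. recovery within the tolerances the test suite enforces.
The selected fit itself:

```r
result$fits[["CHO 0% SA / hba1c_pctpoint"]]$selected
#> power exposure-response fit (n = 30)
#>   a = 0.1367  [0.1028, 0.1706]
#>   b = 0.5135  [0.4827, 0.5444]
#>   weighted RMSE 0.199, AICc -92.41
```

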