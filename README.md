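# refmix

Indirect estimation of clinical **reference intervals** (RIs) from routinely
collected, *mixed* laboratory data — no recruited healthy cohort required —
plus the population analyses that interpretation of such intervals needs:
selective-mortality quantification from census counts and comorbidity
implication networks built from laboratory-only diagnoses.

## The idea

Routine results for the lipid panel (CHOL, TRIG, HDL, LDL, VLDL) together
with two comorbidity markers (A1C, creatinine) are modeled jointly. After
log-transforming the skewed lipid analytes, the seven-dimensional density in
each (sex, age) stratum is a Gaussian mixture

> p(x) = Σₖ wₖ N(x | μₖ, Σₖ)

fitted by variational inference with a Dirichlet-process prior (truncation
K = 7, stick concentration 1e-6, mean precision 200, feature-wise-median
prior mean, diagonally shrunk covariance prior). The dominant component is
the healthy subpopulation; pathological subgroups form separate satellite
modes in 7-D even though they overlap in any single analyte. The RI is the
central 95% of the chosen scenario distribution — for a Gaussian,
μ ± 1.96σ — computed in transformed space and mapped back to native units:

* **overall** — marginal of the principal (healthy) component;
* **diabetic** — mixture conditional at A1C = 9.0%;
* **renal** — mixture conditional at CREA = 2.0 mg/dL;
* **healthy-constrained** — conditional at A1C = 5.7%, CREA = 1.0 mg/dL
  (comorbidity effects excluded without diagnostic codes);

with Schur-complement conditioning μ_A|B = μ_A + Σ_AB Σ_BB⁻¹ (b − μ_B),
Σ_A|B = Σ_AA − Σ_AB Σ_BB⁻¹ Σ_BA, bootstrap errors (100 × 50% patient
subsamples), and continuous percentile reporting of individual results.

Because real clinical datalakes are proprietary, the package ships a
synthetic-cohort generator with known ground truth (healthy component +
diabetic-like and renal-like satellites with age-increasing prevalence,
exact Friedewald LDL/VLDL, Gompertz mortality with elevated hazard for
high-risk patients) against which every stage is validated.

## Worked example

```r
library(refmix)

cfg <- run_config(
  cohort = cohort_config(n_patients = 6000, age_range = c(40, 70), seed = 5),
  hyperparams = fit_hyperparams(n_restarts = 1),
  ages = c(50, 62), window = 4, analytes = c("CHOL", "TRIG"),
  scenarios = c("overall", "diabetic", "healthy"), seed = 5)
res <- run_pipeline(cfg, out_dir = "refmix_demo")
subset(as.data.frame(res$ri), sex == "M" & analyte == "TRIG")
#>    sex age analyte scenario    low  high  mean   n
#> 4    M  50    TRIG  overall  71.00 289.1 143.3 673
#> 5    M  50    TRIG diabetic 110.81 539.0 244.4 673
#> 6    M  50    TRIG  healthy  74.82 285.8 146.0 673
res$mortality$gompertz
#>   sex intercept  slope r_squared n_ages
#> 1   M     -9.88 0.0858     0.998     50
#> 2   F    -10.3  0.0842     0.998     50
```

Reading: the male TRIG reference interval at age 50 is 71–289 mg/dL overall;
conditioning on a diabetic A1C of 9.0% roughly doubles the upper limit
(539 mg/dL), while constraining the comorbidity markers to healthy values
reproduces the overall interval within a few percent — the mixture has
isolated the healthy mode. The Gompertz check on the simulated census
recovers the configured log-hazard slope (0.085) and intercept (−9.81).

A thin CLI over the same functions is installed at
`system.file("cli", "refmix.R", package = "refmix")` with subcommands
`simulate | ri | mortality | network | percentile | all`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the headline quantities of the validation plan: the strict-threshold
boundaries of the laboratory diagnosis rules swept over value grids, the
principal-component weight recovered by the mixture fit on a synthetic
20,000-patient stratum with known healthy fraction, and the
triglyceride-to-VLDL constant of the Friedewald computation. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON output maps each target id to its recomputed value and problem size.

## Layout

* `R/synthetic.R` — cohort/census generator with ground truth
* `R/preprocess.R` — monthly coarse-graining, panel merge, plausibility
  filter, transforms
* `R/bgmm.R` — variational Bayesian Gaussian mixture (Dirichlet-process
  sticks), principal-component extraction, stratified weight profiles
* `R/gaussian.R` — exact marginals/conditionals, intervals, percentiles
* `R/ri.R` — RI curves per scenario, bootstrap errors, Friedewald
* `R/mortality.R` — annual rates, survival function, Gompertz check
* `R/network.R` — Table of laboratory diagnosis rules, implication matrix,
  HITS scores, edge pruning
* `R/pipeline.R` — end-to-end orchestration with manifest and seed fan-out
* `vignettes/indirect-reference-intervals.Rmd` — model, assumptions,
  synthetic world, numerical choices, limitations
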