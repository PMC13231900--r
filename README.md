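# neocef

Population pharmacokinetics and dose optimization of ceftazidime in
neonates, built for sparse whole-blood (dried-blood-spot) data.

Ceftazidime kills gram-negative pathogens in a time-dependent way: what
matters clinically is **%fT>MIC**, the percentage of the dosing
interval during which the unbound plasma concentration stays above the
pathogen's MIC. Neonatal clearance is dominated by renal maturation, so
a dose that is right at term can be wrong a few weeks earlier. `neocef`
implements the full analysis chain used to derive maturation-aware
dosing recommendations from a sparse neonatal study (72 infants, 1-4
samples each):

* **Model.** One-compartment IV-infusion kinetics with fixed allometry
  and a sigmoidal maturation of clearance:

  ```
  CL = TVCL * (WT/70)^0.75 * PMA^H / (PMA^H + TM50^H) * exp(eta_CL)
  V  = TVV  * (WT/70)                                 * exp(eta_V)
  ```

  with TM50 = 47.7 weeks, H = 3.4 (fixed), log-normal interindividual
  variability on CL and V, and an exponential residual (additive on the
  log scale).

* **Estimation.** FOCE-type conditional estimation: per-subject
  conditional modes by damped Gauss-Newton (compiled core, analytic
  derivatives, multistart for the multimodal sparse-data case) and a
  Laplace expansion of the marginal likelihood, cross-checked in the
  test suite against adaptive Gauss-Hermite quadrature, grid-search
  empirical-Bayes oracles, and ODE integration of the kinetics.

* **Diagnostics.** Goodness-of-fit tables (PRED/IPRED/CWRES/IWRES),
  visual predictive checks, nonparametric subject-level bootstrap,
  stepwise covariate screening with likelihood-ratio thresholds.

* **Dosing simulation.** Steady-state %fT>MIC evaluated *analytically*
  (every segment of the superposed profile is `P + Q exp(-k s)`, so MIC
  crossings are exact), blood-to-unbound-plasma conversion
  (fu = 0.9, blood-to-plasma ratio 0.72), and PTA tables over the
  12-regimen grid (25/50/75/100 mg/kg x q6/q8/q12h, 30-min infusions),
  MIC 0.25-32 mg/L, PMA subgroups 32-35 / 35-38 / 38-42 weeks.

* **Synthetic studies.** A generator that reproduces the sparse design
  (sampling windows 0-0.5 / 2-3 / 4-6 h post dose, median 2 samples per
  infant, published covariate distributions) with known ground truth,
  so every stage is testable without patient data.

## Worked example

```r
library(neocef)

# a synthetic study at the sparse neonatal design, with known truth
gen <- generate_study(seed = 7)
ds  <- handle_blq(impute_missing_scr(gen$dataset))

fit <- fit_population(ds, ceftazidime_neonatal_params())
fit
#> <neocef_fit> 72 subjects, 139 observations
#>   OFV 118.320   converged: TRUE
#> <pop_params>
#>   TVCL 18.36 L/h/70kg   TVV 66.77 L/70kg
#>   omega2(CL) 0.07724 (CV 28.3%)   omega2(V) 0.163 (CV 42.1%)
#>   sigma2 0.04918 (CV 22.5%)   TM50 47.7 wk (fixed)   Hill 3.4 (fixed)
#>   shrinkage %: eta(CL) 37.9, eta(V) 16.0, eps 31.7
```

The generating values were TVCL 19.6 and TVV 70.6 with CVs
28.1%/42.4%/22.3%: a single sparse study recovers the fixed effects to
within a few percent, and the variability components closely. The
shrinkage figures (38% on eta-CL) are what 1-4 samples per infant
buys you, and are why dosing decisions below use simulation from the
population model rather than individual EBEs.

```r
pta <- pta_table(fit$params,
                 regimens = list(regimen(25, 8), regimen(25, 12)),
                 mics = c(1, 4, 8),
                 subgroups = list("38-42" = c(38, 42)),
                 n = 5000, seed = 11)
pta
#> <neocef_pta> target 70% fT>MIC, n = 5000 per subgroup
#>        regimen subgroup MIC 1 MIC 4 MIC 8
#>   25 mg/kg q8h    38-42  99.8  95.6  79.5
#>  25 mg/kg q12h    38-42  95.7  72.1  33.9
```

Read: at the *E. coli* breakpoint (MIC 4 mg/L), 25 mg/kg every 8 h
keeps 95.6% of term-age neonates above the 70% fT>MIC target (adequate,
PTA >= 90%), while stretching the same dose to every 12 h drops
attainment to 72% (inadequate).

`run_full_analysis(run_config())` chains all stages - synthetic data or
a NONMEM-style CSV in, parameter table, GOF/VPC/bootstrap diagnostics
and PTA tables (CSV + figures) out, every stage seeded and the
configuration serialized alongside the outputs.

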