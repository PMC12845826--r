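# pafkit

Attributable-fraction calculus for comparative risk assessment, with
synthetic-cohort validation and uncertainty analysis.

`pafkit` is for epidemiologists and public-health modellers who need to turn
a table of exposure prevalences and relative risks into preventable-burden
estimates. It implements:

- **Levin's population attributable fraction** per exposure:
  `PAF = Pe(RR − 1) / (Pe(RR − 1) + 1)`, negative for protective factors;
- **joint PAFs** for factor sets under independence:
  `1 − Π(1 − PAF_i)` (sub-additive relative to the plain sum);
- **potential impact fractions** for partial prevalence reductions
  `p0 → p1`: `PIF = (p0 − p1)(RR − 1) / (p0(RR − 1) + 1)`, combined
  multiplicatively across simultaneous scenarios;
- a **calibrated synthetic cohort**: Bernoulli exposure indicators, a
  baseline log-odds intercept solved by root finding so the mean logistic
  disease probability hits a target incidence, and counterfactual exposure
  elimination that validates the closed forms;
- **uncertainty analysis**: Monte Carlo resampling of RRs (CI-calibrated
  log-normal) and prevalences (method-of-moments beta), plus one-way
  sensitivity ranges at the confidence bounds.

The packaged `"mena_prostate"` fixture carries 14 behavioral and
environmental exposures for prostate cancer among ~47 million MENA men aged
50+ (target incidence 23.7 per 100,000), and a companion file of reported
reference values so reports can flag any divergence from them.

## Worked example

```r
library(pafkit)
tab <- load_fixture("mena_prostate")

head(paf_table(tab)[, c("factor_name", "paf_percent")], 3)
#>           factor_name paf_percent
#> 1     tobacco_smoking         9.5
#> 2             obesity         3.5
#> 3 physical_inactivity         6.7

joint_paf_table(tab)
#>             set joint_paf joint_percent sum_percent
#> 1    behavioral 0.2610385          26.1        29.3
#> 2 environmental 0.2666394          26.7        29.0
#> 3           all 0.4580747          45.8        58.2

pif_table(tab)[, c("factor_name", "pif_percent")]
#>           factor_name pif_percent
#> 1                thms         1.4
#> 2 physical_inactivity         1.7
#> 3             nitrate         5.8
#> 4     tobacco_smoking         3.8
#> 5            combined        12.2
```

Reading: drinking-water nitrate alone accounts for 17.4% of cases and
tobacco smoking 9.5%; eliminating every modelled exposure would avert 45.8%
of cases (the multiplicative joint, well below the 58.2% naive sum); and
feasible 10-percentage-point prevalence reductions in four target exposures
would avert 12.2% of cases. Cohort validation and uncertainty intervals:

```r
sim <- cohort_paf_all(cohort_config(tab, n = 1e5, seed = 1))
sim$factors[1, ]
#>       factor_name   category        paf paf_percent method
#> 1 tobacco_smoking behavioral 0.09506612         9.5 cohort

mc <- monte_carlo_paf(tab, uncertainty_spec(iterations = 1000, seed = 1))
```

`run_report()` writes the full CSV/JSON bundle and `render_figures()` the
two bar charts; `inst/cli/pafkit.R` exposes the same operations as shell
subcommands (`paf`, `joint`, `pif`, `simulate`, `mc`, `oneway`, `report`).

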