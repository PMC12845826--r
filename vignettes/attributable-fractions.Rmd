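---
title: "Attributable-fraction methods in pafkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable-fraction methods in pafkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafkit)
```

## The problem

Comparative risk assessment asks what share of a disease's burden a
population could avoid by removing, or partially reducing, modifiable
exposures. The inputs are deliberately minimal — for each exposure, a
prevalence $P_e$ in the target population and a relative risk $RR$ with its
95% CI — which makes the method usable in regions where individual-level
cohort data do not exist. `pafkit` implements this calculus for an arbitrary
risk-factor table and ships a worked table: 14 behavioral and environmental
exposures for prostate cancer among the roughly 47 million men aged 50+ in
the Middle East and North Africa (MENA), whose age-standardized incidence is
23.7 per 100,000.

## The model

**Levin's population attributable fraction.** For one exposure,

$$\mathrm{PAF} = \frac{P_e (RR - 1)}{P_e (RR - 1) + 1}.$$

It is increasing in $P_e$ when $RR > 1$ and negative for protective factors
($RR < 1$; selenium in the fixture). For valid inputs ($0 \le P_e \le 1$,
$RR > 0$) the denominator is always positive, so the fraction is defined and
below 1; the implementation still guards the degenerate boundary.

**Joint fractions.** Assuming independently acting exposures, fractions
combine multiplicatively, $1 - \prod_i (1 - \mathrm{PAF}_i)$, which is
sub-additive relative to the plain sum for non-negative fractions. A
protective factor enters with $(1 - \mathrm{PAF}) > 1$ and shrinks the joint
fraction — we keep that behavior exactly as the formula implies rather than
excluding protective factors.

**Potential impact fractions.** Partial reduction of prevalence from $p_0$
to $p_1$ gives

$$\mathrm{PIF} = \frac{(p_0 - p_1)(RR - 1)}{p_0 (RR - 1) + 1},$$

which reduces to the PAF at $p_1 = 0$ and to zero at $p_1 = p_0$ (both are
tested exactly). The default scenarios reduce each target factor by an
absolute 10 percentage points; the default factor set is trihalomethanes,
physical inactivity, drinking-water nitrate and tobacco smoking —
trihalomethanes stand in for high calcium intake, whose prevalence comes
from food-supply rather than consumption data and is likely overstated.

## Cohort validation

The closed forms are validated by a synthetic cohort (default $n = 10^5$ men
aged 40–80):

1. exposure indicators $x_{ij} \sim \mathrm{Bernoulli}(P_{e,j})$,
   independent across factors and men;
2. a baseline log-odds intercept $c$ calibrated by root finding so that
   $\frac{1}{n}\sum_i \sigma\!\left(c + \sum_j x_{ij} \log RR_j\right)$
   equals the target incidence, where $\sigma$ is the logistic function;
3. disease probability per man from the logistic model, with case status
   either taken in expectation (default) or drawn as a Bernoulli trial;
4. per-factor cohort PAFs from counterfactual elimination: zero the
   factor's column, keep the intercept at its baseline value and reuse all
   random draws, and measure the proportional incidence reduction.

Numerical choices that matter:

* **Calibration.** The objective is strictly increasing in $c$, so a
  bracketed `uniroot` search converges; a Newton polish then drives the
  residual below $10^{-12}$ (every run asserts $<10^{-10}$). When all men
  share one linear predictor the closed form $\mathrm{logit}(t) - \eta$ is
  returned exactly.
* **No recalibration in counterfactuals.** Recalibrating after zeroing an
  exposure would restore the target incidence and nullify the very effect
  being measured; the counterfactual therefore reuses the baseline
  intercept and common random numbers. This choice reproduces the reference
  cohort results.
* **Expected-case default.** At incidence $2.37\times10^{-4}$ and
  $n = 10^5$ only ~24 cases are expected, so Bernoulli case draws carry
  large Monte Carlo noise; the default measures incidence as the mean
  probability, which is exact given the exposure draws. Bernoulli mode is
  retained for full fidelity to the generative story.
* **Odds vs. risk.** Log-RRs enter on the log-odds scale. At rare-disease
  incidence the OR/RR distinction is negligible; the property that cohort
  PAFs match Levin PAFs within 0.005 absolute at $n = 10^6$ is part of the
  test suite.
* **Inert age.** Age is simulated uniformly over 40–80 for realism but has
  no coefficient in the disease model.
* **Diesel exhaust.** The fixture stores one exposed population (2%) with
  two reported exposure-contrast strata (RR 1.24 and 1.27). Closed-form
  tables report both strata; the joint product includes both by default
  (giving 45.8% for all factors; restricting to one stratum gives 45.5%),
  and the simulation carries the factor once under its default stratum.

## Uncertainty analysis

Probabilistic sensitivity analysis (default 1000 iterations) redraws every
relative risk from a log-normal calibrated to its published CI
($\sigma = (\ln hi - \ln lo)/3.92$, median at the point estimate) and every
prevalence from a method-of-moments beta (mean at the point estimate,
$sd = (hi - lo)/3.92$). Prevalence confidence limits are rarely published
with risk tables, so the default band is ±10% relative around the point
estimate, clipped to $[0,1]$, with per-factor overrides — a transparent,
conservative stand-in that keeps the beta machinery intact. Summaries are
means and empirical 2.5th/97.5th percentiles with linear interpolation.

Each factor draws from its own RNG stream, derived from the master seed and
a stable hash of the factor name, so adding a factor to a table never
perturbs the other factors' draws. The default engine recomputes the closed
form per draw; an optional cohort engine reruns the full simulation per
draw at a documented, much higher cost. One-way sensitivity recomputes the
PAF with a single parameter moved to each of its confidence bounds.

## The synthetic-table generator

`generate_synthetic_table()` is the property-testing counterpart of the
packaged fixture: $k$ factors with prevalences uniform on (0.05, 0.6),
log-RRs normal with SD 0.3, Wald CIs, population $10^6$ and target
incidence $2\times10^{-4}$. These defaults were chosen once to mirror the
fixture's scale (prevalences 2–60%, RRs 0.86–1.70, incidence
$2.37\times10^{-4}$). The generator emulates the *structure* of a real risk
table, not its epidemiology: exposures are independent, CIs are exactly
symmetric on the log scale, and prevalences are exact. Passing property
tests therefore demonstrates the correctness of the calculus and the
simulator, not the validity of any particular substantive risk table.

## Reporting conventions and known limitations

* Percentages are printed at one decimal with **half-up** rounding,
  matching the reference tables; all internal computation is at full
  precision. (Base R's `round()` rounds half to even, which would print
  3.05% as 3.0%.)
* Reported reference values accompany the packaged fixture, and
  `run_report()` flags rows whose recomputed 1-dp percentage differs from
  the reported one instead of forcing agreement. Three such discrepancies
  are expected and deliberate: the reported joint behavioral fraction
  (25.8%) versus the closed-form product (26.1%), the trihalomethane PIF
  (reported 1.5%, formula 1.4%) and the combined PIF (reported 12.1%,
  formula 12.2%). The reported joint figures plausibly derive from a
  simulation rather than the closed-form product; both routes are computed
  and shown side by side.
* Per-increment relative risks (lead, PM2.5, NO2) are applied to printed
  exceedance prevalences as if binary — an inherited simplification of the
  source table, not a recommendation.
* Independence across exposures is assumed throughout (joint products,
  Bernoulli draws, Monte Carlo streams); correlated exposures such as
  co-occurring air pollutants will make joint fractions optimistic.
* Attributable fractions carry a causal interpretation only insofar as the
  input relative risks do.

Test problem sizes were chosen to keep the default suite quick while still
exercising the asymptotics: cohorts of $10^5$ against the published values
(±0.3 points) and $10^6$ for the rare-disease equivalence (0.005 absolute),
1000–2000 Monte Carlo iterations, and 100 random synthetic tables for the
invariant sweep.

## A worked run

```{r, eval = FALSE}
tab <- load_fixture("mena_prostate")
paf_table(tab)                       # 15 closed-form rows
joint_paf_table(tab)                 # behavioral 26.1, environmental 26.7, all 45.8
pif_table(tab)                       # 1.4, 1.7, 5.8, 3.8 -> combined 12.2
cohort_paf_all(cohort_config(tab, n = 1e5, seed = 1))
monte_carlo_paf(tab, uncertainty_spec(iterations = 1000, seed = 1))
```
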