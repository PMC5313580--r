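---
title: "Measuring risk selection without confounding it with insurer efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring risk selection without confounding it with insurer efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskselect)
```

## The measurement problem

In regulated health-insurance markets with open enrollment and community
rating, a risk-equalization scheme pays each insurer a risk-adjusted
amount per insured — predicted annual expenses minus $p\%$ of the overall
mean expenses $m$ — so that cross-subsidies flow from low-risk to
high-risk insured. Equalization formulas are imperfect: any health
variation not captured by the risk adjusters ("unpriced risk
heterogeneity") leaves identifiable groups under- or overcompensated,
which gives insurers and consumers incentives for risk selection:
actions, other than risk rating, with the goal or effect that the
intended cross-subsidies are not achieved.

The natural measure of selection — an insurer's mean *residual expenses*
(actual minus predicted) over all enrollees — is confounded: an insurer
with negative mean residuals may simply deliver care more cheaply than
average. This package implements the estimator that removes that
confound. For insurer $X$, take the persons who *switched* insurer
between the two panel years. Those who newly enrolled with $X$ incurred
their pre-switch-year expenses at their *origin* insurers; those who left
$X$ incurred their post-switch-year expenses at their *destination*
insurers. The mean overcompensation (minus the residual) of these two
flows is therefore untouched by $X$'s own efficiency and, averaged over
the other insurers' efficiencies, it estimates the over- or
undercompensation of the risks $X$ attracts and sheds. A significantly
non-zero flow mean is direct evidence of selection.

The toolkit also provides the complementary measures used around that
estimator: per-group compensation statistics (mean overcompensation,
predictive ratio $PR = \overline{\text{predicted}}/\overline{\text{actual}}$,
reduction versus no equalization), overrepresentation indices of selected
groups within an insurer's portfolio, and the naive per-insurer residual
mean itself, kept on purpose as the biased benchmark.

Sign conventions follow the reporting tables throughout:
overcompensation $=$ predicted $-$ actual, so negative values are
undercompensation; a predictive ratio below 1 marks an undercompensated
group; a "$-75\,\%$" reduction means the equalization scheme removes 75%
of the gap that would exist if every prediction were the population mean.

## The synthetic market

Administrative claim panels of the kind these estimators are designed for
are confidential, so the package ships a generator whose ground truth is
known, and every estimator is validated by parameter recovery. A
`market_config()` describes:

* **Population.** Categorical risk adjusters (default: five age bands,
  sex, four region clusters, and a chronic-condition flag with population
  share 31.5%), plus a per-person *unpriced effect* $u_i$: a monetary
  shift on expected annual expenses drawn from a mixture of a point mass
  at 0 and normal components. By default 18.9% of the population carries
  a shift of mean 826 (sd 300) currency units, which makes that group
  undercompensated by roughly 670 on average — the magnitude reported for
  the worst-health groups in operational Dutch risk equalization.
  Continuous draws are truncated below at $-0.98$ times the person's
  baseline mean so the implied positive-part mean stays positive.
* **Expenses.** A two-part model: zero annual expenses with probability
  $\pi_{0,i}$ (baseline 0.2607, multiplied by 0.2 for the chronically
  ill, giving a population zero-utilization share of 19.5%), otherwise a
  Gamma draw with shape $k = 0.8$ and conditional mean
  $(\text{base}_i + u_i)/(1-\pi_{0,i})$, so that unconditionally
  $E[\text{expenses}_i] = \text{base}_i + u_i$. The baseline scale is
  normalized so population mean expenses are 1570. The marginal
  distribution is zero-inflated and heavy-tailed (CV $\approx$ 1.9,
  skewness $\approx$ 5), as annual health expenditures are.
* **Efficiency.** A positive multiplier per insurer applied to realized
  positive expenses *after* the random draw. This makes common-random-
  number counterfactuals exact: changing a multiplier leaves every
  underlying draw bit-identical and scales affected expenses exactly.
* **Switching and selection.** Year-1 enrollment follows configurable
  market shares; each person switches with probability 0.031 (the
  observed Dutch rate: roughly half a million switchers in a market of
  sixteen million). The destination is drawn among the *other* insurers
  with weights $\text{share}_j \cdot \text{logit}^{-1}(\eta_{ij})$. In
  the default `"health"` mode $\eta_{ij} = -s_j z_i$ with $z_i$ the
  standardized unpriced effect: a positive strength $s_j$ attracts
  overcompensated (healthy) risks. A `"magnitude"` mode sets
  $\eta_{ij} = s_j(|z_i| - E|z|)$, attracting *both* tails — an insurer
  simultaneously practicing positive and negative selection. Optional
  flags tilt the exit decision (`exit_selection`) and the year-1
  baseline assignment (`select_baseline`) by the same weights.

Population, switching and expense draws use three RNG streams derived
from one seed, so editing one configuration block leaves the other
stages' draws bit-identical.

`expected_switcher_truth()` integrates this mechanism over the
unpriced-effect distribution (grid quadrature over the mixture, no
simulation), and `calibrate_selection()` inverts it: it solves for the
strength $s$ that makes the *expected* true inflow overcompensation of
one insurer equal a target, which is how the recovery scenario injects
exactly +100.

## Estimation choices

* The equalization formula is fitted by unweighted OLS of individual
  annual expenses on dummy-encoded adjusters with intercept, separately
  per year — the simplest scheme consistent with individual-level
  risk-adjusted predictions. $m$ is the fit-year mean of actual expenses
  (equal to mean predicted in-sample). A model can instead be supplied as
  fixed coefficients (JSON) and applied without refitting; the
  efficiency-invariance property below is only exactly testable that
  way, because refitting lets a perturbed insurer's expenses leak into
  the coefficients.
* Declared adjuster levels without fit-year observations are dropped with
  a warning; exact collinearity is an error naming the columns; levels
  unseen at fit time map to the reference level at prediction, counted
  and reported, so prediction is total. Negative predictions (and hence
  negative payments) are allowed, as in a linear formula.
* Significance: two-sided one-sample t-test of zero mean residual, with
  a normal approximation above $n = 10^4$; zero-variance samples return
  $p = 1$ with a degeneracy flag, cells with fewer than two observations
  are marked unavailable. No multiple-testing correction is applied
  across insurers: each insurer is starred individually, as in the
  reporting convention the tables mirror. Observations are treated as
  independent; within-person correlation across the two years is not
  modelled.
* Persons present in only one panel year (entrants, leavers) are
  excluded from switcher analysis and tallied in the exclusion log.
* Inflow estimates use year-$(t{-}1)$ residuals under the year-$(t{-}1)$
  model; outflow estimates use year-$t$ residuals under the year-$t$
  model — the years before and after the switch. Insurers are reported,
  by default, in decreasing order of their non-switchers' mean year-$t$
  residual expenses; a flag switches to the overcompensation ordering,
  since the two conventions are mirror images.

## What the validation scenarios show

Four presets (`scenario_preset()`, default 200,000 persons — sized so a
full replicate simulates, fits and measures in about two seconds)
exercise the mechanisms that make naive measurement fail:

* **null-market** — 25 equal insurers, no selection: all estimators
  centred at zero, rejection rates near nominal.
* **efficiency-bias** — multipliers 0.90–1.10, no selection: the naive
  estimator flags the outer insurers essentially always, while switcher
  tests stay at size. With a supplied fixed model and common random
  numbers, perturbing one insurer's multiplier leaves its switcher
  estimates *bit-identical* while its naive estimate moves by many
  standard errors — the efficiency-invariance property stated exactly.
* **cancel-out** — magnitude-mode selection with a symmetric $\pm 250$
  unpriced mixture and baseline tilting: the selecting insurer
  over-represents both tails (overrepresentation index well above 1 for
  each), its naive estimate stays near zero, yet each tail's
  compensation row is large and significant — the
  underestimation-by-cancellation mechanism.
* **recovery** — calibrated destination tilt: across replicates the
  inflow estimate is unbiased for the injected +100 and its 95% CI
  covers the realized truth at the nominal rate.

One calibration caveat, established by the package's own tests: at this
desk scale a 25-insurer null market leaves only ~250 switchers per
insurer flow, and with residual skewness near $-5$ the one-sample t-test
is slightly oversized there (empirical size $\approx 0.07$–$0.075$
instead of 0.05, falling to nominal by cell sizes in the thousands). At
administrative scale — twenty-odd-thousand switchers per insurer — the
distortion vanishes. Users testing small flow cells on heavy-tailed
residuals should read stars near the 0.05 boundary with that in mind.

## What the simulator does not emulate

The generator reproduces the statistical structure the estimators rely
on — unpriced heterogeneity, heavy-tailed two-part costs, multiplicative
efficiency, rare switching with selectable tilt — not the institutional
detail of any real market. It has no cost persistence beyond the chronic
flag and the unpriced effect (so "no utilization last year" is not the
strongly overcompensated group it is in reality), no births, deaths or
mid-year moves by default, no health-plan level below the insurer, no
premiums, and a single currency scale. Passing recovery tests on this
generator therefore shows the estimators are correct *given* the model
class; it cannot show that real markets satisfy the assumptions (notably
efficiency acting only at the insurer level and switchers being exposed
to the average efficiency of the other insurers).

## Reproducing the numbers

`run_pipeline("recovery", seed = 1)` chains simulate → fit both years →
residualize → all measurement tables → recovery report, and writes CSVs
(full precision), Markdown renderings, the ground-truth JSON and a run
manifest when given an output directory. `scripts/acceptance.R` in the
source repository recomputes the package's headline quantities from a
fresh simulation at the same sizes used here.
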