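---
title: "The IRIS cost-utility model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IRIS cost-utility model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iriscea)
```

## The decision problem

IRIS (Identification and Referral to Improve Safety) is a UK general-practice
training and advocacy programme for women experiencing domestic violence and
abuse (DVA). Practices are trained to recognise signs of abuse and refer
patients to a named advocate educator; the programme is commissioned at the
level of a clinical commissioning area. The economic question is whether the
programme's cost — a few tens of pence per registered woman per six months —
is justified by the abuse it helps end, measured as quality-adjusted
life-years (QALYs) gained and abuse-related societal costs avoided, against a
willingness-to-pay (WTP) threshold of £20,000 per QALY.

`iriscea` implements this comparison as a deterministic five-state Markov
cohort model with a full uncertainty analysis, driven entirely by a
plain-text parameter file. The pooled national parameter set ships as the
default fixture (`default_iris_parameters()`, also serialised under
`inst/extdata/`).

## Model structure

A closed cohort of women aged 16+ registered with a general practice moves
between five states in six-month cycles over a ten-year horizon (20 cycles):

| Code | State | Utility (QALY weight/year) |
|------|-------|---------------------------|
| N | not abused | 0.85 |
| U | abused, not identified | 0.63 |
| A | abused, identified, seeing advocate educator | 0.65 |
| I | abused, identified, not seeing advocate educator | 0.63 |
| D | dead (absorbing) | 0 |

Movement is sparse: `N` can only become abused or die; `U` can recover,
be identified (into `A` or `I`) or die; the two identified states can only
recover to `N`, stay, or die. Transitions between the identified states, or
from them back to `U`, are structural zeros. The intervention changes a
single row: identification out of `U` is roughly an order of magnitude more
likely per cycle (into `A`: 0.0056 vs 0.0005; into `I`: 0.0109 vs 0.0027).

Stay probabilities are never inputs. Each row's stay value is the complement
of its exit probabilities, so rows are stochastic by construction
(`build_transition_matrix()`). The historical parameter table also printed
stay values; for the two `U` rows these disagree materially with the
complement of the printed exits (0.9444 vs 0.94126 in the control arm,
0.9419 vs 0.92796 in the intervention arm). We treat the complement as
authoritative — it is the only construction under which a row built from the
printed exits is a probability distribution — and expose the printed values
behind `options$stay_mode = "printed_renormalized"` for exploration only.
This unexplained discrepancy matters: see *Reproduction of the published
results* below.

```{r}
p <- default_iris_parameters()
round(build_transition_matrix(p, "intervention"), 5)
```

The cohort starts with prevalence 0.17 in the abused states, split
0.964/0.003/0.033 over U/A/I, and the rest in `N`. That split equals the
long-run conditional composition of the abused states under the control-arm
transitions, which is how it was originally derived; the package reproduces
it to printed precision (`calibrate_incidence()$solved_start_split`).

## Calibration

The incidence (`N` to `U`) and recovery (`U` to `N`) probabilities are the
least observable inputs. The stated procedure calibrates them so that the
long-run proportion of surviving women who are not abused equals the
observed general-practice prevalence: 83% not abused. With an absorbing
death state the unconditional chain converges to everyone dead, so the
long-run target is interpreted as the quasi-stationary distribution — the
chain iterated (up to 3000 cycles) with mass renormalised among the living
each cycle (`quasi_stationary_distribution()`).

One equation cannot pin down two probabilities, so `calibrate_incidence()`
holds recovery fixed at its tabulated value (0.0500) and solves for
incidence by bisection (tolerance 1e-6 on the achieved fraction, at most
100 iterations; monotonicity is asserted on a grid first). A `solve_for =
"recovery"` option implements the converse.

```{r}
calibrate_incidence(p, target_not_abused = 0.83)
```

Note the solved incidence (about 0.0105) is nearly three times the
tabulated base value 0.0037; under the tabulated pair the long-run abused
fraction is about 7%, not 17%. The package does not silently re-calibrate:
base-case runs use the tabulated values, so that results are computed on
the same inputs the published analysis printed, and the inconsistency is
surfaced here rather than patched.

## Economics

Discounting is annual (3.5%) compounded over elapsed years:
$(1.035)^{-t/2}$ at time point $t$ in half-year cycles. The half-cycle
correction is trapezoid weighting of the occupancy trace — half weight at
time 0 and the final time point — applied identically to QALYs and
per-cycle costs.

Three cost streams (GBP 2015/16):

* **State costs.** £2,043 per six months per woman in any abused state —
  a national cost-of-abuse estimate spanning health services, lost
  economic output, justice-system and personal costs. The two identified
  states carry multiplicative weights (base 1.0, varied ±25% and ±10% in
  sensitivity analysis). Under the NHS perspective this stream is scaled
  by `nhs_cost_share`; the programme and referral costs below are NHS
  costs in full under both perspectives.
* **Referral costs.** £312 once per entrant to the seeing-advocate state,
  discounted at the end-of-cycle time point where the entrant arrives.
  Entrants are flows; the (tiny, 0.00051) initial stock of state `A` is
  not charged unless `options$charge_initial_advocates` is set. The £312
  already folds in referral uptake rates, which is why it attaches to
  advocate contact rather than onward-service use.
* **Programme cost.** £0.46 per living registered woman per cycle
  (a pooled six-month budget of £272,613 over 595,902 registered women),
  intervention arm only, trapezoid-weighted like the state costs.

`nhs_cost_share` has no observable source: no published figure splits the
£2,043 into NHS and non-NHS components. The default (0.2860) was
back-derived once, with `derive_nhs_cost_share()`, from the published
NHS-perspective control-arm total — a deliberately documented circularity.
NHS-perspective outputs are therefore consistency checks, not independent
reproductions, and are excluded from the package's validation targets.

Incremental results use the standard conventions: ICER only when the
increments share a sign, dominance labels otherwise, and net monetary
benefit NMB = WTP × ΔQALY − ΔCost (`compare_arms()`).

```{r}
run_base_case(p, "societal")
```

## Sensitivity analysis

**One-way (tornado).** Every parameter with a non-degenerate 95% interval
is set to each limit in turn with everything else at base, re-running the
full pipeline (`owsa()`). Transition-row members are varied with the stay
complement re-derived; a limit that pushes a row's exits to 1 or beyond is
flagged infeasible, never clamped. Per-parameter override ranges support
narrower policy bands (e.g. varying the control-arm recovery over
0.049–0.051).

**Probabilistic.** Distributions are fitted by method of moments treating
the base value as the mean and (high − low)/3.92 as the standard
deviation: beta for probabilities and utilities, gamma for costs and cost
weights, uniform for the starting-split fractions. Transition rows are
labelled Dirichlet in the source table but no concentration is given and
only per-element limits are printed, so the default honours exactly that
information: independent per-element beta draws re-closed through the stay
complement, with rows rescaled to sum 0.999 (and audited) in the rare case
a draw overflows. A true-Dirichlet mode (`options$dirichlet_mode =
"dirichlet"`, concentration least-squares-fitted to the printed limits) is
available. Parameters are sampled independently; no correlation structure
is asserted anywhere in the source material. Rows shared between arms (the
`N`, `A` and `I` rows) receive one draw applied to both arms; the
arm-specific `U` rows are drawn separately, as they are separate rows of
the input table.

`run_psa()` (default 1,000 draws, seeded and bit-reproducible) records
per-draw incremental cost and QALYs, dominance fractions, the fraction
cost-effective at the threshold, 95% percentile intervals
(linear-interpolation convention, i.e. R's quantile type 7), and the
acceptability curve over a £0–£50,000 grid in £1,000 steps.

```{r, fig.width = 6, fig.height = 4, eval = requireNamespace("ggplot2", quietly = TRUE)}
psa <- run_psa(p, n_sim = 200, seed = 1)
psa$fractions
plot_ceac(psa)
```

## Reproduction of the published results

The control arm reproduces well: its discounted cost and QALYs land within
1–3% of the published £4,430 and 6.669, and the tornado response of the
NMB to the control-arm recovery probability matches the published slope
(about £68 per 0.001 of recovery probability). The calibration solver hits
its 83% target to 1e-6, the quasi-stationary abused-state composition
equals the published starting split at printed precision, and the PSA's
dominated fraction matches the published 18% within noise.

The *between-arm contrast*, however, does not reproduce from the printed
inputs. Building both arms exactly as tabulated (complement stays) yields
an incremental cost of about −£73 and incremental QALYs of about +0.005,
versus the published −£14 and +0.001: the tabulated difference between the
two `U` rows implies an intervention effect roughly 3.5 times the
published one. We probed every defensible alternative construction —
printed stays kept raw, whole-row renormalisation, printed stays with
recovery as the implied complement, exits rescaled into the printed stay
mass, identified states relapsing to `U` instead of recovering — and none
lands on the published increments; they bracket it from roughly −£500 to
+£1,400 of NMB. Our conclusion is that the published implementation
applied a weaker intervention contrast than its printed transition table
implies, through a mechanism not recoverable from the printed material.
The package deliberately ships the faithful construction and reports the
resulting discrepancy rather than tuning any input toward the published
numbers; the affected checks in `tests/testthat/test-acceptance.R` are
expected to fail and say so.

## The synthetic generator and what passing tests show

`random_parameter_set()` draws structurally valid parameter sets — sparse
transition rows below an exit cap, utilities in a configurable range,
non-negative costs, coherent uncertainty limits — and
`toy_models()` provides closed-form miniature chains. Together they back
the property suite: probability conservation, death monotonicity,
agreement between the cycle iterator and matrix powers (1e-12), agreement
with a seeded 10,000-individual microsimulation, and collapse of the PSA
onto the base case as variances shrink. These establish that the *engine*
is correct on the whole class of models it accepts. They cannot establish
that the fixture matches the world: the generator emulates the schema of
the inputs, not the epidemiology of DVA (no age structure, no
time-varying risk, no correlation between parameters, no site
heterogeneity).

## Numerical choices and limitations

* Horizon 20 cycles; quasi-stationary iteration capped at 3000 cycles with
  tolerance 1e-12; bisection tolerance 1e-6 on a fraction, 100 iterations.
  The deterministic base case runs in well under a second; a 1,000-draw
  PSA takes on the order of a second.
* Reported costs are rounded to whole pounds and QALYs to three decimals
  only at the printing stage; all stored values are unrounded.
* Degenerate inputs: zero prevalence, zero exit rows, zero costs, and
  identical arms are all exercised in the test suite and produce exact
  zeros where symmetry demands them.
* Not modelled: effects on children, site-level variation (site-specific
  inputs are not published), currency conversion or inflation (inputs are
  taken as 2015/16 GBP), time-varying transition probabilities, and any
  individual-level heterogeneity beyond the microsimulation test oracle.
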