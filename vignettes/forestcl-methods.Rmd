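---
title: "Methods: deposition response curves, critical loads, and ordinal vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deposition response curves, critical loads, and ordinal vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcl)
```

`forestcl` implements a two-stage analysis of tree demography along
atmospheric nitrogen (N) and sulfur (S) deposition gradients, of the kind
applied to national forest-inventory remeasurement data. Stage one fits
nonlinear growth and survival response models per species × ecoregion
Division, classifies the fitted deposition response shapes, and derives
critical loads. Stage two treats those shapes as an ordered vulnerability
outcome and models them against climate, soil, deposition and
functional-trait covariates. Because real inventory extracts are large,
access-restricted compilations, the package ships a synthetic-data module
that generates inventory-like records *from the same model equations* with
known parameters, so every stage can be validated by parameter and shape
recovery.

## Stage one: demographic response models

### Growth

Observed growth $G$ (kg C tree$^{-1}$ yr$^{-1}$, possibly negative) is
modelled as a potential rate $a$ multiplied by bounded modifier terms:

$$
\mu = a \, m^{z} \, e^{a_2 \mathrm{BAL} + a_3 \ln \mathrm{BA}}
\; g(T; t_1, t_2) \; g(P; p_1, p_2) \; [\,g(N; n_1, n_2)\,]
\; [\,s(S)\,]
$$

where $m$ is aboveground carbon (kg C), BA the plot basal area
(m$^2$ ha$^{-1}$), BAL the basal area of larger trees, $T$ mean annual
temperature (K), $P$ total annual precipitation (dm), and $N$, $S$ the
mean annual deposition rates (kg ha$^{-1}$ yr$^{-1}$). The bracketed
terms appear only in the model variants that include them.

$g(x; c_1, c_2) = \exp\{-\tfrac12 [\ln(x/c_1)/c_2]^2\}$ is a two-term
lognormal modifier in $(0, 1]$: it peaks at $x = c_1$ and declines
symmetrically in log space with width $c_2$. It expresses a unimodal
niche response — for N, a fertilizing effect up to the peak $n_1$ and a
decline beyond it.

The sulfur term has two forms. The sigmoid form
$s(S) = s_3 + (1 - s_3)/(1 + (S/s_1)^{s_2})$ is flat near zero
deposition (soils buffer small acid inputs), passes half of its total
decline at $S = s_1$, declines with steepness $s_2$, and levels off at
the plateau $s_3 \in [0, 1)$. The lognormal form reuses $g$ but is
restricted to its decreasing limb by bounding $s_1$ at or below the
unit's minimum observed deposition; it exists for comparability with
earlier monotone-negative formulations and can produce implausibly low
critical loads, which motivated the sigmoid alternative.

The likelihood is Gaussian, $G \sim \mathcal N(\mu, \sigma^2)$ with a
constant residual SD $\sigma$ estimated by maximum likelihood and counted
as a free parameter. A Gaussian error supports negative observed growth
and matches the conventions of the likelihood-based forest modelling
literature this family of models comes from; nothing in the model
structure depends on that choice.

Seven growth variants of increasing complexity are fitted
(`enumerate_models("growth")`): intercept-only; the "base" model (size,
competition, temperature, precipitation); base + N; base + sigmoid S;
base + lognormal S; and base + N with each S form.

### Survival

Survival over a census interval of $dt$ years is Bernoulli with
$p = b^{dt}$, where the bracket $b \in (0, 1]$ is *annual* survival:
a baseline multiplier $a$ times size, competition, climate and
deposition terms. Two competition representations are crossed with the
same six structured variants (13 survival models in all, the
intercept-only model having no competition term):

* **Form A** — saturating size effects
  $(1 - z_{c1} e^{-z_{c2} m}) e^{-z_{c3} m^{z_{c4}}}$ (juvenile risk
  declining with size, senescent risk rising) and a crowding term
  $e^{-b_{r1} \mathrm{BAratio}^{b_{r2}} \mathrm{BA}^{b_{r3}}}$ with
  BAratio $= \mathrm{BAL}/\mathrm{BA} \in [0, 1]$, the only
  dimensionless crowding index constructible from the declared inputs.
* **Form B** — lognormal modifiers in size, BA, and BAL + 1 (the offset
  keeps zero-BAL trees in the domain of the log).

The exponent is the interval in *years*, so the bracket is annual
survival; the conventional 10-year reporting scale is `survival_prob_10yr()`
($b^{10}$). The exponent's units were a genuinely open choice; it is
isolated in `survival_prob()` so a different convention is a one-line
change. Parameter vectors that put any record's bracket outside
$(0, 1]$ get a $-\infty$ log-likelihood — a rejection the optimizer
treats as an infeasible move, not an error.

Zero deposition is legal: the sigmoid S term is defined at $S = 0$, and
N (or lognormal S) is floored at $\epsilon = 0.01$ kg ha$^{-1}$ yr$^{-1}$
before the log so records in pristine regions do not crash the modifier.

### Fitting

Each candidate is fitted by maximizing the log-likelihood with simulated
annealing inside data-driven box constraints (`fit_config()`,
`fit_model()`): geometric cooling from $t_0 = 2$ to $10^{-3}$
(log-likelihood units), one-coordinate Gaussian proposals reflected at
the bounds, per-parameter proposal widths adapted every 25 sweeps toward
a 35% acceptance rate, and restarts (first from a data-informed start,
the rest from random points in the box) splitting the total iteration
budget; the best point over all restarts is returned. The reference
budget is 100,000 iterations; the package's tests use 1,500–20,000
depending on what the test demonstrates, which parameter-recovery checks
show is sufficient at those problem sizes. Every fit is deterministic
given its seed, and all pipeline seeds derive from the single run seed.

Bounds default to $[0.5 \times \min, 2 \times \max]$ of the matching
covariate for the lognormal locations, $[0.05, 10]$ for the widths
(ln-scale), $(0, 1]$ for the survival baseline, ten times the largest
observed |growth| for $a$, and $[0, 0.99]$ for the sigmoid plateau —
wide enough to contain any data-compatible optimum while keeping the
search in the identifiable region.

### Model selection and exclusion

Per species × Division × endpoint (units under 500 trees are flagged
`insufficient_data`), candidates within $\Delta\mathrm{AIC} \le 4$ of
the best AIC form the candidate set. If any candidate carries *separate*
N and S terms, the lowest-AIC such candidate is selected — the rule
prefers attributing deposition effects to both pollutants explicitly
when the data cannot distinguish it from cheaper alternatives. Otherwise
the lowest-AIC candidate wins, *unless* the unit's N–S deposition
correlation is at or above $r = 0.7$ and some candidate carries a
deposition term: then a single-pollutant effect cannot be attributed to
N versus S and the unit is excluded (`excluded_ns_collinearity`). A
candidate set with no deposition term at all is never excluded — there
is no attribution to confound. AIC ties break toward fewer parameters,
then enumeration order. An undefined correlation (zero deposition
variance) is treated as below the threshold.

### Response shapes and critical loads

Shapes live on an ordered vulnerability scale: increase < flat <
unimodal/sigmoid < decrease — ranked by how much of the population
responds negatively. For N, the realized shape over the unit's observed
deposition range $[N_{\min}, N_{\max}]$ follows from the fitted peak:
no N term is flat; $n_1 \ge N_{\max}$ realizes a monotone increase;
$n_1 \le N_{\min}$ a monotone decrease; an interior peak is unimodal.
Boundary equality goes to the monotone class (the realized curve is
monotone on the closed range). For S: no term is flat, the lognormal
form is decreasing by construction, the sigmoid form is sigmoid. A
sigmoid fit whose decline lies wholly above the observed S range is
still reported as sigmoid; the critical-load table carries the observed
range so such cases are flaggable downstream.

Critical loads (kg ha$^{-1}$ yr$^{-1}$): for N, the fitted $n_1$ — the
deposition above which the response begins to decline; for lognormal S,
$s_1$ likewise. The sigmoid midpoint $s_{1}$ is *too high* to be a
protective threshold, so the sigmoid CL is obtained by inversion:
choosing a tolerated fractional reduction $f$ and solving
$s(S) = 1 - f$ gives

$$ \mathrm{CL} = s_1 \left( \frac{f}{1 - f - s_3} \right)^{1/s_2}, $$

with defaults $f = 0.05$ for growth and $f = 0.01$ for survival (5% and
1% reductions; $f = 0.001$ is another conventional choice for a
near-zero threshold). When $f \ge 1 - s_3$ the fitted curve never
declines that far and the CL is reported undefined rather than clipped.
Note the CL *increases* with $f$: tolerating a larger reduction moves
the threshold further down the declining curve.

## Stage two: ordinal vulnerability models

Each selected unit contributes one row per pollutant: its shape plus
Division-level species means of long-term covariates (MAT in °C, MAP in
mm, soil pH, N and S deposition averaged over the plots where the
species occurs) and two species-level traits (mycorrhizal association
AM/EcM, leaf habit deciduous/evergreen). Stage one uses between-census
covariate means per tree; stage two deliberately uses long-term
(climate-normal-like) means, because the question changes from "what did
this tree experience" to "where on the landscape do vulnerable responses
concentrate". Species missing from the trait table are dropped with a
warning, mirroring the removal of trait-unclassifiable species from the
motivating analysis. Growth and survival rows form separate tables
(their unit sets differ, since growth needs trees alive at both
censuses), so four ordinal models are fitted: endpoint × pollutant.

The proportional-odds model
$P(Y \le j) = \mathrm{logit}^{-1}(\alpha_j - x'\beta)$ is fitted by
maximum likelihood (`MASS::polr`); when only two outcome categories are
realized — where the cumulative-logit model *is* binary logistic
regression, a case `polr` refuses — the package fits the same likelihood
directly (`polr2`, checked against a `glm` oracle). Stepwise selection
(`MASS::stepAIC`, both directions, marginality respected) starts from
the full hypothesis scope: seven main effects and six hypothesis-driven
first-order interactions (MAT×MAP, MAT×Ndep, pH×Sdep, Ndep×Sdep,
Ndep×myco, pH×myco). Continuous predictors enter in raw units, so odds
ratios are per unit of the covariate; an analysis wanting standardized
effects can scale the table first. Reported per model: coefficients and
strictly increasing thresholds, AIC and AICc, Nagelkerke's
$R^2 = [1 - e^{2(L_0 - L_1)/n}] / [1 - e^{2 L_0 / n}]$, and
odds ratios $e^{\beta}$ with 95% Wald CIs from the observed information
(profile CIs are out of scope). One caution from simulation: AIC
stepwise from a 13-term scope retains *some* spurious interaction in
roughly a third of null replicates (each survives with probability
$\approx P(\chi^2_1 > 2) \approx 0.16$); the true driver is reliably
retained, but single retained interactions should not be
over-interpreted.

Supporting tests: Fisher's exact test on shape × Division contingency
tables (exact two-sided by probability ordering for 2×2; margin-
preserving Monte-Carlo $p = (1 + \#\{P_{sim} \le P_{obs}\})/(B+1)$ for
larger tables — the two-sided rule for R×C tables is conventional, not
uniquely defined, and probability ordering is the one used throughout);
one-way ANOVA with Tukey HSD for Division differences in each
covariate; and Blomberg's $K$ on species-level residuals of the selected
ordinal models (observed minus expected vulnerability rank, averaged per
species) against a species phylogeny. $K$ compares the ratio of the
trait's variance about the GLS phylogenetic mean to its phylogenetically
corrected variance with the same ratio expected under Brownian motion:
$K \approx 1$ indicates Brownian-like signal, $K \approx 0$ none. On a
star phylogeny the statistic is identically 1, a useful exactness check.
The permutation $p$ shuffles trait values across tips and counts
permutations whose corrected mean squared error is at most the observed
one.

## The synthetic-data module

`generate_trees()` draws plot covariates from Division-level gradients
(11 Divisions with an east–west deposition gradient, interior pH
maximum, wet east/northwest — a qualitative mimic, not data), sizes and
competition from lognormal/beta laws, census intervals from a
truncated normal (mean 8.2, SD 2.9, range 5–10 years, like inventory
remeasurement cycles), and N–S deposition jointly with a configurable
correlation `ns_rho` (default 0.35–0.4; sweeping it to 0.9 exercises the
exclusion rule). Growth and survival outcomes are then generated *from
the package's own mean functions* with known parameters; the defaults
place the N peak just above the Division mean with a strongly peaked
width (`n2 = 0.6`) and the sigmoid S midpoint above the S mean — i.e.
strong, recoverable effects. Every dataset ships a truth manifest with
the generating spec, parameters, expected shapes on the realized
deposition range, and true critical loads.

What passing recovery tests show: the estimation machinery (annealing,
AIC selection, classification, inversion) recovers known structure at
realistic sample sizes under the model's own assumptions. What they do
not show: robustness to the ways real inventory data violate those
assumptions — spatial autocorrelation among plots, measurement error in
biomass increments, heteroscedastic growth errors, panel revisit
designs, and deposition trends within the census interval (only the
interval mean enters). Conclusions about real forests still require the
real extracts.

`generate_shape_dataset()` draws stage-2 covariate rows and ordinal
outcomes from a known proportional-odds model (used for coverage and
equivalence checks; 268 units reproduces the scale of a national
survival analysis set), and `generate_phylogeny()` supplies Yule trees
with Brownian or tip-shuffled traits for the $K$ checks.

## Numerical choices and edge cases

* $-\infty$ objectives (infeasible survival brackets, non-positive
  $\sigma$) are rejections inside the optimizer, never exceptions; a
  unit whose entire search is infeasible is flagged non-converged and
  drops out of the candidate set.
* `aicc()` refuses $n \le k + 1$; `classify_n_shape()` refuses a
  degenerate deposition range; `critical_load_sigmoid()` signals (not
  clips) an unreachable reduction.
* Ingest validation rejects rows with BAL > BA, non-positive sizes or
  intervals, or non-finite covariates, and fails hard when more than 1%
  of rows are invalid.
* All output tables are plain CSV/JSON; reruns with the same seed are
  byte-identical, which the test suite asserts end to end.

## Problem sizes used by the checks

Chosen as this package's own test conditions: parameter recovery runs 20
replicates of 2,000 trees at a 20,000-iteration budget (recovering the
N peak within 15% relative error); selection-rule and detection
properties use 6–8 replicates of 700-tree units at 4,000 iterations;
ordinal coverage uses 100 replicates of 500 units; Brownian $K$ uses 50
simulations on 50-tip trees; the bundled end-to-end scenario is 4
species × 3 Divisions × 600 trees. The demonstration workflow under
`analysis/` uses 6 species × 4 Divisions × 700 trees at a 3,000-iteration
budget (a deliberate speed/recovery trade-off: its shape recovery is
partial, which the script reports honestly against the truth manifest).

## Known limitations

* The annealing optimizer has no gradient-refinement stage (by design);
  near-flat likelihoods (very wide modifiers) can leave location
  parameters imprecise at small budgets.
* The lognormal-S constraint ties $s_1$ to the observed minimum
  deposition, so its CL is range-dependent by construction.
* Shape classification is relative to the *observed* deposition range;
  the same fitted curve can classify differently in Divisions with
  different exposure windows. This is intended (vulnerability is a
  statement about the resident population) but worth remembering when
  comparing across Divisions.
* Stage-2 models treat species × Division rows as independent given
  covariates; the phylogenetic check quantifies, but does not correct
  for, residual relatedness.
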