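# forestcl

Tree species do not respond uniformly to atmospheric nitrogen (N) and
sulfur (S) deposition: modest N can fertilize growth while chronic N or S
loading acidifies soils and raises mortality, and the same species can
respond differently in different ecoregions. `forestcl` implements, as a
tested R package plus an analysis workflow, a two-stage approach to
quantifying that variation from forest-inventory remeasurement data and
to deriving **critical loads** — the deposition rate
(kg ha⁻¹ yr⁻¹) above which a harmful demographic effect begins.

It is aimed at forest ecologists and air-quality analysts working with
inventory-style data (remeasured trees with growth or survival outcomes,
plot competition, climate and deposition covariates). Because real
national extracts are large restricted compilations, the package ships a
synthetic-data module that generates inventory-like records **from the
same model equations with known parameters**, so the entire pipeline is
testable by parameter, shape, and critical-load recovery.

## The models

**Stage one** fits, per species × ecoregion Division, nonlinear response
models by simulated-annealing maximum likelihood. Growth
(kg C tree⁻¹ yr⁻¹) is a potential rate shaped by bounded multipliers:

    G ~ Normal( a · m^z · exp(a2·BAL + a3·ln BA) · g(T) · g(P) · [g(N)] · [s(S)] , σ² )

with `g(x; c1, c2) = exp(−½ [ln(x/c1)/c2]²)` a unimodal lognormal
modifier (peak `c1`, log-width `c2`) and
`s(S) = s3 + (1−s3)/(1 + (S/s1)^s2)` a declining sigmoid (midpoint `s1`,
steepness `s2`, plateau `s3`). Survival over a census interval of `dt`
years is Bernoulli with annual-survival bracket raised to `dt`, with two
competition representations. Seven growth and 13 survival candidate
models are compared by AIC; within a ΔAIC ≤ 4 candidate set the rule
prefers models separating N from S, and units whose N–S deposition
correlation is ≥ 0.7 with no separating candidate are excluded.

Fitted curves are classified on an ordered **vulnerability scale**
(increase < flat < unimodal/sigmoid < decrease) over the unit's observed
deposition range, and critical loads are read off as the N peak `n1`,
the lognormal-S location `s1`, or — for sigmoid S — by inversion at a
tolerated reduction `f` (defaults: 5% growth, 1% survival):

    CL = s1 · ( f / (1 − f − s3) )^(1/s2)

**Stage two** models the shapes as an ordinal outcome with
proportional-odds regressions (`P(Y ≤ j) = logistic(αj − x'β)`) against
Division-level climate normals, soil pH, long-term deposition, and
mycorrhizal/leaf-habit traits, with six hypothesis-driven interactions
and stepwise AIC selection; plus Fisher exact tests of shape × Division
distributions, ANOVA/Tukey covariate contrasts, and a Blomberg's *K*
phylogenetic-signal check on species-level residuals.

## Worked example

Generate one synthetic species × Division unit with a known N peak,
fit and select among the seven growth candidates, classify, and invert
the critical loads:

```r
library(forestcl)

sc  <- scenario_config("PIPO", "26", n_trees_per_unit = 1000, seed = 42)
gen <- generate_trees(sc)
gen$manifest[["PIPO|26"]]$growth$params$n1   # true N peak: 6.6

sel <- fit_unit(gen$trees, "growth",
                fit_config(iterations = 8000, restarts = 2,
                           min_trees = 500, seed = 42),
                species = "PIPO", division = "26")
sel$selected_fit
#> <fit> growth:base+N+Ssigmoid  logLik = -2002.89  AIC = 4033.77  n = 1000

classify_n_shape(sel, range(gen$trees$ndep_kgN_ha_yr))
#> [1] "unimodal_sigmoid"

cls <- unit_critical_loads(sel)
cls$N
#> <critical load> N basis: n1 6.517 kg ha-1 yr-1
cls$S
#> <critical load> S basis: sigmoid_inversion 1.73 kg ha-1 yr-1
```

The selected model is the generating family (base + lognormal N +
sigmoid S); the fitted N critical load 6.52 kg N ha⁻¹ yr⁻¹ recovers the
true peak 6.6 within 1.3%, and the fitted curve's interior peak
classifies as unimodal — some trees in the unit sit above the threshold
and respond negatively. The S critical load is the deposition producing
a 5% growth reduction on the fitted sigmoid.

## The analysis workflow

`analysis/01_simulate.R` … `05_report.R` drive a full demonstration
(6 species × 4 Divisions, 700 trees per unit): generate inputs, fit and
select all units, classify shapes and compute critical loads, run the
four ordinal vulnerability models with supporting tests, and reconcile
a run report. Each script prints what it found and writes its tables
under `results/demo/` (`fits.csv`, `selection.csv`, `shapes.csv`,
`cl.csv`, `ordinal_results.json`, `tests.csv`, `phylo_signal.json`,
`report.json`). Run them in order from the repository root:

    Rscript analysis/01_simulate.R
    Rscript analysis/02_fit_select.R     # ~7 min on one CPU
    Rscript analysis/03_shapes_critical_loads.R
    Rscript analysis/04_vulnerability.R
    Rscript analysis/05_report.R

The same flow is available as a single call (`run_pipeline()`), and a
bundled small scenario (`small_run_config()`) runs end to end in a few
minutes.

## Method vignette

`vignettes/forestcl-methods.Rmd` documents the model equations and
assumptions, fitting and selection rules, critical-load conventions, the
stage-2 ordinal models, what the synthetic generator does and does not
emulate about real inventory data, and the package's numerical choices
and limitations.
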