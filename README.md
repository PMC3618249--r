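# rulescale

Rule-based multi-scale qualitative simulation of drug effect pathways.

## What problem this solves, and for whom

Predicting what a drug — or a drug combination — does to a whole-body
phenotype requires crossing scales: a compound perturbs a molecular target
inside one cell type, but the diagnostic readout (here: blood glucose)
lives at the organ level, and quantitative kinetic parameters simply do
not exist above the pathway scale. `rulescale` is for systems
biologists and computational pharmacologists who want to wire curated,
direction-only knowledge ("when PRKAB1 rises in the hepatocyte, PEPCK
falls") into an executable multi-scale model, inject drugs, and read off
effect pathways and efficacy verdicts — without estimating a single rate
constant.

## The formalism

A model is a set of **components** (organs, cells, drugs) carrying typed
**attributes** with discrete states (`low < normal < high` for ordered
domains; `absent/present`, `close/open` for categorical ones), plus
condition→action **rules** over 5-tuples:

```
Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,AGRP,up
```

The condition `up` holds when the source attribute moved one level up or
is held at the top level; the action `up` moves the target one level up
(absorbing at the top). Dynamics are asynchronous and stochastic: each
step one satisfied rule is drawn uniformly at random and executed. Scale
separation comes from per-component **rule execution thresholds** TH(c)
with a firing-score accumulator RFS(c): each firing adds the rule's
effect score RS(r) (default 1.0), and the target state changes only when
RFS(c) ≥ TH(c), then resets. Defaults TH = 1.0 (molecule/cell/drug) and
TH = 60.0 (tissue/organ) make molecular rules single-hit while organ
attributes integrate 60 hits — a 60-fold timescale separation with no
clock. Monte Carlo ensembles (default 100 seeded runs) aggregate rule
firings into a drug-effect pathway graph and terminal-state efficacy
fractions. See `vignettes/rulescale-methods.Rmd` for the full account.

## Worked example

The packaged miniature type-2-diabetes model has beta-cell, hepatocyte,
adipocyte and muscle cells around a circulation organ, 22 anti-diabetic
drugs in three mechanistic classes, and persistent insulin-resistance
disease rules that hold blood glucose high and push back against therapy.

```r
library(rulescale)

fx <- build_t2d_fixture()
fx$model
#> <model_spec> 5 state domains, 27 components, 39 rules

ens <- run_ensemble(fx$model, fx$disease, drug_spec("metformin"),
                    n_runs = 100, base_seed = 1)
assess_efficacy(ens, fx$criterion, "normal")
#> <efficacy_result> metformin: Organ,circulation,metabolite,glucose == normal
#>   in 1 of runs -> effective (cutoff 0.5)

build_pathway_graph(ens)
#> <pathway_graph> 8 nodes, 13 edges, roots: Drug,metformin,presence,status

ctrl <- run_ensemble(fx$model, fx$disease, n_runs = 100, base_seed = 1)
assess_efficacy(ctrl, fx$criterion, "normal")
#> <efficacy_result> (no drug): Organ,circulation,metabolite,glucose == normal
#>   in 0 of runs -> not effective (cutoff 0.5)
```

Metformin normalises glucose in every run (fraction 1), the untreated
patient in none (fraction 0). The pathway graph is the metformin
mechanism traced from its target to the phenotype: drug → PRKAB1 →
{GLUT4 up; PEPCK, Glucose-6-phosphatase down} → circulation glucose
down; export it with `write_sif()` or `write_dot()`. Combination
screening over the catalogue:

```r
screen_combinations(fx$model, fx$disease, fx$drugs$name,
                    anchor = "metformin", k = 2,
                    criterion = fx$criterion, target_state = "normal",
                    n_runs = 100, base_seed = 1)
# 21 metformin pairs, sorted by efficacy fraction
```

A command-line interface mirrors the API (`simulate`, `ensemble`,
`screen`, `convert-ode`, `convert-petri`, `generate`, `validate`); see
`exec/rulescale` and `main()`. The fixture ships as plain-text input
files under `inst/extdata/t2d/`.

## Converters

`ode_to_rules()` extracts direction-only rules from an ODE system by
finite-difference sign analysis of each pairwise influence (monotone →
rule pair; sign change along the source axis → partitioned rules with
validity ranges; non-separable sign → reported unconvertible).
`petrinet_to_rules()` maps each Petri-net transition to one rule (inputs
→ conjunctive conditions, outputs → actions).

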