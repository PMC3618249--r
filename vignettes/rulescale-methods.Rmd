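---
title: "Rule-based multi-scale simulation: model, semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based multi-scale simulation: model, semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulescale)
```

## The modelling problem

Drug response is a multi-scale phenomenon: a compound binds a molecular
target inside one cell type, but the clinically relevant readout — blood
glucose, blood pressure, tumour burden — lives at the organ or whole-body
level. Quantitative whole-body models (large ODE systems) founder on the
lack of kinetic parameters above the pathway scale. `rulescale` takes the
qualitative route: every biological quantity is an **attribute** of a
**component** (an organ, cell, tissue or drug) holding one of a small set
of discrete states, and all dynamics are expressed as condition→action
**rules**

```
ComponentType,ComponentName,AttributeType,AttributeName,Condition ->
ComponentType,ComponentName,AttributeType,AttributeName,Action
```

read "when the source attribute is moving in this direction, push the
target attribute in that direction". Because rules are direction-only,
they can be curated from literature and pathway databases, or extracted
automatically from ODE and Petri-net models (see *Converters* below), and
freely mixed in one simulation.

## State domains and transition semantics

Each attribute type is governed by a `state_domain()`. Two kinds exist:

* **ordered** domains (genes, metabolites, hormones, processes) with a
  severity axis, canonically `low < normal < high`. The condition `up`
  holds on a (previous, current) state pair iff the state moved one level
  upward *or is being held at the top level*; `down` mirrors it at the
  bottom. The action `up` moves the state one level up with an absorbing
  top; `down` symmetrically.
* **categorical** domains (ion channels `close/open`, drug presence
  `absent/present`) with no axis: a condition labelled with a state holds
  iff the current state equals it, and an action sets the state.

Two consequences of the ordered semantics are worth spelling out. First,
conditions are judged on a one-step history, so the engine keeps every
attribute's previous state; a rule can distinguish "glucose is rising"
from "glucose is high". Second, the extremes are self-sustaining: a state
pinned at `high` keeps satisfying `up`. We implement this literal reading
deliberately — it is what lets a chronic process (insulin resistance held
`high`) act as a standing force rather than a single event. The
alternative, event-only reading (excluding the `high→high` pair) would
make every persistent rule fire at most once per upstream transition; if
you want that behaviour, model the source on a categorical domain
instead.

## Thresholds: one accumulator per component

Organs respond more slowly than enzymes. The platform encodes this with a
**rule execution threshold** `TH(c)` per component and a **rule firing
score** accumulator `RFS(c)`: each firing of a rule adds its **effect
score** `RS(r)` (default 1.0) to the accumulator of every component it
targets, and only when `RFS(c) ≥ TH(c)` is the action actually applied to
the target attribute, after which the accumulator resets to zero.
Defaults are `TH = 1.0` for molecules, cells and drugs and `TH = 60.0`
for tissues and organs: a molecular rule acts on its first firing, an
organ-level attribute changes only after 60 accumulated hits, giving the
two scales a 60-fold timescale separation without any real-time clock.

Numerical choices here, all switchable:

* **`≥`, not `>`.** The crossing test is `RFS ≥ TH`. A strict inequality
  with the default `RS = TH = 1.0` would leave molecular rules unable to
  act in a single firing, which contradicts the intended single-hit
  molecular semantics; `strict_threshold = TRUE` restores the literal
  strict reading for sensitivity analysis.
* **Reset to zero after crossing** (rather than carrying the overshoot):
  this prevents one crossing from subsidising the next and keeps the
  60-hit organ semantics meaningful.
* **Pooling per component.** The accumulator is per component, so all
  rules targeting any attribute of the circulation pool their scores —
  competing up- and down-regulating rules race for the crossing, and
  whichever lands the threshold hit applies *its* action.
  `rfs_per_attribute = TRUE` switches to per-attribute accumulators.
* **No decay.** Accumulated score persists while no rule fires; nothing
  in the formalism motivates a decay constant and we do not invent one.

## The asynchronous engine

Simulation state is initialised from the component file's domain defaults,
overridden by the disease file (the patient model) and by drug injection
(every presence attribute of an injected drug becomes `present` at t = 0
— injection is the event that starts the run). One step of the engine:

1. purge the active-rule set `AR(t)` of rules whose condition no longer
   holds on the (previous, current) pair — *stale* rules;
2. draw one rule uniformly at random from the satisfied remainder and
   execute it through the threshold machinery above;
3. form `AR(t+1)`: the satisfied non-fired rules, plus every rule newly
   enabled by this step's state changes, plus the fired rule itself if it
   is flagged `persistent` and still satisfied;
4. roll the one-step history forward.

The run ends when `AR` is empty (quiescence) or at `max_steps` (default
10 000 — the formalism has no natural clock, so the cap is a safety net,
not a model parameter). Random-order single-rule updating is what models
variable signal-propagation speed: on any given run the hepatic branch
may outpace the adipocyte branch or vice versa, and Monte Carlo
aggregation over runs recovers the ensemble behaviour.

One deliberate deviation from a draw-and-retry formulation: we purge all
stale rules *before* drawing rather than discarding them one at a time as
they happen to be drawn. The fired rule's distribution is identical
(uniform over the satisfied subset either way), but purge-first makes the
set of surviving rules a deterministic function of the configuration,
which in turn lets the brute-force oracle (below) enumerate exactly the
engine's reachable configurations. A rule purged as stale re-enters `AR`
whenever a later state change re-satisfies its condition.

Persistence deserves a note: a persistent rule conditioned on a sustained
extreme fires every step it is drawn, which is how a chronic disease
process (`insulin_resistance` held `high`) and a standing drug effect
compete; the uniform draw resolves the competition stochastically.
Determinism is strict throughout: `(model, disease, drugs, seed)` fixes
the trace bit for bit, and the engine's RNG is saved and restored around
every run so callers' random streams are untouched.

## Monte Carlo pathways, efficacy and screening

`run_ensemble()` repeats the run with seeds `base_seed + 0 … n_runs − 1`
(default 100 runs). From an ensemble:

* `build_pathway_graph()` draws one directed edge per (LHS attribute, RHS
  attribute) pair of each rule, labelled with the rule id, the effect
  direction and the **firing frequency** — the fraction of runs in which
  the rule fired at least once. A per-run indicator (not a firing count)
  is used so that long traces do not dominate the aggregate. Edges under
  `min_frequency` (default 0.05) are pruned and only nodes reachable from
  the injected drug roots are kept: the result is the drug-effect pathway
  from target to phenotype. Exports: SIF and Graphviz DOT, in
  deterministic order.
* `assess_efficacy()` reads the diagnostic criterion — for the diabetes
  model, blood glucose in the circulation — in each terminal state and
  calls the drug set *effective* when the target state is reached in at
  least `cutoff` (default 0.5, `≥` at the boundary) of the runs.
* `screen_combinations()` evaluates every k-subset of a drug catalogue
  (or anchor + (k−1)-subsets) with one ensemble per combination.
  Synergy versus additivity is *not* classified — the efficacy criterion
  for a combination is the same terminal-state criterion as for a single
  drug, nothing more.

## Converters

**ODE systems.** The converter asks only for the *sign* of each
variable-to-variable effect. For source s and target x it estimates
∂(dx/dt)/∂s by central finite differences (half-step `1e-4` of the source
range) at every point of a 7-per-dimension full-factorial grid over the
declared variable ranges; effects below `zero_tol = 1e-9` count as zero.
A uniformly positive sign emits the activation pair `s up → x up`,
`s down → x down`; uniformly negative the crossed pair. Mixed signs are
usable only when the sign depends on the source value alone: then the
sign-change point is bracketed on the grid and located by bisection on
the 1-D finite-difference estimate (other variables held at range
midpoints), and each sub-interval emits its pair with the validity range
recorded in the rule provenance. If the sign depends non-separably on
other variables the pair is reported *unconvertible* and nothing is
emitted — a wrong-direction rule is worse than a missing one. The grid
defaults trade resolution against cost; the breakpoint is recovered to
within one grid cell on polynomial systems, which is as precise as a
direction-only formalism can use.

**Petri nets.** A transition *is* the changing action: each transition
maps to one rule with input places (and their condition labels) as the
conjunctive LHS and output places as the RHS. Token/marking dynamics are
deliberately not simulated — the rule engine replaces them.

## The packaged diabetes model

`build_t2d_fixture()` reconstructs a miniature type-2-diabetes model:
beta-cell, hepatocyte, adipocyte and muscle (TH 1.0) around a circulation
organ carrying glucose and insulin (TH 60.0), with a 22-drug catalogue in
three mechanistic classes — metformin through hepatic PRKAB1 (raising
GLUT4, repressing PEPCK and Glucose-6-phosphatase, relieving hepatic
insulin resistance), the three glitazones through adipocyte PPARG
(relieving adipocyte/muscle insulin resistance, raising muscle glucose
uptake), and the remaining 18 drugs wired at class level as beta-cell
secretagogues that raise circulating insulin. The patient model sets
circulation glucose and the three tissue insulin-resistance processes
`high`; three persistent disease rules push glucose back up whenever a
drug pulls it down.

What the fixture does and does not establish: it is an explicit
reconstruction at drug-class resolution, not a recovered curated rule
base. Mechanistic detail below the class level (incretin pathways,
alpha-glucosidase action in the gut, amylin signalling) is deliberately
collapsed onto the secretagogue axis, so a green "all 22 drugs effective"
test establishes that the *platform* propagates each wiring to the
phenotype under threshold competition — not that the wiring is
pharmacologically complete. Glucose-gated effector rules (conditioned on
glucose still being `up`) make every treated run quiesce once glucose
normalises; the untreated patient quiesces immediately with glucose high,
because the disease rules only engage to *oppose* a fall.

## The random generator and the oracle

`generate_random_model()` is first-class, tested code: a seeded generator
of valid models at chosen scale counts, with optional guaranteed
drug-to-phenotype rule chains. For oracle comparisons it is used with
`persistent_fraction = 0` and acyclic wiring (every rule points forward
in a fixed attribute order), because set-equality between sampled and
enumerated terminal states is only well-defined when every firing order
quiesces; cyclic and persistent behaviour is exercised separately against
the `max_steps` cap and the oracle's `partial` flag.

`brute_force_reachable()` enumerates every firing order by depth-first
search with configuration memoisation, *sharing* the engine's
condition/threshold/firing implementation (`fire_pure`, `next_active`) so
it tests scheduling, not semantics drift. On ≤6-rule models the terminal
set observed over 500 seeded engine runs equals the enumeration exactly
(and is contained in it at any sample size). Self-sustaining cycles are
cut by memoisation and simply contribute no quiescent terminal;
configurations that never repeat (an ever-filling organ accumulator) are
cut by `max_depth` and flag the result partial.

## Known limitations

* Three ordered levels only are exercised; `state_domain()` accepts more
  but no packaged model uses them.
* No continuous time, rates or propensities: steps are events, and the
  60-hit organ threshold is the only timescale device.
* No dose: a drug is present or absent.
* Combination screening reports the same terminal-state criterion as
  single drugs; synergy/additivity classification is out of scope.
* The ODE converter's grid is full-factorial and so exponential in the
  variable count; it is intended for the small hand-written systems the
  direction-only abstraction suits.
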