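---
title: "Constraint-based analysis with fbatools: models, conventions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis with fbatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbatools)
```

## The model

A stoichiometric model is a metabolic network summarized by its
stoichiometric matrix $S$ (one row per non-boundary metabolite, one column
per reaction) together with flux bounds $l \le v \le u$ (mmol·gDW⁻¹·h⁻¹ by
convention; dimensionless to the solver). At steady state, internal
metabolite pools neither accumulate nor drain, giving the flux cone
$\{v : S v = 0,\; l \le v \le u\}$. Boundary metabolites are exempt from
mass balance, so their rows are dropped. **Flux balance analysis (FBA)**
optimizes a linear objective $c^\top v$ (typically a single sink or biomass
reaction) over that cone.

Three companion analyses share the same linear program:

* **Flux variability analysis (FVA)** minimizes and maximizes each flux
  separately subject to near-optimality of the objective,
  $c^\top v \ge f \cdot z^\*$ for maximization objectives, with
  $f \in (0, 1]$ (default 1). Two LPs per reaction.
* **Flux-sum minimization** re-solves for the flux vector of smallest
  $\sum_r |v_r|$ that still attains $z^\*$. Each flux is split into
  nonnegative forward and backward parts $v = p - q$, which keeps the
  problem linear and, at the optimum, makes $\min(p_r, q_r) = 0$
  automatically. Futile cycles — loops that carry flux without affecting
  the objective — collapse to their net flux. The split bounds preserve
  the original box: reactions with $l \ge 0$ pin $q = 0$, those with
  $u \le 0$ pin $p = 0$.
* **Producibility** asks whether a metabolite can be made at all: a
  temporary demand reaction $\{m: -1\}$ with bounds $(0, 1000)$ is added,
  its flux maximized (the model objective is ignored), and the metabolite
  is called producible when the maximum exceeds $10^{-6}$. The model is
  never mutated; all analyses operate on working copies of the matrices.

## Sensitivities and sign conventions

Optimal solves report two dual quantities:

* **Shadow prices** (right-hand-side sensitivities): $\partial z /
  \partial b_i$ for a perturbation $S v = b$ of metabolite $i$'s balance,
  in the problem's own optimization sense — no sign flip for minimization.
  Note the orientation: a *positive* $b_i$ demands net accumulation of the
  metabolite, so on a producing pathway the shadow price is typically
  negative (supplying the metabolite for free, $b_i < 0$, raises the
  objective).
* **Reduced costs**: $\partial z / \partial(\text{active bound})$ of each
  reaction, i.e. the marginal objective gain from relaxing the bound the
  flux currently sits on; zero for basic (interior) fluxes.

Both are whatever optimal dual the solver lands on. On degenerate models
alternate optimal duals exist; the test fixtures used for the
finite-difference checks (the linear chain and futile-cycle models) were
chosen because their duals are unique.

## The solver

No linear-programming backend with dual reporting is part of this
package's dependency set, and exact duals under the conventions above are
the point of the exercise, so the solver is implemented here: a
two-phase bounded-variable revised simplex. Phase 1 drives signed
artificial variables to zero (their residual sum above $10^{-7}$ means
infeasibility, which is reported as a status plus a warning, never an
exception — as is an unbounded objective); phase 2 optimizes the true
objective with artificials pinned at zero. Numerical choices:

* pivot tolerance $10^{-9}$ at the solver; the API promises $10^{-6}$
  (mass-balance residual, bound violations, objective preservation), which
  decouples backend precision from the contract;
* the basis inverse is updated by rank-one pivots and refactorized from
  scratch every 60 pivots to cap drift;
* Dantzig (most-violating) pricing with ratio-test ties broken toward the
  largest pivot magnitude; after $10 \cdot n_{vars} + 200$ iterations the
  rule switches to Bland's smallest-index, which guarantees termination on
  degenerate problems;
* all variable bounds must be finite except where an analysis knowingly
  introduces a capped auxiliary (the FVA optimality slack is bounded by
  $\sum_j |c_j| \max(|l_j|, |u_j|) + 1$, which no feasible $c^\top v$ can
  exceed).

The flux-minimization LP fixes the objective as an equality row at the
computed $z^\*$. A 1000-reaction network solves in a few seconds; the
dense basis-inverse representation is the main scale limit (practical to
a few thousand reactions, far above the package's fixture sizes).

## SBML dialects

Three dialects are read; two are written.

* **L3_FBC**: SBML Level 3 with the Flux Balance Constraints package.
  FBC v2 is targeted as the surviving standard. Bounds are parameters
  referenced per reaction, objectives and gene-product associations are
  FBC elements.
* **L2_NOTES**: SBML Level 2 with COBRA-style `KEY: value` lines in
  reaction notes — `LOWER_BOUND`, `UPPER_BOUND`, `OBJECTIVE_COEFFICIENT`,
  `FLUX_VALUE`, `GENE_ASSOCIATION` (also spelled `GENE ASSOCIATION`),
  `SUBSYSTEM`, `PROTEIN_CLASS` (EC numbers), `KEGG ID`; matching is
  case-insensitive. This dialect cannot encode an objective direction, so
  a model-level note line `OBJECTIVE_DIRECTION: maximize|minimize` is
  emitted and parsed (maximize is the default on read).
* **PLAIN**: bare stoichiometry. Constraints are synthesized so the result
  is always runnable: $(-1000, 1000)$ for reversible reactions,
  $(0, 1000)$ for irreversible — the community's conventional
  effectively-unbounded sentinels. No objective is invented; analyses
  refuse to run until the user sets one, mirroring the intended workflow.

Further import conventions: a reaction is flagged as an exchange when it
has a single stoichiometric entry or an `EX_` id prefix (covers BiGG-style
models); note lines that parse as none of the recognized keys are
preserved verbatim and re-emitted on export, so no metadata is ever
dropped; bounds imported in the wrong order are swapped with a warning so
a loaded model never violates `lower <= upper`; gene associations are
written both as FBC trees and as note lines, and the note line wins on
read, which keeps raw association strings byte-identical across round
trips. Canonical model equality (`models_canonically_equal()`) compares
id sets, stoichiometries, bounds within $10^{-9}$, objectives, and
associations by parsed tree.

## Editing and structural diagnostics

Editing operations (`set_bounds()`, `set_objective()`,
`add_exchange_reaction()`, `assign_compartment()`, `rename_entity()`, ...)
validate the full model after every mutation and leave it untouched on
error. New exchange reactions use coefficient $-1$, so positive flux is
excretion and negative flux uptake — the dominant community convention.
The batch grammar is one whitespace-tokenized command per line with `#`
comments; execution is transactional per line: the first failure stops
the script, earlier edits persist, and the log records the line number.
This matches an interactive editing session; a full-rollback mode would
be a wrapper that discards the returned model when `ok` is `FALSE`.

Two diagnostics deserve their definitions spelled out:

* **Dead-end (orphan) metabolites** are found bound-aware, not merely
  topologically: a reaction produces a metabolite only if it has a
  positive coefficient *and* can run forward (`upper_bound > 0`), or a
  negative coefficient *and* can run in reverse (`lower_bound < 0`). An
  irreversible consumer therefore never counts as a producer, which a
  purely topological scan would miss.
* **Synonymous reactions** are grouped on exact stoichiometry maps, or
  exact after global negation (the same conversion written backwards).
  Scalar multiples (`2A -> 2B` vs `A -> B`) are deliberately *not*
  merged: under shared bounds they have different flux semantics.

## Gene associations and knockouts

Associations follow the COBRA-era grammar: identifiers, case-insensitive
`and`/`or`, parentheses, with `and` binding tighter than `or`; `NOT` is
not part of the dialect. Parse errors carry a character offset. Empty or
unparseable strings are treated as *no association* — such reactions are
never disabled — with the raw string preserved, in keeping with the
permissive-import philosophy. A knockout evaluates every association with
the knocked genes set to false and zeroes both bounds of failing
reactions on a deep copy; the session model is never mutated. Genes
absent from every association warn (per gene) rather than error, and the
result reports the knockout/wild-type objective ratio with $0/0 \to 0$.

## Pathway maps

The layout is a layered, KEGG-like top-to-bottom scheme chosen for
determinism and testability: metabolites are ranked by longest path from
the selection's source metabolites (those only consumed within it; on a
fully cyclic selection the lexicographically first metabolite seeds rank
0, and rank growth is capped at the metabolite count so cycles
terminate); reactions sit midway between their substrate and product
layers, single-sided reactions half a layer outside; within each layer,
entities are ordered by the barycenter of their neighbors over three
sweeps to reduce crossings, ties broken lexicographically. A user layout
TSV (`entity_id`, `x`, `y`) overrides any subset of positions; unknown
ids are skipped with a warning.

Rendering is pure text generation: identical inputs give byte-identical
SVG. Flux is encoded redundantly — stroke width interpolates $|v|$
linearly from $[0, \max|v|]$ into the configured width range, color
diverges by sign, magnitudes at or below `zero_epsilon` are dashed, and
the signed value is printed. A reversible reaction carrying negative flux
flips its arrowhead but keeps its reference direction in the printed
(signed) label. KEGG ids become `xlink` hyperlinks to the compound or
reaction entry page; no network access happens at render time. Currency
metabolites are drawn once wherever they occur; KEGG-style duplication of
ATP-like hubs is out of scope.

## Fixtures and what the tests show

The demo model is a deterministic glycolysis-style toy: a glucose
exchange at uptake bound 10, a transport step, ten internal reactions
over two subsystems, the PFK/FBPase futile pair, gene associations on
five enzymes, and KEGG compound ids on key metabolites. Its objective is
deliberately unset so the set-objective-then-run workflow is exercised.
With the pyruvate sink as objective the optimum is 20 (two pyruvate per
glucose).

The random-model generator emulates the *shape* of small metabolic
networks — a connected conversion backbone, extra random links, some
reversible, one intake and one outflow exchange, every bound finite and
containing zero — at sizes where a brute-force vertex-enumeration oracle
is exact. The test suite compares FBA and FVA against that oracle on 50
seeded models of 4–6 reactions, checks every shadow price by
finite-difference re-solves, and runs one ~1000-reaction instance as a
scale check (steady-state residual below $10^{-6}$). These sizes are the
package's own choice of exhaustive-verifiability over realism: the
generator does not emulate biomass compositions, cofactor coupling,
compartmentalized transport, or the degeneracy structure of genome-scale
reconstructions, so passing tests certify the algorithms and conventions,
not biological conclusions drawn from any particular reconstruction.

## Known limitations

* Dense matrices throughout; genome-scale models load and solve but a
  sparse backend would be preferable beyond a few thousand reactions.
* Dual values on degenerate models are one valid choice among many.
* No MOMA or other quadratic objectives, no thermodynamic loop-law
  constraints, no kinetic laws, events or rules from SBML, and no
  KEGG-derived model construction.
* The L2 notes dialect stores the objective direction in a model-level
  note; other tools will default to maximize when they ignore it.
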