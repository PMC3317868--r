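# fbatools

Constraint-based analysis of stoichiometric metabolic models in R: load,
edit and export SBML models, run flux balance analysis with full
sensitivity output, simulate gene knockouts, and draw interactive SVG
pathway maps — all from a library API or a small command-line tool.

It is aimed at modelers who want a desk-scale, scriptable companion to
the usual constraint-based workflow: import a reconstruction (or a bare
stoichiometry), set bounds and an objective, run the analyses, and export
tables and maps.

## What it computes

A metabolic network is its stoichiometric matrix *S* (metabolites ×
reactions) plus flux bounds. At steady state, feasible flux vectors
satisfy

    S v = 0,   lb ≤ v ≤ ub

* **FBA** — maximize (or minimize) an objective `c'v` over that set, with
  **shadow prices** (∂z/∂bᵢ of each metabolite balance) and **reduced
  costs** (∂z/∂bound of each reaction) from the solver's duals.
* **FVA** — per-reaction min/max flux subject to `c'v ≥ f·z*`, `f ∈ (0,1]`.
* **Flux-sum minimization** — the flux vector of smallest Σ|v| that still
  attains z*, via forward/backward flux splitting; removes futile cycles.
* **Producibility** — maximal rate of a temporary demand reaction per
  metabolite.
* **Knockouts** — boolean gene–protein–reaction expressions (`and`/`or`,
  parentheses) evaluated under a knockout set; failing reactions are
  closed and the model re-solved.
* **Structure** — dead-end (orphan) metabolites under bound-aware
  directionality; synonymous reactions (identical stoichiometry up to
  global negation).

All linear programs are solved by the package's bounded-variable
two-phase revised simplex, which reports exact optimal duals. SBML is
read in three dialects (Level 3 + FBC, Level 2 with COBRA-style notes,
and plain stoichiometry, which is auto-constrained on import) and written
in the first two.

## Worked example

```r
library(fbatools)

model <- set_objective(demo_model(), "EX_pyr_e")  # glycolysis toy, pyruvate sink
res <- run_fba(model)
res
#> Flux analysis result: status optimal
#>   objective (maximize): 20
#>   total |flux|: 150
#>   nonzero fluxes: 11 of 12
```

Two pyruvate per glucose at an uptake bound of 10 gives the optimum 20.
A plain FBA solution is free to route flux through the PFK/FBPase futile
cycle (any amount changes nothing downstream); flux-sum minimization
certifies the cycle-free distribution whatever vertex FBA happened to
return:

```r
pf <- minimize_total_flux(model)
pf$total_flux
#> [1] 150
pf$fluxes[c("PFK", "FBP")]
#> PFK FBP
#>  10   0
```

FVA shows how free that cycle is at the optimum, knockouts use the gene
associations, and the map renders the solution:

```r
run_fva(model, reactions = c("PFK", "FBP"))
#>   reaction min_flux max_flux
#> 1      PFK       10     1000
#> 2      FBP        0      990

simulate_knockout(model, c("g_hk1", "g_hk2"))$objective_ratio
#> [1] 0    # both hexokinase isoenzymes gone: no glycolysis

svg <- render_svg(model, layout_pathway(model, "Glycolysis"), run_fba(model))
write_svg(svg, "glycolysis.svg")   # interactive map with KEGG hyperlinks
```

The same workflow is available from the shell via the installed
`exec/fbatools` script:

```sh
fbatools demo --out demo.xml
fbatools fba --model demo.xml --objective EX_pyr_e --out-tsv fluxes.tsv --out-svg map.svg
```

Exit codes: 0 success, 2 validation error, 3 infeasible/unbounded, 64
usage.

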