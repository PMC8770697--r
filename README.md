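# fluxspan

Constraint-based modeling of how oxidative stress rewires gut-microbe
metabolism, and of host–microbe metabolic interactions in colorectal
cancer.

## The problem

Reactive oxygen and nitrogen species (superoxide, hydroxyl radical,
nitric oxide) attack amino acids, nucleotides and the cellular folate
pool. For a gut bacterium under nanoparticle-induced oxidative stress,
the metabolic consequences ripple far beyond the damage reactions
themselves — and some of them (elevated folate secretion, altered
short-chain-fatty-acid output) matter directly for the colonic
epithelium and for colorectal-cancer (CRC) chemoprevention. Wet-lab
assays cannot watch every pathway at once; genome-scale constraint-based
models can.

`fluxspan` implements that modeling workflow as a tested R package:

* a tidy **metabolic model container** (reactions/metabolites as
  tibbles; TSV, JSON and SBML L3+FBC readers and writers),
* the optimization engines — **FBA**, **FVA**, minimum-norm optimal
  flux distributions, blocked-reaction and dead-end detection, leak
  tests — over a built-in bounded-variable simplex with exact duals,
* **quality-controlled model expansion**: grafting a curated
  reactive-species reaction set onto a model, then auto-debugging the
  blocked additions with demand/sink reactions, every step captured in
  a replayable curation log,
* the **flux-span-ratio (FSr)** comparison statistic with
  classification and hypergeometric flux-enrichment analysis,
* **iMAT context-specific model extraction** from categorical
  protein-expression evidence (a MILP solved by branch and bound),
* **host–microbe pairing** through a shared lumen compartment with
  optional growth-coupling constraints, interaction FVA and secretome
  profiling,
* deterministic **toy generators** (microbe, host, reactive-species
  fixture, planted expression evidence) whose ground truth is derivable
  by hand, so every pipeline stage is testable end to end.

## The statistic

For each reaction *i*, FVA yields the span of attainable flux at
optimality fraction γ:

```
span_i = v_i^max − v_i^min   subject to  S·v = 0,  lb ≤ v ≤ ub,  c·v ≥ γ·Z*
```

The flux span ratio compares a reference condition A ("healthy") with a
perturbed condition B ("disease"):

```
FSr_i = span_i(A) / span_i(B)
```

Reactions with FSr outside the band [0.8, 2] are *affected*: FSr < 0.8
means the perturbation widened the reaction's attainable flux range
(`increased_in_b`), FSr > 2 means it narrowed (`decreased_in_b`). The
affected set is then interrogated by subsystem enrichment
(hypergeometric upper tail, Benjamini–Hochberg adjusted) and by
minimum-norm flux differences.

The iMAT extraction solves, over binaries y⁺, y⁻ (activation of a
high-evidence reaction forward/backward at flux ≥ ε) and z (silencing of
a low-evidence reaction):

```
max Σ_{i∈R_H} (y⁺_i + y⁻_i) + Σ_{i∈R_L} z_i
s.t. S·v = 0,  lb ≤ v ≤ ub,
     v_i + y⁺_i(lb_i − ε) ≥ lb_i,   v_i + y⁻_i(ub_i + ε) ≤ ub_i,  y⁺_i + y⁻_i ≤ 1   (i ∈ R_H)
     lb_i(1 − z_i) ≤ v_i ≤ ub_i(1 − z_i)                                             (i ∈ R_L)
```

Community models couple each organism reaction j to its organism's
biomass: |v_j| ≤ c·v_bio + u (defaults c = 400, u = 0.01).

## Worked example

The built-in perturbation pair is the study design in miniature: a toy
gut microbe before and after expansion with an 8-reaction / 11-metabolite
reactive-species set plus the demand/sink reactions its debugging adds.

```r
library(fluxspan)

microbe <- toy_microbe()
fba(microbe)
#> <flux_solution> status: optimal, objective: 6.666667

pair <- perturbation_pair()
fva_ref <- fva(pair$model_a, gamma = 1)
fva_ros <- fva(pair$model_b, gamma = 1)
fsr <- classify_fsr(flux_span_ratio(fva_ref, fva_ros), low = 0.8, high = 2)
affected_reactions(fsr)
#> # A tibble: 3 × 5
#>   reaction_id span_a span_b   fsr class
#>   <chr>        <dbl>  <dbl> <dbl> <chr>
#> 1 R_dhfsyn     0.500   2.67 0.187 increased_in_b
#> 2 R_dhfr      0.500   2.67 0.187 increased_in_b
#> 3 R_folrel     0.500   2.67 0.187 increased_in_b

head(flux_enrichment(affected_reactions(fsr)$reaction_id, pair$model_a), 2)
#> # A tibble: 2 × 7
#>   subsystem                 k     K     n     N       p p_adjusted
#>   <chr>                 <int> <int> <int> <int>   <dbl>      <dbl>
#> 1 Folate metabolism         3     6     3    32 0.00403     0.0363
#> 2 Amino acid metabolism     0     3     3    32 1           1
```

Reading the numbers: the microbe grows at 6.67 mmol/g-DW/h on its rich
medium. After the reactive-species expansion, exactly three reactions
change their flux span — dihydrofolate synthesis, dihydrofolate
reductase and folate release. Their spans widen from 0.5 to 2.67 flux
units (FSr ≈ 0.19 < 0.8, class `increased_in_b`): the new oxidative
drain on the folate pool lets the folate branch carry up to fivefold
more flux at the unchanged growth optimum. The affected set is
significantly enriched in the folate subsystem (p ≈ 0.004). This is the
package's planted ground truth — `pair$truth` records the same three
reactions — and the same logic applies unchanged to genome-scale models
supplied via `read_model()`.

Higher-level entry points run whole studies:
`run_ros_workflow()` (expand → debug → FVA ×2 → FSr → minNorm →
enrichment), `run_host_workflow()` (expression evidence → iMAT →
context models → biomass comparison → secretome) and
`run_community_workflow()` (pairing, diet, interaction FVA, secretome
classification matrix). Each returns tidy tables, writes a reproducible
TSV bundle when given an output directory, and records its resolved
configuration.

## Documentation

The methods vignette (`vignettes/fluxspan-methods.Rmd`) describes the
model formulations, the tunable parameters and their defaults, what the
toy generators do and do not emulate, and the package's numerical
choices and limitations.
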