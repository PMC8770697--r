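---
title: "Methods: flux-span comparison of stressed and context-specific metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flux-span comparison of stressed and context-specific metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxspan)
```

## The modeling framework and its assumptions

Everything in this package rests on the steady-state constraint-based
view of metabolism: a network of `n` reactions over `m` metabolites is
summarised by its stoichiometric matrix `S` (m × n), and a physiological
state is a flux vector `v` (mmol per gram dry weight per hour) with

* mass balance, `S v = 0` — internal metabolite pools neither
  accumulate nor drain;
* capacity bounds, `lb ≤ v ≤ ub` — thermodynamic direction and
  transporter/enzyme capacity, with reversibility encoded purely by
  `lb < 0`;
* boundary pseudo-reactions — exchanges (`EX_`, one metabolite,
  secretion-positive: negative flux is uptake), demands (`DM_`, forced
  consumption-only drains) and sinks (`SK_`, reversible unconstrained
  supplies).

Flux balance analysis (`fba()`) maximises a linear objective `c·v`,
normally the flux of a biomass pseudo-reaction. The assumptions worth
keeping in mind: growth is the right objective only for unicellular
growth states (for mammalian tissue models the iMAT extraction below
deliberately does *not* impose one during extraction); bounds, not
kinetics, are the only rate information; and alternative optima are the
rule, not the exception, which is why the package leans on variability
(FVA) and minimum-norm representatives rather than single FBA solutions.

## Flux variability and the span ratio

`fva()` minimises and maximises each reaction flux subject to retaining
a fraction γ of the optimum: `c·v ≥ γZ* − 1e-6·max(1, |Z*|)`. The small
absolute slack prevents a floating-point optimum from emptying the
feasible set; `gamma = 0` means *no* objective floor, the setting used
for blocked-reaction detection (`find_blocked_reactions()`: a reaction
is blocked when its γ=0 span lies within 1e-6 of zero in both
directions).

The flux span ratio between a reference model A and a perturbed model B
is `FSr_i = span_i(A)/span_i(B)` per shared reaction. Three numerical
conventions:

* spans below the tolerance (default 1e-6) in both conditions make the
  record *degenerate* — a ratio of two numerical zeros carries no
  information and is excluded from classification;
* a vanishing span in B alone yields `FSr = Inf` (a genuinely
  collapsed reaction), kept and classified as `decreased_in_b`;
* reactions present in only one model (the perturbation's own new
  reactions, their debugging demands) are reported in attributes, never
  silently dropped and never classified.

The affected band is the complement of `[0.8, 2]`. The interval is
stated in the source analyses in a form ("0.8 > FSr > 2") that is empty
if read literally; the only reading under which any reaction can be
affected is FSr < 0.8 *or* FSr > 2, and that is what `classify_fsr()`
implements, with both thresholds exposed as arguments. Likewise the
statistic's name says *span* while the describing text says "absolute
flux values"; the span definition is the primary mode, and
`flux_span_ratio(mode = "maxabs")` provides the max-|flux| alternative
for sensitivity analysis.

FSr is anti-symmetric (swapping conditions maps finite ratios to their
reciprocals and swaps the increased/decreased classes) — this is a
tested invariant, as is the exact partition of non-degenerate records.

## Minimum-norm flux distributions

Among the alternative optima at `c·v = Z*`, `min_norm_solution()`
returns the flux vector of minimal Euclidean norm — a strictly convex
quadratic program solved with `quadprog`, after reducing the equality
rows of `S` to an independent set by QR. The Euclidean choice follows
the conventional toolbox meaning of a minimum-norm optimum: it splits
symmetric parallel routes evenly and assigns exactly zero flux to
thermodynamically spurious internal cycles, both of which are tested
against small grid/symmetry oracles. A 1-norm variant (an LP on split
variables) is available where a sparser representative is wanted. The
optimum is held by a two-sided constraint with slack
`1e-8·max(1, |Z*|)` so the QP never becomes infeasible by rounding.

## The optimization engines

No LP/MILP library is assumed: the package carries its own dense
two-phase bounded-variable simplex (`solve_lp()`), with Dantzig pricing,
a Bland anti-cycling fallback after a run of degenerate pivots, and
lowest-index tie-breaks throughout, so that the pivot sequence — and
hence the reported optimal vertex among alternative optima — is
deterministic across runs and platforms. It returns exact row duals
(metabolite shadow prices) and reduced costs; a duality identity test
(`Z* = y·b + d·x`) guards the sign conventions. The iMAT MILP is solved
by depth-first branch and bound over the activity binaries
(`solve_milp()`), branching on the lowest-index fractional binary and
exploring the rounded-up child first — again fully deterministic.

Because these engines are home-grown, the package also ships an
independent brute-force reference: `enumerate_vertices()` enumerates
every basic feasible solution of a small bounded system, and
`brute_force_lp()` / `imat_brute_force()` optimise by exhaustion. The
test suite and the acceptance script cross-check `fba()`, `fva()`,
blocked detection and `imat_extract()` against these oracles on
families of randomly generated instances (kept at ≤ 10 reactions, where
enumeration is exact and fast); agreement is at 1e-6.

Feasibility tolerance is 1e-6 on `‖S v‖∞` and 1e-9 on bounds; both are
asserted on every fixture in the tests.

## Curation: expansion, debugging, replay

`expand_with_ros()` adds a curated reaction set under quality control
(`add_reactions_qc()`): new metabolites are registered before any
reaction that uses them, duplicates by id *or* by identical
chemistry+bounds are skipped with a logged reason, and an id collision
with different content is a hard error. Each added reaction is
immediately tested for blockage.

`unblock_reactions()` mirrors the manual debugging protocol: prefer
literature reactions when supplied (`literature_first`), otherwise add a
demand for each dead-end product and a sink for each dead-end reactant
of the blocked reaction — greedily, re-testing after each addition, in
id-sorted order with lexicographic tie-breaks (no selection rule is
inherent to the protocol, so determinism is imposed). Demands default to
`[0, 1000]`, sinks to `[-1000, 1000]`; both are configurable. Additions
carry the reason "no literature evidence". Reactions that remain blocked
after all candidates are exhausted are reported, never dropped.

Every mutation appends to a `curation_log`, and
`replay_curation_log()` re-applies a log to the base model; replay
reproducing the curated model field-for-field (and byte-for-byte through
serialisation) is a tested invariant. `apply_medium()` is idempotent and
closes uptake through unlisted exchanges by default, so a medium table
is the complete statement of nutrient availability.

## Context extraction from categorical evidence

Protein-atlas-style evidence is categorical (high/medium/low/NA per
gene). GPR rules are evaluated on the ordinal scale low < medium < high
with AND = min and OR = max *over the genes whose category is known*: an
unmeasured gene does not veto an otherwise supported reaction, and a
rule with no measured gene leaves the reaction uncategorized. High and
medium map to the core-active set (matching the convention that both
levels indicate presence in the tissue); low maps to core-inactive;
literature-curated upregulated genes enter as overrides to high.

`imat_extract()` then maximises the number of satisfied evidence terms
(formulation in the README). Numerical choices: ε defaults to 1 flux
unit (the activation threshold is not stated by the protocols this
follows; 1 is well inside every toy bound and scales with the uptake
normalisation below), infinite bounds are clamped to ±1000 before the
MILP, and the biomass reaction is never scored as core-inactive — the
context model always retains it. Activity is reported from the first
optimal witness of the deterministic search; on instances with at most
a dozen evidence reactions the optimum is verified against exhaustive
enumeration. The objective is monotone non-increasing in ε (tested).

`build_context_model()` removes silenced reactions, optionally adds
literature transporters, prunes reactions the removals left blocked
(removal of a blocked reaction cannot block anything else, so one pass
suffices), rescues a blocked biomass via the debugging protocol, and
attaches a full sanity report. With `repair = FALSE` the blocked
remainder is retained but reported.

## Host–microbe pairing

`pair_models()` merges two organisms through a shared lumen `[u]`: each
organism-level extracellular exchange becomes a reversible
intercellular transport (±1000) between the organism's `[e]` species
and the canonical lumen species, one community exchange per lumen
species carries the diet, and host body-fluid `[b]` exchanges survive
untouched so the host secretome remains readable. The merged reaction
count is `n_host + n_microbe + (number of distinct lumen species)`. The
community objective defaults to host biomass; coupling constraints
`|v_j| ≤ c·v_bio + u` (defaults c = 400, u = 0.01, the community-model
convention) are attached to microbe reactions by default and ride on
the model through every LP-based analysis. Whether to couple at all is
left to the caller — both modes are first-class and tested — because
coupling is optional in the community-modeling convention this follows.

Tested invariants: lumen mass balance at every optimum; pairing
neutrality (a paired model with its microbe closed reproduces the
standalone host optimum to 1e-6); coupling monotonicity (smaller c
never widens an organism span); organism attribution is a partition.

## What the toy generators emulate — and what they do not

`toy_microbe()` (~32 reactions) and `toy_host()` (~29) are
hand-designed templates, not random graphs: every optimum and span used
as an expected value is derivable with pencil and paper. Flux units are
normalised to a maximal uptake of 10, so the hand numbers stay small
rationals (microbe optimum 20/3, host optimum 5). The microbe carries
the structural roles of the study organism: glucose/serine uptake,
ATP-yielding glycolysis, SCFA (butyrate-like) secretion, a folate cycle
with a capacity-limited exporter, folate-dependent nucleotide synthesis
with an exporter (the cross-feeding currency), and the amino-acid,
nucleotide and folate pools the reactive-species fixture attacks. The
host adds a body-fluid compartment with lactate/acetate/folate
secretion, dietary folate dependence, and a GPR on every internal
reaction.

`ros_fixture()` matches the documented shape of the curated stress set —
8 reactions, 11 metabolites — with deliberately dead-ended products and
source-less radicals so that expansion exercises the full debugging
protocol (on the toy microbe it adds 6 demands and 2 sinks). The
perturbation's planted truth is provable: the demand for oxidised
folate opens a drain that widens the folate-branch spans from 0.5 to
8/3 at full optimality (FSr = 3/16) while every other shared span is
pinned by the ATP balance; the generators' seeds shuffle only cosmetic
aspects (evidence row order), never network content.

What passing these tests shows: the statistics, the debugging protocol,
the MILP and the pairing bookkeeping are implemented correctly at
hand-verifiable scale. What it does not show: behaviour on genome-scale
reconstructions — degenerate alternate optima at much higher
dimension, inconsistent annotation, mass-imbalanced legacy reactions —
nor any statistical property of real expression data. The toys have no
kinetics and no regulation, and their biomass compositions are
stylised. Genome-scale inputs enter through `read_model()` and the same
code paths, but the dense simplex is sized for teaching-scale networks;
a genome-scale deployment would swap in a sparse/revised factorisation
behind the same `solve_lp()` contract.

## The context-model contrast

The packaged host workflow emulates the healthy-versus-disease tissue
contrast: the healthy ("colon") branch first edits the biomass —
removing the replicating nucleotide precursor and strengthening the
folate dependency (`edit_biomass()`), after which folate availability,
not carbon, limits growth — and silences lactate dehydrogenase through
its evidence; the disease ("CRC") branch keeps the generic proliferative
biomass and high glycolytic/lactate evidence. On the toys this yields
biomass fluxes of 2 and 5 (a 60% increase, computed by the same
`percent_biomass_increase()` arithmetic the acceptance script applies to
the published tissue-model fluxes 0.0003 and 0.0223, where it gives
98.65% ≈ 98%), a healthy context that has lost its lactate secretion,
and a disease secretome with increased lactate, acetate and folate
export — the qualitative pattern the secretome classification matrix is
designed to display.

## Known limitations

* The simplex and branch-and-bound are dense and single-threaded;
  fine (and exactly reproducible) at the scales shipped, not tuned for
  genome-scale FVA sweeps.
* SBML support covers L3 core plus the FBC bounds/objective/gene
  subset; annotations and notes do not round-trip, and bracketed ids
  are sanitised (originals preserved in `name`).
* Auto-unblocking is greedy and deterministic, not minimal-cardinality;
  a literature set always takes precedence when supplied.
* Secretome classification compares maximal capacities (FVA `vmax`),
  not realised secretion rates; the same/increased/decreased tolerance
  (5% relative, with an absolute zero-floor of 1e-5) is a reporting
  choice, not an inference.
* Two-organism communities only; no dynamic FBA, no loopless FVA, no
  thermodynamic constraints.
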