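---
title: "Pathway-centric model curation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-centric model curation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcurator)
```

## The problem

Constraint-based metabolic models describe an organism's metabolism as a
stoichiometric network: metabolites partitioned into compartments, reactions
with signed coefficients and flux bounds (mmol·gDW⁻¹·h⁻¹), gene
associations, and an objective. Analysis rests on flux balance analysis
(FBA), the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

where $S$ is the metabolites × reactions matrix of coefficients. Modellers
rarely extend such models one reaction at a time; the natural unit is the
*pathway*, a curated, ordered set of reactions taken from a database (KEGG,
the BioCyc collection, BiGG) or from the modeller's own notes. Every import
is a chance to introduce silent damage: duplicated content under a
different identifier, metabolites without formulas that make balance
checking impossible, elementally or charge-imbalanced reactions, direction
annotations contradicting the bounds, and reactions that can never carry
flux because a precursor or byproduct has no other producer or consumer.

`pathcurator` makes each of those failure modes an explicit, logged,
non-fatal finding, and couples the bookkeeping with two functional checks:
plain FBA and a per-reaction non-zero flux test with automatic auxiliary
boundary insertion.

## Record retrieval and conversion

Records are fetched through a local cache laid out as
`<cache_dir>/<source>/<kind>/<identifier>.<ext>` (`.txt` KEGG, `.xml`
BioCyc, `.json` BiGG). The raw text is stored verbatim and parsing is a
pure function of it, so a cached workspace fully determines every result.
Network access is abstracted behind a provider function
(`tool_config(provider = ...)`); the default is offline-only, and the test
suite exercises retrieval exclusively against generated fixtures. This
mirrors how reproducible curation pipelines should behave: the first fetch
freezes the record, later runs reuse it byte-for-byte.

Each dialect parser covers the subset of its format that carries model
content:

- **KEGG flat file** — 12-column keyword field, continuation lines, `///`
  terminator; `EQUATION` (`lhs <=> rhs`, optional integer coefficients)
  parses as a reversible reaction, `FORMULA` as a chemical formula,
  a module/pathway `REACTION` block as an ordered reaction list, `ENZYME`
  as `ec-code` cross-references.
- **BioCyc ptools-xml** — `Reaction` frames with `left`/`right` compound
  references and optional `coefficient` children; `reaction-direction`
  literals `LEFT-TO-RIGHT` / `RIGHT-TO-LEFT` / `REVERSIBLE` (a `PHYSIOL-`
  prefix is stripped) map to forward/backward/reversible; `Compound` frames
  carry a formula (cml `concise` attribute or plain text); `Pathway` frames
  carry a `reaction-list`.
- **BiGG JSON** — reaction records with a `metabolites` array
  (`bigg_id`, `compartment_bigg_id`, `stoichiometry`); records flagged
  `pseudoreaction` (exchanges, biomass) are rejected as non-importable
  pathway content. The record subset carries no direction, so converted
  reactions are `unspecified` with the reversible default bounds.
- **User text format** — our own documented line grammar
  (`M id, name, compartment, formula|-, charge|-` and
  `R id, name | lhs -> rhs | lb, ub`), since no community standard exists
  for hand-curated additions; `->`, `<->`, `<-` map to forward /
  reversible / backward with the direction-specific default bounds
  (0, 1000), (−1000, 1000), (−1000, 0).

Conversion into model objects resolves each participant metabolite in a
fixed order: exact compartment-suffixed id in the model, then
cross-reference match, then a stub metabolite built from the cached
compound record. The order minimizes spurious duplicates: an entity already
known under any identifier is reused before anything new is created.
Database gene lists become OR-joined gene rules — an isozyme assumption,
appropriate because the supported record subsets carry no complex/subunit
structure.

## The curation battery

For each entity the checks run in a fixed order: **duplicate → missing
formula → mass balance → reversibility**.

- *Duplicates* match by identical id, any shared cross-reference pair, or
  (reactions only) coefficient-identical stoichiometry. Duplicates are
  skipped, everything else is added — this short-circuit is what makes
  pathway addition idempotent, which we consider the central contract of a
  curation tool: re-running a workflow must not grow the model.
- *Mass balance* computes per-element residuals
  $r_e = \sum_m \nu_m \cdot \text{formula}(m)_e$ (products minus
  reactants) plus the analogous charge residual, with missing charges
  treated as 0 (charge is optional in community models; a missing charge
  should not block elemental checking). Any participant without a usable
  formula — absent, or containing generic R/X group tokens — forces the
  verdict `undetermined`: the checker never guesses. Imbalances come with a
  concrete suggestion ("add 1 H to the product side").
- *Reversibility* flags declared directions that the bounds cannot
  realize (e.g. declared reversible with `lower_bound ≥ 0`) and suggests
  the reconciling bound.

Findings are warnings, never errors, matching how an interactive curation
session should behave: the modeller sees every issue on the console and in
the timestamped log (`LEVEL | check | entity | message`), but the tool does
not decide for them. Only structural impossibilities (unwritable log,
broken referential integrity) raise, and they raise before any model
mutation.

## The non-zero flux test

`test_non_zero_flux()` works on a scratch copy. It first maximizes the
reaction's flux (and also minimizes it when the lower bound is negative).
If the magnitude stays below the tolerance (default 1e-7, the conventional
LP feasibility scale), it enumerates candidate metabolites by breadth-first
traversal of the metabolite–reaction graph starting from the tested
reaction's participants, id-sorted within each level — a deterministic
order that visits the most local explanation first. At each candidate that
is *currently* a dead end (its stoichiometric row is sign-uniform), it
inserts a reversible boundary reaction `SK_<met>` with stoichiometry
{met: −1} and bounds (−1000, 1000), and re-solves. A single reversible
construct covers both roles — a source for an unproduced precursor, a sink
for an unconsumed byproduct — and the report names the role actually
played. Every insertion becomes one suggestion, because each names exactly
the connectivity the model is missing. Auxiliaries persist only when
`keep_auxiliary = TRUE`; by default the caller's model is returned
untouched, since a probe should not edit the model it probes.

The LP itself is solved with `pracma::linprog` after an affine change of
variables `x = v − lb` (upper bounds enter as inequality rows), with a
big-M constant of 1e6 — large relative to the conventional ±1000 bound
magnitude. Bounds are finite by construction, so the program is never
unbounded; infeasibility is reported in the result status. The test suite
cross-checks optima against an independent brute-force vertex enumeration
over $\{Sv = 0,\; lb \le v \le ub\}$, which is exact for the network sizes
used there.

## Map generation

`order_reactions()` produces a deterministic topological order: Kahn's
algorithm with a lexicographic min-queue over the directed graph "some
product of u is a substrate of v" (backward-declared reactions are flipped
first; reversible ones keep their stoichiometric orientation); cycles are
broken at the lexicographically smallest stalled reaction, and weakly
connected components are concatenated by smallest member id.

`build_escher_map()` lays reactions left-to-right: reaction *i* gets a
midmarker at `x = margin + i·spacing` on a fixed axis (y = 400, a typical
Escher viewport line). Each reaction's primary substrate/product — the
metabolite shared with the neighboring reaction, else the
highest-|coefficient| participant, ties broken lexicographically — sits on
the axis at `x ∓ spacing/2.5`; a primary shared between consecutive
reactions is one node and keeps the position assigned by the reaction that
created it (the two prescriptions `x_i + spacing/2.5` and
`x_{i+1} − spacing/2.5` differ, and first-creator-wins is the
deterministic choice). Remaining participants fan above (substrates) and
below (products) the axis at ±80. One segment joins each participant node
to the midmarker, so segments = Σ participants and nodes = distinct
metabolite positions + one midmarker per reaction. Bezier control points
are null (straight segments) — the simplest geometry Escher accepts.
Serialization is canonical (sorted keys, numerically ordered node/segment
ids), so identical maps are byte-identical on disk, and a written map
re-parses and re-serializes to the same bytes.

Flux overlays transform |flux| to $t \in [0,1]$ either linearly
(min–max; an all-equal vector maps to 1 — with no contrast, full
saturation is the least misleading) or by quantile (average ranks,
`(rank−1)/(n−1)`), which is invariant under any strictly monotone
transformation of the fluxes and therefore robust to heavy-tailed flux
distributions. Colors interpolate per RGB channel between gradient stops
with half-up rounding; stroke width is `2 + 8t`. Absolute values are used
because reversible fluxes may be negative and magnitude is what a
comparison of pathway activity encodes. Styles are written as a sidecar
document rather than into the map: the Escher map schema carries geometry,
data overlays are supplied at render time. Cross-condition comparisons
should style both flux vectors with a shared min/max, which the caller can
do by normalizing before styling.

## What the synthetic fixtures emulate — and what they do not

`generate_toy_model()` builds linear chains `m0 → m1 → ... → mn` with
integer capacities drawn uniformly from [1, 10] under a caller-supplied
seed, optional exchange reactions at both ends, per-reaction single-gene
rules, and an optional dead-end byproduct. The chain shape is chosen
because its FBA optimum has a closed form (the minimum capacity), giving
the solver tests an exact independent answer; the capacity range keeps all
quantities small integers so "exact" is meaningful in floating point.
`generate_fixture_records()` emits the same network in all three database
dialects, which is what lets the suite assert that the three parsers agree
stoichiometrically without any network access.

These fixtures are deliberately simple: they have no compartmentalization
beyond a single cytosol, no shared cofactors, no reaction with more than
three participants, and formulas chosen so chain reactions balance
trivially. Passing tests therefore demonstrate the correctness of the
machinery — parsing, conversion, checking, solving, layout — not the
biological plausibility of any particular genome-scale model; real models
exercise the same code paths with messier content (generic-group formulas,
isozyme lists, multi-compartment transport), whose handling is covered by
the dedicated per-module tests.

Problem sizes used by the suite and the acceptance script — chains of
length 3–10, random networks of up to 8 reactions, 200 random
mass-balance cases, 50 generated layouts — were chosen so the independent
oracles (vertex enumeration, brute-force tallies) remain exact and the
whole battery completes in seconds.

## Numerical and design choices

- Entity ordering wherever "first" matters is lexicographic by id;
  stoichiometric matrix rows/columns are id-sorted. Determinism throughout
  is a hard requirement: byte-stable maps and reproducible reports depend
  on it.
- Canonical COBRA JSON: sorted keys, id-sorted entity arrays, maximal
  float precision. Unknown keys are preserved opaquely and logged, never
  silently dropped. Pathways are persisted under a `pathways` key of our
  own, since the COBRA schema has no pathway concept.
- Default bounds by declared direction: reversible (−1000, 1000), forward
  (0, 1000), backward (−1000, 0) — the community's conventional magnitude.
- The flux-test tolerance (1e-7) and the balance residual tolerance
  (1e-9) sit well below the integer scales of any realistic stoichiometry
  while staying above double-precision noise.
- The CLI layer maps outcomes to exit codes 0 (success), 1 (domain
  failure — a reaction failed or needed auxiliaries, an output could not
  be written) and 2 (usage or missing-data error). A reaction that only
  carries flux after auxiliary insertion counts as a domain failure at the
  CLI level: the model as shipped is not functional, even though the
  library-level report records the rescue as a pass.

## Known limitations

- No SBML I/O; COBRA JSON is the interchange format.
- Gene rules are stored and their gene sets tracked, but boolean
  evaluation (gene deletion analysis) is out of scope.
- The auxiliary-insertion heuristic is greedy and local; it is not a
  MILP gap-filler and may insert more sinks than a minimal repair would.
- Mass balance cannot classify reactions involving generic-group formulas
  (R/X); these are reported `undetermined` by design.
- Live database access is not implemented; a provider function must be
  supplied, and all bundled workflows run from local caches.
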