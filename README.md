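# pathcurator

Pathway-centric curation of constraint-based metabolic models in R.

Genome-scale metabolic models (GEMs) are compartmentalized networks of
reactions analyzed with constraint-based methods such as flux balance
analysis (FBA): maximize `c·v` subject to the steady-state constraint
`S·v = 0` and flux bounds `lb ≤ v ≤ ub`, where `S` is the metabolites ×
reactions stoichiometric matrix. Modellers extend such models one *pathway*
at a time — a biologically meaningful, ordered set of reactions pulled from
a database — and each addition risks importing duplicates, metabolites
without chemical formulas, elementally imbalanced reactions, or direction
annotations that contradict the flux bounds.

`pathcurator` supports that workflow end to end:

- **Model I/O** — read/write constraint-based models in COBRA JSON, with
  identifiers.org-style annotations (`kegg.reaction`, `biocyc`,
  `bigg.metabolite`, ...) mapped to entity cross-references and a canonical,
  byte-stable serialization.
- **Record retrieval** — parse metabolite/reaction/pathway records in three
  database dialects (KEGG flat-file, BioCyc ptools-xml, BiGG JSON) plus a
  line-oriented user text format, through a local cache
  (`<cache>/<source>/<kind>/<id>.<ext>`) so every run is reproducible
  offline.
- **Curation battery** — every added entity is checked for duplicates
  (by id, cross-reference, or identical stoichiometry), missing or
  indeterminate formulas, elemental *and* charge balance, and
  declared-direction/bounds consistency. Curation warns and logs; it never
  blocks, and repeated addition of the same pathway is idempotent.
- **Non-zero flux test** — verifies a reaction can carry steady-state flux;
  if not, it walks the metabolite–reaction graph from the reaction outward,
  inserts reversible auxiliary boundary reactions (`SK_*`) at dead-end
  metabolites one at a time, and turns each insertion into a concrete
  manual-curation suggestion. The user's model is never modified unless
  asked.
- **Escher maps** — pathways are topologically ordered and laid out
  automatically as Escher-compatible map JSON, with optional flux-to-color
  overlays (linear or quantile normalized gradients) written as a style
  sidecar.

## Worked example

```r
library(pathcurator)

# a toy chain model plus database records describing the same network
model   <- generate_toy_model(3, with_exchanges = TRUE, seed = 7)
records <- generate_fixture_records(model)
cache   <- tempfile()
write_fixture_cache(records, cache)
config  <- tool_config(cache_dir = cache, offline = TRUE,
                       log_path = file.path(cache, "curation.log"))

# fetch the pathway record, convert, curate into a fresh model
host <- new_model("host")
rec  <- fetch_record("kegg", "TOYPATH", "pathway", config)
ent  <- create_object(rec, host, config)
res  <- run_curation(host, list(ent), log_path = config$log_path)
#> curation summary: 7 added, 0 skipped, 0 finding(s)

solve_fba(generate_toy_model(3, TRUE, seed = 7))$objective_value
#> [1] 3        # the chain bottleneck: min of the drawn capacities (10, 3, 7)

# a dead-end byproduct blocks flux; the test inserts one auxiliary and says why
dead <- generate_toy_model(3, TRUE, dead_end_at = 2, seed = 7)
test_non_zero_flux(dead, "R2")
#> <non-zero flux test> R2: PASSED (flux 3, 1 auxiliary)
#>   suggestion: metabolite d_c required an auxiliary sink (SK_d_c) — add a
#>   consuming reaction or transport for it

# visualize with a flux overlay
pw  <- pathway("chain", c("R1", "R2", "R3"))
map <- build_escher_map(pw, model)
sol <- solve_fba(model)
sty <- map_flux_to_style(sol$fluxes[pw$reaction_ids],
                         gradient_spec(c("#FFFFFF", "#FF0000"), "linear"))
write_escher_json(map, "chain_map.json", style = sty)
```

The printed summary means all seven entities (4 metabolites + 3 reactions)
passed curation cleanly; a second `run_curation` with the same pathway adds
nothing and reports one duplicate finding per reaction. The flux test's
suggestion names the dead-end metabolite so the modeller knows which
consuming reaction or transport the network is missing.

A shell wrapper for the same operations ships in
`inst/scripts/pathcurator.R` (subcommands `fetch`, `add-pathway`,
`test-flux`, `visualize`).

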