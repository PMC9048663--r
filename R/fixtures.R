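# Fixture/toy-model generation: every other module is testable against
# these without any network access.

.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a toy linear-chain model
#'
#' Builds a linear chain `m0_c -> m1_c -> ... -> mn_c` of `n_reactions`
#' forward reactions `R1..Rn` whose capacities (upper bounds) are drawn as
#' seeded uniform integers in \[1, 10\]. All chain metabolites share the same
#' formula, so the chain reactions are elementally balanced. Optionally adds
#' boundary exchange reactions at both ends (making the chain's maximal flux
#' equal its minimum capacity) and a dead-end byproduct `d_c` (no formula,
#' no consumer) on one chain reaction. Each chain reaction carries a
#' one-gene rule `g<i>`. Deterministic for a fixed seed.
#'
#' @param n_reactions chain length, at least 1.
#' @param with_exchanges add `EX_m0_c` (supply) and `EX_m<n>_c` (drain,
#'   also the objective).
#' @param dead_end_at optional 1-based chain reaction index receiving the
#'   dead-end byproduct.
#' @param seed RNG seed for the capacity draw.
#' @return A `cb_model`.
#' @export
generate_toy_model <- function(n_reactions, with_exchanges = TRUE,
                               dead_end_at = NULL, seed = 1L) {
  stopifnot(n_reactions >= 1L)
  if (!is.null(dead_end_at) &&
      (dead_end_at < 1L || dead_end_at > n_reactions)) {
    stop(sprintf("dead_end_at must be in 1..%d", n_reactions), call. = FALSE)
  }
  caps <- .with_local_seed(seed, sample.int(10L, n_reactions, replace = TRUE))
  model <- new_model(id = sprintf("toy_chain_%d", n_reactions))
  for (i in 0:n_reactions) {
    model <- .insert_metabolite(model, metabolite(
      id = sprintf("m%d_c", i), name = sprintf("chain metabolite %d", i),
      formula = "C1H2O1", charge = 0))
  }
  if (!is.null(dead_end_at)) {
    model <- .insert_metabolite(model, metabolite(
      id = "d_c", name = "dead-end byproduct"))
  }
  for (i in seq_len(n_reactions)) {
    stoich <- stats::setNames(c(-1, 1),
                              c(sprintf("m%d_c", i - 1), sprintf("m%d_c", i)))
    if (!is.null(dead_end_at) && i == dead_end_at) {
      stoich <- c(stoich, d_c = 1)
    }
    model <- .insert_reaction(model, reaction(
      id = sprintf("R%d", i), stoichiometry = stoich,
      name = sprintf("chain step %d", i),
      declared_direction = "forward",
      lower_bound = 0, upper_bound = caps[i],
      gene_rule = sprintf("g%d", i)))
  }
  if (with_exchanges) {
    model <- .insert_reaction(model, reaction(
      id = "EX_m0_c", stoichiometry = c(m0_c = 1),
      name = "supply exchange", declared_direction = "forward",
      lower_bound = 0, upper_bound = 1000))
    drain <- sprintf("EX_m%d_c", n_reactions)
    model <- .insert_reaction(model, reaction(
      id = drain,
      stoichiometry = stats::setNames(-1, sprintf("m%d_c", n_reactions)),
      name = "drain exchange", declared_direction = "forward",
      lower_bound = 0, upper_bound = 1000))
    model <- set_objective(model, stats::setNames(1, drain))
  } else {
    model <- set_objective(model, stats::setNames(1, sprintf("R%d", n_reactions)))
  }
  model
}

# Identifier mappings between the model namespace and each database dialect.
.fixture_maps <- function(model) {
  met_ids <- sort(names(model$metabolites))
  rxn_ids <- sort(setdiff(names(model$reactions),
                          grep("^(EX|SK)_", names(model$reactions), value = TRUE)))
  base <- sub("_[a-z0-9]+$", "", met_ids)
  list(
    met_ids = met_ids, rxn_ids = rxn_ids,
    kegg_met = stats::setNames(sprintf("C%05d", seq_along(met_ids)), met_ids),
    kegg_rxn = stats::setNames(sprintf("R%05d", seq_along(rxn_ids)), rxn_ids),
    biocyc_met = stats::setNames(toupper(base), met_ids),
    biocyc_rxn = stats::setNames(paste0(toupper(rxn_ids), "-RXN"), rxn_ids),
    bigg_met = stats::setNames(base, met_ids),
    bigg_rxn = stats::setNames(tolower(rxn_ids), rxn_ids))
}

#' Emit dialect-faithful database records for a model
#'
#' Produces KEGG flat-file, BioCyc ptools-xml and BiGG JSON record texts
#' describing every non-boundary reaction, every metabolite, and one
#' pathway record per dialect covering the full reaction set, such that
#' fetching and converting them rebuilds a stoichiometrically identical
#' model (up to each dialect's identifier namespace). The returned nested
#' list `records[[source]][[kind]][[identifier]]` plugs directly into
#' [fixture_provider()] or [write_fixture_cache()]; identifier mapping
#' tables are attached as `attr(, "maps")`.
#'
#' @param model a `cb_model`, typically from [generate_toy_model()].
#' @param pathway_id identifier for the emitted pathway records.
#' @return Nested list of raw record texts.
#' @export
generate_fixture_records <- function(model, pathway_id = "TOYPATH") {
  maps <- .fixture_maps(model)
  recs <- list(kegg = list(metabolite = list(), reaction = list(), pathway = list()),
               biocyc = list(metabolite = list(), reaction = list(), pathway = list()),
               bigg = list(metabolite = list(), reaction = list()))

  for (mid in maps$met_ids) {
    m <- model$metabolites[[mid]]
    f <- if (is.null(m$formula)) NULL else formula_to_string(m$formula)
    kid <- maps$kegg_met[[mid]]
    recs$kegg$metabolite[[kid]] <- paste0(
      sprintf("ENTRY       %-26s  Compound\n", kid),
      sprintf("NAME        %s;\n", m$name),
      if (!is.null(f)) sprintf("FORMULA     %s\n", f) else "",
      "///")
    bid <- maps$biocyc_met[[mid]]
    recs$biocyc$metabolite[[bid]] <- paste0(
      "<ptools-xml>\n  <Compound frameid=\"", bid, "\">\n",
      "    <cname>", m$name, "</cname>\n",
      if (!is.null(f)) paste0("    <formula>", f, "</formula>\n") else "",
      "  </Compound>\n</ptools-xml>")
    gid <- maps$bigg_met[[mid]]
    recs$bigg$metabolite[[gid]] <- as.character(jsonlite::toJSON(list(
      bigg_id = gid, name = m$name,
      formulae = as.list(if (is.null(f)) character(0) else f),
      charges = as.list(if (is.null(m$charge)) numeric(0) else m$charge)),
      auto_unbox = TRUE, digits = NA))
  }

  for (rid in maps$rxn_ids) {
    r <- model$reactions[[rid]]
    s <- r$stoichiometry
    subs <- names(s)[s < 0]; prods <- names(s)[s > 0]
    eq_side <- function(mids, map) paste(vapply(mids, function(m) {
      k <- abs(s[[m]])
      if (k == 1) map[[m]] else paste(format(k), map[[m]])
    }, character(1)), collapse = " + ")
    kid <- maps$kegg_rxn[[rid]]
    recs$kegg$reaction[[kid]] <- paste0(
      sprintf("ENTRY       %-26s  Reaction\n", kid),
      sprintf("NAME        %s\n", r$name),
      sprintf("EQUATION    %s <=> %s\n",
              eq_side(subs, maps$kegg_met), eq_side(prods, maps$kegg_met)),
      "///")
    bid <- maps$biocyc_rxn[[rid]]
    side_xml <- function(mids, tag) paste(vapply(mids, function(m) {
      k <- abs(s[[m]])
      paste0("    <", tag, ">\n      <Compound frameid=\"",
             maps$biocyc_met[[m]], "\"/>\n",
             if (k != 1) paste0("      <coefficient>", format(k), "</coefficient>\n") else "",
             "    </", tag, ">")
    }, character(1)), collapse = "\n")
    dir_lit <- switch(r$declared_direction,
                      forward = "LEFT-TO-RIGHT", backward = "RIGHT-TO-LEFT",
                      "REVERSIBLE")
    recs$biocyc$reaction[[bid]] <- paste0(
      "<ptools-xml>\n  <Reaction frameid=\"", bid, "\">\n",
      side_xml(subs, "left"), "\n", side_xml(prods, "right"), "\n",
      "    <reaction-direction>", dir_lit, "</reaction-direction>\n",
      "  </Reaction>\n</ptools-xml>")
    gid <- maps$bigg_rxn[[rid]]
    recs$bigg$reaction[[gid]] <- as.character(jsonlite::toJSON(list(
      bigg_id = gid, name = r$name, pseudoreaction = FALSE,
      metabolites = lapply(names(s), function(m) list(
        bigg_id = maps$bigg_met[[m]],
        compartment_bigg_id = model$metabolites[[m]]$compartment,
        stoichiometry = s[[m]]))),
      auto_unbox = TRUE, digits = NA))
  }

  kegg_rxn_ids <- unname(maps$kegg_rxn[maps$rxn_ids])
  recs$kegg$pathway[[pathway_id]] <- paste0(
    sprintf("ENTRY       %-26s  Module\n", pathway_id),
    sprintf("NAME        toy pathway\n"),
    "REACTION    ", paste(kegg_rxn_ids, collapse = " "), "\n",
    "///")
  recs$biocyc$pathway[[pathway_id]] <- paste0(
    "<ptools-xml>\n  <Pathway frameid=\"", pathway_id, "\">\n",
    "    <reaction-list>\n",
    paste(sprintf("      <Reaction frameid=\"%s\"/>",
                  unname(maps$biocyc_rxn[maps$rxn_ids])), collapse = "\n"), "\n",
    "    </reaction-list>\n  </Pathway>\n</ptools-xml>")

  attr(recs, "maps") <- maps
  recs
}

#' Write fixture records into a cache directory
#'
#' Materializes the output of [generate_fixture_records()] under the
#' standard cache layout `<cache_dir>/<source>/<kind>/<identifier>.<ext>`.
#'
#' @param records nested record list.
#' @param cache_dir target directory (created if needed).
#' @return `cache_dir`, invisibly.
#' @export
write_fixture_cache <- function(records, cache_dir) {
  for (source in names(records)) {
    for (kind in names(records[[source]])) {
      dir <- file.path(cache_dir, source, kind)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (id in names(records[[source]][[kind]])) {
        writeLines(records[[source]][[kind]][[id]],
                   file.path(dir, paste0(id, ".", .cache_ext[[source]])),
                   useBytes = TRUE)
      }
    }
  }
  invisible(cache_dir)
}
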