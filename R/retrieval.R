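#' Database records
#'
#' A `db_record` wraps one record obtained from a pathway database (or the
#' user text format): the source dialect, the identifier, the record kind,
#' the verbatim raw text as cached, and the parsed object — a
#' `cb_metabolite`, `cb_reaction`, or `pathway_template`. Parsing is a pure
#' function of the raw text, so the cache fully determines the result.
#'
#' @name db_record
NULL

.db_sources <- c("kegg", "biocyc", "bigg", "user")
.db_kinds <- c("metabolite", "reaction", "pathway")
.cache_ext <- c(kegg = "txt", biocyc = "xml", bigg = "json", user = "txt")

.new_record <- function(source, identifier, kind, raw, parsed) {
  structure(list(source = source, identifier = identifier, kind = kind,
                 raw = raw, parsed = parsed),
            class = "db_record")
}

#' @export
print.db_record <- function(x, ...) {
  cat(sprintf("<db_record> %s %s '%s' (%d chars raw)\n",
              x$source, x$kind, x$identifier, nchar(x$raw)))
  invisible(x)
}

# A pathway template: the database-side view of a pathway, before its
# reaction identifiers are resolved against a model.
pathway_template <- function(identifier, reaction_identifiers,
                             gene_associations = list()) {
  if (anyDuplicated(reaction_identifiers)) {
    stop(sprintf("pathway '%s': duplicate reaction identifiers", identifier),
         call. = FALSE)
  }
  structure(list(identifier = identifier,
                 reaction_identifiers = as.character(reaction_identifiers),
                 gene_associations = gene_associations),
            class = "pathway_template")
}

#' Fetch a database record through the local cache
#'
#' Raw records live at `<cache_dir>/<source>/<kind>/<identifier>.<ext>`
#' (`.txt` for KEGG, `.xml` for BioCyc, `.json` for BiGG). A cache hit reads
#' the stored text verbatim; a miss consults `config$provider` unless
#' `config$offline`, and stores the retrieved text before parsing. Two
#' fetches of the same identifier therefore always yield byte-identical raw
#' text, and the second never invokes the provider.
#'
#' @param source one of `"kegg"`, `"biocyc"`, `"bigg"`, `"user"`.
#' @param identifier database identifier of the record.
#' @param kind one of `"metabolite"`, `"reaction"`, `"pathway"`.
#' @param config a [tool_config()].
#' @return A `db_record`.
#' @export
fetch_record <- function(source, identifier, kind, config) {
  source <- match.arg(source, .db_sources)
  kind <- match.arg(kind, .db_kinds)
  dir <- file.path(config$cache_dir, source, kind)
  path <- file.path(dir, paste0(identifier, ".", .cache_ext[[source]]))
  if (file.exists(path)) {
    .bump(config, "cache_hits")
    raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    .bump(config, "cache_misses")
    if (config$offline || is.null(config$provider)) {
      stop(structure(class = c("pc_data_error", "error", "condition"),
                     list(message = sprintf(
                       "record not retrievable offline; expected cache file '%s'", path),
                       call = NULL)))
    }
    .bump(config, "provider_calls")
    raw <- config$provider(source, identifier, kind)
    if (is.null(raw)) {
      stop(structure(class = c("pc_data_error", "error", "condition"),
                     list(message = sprintf(
                       "provider has no %s %s record '%s'", source, kind, identifier),
                       call = NULL)))
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(raw, path, useBytes = TRUE)
  }
  rec <- switch(source,
                kegg = parse_kegg(raw),
                biocyc = parse_biocyc(raw),
                bigg = parse_bigg(raw, kind),
                user = {
                  recs <- parse_user_table(raw)
                  hit <- Filter(function(r) r$identifier == identifier, recs)
                  if (!length(hit)) stop(sprintf("user record '%s' not in file", identifier),
                                         call. = FALSE)
                  hit[[1]]
                })
  if (!identical(rec$kind, kind)) {
    stop(sprintf("record '%s' parsed as kind '%s', expected '%s'",
                 identifier, rec$kind, kind), call. = FALSE)
  }
  rec
}

# ---------------------------------------------------------------------------
# KEGG flat file dialect
# ---------------------------------------------------------------------------

#' Parse a KEGG flat-file record
#'
#' Supports the keyword subset ENTRY, NAME, EQUATION, ENZYME (reactions),
#' FORMULA (compounds) and REACTION (modules/pathways). The keyword occupies
#' a 12-column field; continuation lines are indented; the record terminates
#' with `///`. Equations use `lhs <=> rhs` (parsed as reversible) with
#' optional integer coefficients, e.g. `2 C00001 + C00002 <=> C00009`.
#'
#' @param text raw record text.
#' @return A `db_record`.
#' @export
parse_kegg <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!any(trimws(lines) == "///")) {
    stop("KEGG parse error: record terminator '///' missing", call. = FALSE)
  }
  lines <- lines[seq_len(which(trimws(lines) == "///")[1] - 1L)]
  fields <- list()
  current <- NULL
  for (ln in lines) {
    key <- trimws(substr(ln, 1, 12))
    val <- if (nchar(ln) > 12) substring(ln, 13) else ""
    if (nzchar(key)) {
      current <- key
      fields[[current]] <- c(fields[[current]], val)
    } else if (!is.null(current)) {
      fields[[current]] <- c(fields[[current]], trimws(val))
    }
  }
  if (is.null(fields$ENTRY)) {
    stop("KEGG parse error: missing ENTRY field", call. = FALSE)
  }
  toks <- strsplit(trimws(fields$ENTRY[1]), "\\s+")[[1]]
  id <- toks[1]
  entry_type <- tolower(toks[length(toks)])
  nm <- if (is.null(fields$NAME)) id else sub(";$", "", trimws(fields$NAME[1]))

  if (entry_type == "compound" || entry_type == "glycan") {
    formula <- if (is.null(fields$FORMULA)) NULL else parse_formula(trimws(fields$FORMULA[1]))
    parsed <- list(identifier = id, name = nm, formula = formula, charge = NULL)
    return(.new_record("kegg", id, "metabolite", text, parsed))
  }
  if (entry_type == "reaction") {
    if (is.null(fields$EQUATION)) {
      stop("KEGG parse error: reaction record lacks EQUATION", call. = FALSE)
    }
    eq <- paste(fields$EQUATION, collapse = " ")
    stoich <- .parse_kegg_equation(eq)
    xrefs <- list()
    if (!is.null(fields$ENZYME)) {
      xrefs[["ec-code"]] <- strsplit(trimws(paste(fields$ENZYME, collapse = " ")),
                                     "\\s+")[[1]]
    }
    parsed <- list(identifier = id, name = nm, stoichiometry = stoich,
                   declared_direction = "reversible", cross_refs = xrefs)
    return(.new_record("kegg", id, "reaction", text, parsed))
  }
  if (entry_type %in% c("module", "pathway")) {
    if (is.null(fields$REACTION)) {
      stop("KEGG parse error: module/pathway record lacks REACTION block", call. = FALSE)
    }
    toks <- unlist(strsplit(fields$REACTION, "[,;+[:space:]]+"))
    toks <- sub("^rn:", "", toks[nzchar(toks)])
    rids <- unique(toks[grepl("^[A-Za-z][A-Za-z0-9_]*$", toks)])
    parsed <- pathway_template(id, rids)
    return(.new_record("kegg", id, "pathway", text, parsed))
  }
  stop(sprintf("KEGG parse error: unsupported entry type '%s'", entry_type),
       call. = FALSE)
}

.parse_kegg_equation <- function(eq) {
  sides <- strsplit(eq, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop(sprintf("KEGG parse error: EQUATION lacks '<=>': '%s'", eq), call. = FALSE)
  }
  parse_side <- function(side, sign) {
    out <- numeric(0)
    for (tok in strsplit(side, "+", fixed = TRUE)[[1]]) {
      tok <- trimws(tok)
      if (!nzchar(tok)) next
      m <- regmatches(tok, regexec("^(?:([0-9]+)\\s+)?([A-Za-z][A-Za-z0-9_]*)$", tok))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("KEGG parse error: unparseable EQUATION token '%s'", tok),
             call. = FALSE)
      }
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      out[m[3]] <- (if (is.na(out[m[3]])) 0 else out[m[3]]) + sign * coef
    }
    out
  }
  c(parse_side(sides[1], -1), parse_side(sides[2], +1))
}

# ---------------------------------------------------------------------------
# BioCyc ptools-xml dialect
# ---------------------------------------------------------------------------

#' Parse a BioCyc ptools-xml record
#'
#' Supports the web-service XML subset: a `ptools-xml` root holding one
#' `Reaction` (with `left`/`right` compound references, optional
#' `coefficient` children and a `reaction-direction`), `Compound` (with a
#' `formula` child, either `concise`-attributed cml style or plain text), or
#' `Pathway` (with a `reaction-list`). Direction literals LEFT-TO-RIGHT,
#' RIGHT-TO-LEFT and REVERSIBLE map to forward/backward/reversible; a
#' `PHYSIOL-` prefix is stripped first.
#'
#' @param text raw XML text.
#' @return A `db_record`.
#' @export
parse_biocyc <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop(sprintf("BioCyc parse error: %s",
                                                   conditionMessage(e)), call. = FALSE))
  if (xml2::xml_name(doc) != "ptools-xml") {
    stop("BioCyc parse error: root element is not 'ptools-xml'", call. = FALSE)
  }
  rxn <- xml2::xml_find_first(doc, "./Reaction")
  cpd <- xml2::xml_find_first(doc, "./Compound")
  pwy <- xml2::xml_find_first(doc, "./Pathway")
  if (!inherits(rxn, "xml_missing")) return(.parse_biocyc_reaction(rxn, text))
  if (!inherits(cpd, "xml_missing")) return(.parse_biocyc_compound(cpd, text))
  if (!inherits(pwy, "xml_missing")) return(.parse_biocyc_pathway(pwy, text))
  stop("BioCyc parse error: no Reaction/Compound/Pathway element", call. = FALSE)
}

.parse_biocyc_reaction <- function(node, text) {
  id <- xml2::xml_attr(node, "frameid")
  side_coefs <- function(tag, sign) {
    out <- numeric(0)
    for (el in xml2::xml_find_all(node, paste0("./", tag))) {
      ref <- xml2::xml_find_first(el, "./Compound|./Protein")
      if (inherits(ref, "xml_missing")) next
      cid <- xml2::xml_attr(ref, "frameid")
      co <- xml2::xml_find_first(el, "./coefficient")
      k <- if (inherits(co, "xml_missing")) 1 else as.numeric(xml2::xml_text(co))
      out[cid] <- (if (is.na(out[cid])) 0 else out[cid]) + sign * k
    }
    out
  }
  left <- side_coefs("left", -1)
  right <- side_coefs("right", +1)
  if (length(left) == 0L || length(right) == 0L) {
    stop(sprintf("BioCyc parse error: reaction '%s' has an empty side", id),
         call. = FALSE)
  }
  dir_node <- xml2::xml_find_first(node, "./reaction-direction")
  dir_txt <- if (inherits(dir_node, "xml_missing")) "REVERSIBLE"
             else trimws(xml2::xml_text(dir_node))
  dir_txt <- sub("^PHYSIOL-", "", dir_txt)
  direction <- switch(dir_txt,
                      "LEFT-TO-RIGHT" = "forward",
                      "RIGHT-TO-LEFT" = "backward",
                      "REVERSIBLE" = "reversible",
                      stop(sprintf("BioCyc parse error: unknown direction '%s'", dir_txt),
                           call. = FALSE))
  parsed <- list(identifier = id, name = id, stoichiometry = c(left, right),
                 declared_direction = direction,
                 cross_refs = list(biocyc = id))
  .new_record("biocyc", id, "reaction", text, parsed)
}

.parse_biocyc_compound <- function(node, text) {
  id <- xml2::xml_attr(node, "frameid")
  formula <- NULL
  fn <- xml2::xml_find_first(node, ".//formula")
  if (!inherits(fn, "xml_missing")) {
    concise <- xml2::xml_attr(fn, "concise")
    ftxt <- if (!is.na(concise)) gsub(" ", "", concise) else trimws(xml2::xml_text(fn))
    if (nzchar(ftxt)) formula <- parse_formula(ftxt)
  }
  cn <- xml2::xml_find_first(node, "./cname|./common-name")
  nm <- if (inherits(cn, "xml_missing")) id else trimws(xml2::xml_text(cn))
  parsed <- list(identifier = id, name = nm, formula = formula, charge = NULL,
                 cross_refs = list(biocyc = id))
  .new_record("biocyc", id, "metabolite", text, parsed)
}

.parse_biocyc_pathway <- function(node, text) {
  id <- xml2::xml_attr(node, "frameid")
  rids <- xml2::xml_attr(
    xml2::xml_find_all(node, "./reaction-list/Reaction"), "frameid")
  if (!length(rids)) {
    stop(sprintf("BioCyc parse error: pathway '%s' has an empty reaction-list", id),
         call. = FALSE)
  }
  .new_record("biocyc", id, "pathway", text, pathway_template(id, unique(rids)))
}

# ---------------------------------------------------------------------------
# BiGG JSON dialect
# ---------------------------------------------------------------------------

#' Parse a BiGG-style JSON record
#'
#' Reaction records carry `bigg_id`, `name`, a `metabolites` array of
#' `{bigg_id, compartment_bigg_id, stoichiometry}` and a `pseudoreaction`
#' flag; pseudoreactions (exchanges, biomass) are rejected as non-importable
#' pathway content. Metabolite records carry `bigg_id`, `name`, `formulae`
#' and `charges`; the first formula/charge entry is used. Participant ids
#' compose as `<bigg_id>_<compartment_bigg_id>`.
#'
#' @param text raw JSON text.
#' @param kind expected record kind (`"metabolite"` or `"reaction"`).
#' @return A `db_record`.
#' @export
parse_bigg <- function(text, kind) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop(sprintf("BiGG parse error: %s",
                                                   conditionMessage(e)), call. = FALSE))
  if (is.null(doc$bigg_id)) stop("BiGG parse error: missing 'bigg_id'", call. = FALSE)
  id <- doc$bigg_id
  if (!is.null(doc$metabolites) || identical(kind, "reaction")) {
    if (isTRUE(doc$pseudoreaction)) {
      stop(sprintf(
        "BiGG record '%s' is a pseudoreaction (exchange/biomass); not importable pathway content",
        id), call. = FALSE)
    }
    stoich <- numeric(0)
    for (m in doc$metabolites) {
      mid <- paste0(m$bigg_id, "_", m$compartment_bigg_id)
      stoich[mid] <- (if (is.na(stoich[mid])) 0 else stoich[mid]) +
        as.numeric(m$stoichiometry)
    }
    parsed <- list(identifier = id,
                   name = if (is.null(doc$name)) id else doc$name,
                   stoichiometry = stoich,
                   declared_direction = "unspecified",
                   lower_bound = doc$lower_bound, upper_bound = doc$upper_bound,
                   cross_refs = list(bigg.reaction = id))
    return(.new_record("bigg", id, "reaction", text, parsed))
  }
  formula <- if (length(doc$formulae)) parse_formula(doc$formulae[[1]]) else NULL
  charge <- if (length(doc$charges)) as.numeric(doc$charges[[1]]) else NULL
  parsed <- list(identifier = id,
                 name = if (is.null(doc$name)) id else doc$name,
                 formula = formula, charge = charge,
                 cross_refs = list(bigg.metabolite = id))
  .new_record("bigg", id, "metabolite", text, parsed)
}

# ---------------------------------------------------------------------------
# User text format
# ---------------------------------------------------------------------------

#' Parse the user curation text format
#'
#' Line-oriented; `#` starts a comment line. Metabolite lines:
#' `M <id>, <name>, <compartment>, <formula|->, <charge|->`. Reaction lines:
#' `R <id>, <name> | <coef> <met_id>[, ...] <arrow> <coef> <met_id>[, ...]
#' | <lb>, <ub>` with arrow `->` (forward), `<->` (reversible) or `<-`
#' (backward); coefficients default to 1 and the trailing bounds group is
#' optional (defaults follow the declared direction).
#'
#' @param text file content.
#' @return List of `db_record` objects with `source = "user"`.
#' @export
parse_user_table <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  records <- list()
  seen <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tag <- substr(ln, 1, 1)
    body <- trimws(substring(ln, 2))
    rec <- switch(tag,
                  M = .parse_user_metabolite(body, i),
                  R = .parse_user_reaction(body, i),
                  stop(sprintf("user table parse error at line %d: unknown record tag '%s'",
                               i, tag), call. = FALSE))
    if (rec$identifier %in% seen) {
      stop(sprintf("user table parse error at line %d: duplicate id '%s'",
                   i, rec$identifier), call. = FALSE)
    }
    seen <- c(seen, rec$identifier)
    records[[length(records) + 1L]] <- rec
  }
  records
}

.parse_user_metabolite <- function(body, lineno) {
  parts <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  if (length(parts) != 5L) {
    stop(sprintf("user table parse error at line %d: metabolite line needs 5 comma-separated fields",
                 lineno), call. = FALSE)
  }
  parsed <- list(identifier = parts[1], name = parts[2], compartment = parts[3],
                 formula = if (parts[4] == "-") NULL else parse_formula(parts[4]),
                 charge = if (parts[5] == "-") NULL else as.numeric(parts[5]))
  .new_record("user", parts[1], "metabolite", paste("M", body), parsed)
}

.parse_user_reaction <- function(body, lineno) {
  groups <- trimws(strsplit(body, "|", fixed = TRUE)[[1]])
  if (length(groups) < 2L || length(groups) > 3L) {
    stop(sprintf("user table parse error at line %d: reaction line needs 2 or 3 '|' groups",
                 lineno), call. = FALSE)
  }
  head_parts <- trimws(strsplit(groups[1], ",", fixed = TRUE)[[1]])
  id <- head_parts[1]
  nm <- if (length(head_parts) > 1L) paste(head_parts[-1], collapse = ", ") else id
  if (!nzchar(id)) {
    stop(sprintf("user table parse error at line %d: missing reaction id", lineno),
         call. = FALSE)
  }
  eq <- groups[2]
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->"
           else if (grepl("->", eq, fixed = TRUE)) "->"
           else if (grepl("<-", eq, fixed = TRUE)) "<-"
           else stop(sprintf("user table parse error at line %d: no arrow in equation", lineno),
                     call. = FALSE)
  direction <- switch(arrow, "->" = "forward", "<->" = "reversible", "<-" = "backward")
  sides <- trimws(strsplit(eq, arrow, fixed = TRUE)[[1]])
  if (length(sides) != 2L || !nzchar(sides[1]) || !nzchar(sides[2])) {
    stop(sprintf("user table parse error at line %d: empty reaction side", lineno),
         call. = FALSE)
  }
  parse_side <- function(side, sign) {
    out <- numeric(0)
    for (tok in trimws(strsplit(side, ",", fixed = TRUE)[[1]])) {
      m <- regmatches(tok, regexec("^(?:([0-9.]+)\\s+)?([A-Za-z0-9_]+)$", tok))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("user table parse error at line %d: bad participant '%s'",
                     lineno, tok), call. = FALSE)
      }
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      out[m[3]] <- (if (is.na(out[m[3]])) 0 else out[m[3]]) + sign * coef
    }
    out
  }
  stoich <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  lb <- ub <- NULL
  if (length(groups) == 3L && nzchar(groups[3])) {
    bparts <- trimws(strsplit(groups[3], ",", fixed = TRUE)[[1]])
    if (length(bparts) != 2L) {
      stop(sprintf("user table parse error at line %d: bounds group needs 'lb, ub'", lineno),
           call. = FALSE)
    }
    lb <- as.numeric(bparts[1]); ub <- as.numeric(bparts[2])
  }
  parsed <- list(identifier = id, name = nm, stoichiometry = stoich,
                 declared_direction = direction,
                 lower_bound = lb, upper_bound = ub, cross_refs = list())
  .new_record("user", id, "reaction", paste("R", body), parsed)
}

# ---------------------------------------------------------------------------
# Conversion into model objects
# ---------------------------------------------------------------------------

#' Convert a database record into a model object
#'
#' Metabolite records become compartment-suffixed `cb_metabolite`s. For
#' reaction records each participant is resolved against the model in a
#' fixed order: (1) exact id `<db_id>_<compartment>` already in the model,
#' (2) cross-reference match via [find_by_cross_reference()], (3) a new stub
#' metabolite built from the cached metabolite record (fetched on demand
#' through `config`). Stub metabolites travel on the returned reaction as
#' `attr(, "stub_metabolites")` until [run_curation()] inserts them. When
#' the model already contains an entity with the record's id or
#' cross-reference, that existing entity is returned (the duplicate is then
#' reported by the curation battery). Pathway records convert every member
#' reaction and return a `cb_pathway` carrying the converted reactions as
#' `attr(, "reactions")`; database gene associations become OR-joined gene
#' rules.
#'
#' @param record a `db_record`.
#' @param model the target `cb_model`.
#' @param config a [tool_config()]; needed to fetch participant metabolite
#'   records on demand.
#' @param compartment target compartment tag; defaults to
#'   `config$default_compartment`.
#' @return A `cb_metabolite`, `cb_reaction`, or `cb_pathway`.
#' @export
create_object <- function(record, model, config,
                          compartment = config$default_compartment) {
  stopifnot(inherits(record, "db_record"))
  if (!compartment %in% names(model$compartments)) {
    warning(sprintf("compartment '%s' not registered in model; it will be added",
                    compartment), call. = FALSE)
  }
  switch(record$kind,
         metabolite = .record_to_metabolite(record, compartment),
         reaction = .record_to_reaction(record, model, config, compartment),
         pathway = .record_to_pathway(record, model, config, compartment))
}

.xref_ns <- function(source, kind) {
  switch(source,
         kegg = if (kind == "metabolite") "kegg.compound" else "kegg.reaction",
         biocyc = "biocyc",
         bigg = if (kind == "metabolite") "bigg.metabolite" else "bigg.reaction",
         user = NA_character_)
}

.record_to_metabolite <- function(record, compartment) {
  p <- record$parsed
  comp <- if (record$source == "user" && !is.null(p$compartment)) p$compartment else compartment
  id <- if (grepl(paste0("_", comp, "$"), p$identifier)) p$identifier
        else paste0(p$identifier, "_", comp)
  xr <- p$cross_refs
  ns <- .xref_ns(record$source, "metabolite")
  if (!is.na(ns)) xr[[ns]] <- unique(c(xr[[ns]], record$identifier))
  metabolite(id = id, name = p$name, compartment = comp,
             formula = p$formula, charge = p$charge, cross_refs = xr)
}

.record_to_reaction <- function(record, model, config, compartment) {
  p <- record$parsed
  ns <- .xref_ns(record$source, "reaction")
  # duplicate path: an entity for this very record already lives in the model
  if (p$identifier %in% names(model$reactions)) {
    return(model$reactions[[p$identifier]])
  }
  if (!is.na(ns)) {
    existing <- find_by_cross_reference(model, ns, record$identifier)
    if (!is.null(existing) && existing %in% names(model$reactions)) {
      return(model$reactions[[existing]])
    }
  }
  stoich <- numeric(0)
  stubs <- list()
  missing <- character(0)
  for (db_id in names(p$stoichiometry)) {
    res <- .resolve_participant(db_id, record$source, model, config, compartment)
    if (is.null(res$id)) {
      missing <- c(missing, res$missing)
      next
    }
    stoich[res$id] <- (if (is.na(stoich[res$id])) 0 else stoich[res$id]) +
      p$stoichiometry[[db_id]]
    if (!is.null(res$stub)) stubs[[res$stub$id]] <- res$stub
  }
  if (length(missing)) {
    stop(structure(class = c("pc_data_error", "error", "condition"),
                   list(message = sprintf(
                     "cannot resolve participant metabolite record(s): %s",
                     paste(missing, collapse = ", ")), call = NULL)))
  }
  stoich <- stoich[stoich != 0]
  xr <- p$cross_refs
  if (!is.na(ns)) xr[[ns]] <- unique(c(xr[[ns]], record$identifier))
  gene_rule <- ""
  if (!is.null(p$genes) && length(p$genes)) {
    gene_rule <- paste(p$genes, collapse = " or ")
  }
  rxn <- reaction(id = p$identifier, stoichiometry = stoich, name = p$name,
                  declared_direction = p$declared_direction,
                  lower_bound = p$lower_bound, upper_bound = p$upper_bound,
                  gene_rule = gene_rule, cross_refs = xr)
  attr(rxn, "stub_metabolites") <- stubs
  rxn
}

.resolve_participant <- function(db_id, source, model, config, compartment) {
  # BiGG participants arrive pre-suffixed with their compartment
  cand <- if (grepl("^[A-Za-z0-9_]+_[a-z0-9]+$", db_id) && source == "bigg") db_id
          else paste0(db_id, "_", compartment)
  if (cand %in% names(model$metabolites)) return(list(id = cand))
  ns <- .xref_ns(source, "metabolite")
  lookup_id <- if (source == "bigg") sub("_[a-z0-9]+$", "", db_id) else db_id
  if (!is.na(ns)) {
    hit <- find_by_cross_reference(model, ns, lookup_id)
    if (!is.null(hit) && hit %in% names(model$metabolites)) return(list(id = hit))
  }
  if (source == "user") {
    return(list(id = NULL, missing = db_id))
  }
  rec <- tryCatch(fetch_record(source, lookup_id, "metabolite", config),
                  pc_data_error = function(e) NULL,
                  error = function(e) NULL)
  if (is.null(rec)) {
    return(list(id = NULL, missing = sprintf("%s:%s", source, lookup_id)))
  }
  stub_comp <- if (source == "bigg" && grepl("_[a-z0-9]+$", db_id))
    sub("^.*_", "", db_id) else compartment
  stub <- .record_to_metabolite(rec, stub_comp)
  list(id = stub$id, stub = stub)
}

.record_to_pathway <- function(record, model, config, compartment) {
  tmpl <- record$parsed
  rxns <- list()
  for (rid in tmpl$reaction_identifiers) {
    rec <- fetch_record(record$source, rid, "reaction", config)
    genes <- tmpl$gene_associations[[rid]]
    if (!is.null(genes)) rec$parsed$genes <- genes
    rxn <- .record_to_reaction(rec, model, config, compartment)
    rxns[[rxn$id]] <- rxn
  }
  pw <- pathway(id = record$identifier,
                reaction_ids = names(rxns),
                source = c(record$source, record$identifier))
  attr(pw, "reactions") <- rxns
  pw
}
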