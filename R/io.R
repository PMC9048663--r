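#' Read and write models in COBRA JSON
#'
#' The interchange format is the community COBRA JSON model schema: a single
#' object with `id`, `metabolites`, `reactions` and `genes` arrays; reaction
#' entries carry a `metabolites` coefficient mapping, `lower_bound`,
#' `upper_bound`, `gene_reaction_rule` and `objective_coefficient`;
#' metabolite entries carry `id`, `name`, `compartment`, `formula`, `charge`
#' and an `annotation` block. Annotations use identifiers.org-style
#' namespaces (`kegg.reaction`, `biocyc`, `bigg.metabolite`, ...) and map to
#' the entities' `cross_refs`. Pathway objects attached to the model are
#' persisted under a `pathways` key (the COBRA schema itself has no pathway
#' concept). Serialization is canonical — keys sorted, entity arrays sorted
#' by id — so writing the same model twice is byte-identical.
#'
#' Unknown keys encountered while reading are preserved opaquely on the
#' entity (`extra`) and re-emitted on write; a message notes them.
#'
#' @param path file path.
#' @param model a `cb_model`.
#' @return `read_model()` returns a `cb_model`; `write_model()` returns
#'   `path` invisibly.
#' @export
read_model <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop(sprintf("malformed COBRA JSON '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  for (k in c("metabolites", "reactions", "genes")) {
    if (is.null(doc[[k]])) stop(sprintf("malformed COBRA JSON: missing key '%s'", k),
                                call. = FALSE)
  }
  comp <- if (length(doc$compartments)) {
    stats::setNames(as.character(unlist(doc$compartments)), names(doc$compartments))
  } else c(c = "cytosol")
  model <- new_model(id = if (is.null(doc$id)) "model" else doc$id,
                     compartments = comp)

  known_top <- c("id", "metabolites", "reactions", "genes", "compartments",
                 "pathways", "version")
  extra_top <- setdiff(names(doc), known_top)
  if (length(extra_top)) {
    message("preserving unknown model keys: ", paste(extra_top, collapse = ", "))
    model$extra <- doc[extra_top]
  }

  known_met <- c("id", "name", "compartment", "formula", "charge", "annotation")
  for (i in seq_along(doc$metabolites)) {
    m <- doc$metabolites[[i]]
    if (is.null(m$id)) stop(sprintf("metabolites[%d]: missing 'id'", i), call. = FALSE)
    met <- tryCatch(
      metabolite(id = m$id,
                 name = if (is.null(m$name)) m$id else m$name,
                 compartment = m$compartment,
                 formula = if (is.null(m$formula) || !nzchar(m$formula)) NULL else m$formula,
                 charge = m$charge,
                 cross_refs = .annotation_to_xrefs(m$annotation)),
      error = function(e) stop(sprintf("metabolites[%d] ('%s'): %s",
                                       i, m$id, conditionMessage(e)), call. = FALSE))
    unk <- setdiff(names(m), known_met)
    if (length(unk)) {
      message(sprintf("metabolite '%s': preserving unknown keys: %s",
                      m$id, paste(unk, collapse = ", ")))
      met$extra <- m[unk]
    }
    model <- .insert_metabolite(model, met)
  }

  known_rxn <- c("id", "name", "metabolites", "lower_bound", "upper_bound",
                 "gene_reaction_rule", "objective_coefficient", "annotation",
                 "declared_direction")
  objective <- stats::setNames(numeric(0), character(0))
  for (i in seq_along(doc$reactions)) {
    r <- doc$reactions[[i]]
    if (is.null(r$id)) stop(sprintf("reactions[%d]: missing 'id'", i), call. = FALSE)
    stoich <- vapply(r$metabolites, as.numeric, numeric(1))
    rxn <- tryCatch(
      reaction(id = r$id,
               stoichiometry = stoich,
               name = if (is.null(r$name)) r$id else r$name,
               declared_direction = if (is.null(r$declared_direction))
                 "unspecified" else r$declared_direction,
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               gene_rule = if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule,
               cross_refs = .annotation_to_xrefs(r$annotation)),
      error = function(e) stop(sprintf("reactions[%d] ('%s'): %s",
                                       i, r$id, conditionMessage(e)), call. = FALSE))
    unk <- setdiff(names(r), known_rxn)
    if (length(unk)) {
      message(sprintf("reaction '%s': preserving unknown keys: %s",
                      r$id, paste(unk, collapse = ", ")))
      rxn$extra <- r[unk]
    }
    model <- .insert_reaction(model, rxn)
    oc <- r$objective_coefficient
    if (!is.null(oc) && oc != 0) objective[r$id] <- as.numeric(oc)
  }
  model$objective <- objective

  for (p in doc$pathways) {
    pw <- pathway(id = p$id,
                  reaction_ids = as.character(unlist(p$reaction_ids)),
                  source = if (length(p$source)) as.character(unlist(p$source)) else NULL,
                  notes = if (is.null(p$notes)) "" else p$notes)
    model$pathways[[pw$id]] <- pw
  }
  check_model_integrity(model)
  model
}

.annotation_to_xrefs <- function(ann) {
  if (is.null(ann) || length(ann) == 0L) return(list())
  lapply(ann, function(v) as.character(unlist(v)))
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  check_model_integrity(model)
  mets <- lapply(sort(names(model$metabolites)), function(id) {
    m <- model$metabolites[[id]]
    o <- list(annotation = .xrefs_to_annotation(m$cross_refs),
              compartment = m$compartment, id = m$id, name = m$name)
    if (!is.null(m$charge)) o$charge <- m$charge
    if (!is.null(m$formula)) o$formula <- formula_to_string(m$formula)
    c(o, m$extra)[order(names(c(o, m$extra)))]
  })
  rxns <- lapply(sort(names(model$reactions)), function(id) {
    r <- model$reactions[[id]]
    oc <- if (id %in% names(model$objective)) model$objective[[id]] else 0
    o <- list(annotation = .xrefs_to_annotation(r$cross_refs),
              declared_direction = r$declared_direction,
              gene_reaction_rule = r$gene_rule, id = r$id,
              lower_bound = r$lower_bound,
              metabolites = as.list(r$stoichiometry[order(names(r$stoichiometry))]),
              name = r$name, objective_coefficient = oc,
              upper_bound = r$upper_bound)
    c(o, r$extra)[order(names(c(o, r$extra)))]
  })
  genes <- lapply(sort(model$genes), function(g) list(id = g, name = g))
  pws <- lapply(sort(names(model$pathways)), function(id) {
    p <- model$pathways[[id]]
    list(id = p$id, notes = p$notes,
         reaction_ids = as.list(p$reaction_ids),
         source = if (is.null(p$source)) NULL else as.list(p$source))
  })
  doc <- list(compartments = as.list(model$compartments[order(names(model$compartments))]),
              genes = genes, id = model$id, metabolites = mets,
              pathways = pws, reactions = rxns, version = "1")
  doc <- c(doc, model$extra)[order(names(c(doc, model$extra)))]
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

.xrefs_to_annotation <- function(xr) {
  if (length(xr) == 0L) return(stats::setNames(list(), character(0)))
  lapply(xr[order(names(xr))], as.list)
}
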