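#' Constraint-based model container
#'
#' A `cb_model` holds named collections of metabolites and reactions, the
#' gene set (always the union of identifiers over all gene rules), the
#' objective (reaction id to weight), registered compartments, and any
#' pathway objects attached to the model. Models are plain R values: all
#' mutators return the updated model.
#'
#' @param id model identifier.
#' @param compartments named character vector, tag to display name.
#' @return A `cb_model`.
#' @export
new_model <- function(id = "model", compartments = c(c = "cytosol")) {
  structure(list(id = id,
                 metabolites = stats::setNames(list(), character(0)),
                 reactions = stats::setNames(list(), character(0)),
                 genes = character(0),
                 objective = stats::setNames(numeric(0), character(0)),
                 compartments = compartments,
                 pathways = stats::setNames(list(), character(0)),
                 extra = list()),
            class = "cb_model")
}

#' @export
print.cb_model <- function(x, ...) {
  cat(sprintf("<model> %s: %d metabolites, %d reactions, %d genes, %d pathways\n",
              x$id, length(x$metabolites), length(x$reactions),
              length(x$genes), length(x$pathways)))
  invisible(x)
}

.rule_gene_union <- function(reactions) {
  sort(unique(as.character(unlist(
    lapply(reactions, function(r) .genes_in_rule(r$gene_rule)),
    use.names = FALSE))))
}

.recompute_genes <- function(model) {
  model$genes <- .rule_gene_union(model$reactions)
  model
}

# Low-level insertion; curated addition lives in run_curation()/add_*().
.insert_metabolite <- function(model, met) {
  stopifnot(inherits(met, "cb_metabolite"))
  if (met$id %in% names(model$metabolites)) {
    stop(sprintf("metabolite id '%s' already in model", met$id), call. = FALSE)
  }
  if (!met$compartment %in% names(model$compartments)) {
    warning(sprintf("auto-registering compartment '%s'", met$compartment),
            call. = FALSE)
    model$compartments[met$compartment] <- met$compartment
  }
  model$metabolites[[met$id]] <- met
  model
}

.insert_reaction <- function(model, rxn) {
  stopifnot(inherits(rxn, "cb_reaction"))
  if (rxn$id %in% names(model$reactions)) {
    stop(sprintf("reaction id '%s' already in model", rxn$id), call. = FALSE)
  }
  missing <- setdiff(names(rxn$stoichiometry), names(model$metabolites))
  if (length(missing)) {
    stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                 rxn$id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  model$reactions[[rxn$id]] <- rxn
  .recompute_genes(model)
}

#' Check model referential integrity
#'
#' Verifies that every stoichiometry entry resolves to a model metabolite,
#' that the objective references existing reactions, and that the gene set
#' equals the union over gene rules.
#'
#' @param model a `cb_model`.
#' @return Invisibly `TRUE`; errors name the dangling identifier otherwise.
#' @export
check_model_integrity <- function(model) {
  stopifnot(inherits(model, "cb_model"))
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), names(model$metabolites))
    if (length(missing)) {
      stop(sprintf("integrity violation: reaction '%s' references missing metabolite '%s'",
                   r$id, missing[1]), call. = FALSE)
    }
  }
  dangling <- setdiff(names(model$objective), names(model$reactions))
  if (length(dangling)) {
    stop(sprintf("integrity violation: objective references missing reaction '%s'",
                 dangling[1]), call. = FALSE)
  }
  expected <- .rule_gene_union(model$reactions)
  if (!identical(sort(as.character(model$genes)), expected)) {
    stop("integrity violation: gene set does not match gene rules", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build the stoichiometric matrix
#'
#' Returns the dense metabolites-by-reactions matrix S with rows and columns
#' in id-sorted order; entry (i, j) is the coefficient of metabolite i in
#' reaction j (0 when absent).
#'
#' @param model a `cb_model` passing [check_model_integrity()].
#' @return A numeric matrix with `dimnames = list(metabolite_ids, reaction_ids)`.
#' @export
build_stoichiometric_matrix <- function(model) {
  check_model_integrity(model)
  met_ids <- sort(names(model$metabolites))
  rxn_ids <- sort(names(model$reactions))
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (rid in rxn_ids) {
    s <- model$reactions[[rid]]$stoichiometry
    S[names(s), rid] <- s
  }
  S
}

#' Look up an entity by cross-reference
#'
#' Searches metabolites and reactions for the first entity (id-sorted over
#' the combined pool) whose `cross_refs[[namespace]]` contains `identifier`.
#'
#' @param model a `cb_model`.
#' @param namespace identifiers.org-style namespace, e.g. `"kegg.reaction"`.
#' @param identifier external identifier to look up.
#' @return The matching entity id, or `NULL` when absent.
#' @export
find_by_cross_reference <- function(model, namespace, identifier) {
  pool <- c(model$metabolites, model$reactions)
  for (id in sort(names(pool))) {
    refs <- pool[[id]]$cross_refs[[namespace]]
    if (!is.null(refs) && identifier %in% refs) return(id)
  }
  NULL
}

#' Set the model objective
#'
#' @param model a `cb_model`.
#' @param objective named numeric vector, reaction id to weight.
#' @return The updated model.
#' @export
set_objective <- function(model, objective) {
  stopifnot(is.numeric(objective), !is.null(names(objective)))
  missing <- setdiff(names(objective), names(model$reactions))
  if (length(missing)) {
    stop(sprintf("objective references unknown reaction(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  model$objective <- objective
  model
}
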