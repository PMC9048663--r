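#' Model entities: metabolites, reactions, pathways
#'
#' Constructors for the building blocks of a constraint-based model.
#' Metabolite ids follow the community convention `<base>_<compartment>`
#' (e.g. `glc__D_c`): the trailing lowercase-alphanumeric tag after the last
#' underscore must equal the `compartment` field. Reaction bounds are flux
#' limits in mmol/gDW/h; the conventional defaults depend on the declared
#' direction: reversible (-1000, 1000), forward (0, 1000), backward
#' (-1000, 0).
#'
#' @name entities
NULL

.default_bounds <- function(direction) {
  switch(direction,
    reversible  = c(-1000, 1000),
    forward     = c(0, 1000),
    backward    = c(-1000, 0),
    unspecified = c(-1000, 1000),
    stop("unknown direction: ", direction, call. = FALSE)
  )
}

.directions <- c("reversible", "forward", "backward", "unspecified")

#' @param id entity identifier (metabolites: compartment-suffixed).
#' @param name human-readable name.
#' @param compartment compartment tag, lowercase alphanumeric.
#' @param formula a [chem_formula()], a formula string, or `NULL` (absent).
#' @param charge integer charge or `NULL` (absent).
#' @param cross_refs named list, database namespace (identifiers.org style,
#'   e.g. `kegg.compound`) to character vector of identifiers.
#' @return `metabolite()` returns a `cb_metabolite`.
#' @rdname entities
#' @export
metabolite <- function(id, name = id, compartment = NULL,
                       formula = NULL, charge = NULL, cross_refs = list()) {
  if (!grepl("^[A-Za-z0-9_]+_[a-z0-9]+$", id)) {
    stop(sprintf("metabolite id '%s' must be <base>_<compartment-tag>", id),
         call. = FALSE)
  }
  tag <- sub("^.*_", "", id)
  if (is.null(compartment)) compartment <- tag
  if (!identical(tag, compartment)) {
    stop(sprintf("id '%s' ends in compartment tag '%s' but compartment is '%s'",
                 id, tag, compartment), call. = FALSE)
  }
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!is.null(formula)) stopifnot(inherits(formula, "chem_formula"))
  if (!is.null(charge)) {
    stopifnot(is.numeric(charge), length(charge) == 1L, charge == round(charge))
    charge <- as.numeric(charge)
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, charge = charge,
                 cross_refs = .norm_xrefs(cross_refs), extra = list()),
            class = "cb_metabolite")
}

.norm_xrefs <- function(cross_refs) {
  stopifnot(is.list(cross_refs))
  if (length(cross_refs)) {
    cross_refs <- lapply(cross_refs, as.character)
    cross_refs <- cross_refs[order(names(cross_refs))]
  }
  cross_refs
}

#' @param stoichiometry named numeric vector, metabolite id to signed
#'   coefficient (negative = consumed). Non-empty, no zero entries.
#' @param lower_bound,upper_bound finite flux bounds, `lower_bound <=
#'   upper_bound`; defaults derive from `declared_direction`.
#' @param gene_rule boolean gene association expression (string; `""` = none).
#' @param declared_direction one of `"reversible"`, `"forward"`,
#'   `"backward"`, `"unspecified"` — the directionality asserted by the data
#'   source, checked against the bounds during curation.
#' @return `reaction()` returns a `cb_reaction`.
#' @rdname entities
#' @export
reaction <- function(id, stoichiometry, name = id,
                     declared_direction = "unspecified",
                     lower_bound = NULL, upper_bound = NULL,
                     gene_rule = "", cross_refs = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  declared_direction <- match.arg(declared_direction, .directions)
  if (length(stoichiometry) == 0L) {
    stop(sprintf("reaction '%s': empty stoichiometry", id), call. = FALSE)
  }
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop(sprintf("reaction '%s': stoichiometry must be a named vector", id),
         call. = FALSE)
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop(sprintf("reaction '%s': duplicate metabolite in stoichiometry", id),
         call. = FALSE)
  }
  if (any(stoichiometry == 0)) {
    stop(sprintf("reaction '%s': zero stoichiometric coefficient", id),
         call. = FALSE)
  }
  defaults <- .default_bounds(declared_direction)
  if (is.null(lower_bound)) lower_bound <- defaults[1]
  if (is.null(upper_bound)) upper_bound <- defaults[2]
  if (!is.finite(lower_bound) || !is.finite(upper_bound)) {
    stop(sprintf("reaction '%s': bounds must be finite", id), call. = FALSE)
  }
  if (lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': lower_bound %g > upper_bound %g",
                 id, lower_bound, upper_bound), call. = FALSE)
  }
  stoichiometry <- stoichiometry[order(names(stoichiometry))]
  structure(list(id = id, name = name,
                 stoichiometry = stats::setNames(as.numeric(stoichiometry), names(stoichiometry)),
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene_rule = gene_rule,
                 declared_direction = declared_direction,
                 cross_refs = .norm_xrefs(cross_refs), extra = list()),
            class = "cb_reaction")
}

#' @param reaction_ids ordered, duplicate-free character vector of reaction
#'   ids belonging to the pathway.
#' @param source optional `c(database, identifier)` provenance pair.
#' @param notes free-text notes.
#' @return `pathway()` returns a `cb_pathway`.
#' @rdname entities
#' @export
pathway <- function(id, reaction_ids, source = NULL, notes = "") {
  stopifnot(is.character(id), length(id) == 1L)
  reaction_ids <- as.character(reaction_ids)
  if (length(reaction_ids) == 0L) {
    stop(sprintf("pathway '%s': reaction_ids must be non-empty", id), call. = FALSE)
  }
  if (anyDuplicated(reaction_ids)) {
    stop(sprintf("pathway '%s': duplicate reaction ids", id), call. = FALSE)
  }
  if (!is.null(source)) {
    stopifnot(is.character(source), length(source) == 2L)
  }
  structure(list(id = id, reaction_ids = reaction_ids,
                 source = source, notes = notes),
            class = "cb_pathway")
}

.stoich_string <- function(r) {
  s <- r$stoichiometry
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  }
  arrow <- switch(r$declared_direction,
                  reversible = "<=>", forward = "-->",
                  backward = "<--", unspecified = "<?>")
  paste(side(s[s < 0]), arrow, side(s[s > 0]))
}

#' @export
print.cb_metabolite <- function(x, ...) {
  cat(sprintf("<metabolite> %s (%s) [%s] formula=%s charge=%s\n",
              x$id, x$name, x$compartment,
              if (is.null(x$formula)) "-" else formula_to_string(x$formula),
              if (is.null(x$charge)) "-" else x$charge))
  invisible(x)
}

#' @export
print.cb_reaction <- function(x, ...) {
  cat(sprintf("<reaction> %s: %s  bounds=(%g, %g)\n",
              x$id, .stoich_string(x), x$lower_bound, x$upper_bound))
  invisible(x)
}

#' @export
print.cb_pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s: %d reactions [%s]%s\n",
              x$id, length(x$reaction_ids),
              paste(x$reaction_ids, collapse = ", "),
              if (is.null(x$source)) "" else
                sprintf(" from %s:%s", x$source[1], x$source[2])))
  invisible(x)
}

# Gene identifiers appearing in a boolean gene rule (tokens minus operators).
.genes_in_rule <- function(rule) {
  if (is.null(rule) || !nzchar(rule)) return(character(0))
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  setdiff(toks, c("and", "or", "AND", "OR"))
}
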