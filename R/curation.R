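#' Curation findings and reports
#'
#' Every issue the curation battery detects becomes a `pc_finding` with a
#' check label (`duplicate`, `missing_formula`, `mass_imbalance`,
#' `charge_imbalance`, `reversibility_mismatch`, `indeterminate_formula`),
#' the entity concerned, a severity (`info` or `warning` — curation warns,
#' it never aborts), a message and an optional suggestion. A
#' `curation_report` aggregates findings with per-check counts and the lists
#' of entities added to and skipped from the model.
#'
#' @name curation_report
NULL

.checks <- c("duplicate", "missing_formula", "mass_imbalance",
             "charge_imbalance", "reversibility_mismatch",
             "indeterminate_formula")

.finding <- function(check, entity_id, message, suggestion = "",
                     severity = "warning") {
  check <- match.arg(check, .checks)
  severity <- match.arg(severity, c("info", "warning"))
  structure(list(check = check, entity_id = entity_id, severity = severity,
                 message = message, suggestion = suggestion),
            class = "pc_finding")
}

.new_report <- function(findings, added, skipped) {
  counts <- stats::setNames(integer(length(.checks)), .checks)
  for (f in findings) counts[f$check] <- counts[f$check] + 1L
  stopifnot(!length(intersect(added, skipped)))
  structure(list(findings = findings, counts = counts,
                 entities_added = added, entities_skipped = skipped),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(curation_summary(x), sep = "\n")
  invisible(x)
}

#' Human-readable curation summary
#'
#' @param report a `curation_report`.
#' @return Character vector of summary lines.
#' @export
curation_summary <- function(report) {
  lines <- c(sprintf("curation summary: %d added, %d skipped, %d finding(s)",
                     length(report$entities_added),
                     length(report$entities_skipped),
                     length(report$findings)))
  nz <- report$counts[report$counts > 0]
  for (chk in names(nz)) {
    lines <- c(lines, sprintf("  %-24s %d", chk, nz[[chk]]))
  }
  lines
}

#' Export a curation report as TSV
#'
#' Columns: check, entity_id, severity, message, suggestion.
#'
#' @param report a `curation_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
report_to_tsv <- function(report, path) {
  df <- data.frame(
    check = vapply(report$findings, `[[`, character(1), "check"),
    entity_id = vapply(report$findings, `[[`, character(1), "entity_id"),
    severity = vapply(report$findings, `[[`, character(1), "severity"),
    message = vapply(report$findings, `[[`, character(1), "message"),
    suggestion = vapply(report$findings, `[[`, character(1), "suggestion"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Elemental and charge balance of a reaction
#'
#' Computes, for every element appearing in the participants' formulas, the
#' residual `sum_m coeff(m) * formula(m)[element]` (products minus
#' reactants) plus the analogous charge residual. A reaction is `balanced`
#' iff all element residuals and the charge residual are zero. Any
#' participant lacking a formula, or carrying an indeterminate formula
#' (generic R/X groups), makes the outcome `undetermined` — the check never
#' guesses. A missing charge is treated as 0.
#'
#' @param rxn a `cb_reaction` resolving in `model`.
#' @param model the owning `cb_model`.
#' @return A list with `status` (`"balanced"`, `"imbalanced"`,
#'   `"undetermined"`), `residuals` (named numeric, per element),
#'   `charge_residual`, and `suggestion` (non-empty when imbalanced).
#' @export
check_mass_balance <- function(rxn, model) {
  stopifnot(inherits(rxn, "cb_reaction"))
  mets <- lapply(names(rxn$stoichiometry), function(mid) {
    m <- model$metabolites[[mid]]
    if (is.null(m)) stop(sprintf("reaction '%s': metabolite '%s' not in model",
                                 rxn$id, mid), call. = FALSE)
    m
  })
  no_formula <- vapply(mets, function(m) is.null(m$formula), logical(1))
  indet <- vapply(mets, function(m) !is.null(m$formula) && m$formula$indeterminate,
                  logical(1))
  if (any(no_formula) || any(indet)) {
    return(list(status = "undetermined",
                residuals = stats::setNames(numeric(0), character(0)),
                charge_residual = NA_real_, suggestion = ""))
  }
  elements <- sort(unique(unlist(lapply(mets, function(m) names(m$formula$counts)))))
  residuals <- stats::setNames(numeric(length(elements)), elements)
  charge_residual <- 0
  for (i in seq_along(mets)) {
    coef <- rxn$stoichiometry[[mets[[i]]$id]]
    cnts <- mets[[i]]$formula$counts
    residuals[names(cnts)] <- residuals[names(cnts)] + coef * cnts
    ch <- if (is.null(mets[[i]]$charge)) 0 else mets[[i]]$charge
    charge_residual <- charge_residual + coef * ch
  }
  balanced <- all(abs(residuals) < 1e-9) && abs(charge_residual) < 1e-9
  suggestion <- ""
  if (!balanced) {
    bits <- character(0)
    for (e in names(residuals)[abs(residuals) > 1e-9]) {
      d <- residuals[[e]]
      side <- if (d < 0) "product" else "reactant"
      bits <- c(bits, sprintf("add %g %s to the %s side", abs(d), e, side))
    }
    if (abs(charge_residual) > 1e-9) {
      bits <- c(bits, sprintf("charge residual %+g", charge_residual))
    }
    suggestion <- paste(bits, collapse = "; ")
  }
  list(status = if (balanced) "balanced" else "imbalanced",
       residuals = residuals, charge_residual = charge_residual,
       suggestion = suggestion)
}

#' Detect a duplicate of a candidate entity
#'
#' Match order: (1) identical id already in the model; (2) any shared
#' cross-reference `(namespace, identifier)` pair; (3) for reactions only,
#' coefficient-identical stoichiometry after id sorting. The first hit wins.
#'
#' @param model a `cb_model`.
#' @param candidate a `cb_metabolite` or `cb_reaction`.
#' @return The id of the existing duplicate entity, or `NULL`.
#' @export
detect_duplicate <- function(model, candidate) {
  is_rxn <- inherits(candidate, "cb_reaction")
  pool_names <- if (is_rxn) names(model$reactions) else names(model$metabolites)
  if (candidate$id %in% pool_names) return(candidate$id)
  for (ns in names(candidate$cross_refs)) {
    for (ident in candidate$cross_refs[[ns]]) {
      hit <- find_by_cross_reference(model, ns, ident)
      if (!is.null(hit) && hit %in% pool_names) return(hit)
    }
  }
  if (is_rxn) {
    cs <- candidate$stoichiometry[order(names(candidate$stoichiometry))]
    for (rid in sort(names(model$reactions))) {
      es <- model$reactions[[rid]]$stoichiometry
      es <- es[order(names(es))]
      if (identical(names(cs), names(es)) && isTRUE(all(cs == es))) return(rid)
    }
  }
  NULL
}

#' Check declared direction against the flux bounds
#'
#' Mismatch table: reversible declared but `lower_bound >= 0`; forward
#' declared but `lower_bound < 0`; backward declared but `upper_bound > 0`.
#' Declared direction `"unspecified"` is never a mismatch.
#'
#' @param rxn a `cb_reaction`.
#' @return A `pc_finding` describing the mismatch with the reconciling bound
#'   change as suggestion, or `NULL` when consistent.
#' @export
check_reversibility <- function(rxn) {
  d <- rxn$declared_direction
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  msg <- sugg <- NULL
  if (d == "reversible" && lb >= 0) {
    msg <- sprintf("declared reversible but lower_bound %g forbids backward flux", lb)
    sugg <- "set lower_bound to -1000"
  } else if (d == "forward" && lb < 0) {
    msg <- sprintf("declared forward but lower_bound %g allows backward flux", lb)
    sugg <- "set lower_bound to 0"
  } else if (d == "backward" && ub > 0) {
    msg <- sprintf("declared backward but upper_bound %g allows forward flux", ub)
    sugg <- "set upper_bound to 0"
  }
  if (is.null(msg)) return(NULL)
  .finding("reversibility_mismatch", rxn$id, msg, sugg)
}

.log_lines <- function(log_path, lines) {
  if (is.null(log_path)) return(invisible(NULL))
  con <- file(log_path, open = "a")
  on.exit(close(con))
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  writeLines(paste0(stamp, " | ", lines), con)
  invisible(NULL)
}

.assert_writable_log <- function(log_path) {
  if (is.null(log_path)) return(invisible(NULL))
  dir <- dirname(log_path)
  if (!dir.exists(dir) || file.access(dir, mode = 2L) != 0L) {
    stop(sprintf("log path '%s' is not writable", log_path), call. = FALSE)
  }
  invisible(NULL)
}

#' Run the curation battery and add entities to a model
#'
#' For each entity the applicable checks run in fixed order: duplicate,
#' missing formula, mass balance, reversibility. Duplicates are skipped (the
#' model is left untouched for them, which makes repeated addition
#' idempotent); every other issue is reported as a warning-level finding and
#' the entity is still added — curation warns, it does not block. Pathway
#' entities contribute their member reactions (plus any stub metabolites
#' those carry) and are then registered on the model. The full narrative is
#' appended to `log_path` and a summary is printed to the console.
#'
#' @param model a `cb_model`.
#' @param entities list of `cb_metabolite` / `cb_reaction` / `cb_pathway`
#'   (a single entity may be passed bare).
#' @param log_path log file (append mode), or `NULL` to skip logging.
#' @param quiet suppress the console summary.
#' @return A list with the updated `model` and the `report`
#'   (`curation_report`).
#' @export
run_curation <- function(model, entities, log_path = NULL, quiet = FALSE) {
  .assert_writable_log(log_path)
  if (inherits(entities, c("cb_metabolite", "cb_reaction", "cb_pathway"))) {
    entities <- list(entities)
  }
  findings <- list()
  added <- character(0)
  skipped <- character(0)
  log_buf <- character(0)
  note <- function(f) {
    findings[[length(findings) + 1L]] <<- f
    log_buf <<- c(log_buf, sprintf("%s | %s | %s | %s",
                                   toupper(f$severity), f$check, f$entity_id, f$message))
    if (!quiet) warning(sprintf("[%s] %s: %s", f$check, f$entity_id, f$message),
                        call. = FALSE)
  }

  add_metabolite_curated <- function(met, silent_dup = FALSE) {
    dup <- detect_duplicate(model, met)
    if (!is.null(dup)) {
      # stub metabolites resolved during conversion are plumbing: a repeat
      # occurrence is expected, not a curation finding
      if (!silent_dup) {
        note(.finding("duplicate", met$id,
                      sprintf("metabolite duplicates existing '%s'; skipped", dup)))
        skipped <<- unique(c(skipped, met$id))
      }
      return(invisible(NULL))
    }
    if (is.null(met$formula)) {
      note(.finding("missing_formula", met$id,
                    "metabolite has no chemical formula",
                    "supply a formula to enable mass-balance checking"))
    } else if (met$formula$indeterminate) {
      note(.finding("indeterminate_formula", met$id,
                    sprintf("formula '%s' contains a generic group; mass balance will be undetermined",
                            formula_to_string(met$formula))))
    }
    model <<- .insert_metabolite(model, met)
    added <<- c(added, met$id)
    log_buf <<- c(log_buf, sprintf("INFO | added | %s | metabolite added", met$id))
  }

  add_reaction_curated <- function(rxn) {
    for (stub in attr(rxn, "stub_metabolites")) {
      add_metabolite_curated(stub, silent_dup = TRUE)
    }
    attr(rxn, "stub_metabolites") <- NULL
    dup <- detect_duplicate(model, rxn)
    if (!is.null(dup)) {
      note(.finding("duplicate", rxn$id,
                    sprintf("reaction duplicates existing '%s'; skipped", dup)))
      skipped <<- unique(c(skipped, rxn$id))
      return(invisible(dup))
    }
    bal <- check_mass_balance(rxn, model)
    if (bal$status == "imbalanced") {
      if (any(abs(bal$residuals) > 1e-9)) {
        note(.finding("mass_imbalance", rxn$id,
                      sprintf("element residuals: %s; charge residual %+g",
                              paste(sprintf("%s%+g",
                                            names(bal$residuals)[abs(bal$residuals) > 1e-9],
                                            bal$residuals[abs(bal$residuals) > 1e-9]),
                                    collapse = ", "),
                              bal$charge_residual),
                      bal$suggestion))
      } else {
        note(.finding("charge_imbalance", rxn$id,
                      sprintf("charge residual %+g", bal$charge_residual),
                      bal$suggestion))
      }
    } else if (bal$status == "undetermined") {
      missing_f <- Filter(function(mid) {
        m <- model$metabolites[[mid]]
        is.null(m$formula) || m$formula$indeterminate
      }, names(rxn$stoichiometry))
      note(.finding("missing_formula", rxn$id,
                    sprintf("mass balance undetermined; participant(s) without usable formula: %s",
                            paste(missing_f, collapse = ", "))))
    }
    rev <- check_reversibility(rxn)
    if (!is.null(rev)) note(rev)
    model <<- .insert_reaction(model, rxn)
    added <<- c(added, rxn$id)
    log_buf <<- c(log_buf, sprintf("INFO | added | %s | reaction added", rxn$id))
    invisible(rxn$id)
  }

  for (ent in entities) {
    if (inherits(ent, "cb_metabolite")) {
      add_metabolite_curated(ent)
    } else if (inherits(ent, "cb_reaction")) {
      add_reaction_curated(ent)
    } else if (inherits(ent, "cb_pathway")) {
      member_ids <- character(0)
      for (rxn in attr(ent, "reactions")) {
        res <- add_reaction_curated(rxn)
        member_ids <- c(member_ids, if (is.null(res)) rxn$id else res)
      }
      pw <- pathway(ent$id, unique(member_ids), source = ent$source, notes = ent$notes)
      attr(pw, "reactions") <- NULL
      model$pathways[[pw$id]] <- pw
      log_buf <- c(log_buf, sprintf("INFO | added | %s | pathway registered (%d reactions)",
                                    pw$id, length(pw$reaction_ids)))
    } else {
      stop("unsupported entity type passed to run_curation", call. = FALSE)
    }
  }

  report <- .new_report(findings, added, skipped)
  log_buf <- c(log_buf, paste("INFO | summary | - |", curation_summary(report)[1]))
  .log_lines(log_path, log_buf)
  if (!quiet) cat(curation_summary(report), sep = "\n")
  list(model = model, report = report)
}

#' Curated addition of metabolites, reactions, or a pathway
#'
#' Thin wrappers over [run_curation()] mirroring the pathway-centric
#' workflow: convert, curate, add, log. `add_pathway()` accepts either a
#' ready `cb_pathway` (from [create_object()]) or a `(source, pathway_id)`
#' pair to fetch and convert first.
#'
#' @param model a `cb_model`.
#' @param mets,rxns,entity entities to add.
#' @param source,pathway_id database source and pathway identifier, used
#'   when `entity` is not given.
#' @param config a [tool_config()].
#' @param log_path curation log (defaults to `config$log_path` when a config
#'   is supplied).
#' @param quiet suppress console output.
#' @return A list with updated `model` and `report`.
#' @export
add_metabolites <- function(model, mets, log_path = NULL, quiet = FALSE) {
  if (inherits(mets, "cb_metabolite")) mets <- list(mets)
  run_curation(model, mets, log_path = log_path, quiet = quiet)
}

#' @rdname add_metabolites
#' @export
add_reactions <- function(model, rxns, log_path = NULL, quiet = FALSE) {
  if (inherits(rxns, "cb_reaction")) rxns <- list(rxns)
  run_curation(model, rxns, log_path = log_path, quiet = quiet)
}

#' @rdname add_metabolites
#' @export
add_pathway <- function(model, entity = NULL, source = NULL, pathway_id = NULL,
                        config = NULL, log_path = NULL, quiet = FALSE) {
  if (is.null(entity)) {
    stopifnot(!is.null(source), !is.null(pathway_id), !is.null(config))
    rec <- fetch_record(source, pathway_id, "pathway", config)
    entity <- create_object(rec, model, config)
    if (is.null(log_path)) log_path <- config$log_path
  }
  stopifnot(inherits(entity, "cb_pathway"))
  run_curation(model, list(entity), log_path = log_path, quiet = quiet)
}
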