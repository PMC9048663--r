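#' Flux balance analysis
#'
#' Solves the standard FBA linear program: optimize `c * v` subject to the
#' steady-state constraint `S v = 0` and the box constraints
#' `lb <= v <= ub`. The LP is solved with the simplex implementation from
#' the pracma package after an affine change of variables `x = v - lb` that
#' makes all variables non-negative (upper bounds enter as inequality
#' rows). Bounds are finite by construction of
#' `cb_reaction`, so the program is never unbounded; infeasibility is
#' reported in the result status, never raised.
#'
#' @param model a `cb_model` passing integrity checks.
#' @param objective named numeric vector of reaction weights; defaults to
#'   the model objective. Must be non-empty.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_result`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, and `fluxes` (named
#'   by reaction id, id-sorted).
#' @export
solve_fba <- function(model, objective = model$objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  check_model_integrity(model)
  if (length(objective) == 0L) {
    stop("objective is empty; set one with set_objective() or pass it explicitly",
         call. = FALSE)
  }
  missing <- setdiff(names(objective), names(model$reactions))
  if (length(missing)) {
    stop(sprintf("objective references unknown reaction '%s'", missing[1]),
         call. = FALSE)
  }
  S <- build_stoichiometric_matrix(model)
  rxn_ids <- colnames(S)
  n <- length(rxn_ids)
  lb <- vapply(rxn_ids, function(id) model$reactions[[id]]$lower_bound, numeric(1))
  ub <- vapply(rxn_ids, function(id) model$reactions[[id]]$upper_bound, numeric(1))
  cc <- stats::setNames(numeric(n), rxn_ids)
  cc[names(objective)] <- objective

  if (n == 0L) {
    return(structure(list(status = "optimal", objective_value = 0,
                          fluxes = stats::setNames(numeric(0), character(0))),
                     class = "flux_result"))
  }
  # x = v - lb >= 0;  S x = -S lb;  x <= ub - lb
  beq <- as.numeric(-S %*% lb)
  keep <- rowSums(S != 0) > 0 | beq != 0
  Aeq <- S[keep, , drop = FALSE]
  beq <- beq[keep]
  res <- tryCatch(
    pracma::linprog(cc, A = diag(n), b = ub - lb,
                    Aeq = if (nrow(Aeq)) Aeq else NULL,
                    beq = if (nrow(Aeq)) beq else NULL,
                    maximize = (sense == "max"),
                    maxiter = 200 + 50 * (n + nrow(Aeq)),
                    bigM = 1e6),
    error = function(e) list(errno = -99, message = conditionMessage(e)))
  if (res$errno != 1) {
    return(structure(list(status = "infeasible", objective_value = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, n), rxn_ids)),
                     class = "flux_result"))
  }
  v <- stats::setNames(as.numeric(res$x) + lb, rxn_ids)
  structure(list(status = "optimal",
                 objective_value = sum(cc * v),
                 fluxes = v),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> status=%s objective=%s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Find dead-end metabolites
#'
#' A dead end is a metabolite whose stoichiometric row is sign-uniform: it
#' is only produced or only consumed across all reactions. Metabolites
#' referenced by no reaction are not dead ends (they are orphans and
#' reported elsewhere).
#'
#' @param model a `cb_model`.
#' @return Id-sorted character vector of dead-end metabolite ids.
#' @export
find_dead_ends <- function(model) {
  S <- build_stoichiometric_matrix(model)
  if (nrow(S) == 0L) return(character(0))
  dead <- apply(S, 1, function(row) {
    nz <- row[row != 0]
    length(nz) > 0L && (all(nz > 0) || all(nz < 0))
  })
  sort(rownames(S)[dead])
}

#' Add an auxiliary boundary (sink/source) reaction
#'
#' Inserts the reversible boundary reaction `SK_<metabolite_id>` with
#' stoichiometry `{metabolite: -1}` and bounds (-1000, 1000); being
#' reversible it can act as a source (negative flux) or a sink (positive
#' flux) for the metabolite.
#'
#' @param model a `cb_model`.
#' @param metabolite_id id of an existing metabolite.
#' @return The updated model; the new reaction id is
#'   `paste0("SK_", metabolite_id)`.
#' @export
add_sink <- function(model, metabolite_id) {
  if (!metabolite_id %in% names(model$metabolites)) {
    stop(sprintf("metabolite '%s' not in model", metabolite_id), call. = FALSE)
  }
  sk_id <- paste0("SK_", metabolite_id)
  if (sk_id %in% names(model$reactions)) {
    stop(sprintf("auxiliary reaction '%s' already present", sk_id), call. = FALSE)
  }
  sk <- reaction(id = sk_id,
                 stoichiometry = stats::setNames(-1, metabolite_id),
                 name = paste("auxiliary boundary for", metabolite_id),
                 declared_direction = "reversible")
  .insert_reaction(model, sk)
}

.best_flux <- function(model, reaction_id, tolerance) {
  obj <- stats::setNames(1, reaction_id)
  res <- solve_fba(model, objective = obj, sense = "max")
  flux <- if (res$status == "optimal") res$fluxes[[reaction_id]] else 0
  if (abs(flux) < tolerance &&
      model$reactions[[reaction_id]]$lower_bound < 0) {
    res2 <- solve_fba(model, objective = obj, sense = "min")
    if (res2$status == "optimal" && abs(res2$fluxes[[reaction_id]]) > abs(flux)) {
      flux <- res2$fluxes[[reaction_id]]
    }
  }
  flux
}

# Breadth-first order over the metabolite-reaction graph starting from the
# tested reaction's participants; id-sorted within each level.
.bfs_metabolites <- function(model, reaction_id) {
  seen_m <- character(0)
  seen_r <- reaction_id
  level <- sort(names(model$reactions[[reaction_id]]$stoichiometry))
  order <- character(0)
  while (length(level)) {
    level <- setdiff(level, seen_m)
    if (!length(level)) break
    seen_m <- c(seen_m, level)
    order <- c(order, level)
    nxt_r <- character(0)
    for (rid in names(model$reactions)) {
      if (rid %in% seen_r) next
      if (any(level %in% names(model$reactions[[rid]]$stoichiometry))) {
        nxt_r <- c(nxt_r, rid)
      }
    }
    nxt_r <- sort(nxt_r)
    seen_r <- c(seen_r, nxt_r)
    level <- sort(unique(unlist(lapply(nxt_r, function(rid)
      names(model$reactions[[rid]]$stoichiometry)))))
  }
  order
}

#' Non-zero flux test
#'
#' Verifies that a reaction can carry steady-state flux above `tolerance`.
#' The algorithm works on a scratch copy of the model: (1) maximize the
#' reaction's flux (and minimize it too when its lower bound is negative);
#' (2) if the magnitude stays below tolerance, walk the metabolite-reaction
#' graph breadth-first from the reaction's participants (id-sorted within
#' each level), and at every metabolite that is currently a dead end insert
#' an auxiliary `SK_` boundary reaction, re-solving after each insertion
#' until the reaction carries flux or candidates are exhausted; (3) each
#' auxiliary translates into one manual-curation suggestion naming the
#' metabolite and the role (source or sink) the auxiliary played. The
#' user's model is returned unchanged unless `keep_auxiliary = TRUE`.
#'
#' @param model a `cb_model`.
#' @param reaction_id reaction to test.
#' @param tolerance minimal flux magnitude that counts as non-zero.
#' @param keep_auxiliary keep the inserted `SK_` reactions in the returned
#'   model.
#' @return An `nzf_report`: list with `reaction_id`, `passed`,
#'   `achieved_flux`, `auxiliary_added` (insertion order), `suggestions`,
#'   `kept_in_model` and `model` (the scratch model when auxiliaries are
#'   kept, otherwise the original).
#' @export
test_non_zero_flux <- function(model, reaction_id, tolerance = 1e-7,
                               keep_auxiliary = FALSE) {
  if (!reaction_id %in% names(model$reactions)) {
    stop(sprintf("unknown reaction id '%s'", reaction_id), call. = FALSE)
  }
  stopifnot(tolerance > 0)
  scratch <- model
  aux <- character(0)
  suggestions <- character(0)
  flux <- .best_flux(scratch, reaction_id, tolerance)
  if (abs(flux) < tolerance) {
    for (mid in .bfs_metabolites(scratch, reaction_id)) {
      if (abs(flux) >= tolerance) break
      if (!mid %in% find_dead_ends(scratch)) next
      if (paste0("SK_", mid) %in% names(scratch$reactions)) next
      S <- build_stoichiometric_matrix(scratch)
      role <- if (all(S[mid, S[mid, ] != 0] > 0)) "sink" else "source"
      scratch <- add_sink(scratch, mid)
      sk_id <- paste0("SK_", mid)
      aux <- c(aux, sk_id)
      suggestions <- c(suggestions, sprintf(
        "metabolite %s required an auxiliary %s (%s) — add a %s reaction or transport for it",
        mid, role, sk_id,
        if (role == "sink") "consuming" else "producing"))
      flux <- .best_flux(scratch, reaction_id, tolerance)
    }
  }
  passed <- abs(flux) >= tolerance
  if (!passed) {
    r <- model$reactions[[reaction_id]]
    if (r$lower_bound == 0 && r$upper_bound == 0) {
      suggestions <- c(suggestions, sprintf(
        "reaction %s has bounds (0, 0), which forbid any flux; widen the bounds",
        reaction_id))
    } else {
      suggestions <- c(suggestions, sprintf(
        "reaction %s cannot carry flux even with %d auxiliary boundary reaction(s); revisit network connectivity",
        reaction_id, length(aux)))
    }
  }
  keep <- keep_auxiliary && length(aux) > 0
  structure(list(reaction_id = reaction_id, passed = passed,
                 achieved_flux = flux, auxiliary_added = aux,
                 suggestions = suggestions, kept_in_model = keep,
                 model = if (keep) scratch else model),
            class = "nzf_report")
}

#' @export
print.nzf_report <- function(x, ...) {
  cat(sprintf("<non-zero flux test> %s: %s (flux %.6g, %d auxiliary)\n",
              x$reaction_id, if (x$passed) "PASSED" else "FAILED",
              x$achieved_flux, length(x$auxiliary_added)))
  for (s in x$suggestions) cat("  suggestion:", s, "\n")
  invisible(x)
}

#' Test every reaction of a pathway for non-zero flux
#'
#' Runs [test_non_zero_flux()] on each member of the pathway, in pathway
#' order.
#'
#' @param model a `cb_model`.
#' @param pw a `cb_pathway` or pathway id registered on the model.
#' @inheritParams test_non_zero_flux
#' @return Named list of `nzf_report`, one per reaction.
#' @export
test_pathway_flux <- function(model, pw, tolerance = 1e-7,
                              keep_auxiliary = FALSE) {
  if (is.character(pw)) {
    pw <- model$pathways[[pw]]
    if (is.null(pw)) stop("pathway not registered on model", call. = FALSE)
  }
  reports <- lapply(pw$reaction_ids, function(rid)
    test_non_zero_flux(model, rid, tolerance, keep_auxiliary))
  stats::setNames(reports, pw$reaction_ids)
}

#' Export non-zero flux reports as TSV lines
#'
#' @param reports an `nzf_report` or list of them.
#' @return Character vector of TSV lines (with header), one row per report.
#' @export
nzf_to_tsv <- function(reports) {
  if (inherits(reports, "nzf_report")) reports <- list(reports)
  rows <- vapply(reports, function(r) {
    paste(r$reaction_id, r$passed, format(r$achieved_flux, digits = 10),
          paste(r$auxiliary_added, collapse = ","),
          paste(r$suggestions, collapse = "; "), sep = "\t")
  }, character(1))
  c("reaction_id\tpassed\tachieved_flux\tauxiliary_added\tsuggestions", rows)
}
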