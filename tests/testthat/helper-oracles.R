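# Independent oracles and generators used across the suite. Everything here
# is deliberately written against the raw data (matrices, count vectors),
# not through the package's own checking/solving code paths.

# --- brute-force LP oracle: enumerate basic solutions of {Sv=0, lb<=v<=ub} ---
# The optimum of a bounded LP is attained at a vertex; every vertex has at
# least n - rank(S) variables at a bound. Enumerating all such fixings and
# solving for the remainder covers all vertices.
oracle_lp <- function(S, lb, ub, cc, sense = "max") {
  n <- ncol(S)
  r <- if (nrow(S)) qr(S)$rank else 0L
  free_k <- n - r
  better <- if (sense == "max") `>` else `<`
  best <- NULL
  consider <- function(v) {
    if (all(v >= lb - 1e-7) && all(v <= ub + 1e-7)) {
      val <- sum(cc * v)
      if (is.null(best) || better(val, best)) best <<- val
    }
  }
  if (free_k == 0L) {
    consider(rep(0, n))  # Sv=0 with full column rank: v = 0 is the only point
    return(best)
  }
  combs <- utils::combn(n, free_k)
  for (ci in seq_len(ncol(combs))) {
    fixed <- combs[, ci]
    basis <- setdiff(seq_len(n), fixed)
    for (mask in 0:(2^free_k - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_len(free_k) - 1)) > 0
      vals <- ifelse(at_ub, ub[fixed], lb[fixed])
      rhs <- if (nrow(S)) -S[, fixed, drop = FALSE] %*% vals else numeric(0)
      sol <- if (length(basis)) {
        tryCatch(qr.solve(S[, basis, drop = FALSE], rhs),
                 error = function(e) NULL)
      } else numeric(0)
      if (is.null(sol)) next
      if (length(basis) &&
          max(abs(S[, basis, drop = FALSE] %*% sol - rhs)) > 1e-7) next
      v <- numeric(n)
      v[fixed] <- vals
      if (length(basis)) v[basis] <- sol
      consider(v)
    }
  }
  best
}

# Solve a cb_model's FBA with the oracle, for comparison with solve_fba().
oracle_fba <- function(model, objective = model$objective, sense = "max") {
  S <- build_stoichiometric_matrix(model)
  ids <- colnames(S)
  lb <- vapply(ids, function(i) model$reactions[[i]]$lower_bound, numeric(1))
  ub <- vapply(ids, function(i) model$reactions[[i]]$upper_bound, numeric(1))
  cc <- stats::setNames(numeric(length(ids)), ids)
  cc[names(objective)] <- objective
  oracle_lp(S, lb, ub, cc, sense)
}

# --- independent element tally for mass-balance classification ---
# Walks the stoichiometry and formula count vectors directly.
oracle_balance_status <- function(rxn, model) {
  tally <- new.env(parent = emptyenv())
  for (mid in names(rxn$stoichiometry)) {
    m <- model$metabolites[[mid]]
    if (is.null(m$formula) || m$formula$indeterminate) return("undetermined")
    coef <- rxn$stoichiometry[[mid]]
    for (el in names(m$formula$counts)) {
      cur <- get0(el, envir = tally, ifnotfound = 0)
      assign(el, cur + coef * m$formula$counts[[el]], envir = tally)
    }
  }
  vals <- vapply(ls(tally), function(el) get(el, envir = tally), numeric(1))
  if (length(vals) == 0L || all(abs(vals) < 1e-9)) "balanced" else "imbalanced"
}

# --- random-reaction generator for the mass-balance battery ---
# Reactant side: 1-3 metabolites with random formulas (unit coefficients).
# Balanced product side: the summed element multiset redistributed over 1-3
# product metabolites. Perturbed variant: +/-1 on one element of one product.
random_balance_case <- function(case_id, balanced) {
  elements <- c("C", "H", "N", "O", "P", "S")
  n_sub <- sample(1:3, 1)
  n_prod <- sample(1:3, 1)
  model <- new_model(sprintf("bal_case_%d", case_id))
  subs <- character(0)
  total <- stats::setNames(numeric(length(elements)), elements)
  for (i in seq_len(n_sub)) {
    k <- sample(2:4, 1)
    els <- sample(elements, k)
    counts <- stats::setNames(sample(1:12, k, replace = TRUE), els)
    id <- sprintf("s%d_%d_c", case_id, i)
    model <- add_metabolites(model, metabolite(id, formula = chem_formula(counts),
                                               charge = 0), quiet = TRUE)$model
    subs <- c(subs, id)
    total[els] <- total[els] + counts
  }
  split <- stats::setNames(lapply(elements, function(e) {
    if (total[[e]] == 0) return(integer(n_prod))
    as.integer(stats::rmultinom(1, total[[e]], rep(1, n_prod)))
  }), elements)
  prods <- character(0)
  prod_counts <- list()
  for (j in seq_len(n_prod)) {
    counts <- vapply(elements, function(e) split[[e]][j], numeric(1))
    counts <- counts[counts > 0]
    if (!length(counts)) next
    prod_counts[[length(prod_counts) + 1L]] <- counts
  }
  if (!length(prod_counts)) prod_counts <- list(total[total > 0])
  if (!balanced) {
    j <- sample(length(prod_counts), 1)
    counts <- prod_counts[[j]]
    el <- sample(elements, 1)
    delta <- sample(c(-1, 1), 1)
    cur <- if (el %in% names(counts)) counts[[el]] else 0
    new <- cur + delta
    if (new <= 0) new <- cur + 1  # keep counts positive: force a surplus
    counts[el] <- new
    prod_counts[[j]] <- counts
  }
  for (j in seq_along(prod_counts)) {
    id <- sprintf("p%d_%d_c", case_id, j)
    model <- add_metabolites(model, metabolite(id, formula = chem_formula(prod_counts[[j]]),
                                               charge = 0), quiet = TRUE)$model
    prods <- c(prods, id)
  }
  stoich <- c(stats::setNames(rep(-1, length(subs)), subs),
              stats::setNames(rep(1, length(prods)), prods))
  rxn <- reaction(sprintf("RB%d", case_id), stoich, declared_direction = "forward")
  list(model = model, rxn = rxn)
}

# --- random small networks for the LP cross-check ---
random_network <- function(n_rxns, n_mets) {
  model <- new_model("rnd")
  mids <- sprintf("x%d_c", seq_len(n_mets))
  for (mid in mids) {
    model <- add_metabolites(model, metabolite(mid), quiet = TRUE)$model
  }
  for (i in seq_len(n_rxns)) {
    k <- sample(2:min(3, n_mets), 1)
    mets <- sample(mids, k)
    coefs <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    if (all(coefs > 0)) coefs[1] <- -coefs[1]
    if (all(coefs < 0)) coefs[k] <- -coefs[k]
    lb <- sample(c(0, -10), 1)
    ub <- sample(5:10, 1)
    rxn <- reaction(sprintf("RR%d", i), stats::setNames(coefs, mets),
                    declared_direction = "unspecified",
                    lower_bound = lb, upper_bound = ub)
    model <- suppressWarnings(add_reactions(model, rxn, quiet = TRUE)$model)
  }
  obj_rxn <- sample(names(model$reactions), 1)
  set_objective(model, stats::setNames(1, obj_rxn))
}

# Fixture cache shared by retrieval/cli tests.
make_fixture_config <- function(model = generate_toy_model(3, TRUE, seed = 7),
                                cache_dir = withr::local_tempdir(.local_envir = parent.frame())) {
  recs <- generate_fixture_records(model)
  write_fixture_cache(recs, cache_dir)
  cfg <- tool_config(cache_dir = cache_dir, offline = TRUE,
                     log_path = file.path(cache_dir, "curation.log"))
  list(config = cfg, records = recs, model = model,
       maps = attr(recs, "maps"))
}
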