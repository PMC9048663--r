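hexokinase_model <- function(with_proton = FALSE) {
  m <- new_model()
  mets <- list(
    metabolite("atp_c", formula = "C10H12N5O13P3", charge = -4),
    metabolite("glc__D_c", formula = "C6H12O6", charge = 0),
    metabolite("adp_c", formula = "C10H12N5O10P2", charge = -3),
    metabolite("g6p_c", formula = "C6H11O9P", charge = -2),
    metabolite("h_c", formula = "H", charge = 1))
  m <- add_metabolites(m, mets, quiet = TRUE)$model
  stoich <- c(atp_c = -1, glc__D_c = -1, adp_c = 1, g6p_c = 1)
  if (with_proton) stoich <- c(stoich, h_c = 1)
  list(model = m, rxn = reaction("HEX1", stoich, declared_direction = "forward"))
}

test_that("methane combustion is balanced", {
  m <- new_model()
  m <- add_metabolites(m, list(
    metabolite("ch4_c", formula = "CH4", charge = 0),
    metabolite("o2_c", formula = "O2", charge = 0),
    metabolite("co2_c", formula = "CO2", charge = 0),
    metabolite("h2o_c", formula = "H2O", charge = 0)), quiet = TRUE)$model
  bal <- check_mass_balance(
    reaction("COMB", c(ch4_c = -1, o2_c = -2, co2_c = 1, h2o_c = 2)), m)
  expect_equal(bal$status, "balanced")
  expect_true(all(bal$residuals == 0))
  expect_equal(bal$charge_residual, 0)
})

test_that("hexokinase without the proton is H/charge imbalanced with a suggestion", {
  hm <- hexokinase_model(with_proton = FALSE)
  bal <- check_mass_balance(hm$rxn, hm$model)
  expect_equal(bal$status, "imbalanced")
  expect_equal(bal$residuals[["H"]], -1)
  expect_true(all(bal$residuals[setdiff(names(bal$residuals), "H")] == 0))
  expect_equal(bal$charge_residual, -1)
  expect_match(bal$suggestion, "add 1 H to the product side")

  # with the proton the reaction balances exactly
  hm2 <- hexokinase_model(with_proton = TRUE)
  expect_equal(check_mass_balance(hm2$rxn, hm2$model)$status, "balanced")
})

test_that("missing or indeterminate formulas yield 'undetermined', never a guess", {
  m <- new_model()
  m <- add_metabolites(m, list(metabolite("a_c"),
                               metabolite("b_c", formula = "C2H4")),
                       quiet = TRUE)$model
  bal <- check_mass_balance(reaction("R1", c(a_c = -1, b_c = 1)), m)
  expect_equal(bal$status, "undetermined")

  m2 <- new_model()
  m2 <- suppressWarnings(add_metabolites(m2, list(
    metabolite("x_c", formula = "C5H8NO4R"),
    metabolite("y_c", formula = "C5H8NO4R")), quiet = TRUE))$model
  bal2 <- check_mass_balance(reaction("R2", c(x_c = -1, y_c = 1)), m2)
  expect_equal(bal2$status, "undetermined")
})

test_that("mass-balance classification matches the independent tally on random cases", {
  set.seed(42)
  agree <- 0L
  n_cases <- 60L
  for (i in seq_len(n_cases)) {
    case <- random_balance_case(i, balanced = (i %% 2 == 0))
    got <- check_mass_balance(case$rxn, case$model)$status
    want <- oracle_balance_status(case$rxn, case$model)
    if (identical(got, want)) agree <- agree + 1L
    if (i %% 2 == 0) expect_equal(got, "balanced", label = sprintf("case %d", i))
  }
  expect_equal(agree, n_cases)
})

test_that("duplicate detection applies id, cross-ref, then stoichiometry rules", {
  m <- new_model()
  m <- add_metabolites(m, list(metabolite("A_c"), metabolite("B_c")), quiet = TRUE)$model
  m <- add_reactions(m, reaction("HEX1", c(A_c = -1, B_c = 1),
                                 cross_refs = list(kegg.reaction = "R00299")),
                     quiet = TRUE)$model

  same_id <- reaction("HEX1", c(B_c = -1, A_c = 1))
  expect_equal(detect_duplicate(m, same_id), "HEX1")

  by_xref <- reaction("OTHER", c(B_c = -1, A_c = 1),
                      cross_refs = list(kegg.reaction = "R00299"))
  expect_equal(detect_duplicate(m, by_xref), "HEX1")

  by_stoich <- reaction("THIRD", c(A_c = -1, B_c = 1))
  expect_equal(detect_duplicate(m, by_stoich), "HEX1")

  fresh <- metabolite("C_c")
  expect_null(detect_duplicate(m, fresh))
  different <- reaction("R9", c(A_c = -2, B_c = 1))
  expect_null(detect_duplicate(m, different))
})

test_that("reversibility check follows the mismatch table", {
  f <- check_reversibility(reaction("r", c(A_c = -1), declared_direction = "reversible",
                                    lower_bound = 0, upper_bound = 1000))
  expect_equal(f$check, "reversibility_mismatch")
  expect_match(f$suggestion, "-1000")

  expect_null(check_reversibility(reaction("r", c(A_c = -1),
                                           declared_direction = "forward",
                                           lower_bound = 0, upper_bound = 1000)))
  expect_null(check_reversibility(reaction("r", c(A_c = -1),
                                           declared_direction = "backward",
                                           lower_bound = -1000, upper_bound = 0)))
  b <- check_reversibility(reaction("r", c(A_c = -1), declared_direction = "backward",
                                    lower_bound = -1000, upper_bound = 10))
  expect_match(b$suggestion, "upper_bound")
  expect_null(check_reversibility(reaction("r", c(A_c = -1))))
})

test_that("run_curation adds with warnings, skips duplicates, stays idempotent", {
  fx <- make_fixture_config()
  rec <- fetch_record("kegg", "TOYPATH", "pathway", fx$config)
  m <- new_model()
  ent <- create_object(rec, m, fx$config)
  res1 <- run_curation(m, list(ent), log_path = fx$config$log_path, quiet = TRUE)
  n_rxn <- length(res1$model$reactions)
  n_met <- length(res1$model$metabolites)
  expect_equal(n_rxn, 3)
  expect_equal(n_met, 4)
  expect_true("TOYPATH" %in% names(res1$model$pathways))

  # second pass: one duplicate finding per pathway reaction, nothing added
  ent2 <- create_object(fetch_record("kegg", "TOYPATH", "pathway", fx$config),
                        res1$model, fx$config)
  res2 <- run_curation(res1$model, list(ent2), log_path = fx$config$log_path,
                       quiet = TRUE)
  expect_length(res2$report$entities_added, 0)
  expect_equal(res2$report$counts[["duplicate"]], 3L)
  expect_equal(length(res2$model$reactions), n_rxn)
  expect_equal(length(res2$model$metabolites), n_met)
  expect_length(intersect(res2$report$entities_added, res2$report$entities_skipped), 0)

  # the log records the narrative
  expect_true(any(grepl("duplicate", readLines(fx$config$log_path))))
})

test_that("curation warns without blocking and reports counts consistently", {
  m <- new_model()
  # metabolite without formula: warned but added
  res <- NULL
  expect_warning(
    utils::capture.output(res <- add_metabolites(m, metabolite("orphan_c"),
                                                 quiet = FALSE)),
    "missing_formula")
  expect_true("orphan_c" %in% names(res$model$metabolites))

  # imbalanced reaction: warned but added
  hm <- hexokinase_model(FALSE)
  res2 <- add_reactions(hm$model, hm$rxn, quiet = TRUE)
  expect_true("HEX1" %in% names(res2$model$reactions))
  expect_equal(res2$report$counts[["mass_imbalance"]], 1L)
  expect_equal(sum(res2$report$counts), length(res2$report$findings))

  # TSV export carries the findings
  p <- withr::local_tempfile(fileext = ".tsv")
  report_to_tsv(res2$report, p)
  tab <- utils::read.delim(p)
  expect_equal(tab$check, "mass_imbalance")
  expect_equal(tab$entity_id, "HEX1")
})

test_that("an unwritable log path aborts before any model mutation", {
  m <- new_model()
  expect_error(add_metabolites(m, metabolite("a_c"),
                               log_path = "/no/such/dir/cur.log", quiet = TRUE),
               "not writable")
  expect_length(m$metabolites, 0)
})
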