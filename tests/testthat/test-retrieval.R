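kegg_r00299 <- paste(
  "ENTRY       R00299                      Reaction",
  "NAME        hexokinase",
  "EQUATION    C00002 + C00031 <=> C00008 + C00092",
  "ENZYME      2.7.1.1",
  "///", sep = "\n")

kegg_glc <- paste(
  "ENTRY       C00031                      Compound",
  "NAME        D-Glucose;",
  "FORMULA     C6H12O6",
  "///", sep = "\n")

biocyc_glucokin <- paste(
  '<ptools-xml>',
  '  <Reaction frameid="GLUCOKIN-RXN">',
  '    <left><Compound frameid="ATP"/></left>',
  '    <left><Compound frameid="GLC"/></left>',
  '    <right><Compound frameid="ADP"/></right>',
  '    <right><Compound frameid="GLC-6-P"/></right>',
  '    <reaction-direction>LEFT-TO-RIGHT</reaction-direction>',
  '  </Reaction>',
  '</ptools-xml>', sep = "\n")

bigg_hex1 <- jsonlite::toJSON(list(
  bigg_id = "HEX1", name = "hexokinase", pseudoreaction = FALSE,
  metabolites = list(
    list(bigg_id = "atp", compartment_bigg_id = "c", stoichiometry = -1),
    list(bigg_id = "glc__D", compartment_bigg_id = "c", stoichiometry = -1),
    list(bigg_id = "adp", compartment_bigg_id = "c", stoichiometry = 1),
    list(bigg_id = "g6p", compartment_bigg_id = "c", stoichiometry = 1),
    list(bigg_id = "h", compartment_bigg_id = "c", stoichiometry = 1))),
  auto_unbox = TRUE)

test_that("KEGG reaction records parse equations with coefficients", {
  rec <- parse_kegg(kegg_r00299)
  expect_equal(rec$kind, "reaction")
  expect_equal(rec$identifier, "R00299")
  expect_equal(rec$parsed$stoichiometry,
               c(C00002 = -1, C00031 = -1, C00008 = 1, C00092 = 1))
  expect_equal(rec$parsed$declared_direction, "reversible")
  expect_equal(rec$parsed$cross_refs[["ec-code"]], "2.7.1.1")

  eq <- parse_kegg(paste("ENTRY       R1   Reaction",
                         "EQUATION    2 C00001 + C00002 <=> C00009",
                         "///", sep = "\n"))
  expect_equal(eq$parsed$stoichiometry, c(C00001 = -2, C00002 = -1, C00009 = 1))
})

test_that("KEGG compound and module records parse; malformed records error", {
  rec <- parse_kegg(kegg_glc)
  expect_equal(rec$kind, "metabolite")
  expect_equal(rec$parsed$formula$counts, c(C = 6, H = 12, O = 6))

  mod <- parse_kegg(paste("ENTRY       M00001   Module",
                          "NAME        toy",
                          "REACTION    R00299 R00300",
                          "            R00301",
                          "///", sep = "\n"))
  expect_equal(mod$parsed$reaction_identifiers, c("R00299", "R00300", "R00301"))

  expect_error(parse_kegg("NAME  x\n///"), "ENTRY")
  expect_error(parse_kegg(kegg_glc |> sub("///", "", x = _)), "terminator")
  expect_error(parse_kegg(paste("ENTRY       R2  Reaction",
                                "EQUATION    C1 + ?bad <=> C2",
                                "///", sep = "\n")), "\\?bad")
})

test_that("BioCyc reaction records map direction and coefficient signs", {
  rec <- parse_biocyc(biocyc_glucokin)
  expect_equal(rec$identifier, "GLUCOKIN-RXN")
  expect_equal(rec$parsed$declared_direction, "forward")
  expect_equal(sort(names(rec$parsed$stoichiometry)),
               sort(c("ATP", "GLC", "ADP", "GLC-6-P")))
  expect_equal(rec$parsed$stoichiometry[["ATP"]], -1)
  expect_equal(rec$parsed$stoichiometry[["GLC-6-P"]], 1)

  rev_txt <- sub("LEFT-TO-RIGHT", "REVERSIBLE", biocyc_glucokin)
  expect_equal(parse_biocyc(rev_txt)$parsed$declared_direction, "reversible")
  phys <- sub("LEFT-TO-RIGHT", "PHYSIOL-RIGHT-TO-LEFT", biocyc_glucokin)
  expect_equal(parse_biocyc(phys)$parsed$declared_direction, "backward")
  expect_error(parse_biocyc(sub("LEFT-TO-RIGHT", "SIDEWAYS", biocyc_glucokin)),
               "unknown direction")

  with_coef <- sub('<left><Compound frameid="ATP"/></left>',
                   '<left><Compound frameid="ATP"/><coefficient>2</coefficient></left>',
                   biocyc_glucokin, fixed = TRUE)
  expect_equal(parse_biocyc(with_coef)$parsed$stoichiometry[["ATP"]], -2)

  empty_side <- paste(
    '<ptools-xml><Reaction frameid="X">',
    '<right><Compound frameid="A"/></right>',
    '<reaction-direction>REVERSIBLE</reaction-direction>',
    '</Reaction></ptools-xml>', sep = "\n")
  expect_error(parse_biocyc(empty_side), "empty side")
})

test_that("BiGG records parse and pseudoreactions are rejected", {
  rec <- parse_bigg(bigg_hex1, "reaction")
  expect_equal(rec$identifier, "HEX1")
  expect_length(rec$parsed$stoichiometry, 5)
  expect_equal(rec$parsed$stoichiometry[["glc__D_c"]], -1)
  expect_equal(rec$parsed$stoichiometry[["h_c"]], 1)

  met <- parse_bigg(jsonlite::toJSON(list(bigg_id = "glc__D", name = "D-glucose",
                                          formulae = list("C6H12O6"),
                                          charges = list(0)), auto_unbox = TRUE),
                    "metabolite")
  expect_equal(met$parsed$formula$counts, c(C = 6, H = 12, O = 6))
  expect_equal(met$parsed$charge, 0)

  pseudo <- jsonlite::toJSON(list(bigg_id = "EX_glc", pseudoreaction = TRUE,
                                  metabolites = list()), auto_unbox = TRUE)
  expect_error(parse_bigg(pseudo, "reaction"), "pseudoreaction")
})

test_that("user table grammar covers metabolites, reactions, bounds, errors", {
  txt <- paste(
    "# user curation example",
    "M skm_c, shikimate, c, C7H10O5, -1",
    "M skm6p_c, shikimate 6-phosphate, c, -, -",
    "R SHKK, shikimate kinase | 1 atp_c, 1 skm_c -> 1 adp_c, 1 skm6p_c",
    "R REV1, rev | a_c <-> b_c | -5, 5", sep = "\n")
  recs <- parse_user_table(txt)
  expect_length(recs, 4)
  met <- recs[[1]]$parsed
  expect_equal(met$formula$counts, c(C = 7, H = 10, O = 5))
  expect_equal(met$charge, -1)
  expect_null(recs[[2]]$parsed$formula)

  shkk <- recs[[3]]$parsed
  expect_equal(shkk$declared_direction, "forward")
  expect_equal(shkk$stoichiometry,
               c(atp_c = -1, skm_c = -1, adp_c = 1, skm6p_c = 1))
  expect_null(shkk$lower_bound)  # defaults applied downstream: (0, 1000)

  rev1 <- recs[[4]]$parsed
  expect_equal(rev1$declared_direction, "reversible")
  expect_equal(rev1$lower_bound, -5)

  expect_error(parse_user_table("R BAD | ->"), "line 1")
  expect_error(parse_user_table("M a_c, a, c, -, -\nM a_c, a, c, -, -"),
               "duplicate id")
})

test_that("fetch_record caches verbatim, counts hits, errors offline", {
  fx <- make_fixture_config()
  cfg <- fx$config
  rec1 <- fetch_record("kegg", "TOYPATH", "pathway", cfg)
  expect_s3_class(rec1, "db_record")
  expect_equal(get("cache_hits", envir = cfg$stats), 1L)

  # offline miss names the expected cache path
  expect_error(fetch_record("kegg", "R99999", "reaction", cfg),
               file.path("kegg", "reaction", "R99999.txt"), fixed = TRUE)

  # provider is consulted once, then the cache serves byte-identical text
  cfg2 <- tool_config(cache_dir = withr::local_tempdir(), offline = FALSE,
                      provider = fixture_provider(fx$records))
  a <- fetch_record("kegg", "TOYPATH", "pathway", cfg2)
  b <- fetch_record("kegg", "TOYPATH", "pathway", cfg2)
  expect_identical(a$raw, b$raw)
  expect_equal(get("provider_calls", envir = cfg2$stats), 1L)
  expect_equal(get("cache_hits", envir = cfg2$stats), 1L)
})

test_that("parsing is stable across repeated invocations", {
  for (txt in list(kegg_r00299, biocyc_glucokin)) {
    f <- if (grepl("ptools", txt)) parse_biocyc else parse_kegg
    expect_identical(f(txt)$parsed, f(txt)$parsed)
  }
})

test_that("create_object resolves participants exact-id, cross-ref, stub", {
  fx <- make_fixture_config()
  cfg <- fx$config
  kid <- fx$maps$kegg_rxn[["R1"]]

  # empty model: all participants become stubs from cached compound records
  rec <- fetch_record("kegg", kid, "reaction", cfg)
  empty <- new_model()
  rxn <- create_object(rec, empty, cfg)
  stubs <- attr(rxn, "stub_metabolites")
  expect_length(stubs, 2)
  expect_true(all(grepl("_c$", names(stubs))))
  expect_equal(unname(rxn$stoichiometry[order(names(rxn$stoichiometry))]),
               c(-1, 1))

  # model already containing a reaction annotated with the record id:
  # the existing reaction is returned
  m <- new_model()
  m <- add_metabolites(m, list(metabolite("A_c"), metabolite("B_c")), quiet = TRUE)$model
  m <- add_reactions(m, reaction("HEX1", c(A_c = -1, B_c = 1),
                                 cross_refs = stats::setNames(list(kid), "kegg.reaction")),
                     quiet = TRUE)$model
  same <- create_object(rec, m, cfg)
  expect_equal(same$id, "HEX1")

  # cross-ref resolution of participants: metabolite annotated with the
  # KEGG compound id is reused instead of a stub
  kegg_met <- fx$maps$kegg_met[["m0_c"]]
  m2 <- new_model()
  m2 <- add_metabolites(m2, metabolite("custom_c", cross_refs =
                                         stats::setNames(list(kegg_met), "kegg.compound")),
                        quiet = TRUE)$model
  rxn2 <- suppressWarnings(create_object(rec, m2, cfg))
  expect_true("custom_c" %in% names(rxn2$stoichiometry))

  # unresolvable participant: error lists the missing record
  cfg_empty <- tool_config(cache_dir = withr::local_tempdir(), offline = TRUE)
  rec2 <- parse_kegg(kegg_r00299)
  expect_error(create_object(rec2, new_model(), cfg_empty), "C00002")
})

test_that("pathway records convert to resolved pathway bundles", {
  fx <- make_fixture_config()
  rec <- fetch_record("kegg", "TOYPATH", "pathway", fx$config)
  pw <- create_object(rec, new_model(), fx$config)
  expect_s3_class(pw, "cb_pathway")
  expect_length(attr(pw, "reactions"), 3)
  expect_equal(pw$source, c("kegg", "TOYPATH"))
})

test_that("the three dialects describe stoichiometrically identical reactions", {
  fx <- make_fixture_config()
  cfg <- fx$config
  maps <- fx$maps
  ref <- fx$model

  to_model <- function(source, rxn_map, met_map) {
    m <- new_model()
    for (rid in maps$rxn_ids) {
      rec <- fetch_record(source, rxn_map[[rid]], "reaction", cfg)
      rxn <- create_object(rec, m, cfg)
      m <- suppressWarnings(run_curation(m, list(rxn), quiet = TRUE))$model
    }
    S <- build_stoichiometric_matrix(m)
    # rename rows/columns back to the reference namespace
    rownames(S) <- names(met_map)[match(rownames(S), unname(met_map))]
    colnames(S) <- names(rxn_map)[match(colnames(S), unname(rxn_map))]
    S[order(rownames(S)), order(colnames(S)), drop = FALSE]
  }
  S_ref <- build_stoichiometric_matrix(ref)
  S_ref <- S_ref[, maps$rxn_ids, drop = FALSE]
  S_ref <- S_ref[rowSums(S_ref != 0) > 0, , drop = FALSE]

  kegg_met_model_ids <- stats::setNames(paste0(unname(maps$kegg_met), "_c"),
                                        names(maps$kegg_met))
  S_kegg <- to_model("kegg", maps$kegg_rxn, kegg_met_model_ids)
  biocyc_ids <- stats::setNames(paste0(unname(maps$biocyc_met), "_c"),
                                names(maps$biocyc_met))
  S_biocyc <- to_model("biocyc", maps$biocyc_rxn, biocyc_ids)
  bigg_ids <- stats::setNames(paste0(unname(maps$bigg_met), "_c"),
                              names(maps$bigg_met))
  S_bigg <- to_model("bigg", maps$bigg_rxn, bigg_ids)

  S_ref_cmp <- S_ref[order(rownames(S_ref)), order(colnames(S_ref)), drop = FALSE]
  expect_equal(S_kegg, S_ref_cmp)
  expect_equal(S_biocyc, S_ref_cmp)
  expect_equal(S_bigg, S_ref_cmp)
})
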