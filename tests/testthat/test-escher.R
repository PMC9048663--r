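chain_abcd <- function() {
  m <- new_model()
  for (id in c("A_c", "B_c", "C_c", "D_c", "X_c", "Y_c")) {
    m <- add_metabolites(m, metabolite(id), quiet = TRUE)$model
  }
  m <- add_reactions(m, list(
    reaction("R1", c(A_c = -1, B_c = 1), declared_direction = "forward"),
    reaction("R2", c(B_c = -1, C_c = 1), declared_direction = "forward"),
    reaction("R3", c(C_c = -1, D_c = 1), declared_direction = "forward"),
    reaction("R9", c(X_c = -1, Y_c = 1), declared_direction = "forward")),
    quiet = TRUE)$model
  m
}

test_that("reaction ordering is topological with deterministic tie-breaks", {
  m <- chain_abcd()
  expect_equal(order_reactions(pathway("p", c("R2", "R1", "R3")), m),
               c("R1", "R2", "R3"))

  # cycle: broken at the lexicographically smallest member
  cyc <- new_model()
  cyc <- add_metabolites(cyc, list(metabolite("A_c"), metabolite("B_c")),
                         quiet = TRUE)$model
  cyc <- add_reactions(cyc, list(
    reaction("Ra", c(A_c = -1, B_c = 1), declared_direction = "forward"),
    reaction("Rb", c(B_c = -1, A_c = 1), declared_direction = "forward")),
    quiet = TRUE)$model
  expect_equal(order_reactions(pathway("p", c("Rb", "Ra")), cyc), c("Ra", "Rb"))

  # disconnected components concatenate by smallest member id
  expect_equal(order_reactions(pathway("p", c("R9", "R2", "R1")), m),
               c("R1", "R2", "R9"))

  # backward-declared reactions are flipped before edges are drawn
  mb <- new_model()
  mb <- add_metabolites(mb, list(metabolite("A_c"), metabolite("B_c"),
                                 metabolite("C_c")), quiet = TRUE)$model
  mb <- add_reactions(mb, list(
    reaction("F1", c(A_c = -1, B_c = 1), declared_direction = "forward"),
    reaction("B2", c(C_c = -1, B_c = 1), declared_direction = "backward")),
    quiet = TRUE)$model
  expect_equal(order_reactions(pathway("p", c("B2", "F1")), mb), c("F1", "B2"))
})

test_that("3-reaction chain lays out as 7 nodes and 6 segments", {
  m <- chain_abcd()
  map <- build_escher_map(pathway("p", c("R1", "R2", "R3")), m,
                          spacing = 300, canvas_margin = 150)
  nodes <- map$body$nodes
  expect_length(nodes, 7)
  types <- vapply(nodes, `[[`, character(1), "node_type")
  expect_equal(sum(types == "metabolite"), 4)
  expect_equal(sum(types == "midmarker"), 3)
  segs <- sum(vapply(map$body$reactions, function(r) length(r$segments), integer(1)))
  expect_equal(segs, 6)
  expect_gte(map$body$canvas$width, 2 * 300 + 2 * 150)
  # node ids consecutive from "0"
  expect_setequal(names(nodes), as.character(0:6))
  # chain metabolites sit on one shared axis
  met_y <- vapply(nodes[types == "metabolite"], `[[`, numeric(1), "y")
  expect_equal(unname(unique(met_y)), 400)
})

test_that("side metabolites fan above (substrates) and below (products)", {
  m <- new_model()
  for (spec in list(c("atp_c", "C10H12N5O13P3"), c("glc__D_c", "C6H12O6"),
                    c("adp_c", "C10H12N5O10P2"), c("g6p_c", "C6H11O9P"))) {
    m <- add_metabolites(m, metabolite(spec[1], formula = spec[2]), quiet = TRUE)$model
  }
  m <- suppressWarnings(add_reactions(m, reaction(
    "HEX1", c(atp_c = -1, glc__D_c = -1, adp_c = 1, g6p_c = 1),
    declared_direction = "forward"), quiet = TRUE))$model
  map <- build_escher_map(pathway("p", "HEX1"), m)
  nodes <- map$body$nodes
  types <- vapply(nodes, `[[`, character(1), "node_type")
  mets <- nodes[types == "metabolite"]
  expect_length(mets, 4)
  expect_equal(sum(types == "midmarker"), 1)
  ys <- vapply(mets, `[[`, numeric(1), "y")
  ids <- vapply(mets, `[[`, character(1), "bigg_id")
  primary <- vapply(mets, `[[`, logical(1), "node_is_primary")
  # glc/g6p carry the heaviest... all coefficients tie, so the primaries are
  # the lexicographically smallest participants per side: adp (product) and atp (substrate)
  expect_equal(sort(unname(ids[primary])), c("adp_c", "atp_c"))
  expect_equal(unname(ys[ids == "glc__D_c"]), 400 - 80)  # substrate above
  expect_equal(unname(ys[ids == "g6p_c"]), 400 + 80)     # product below
  segs <- sum(vapply(map$body$reactions, function(r) length(r$segments), integer(1)))
  expect_equal(segs, 4)
})

test_that("node and segment counts follow the closed form on generated pathways", {
  for (i in 1:12) {
    n <- 2 + (i %% 5)
    dead <- if (i %% 3 == 0) 1 + (i %% n) else NULL
    m <- generate_toy_model(n, with_exchanges = TRUE, dead_end_at = dead,
                            seed = 400 + i)
    pw <- pathway("p", sprintf("R%d", seq_len(n)))
    map <- build_escher_map(pw, m)
    extra <- if (is.null(dead)) 0 else 1
    expect_length(map$body$nodes, (n + 1) + n + extra)
    segs <- sum(vapply(map$body$reactions, function(r) length(r$segments), integer(1)))
    expect_equal(segs, 2 * n + extra, label = sprintf("pathway %d", i))
    # generic invariant: nodes = metabolite nodes + one midmarker per reaction
    types <- vapply(map$body$nodes, `[[`, character(1), "node_type")
    expect_equal(sum(types == "midmarker"), n)
  }
})

test_that("map serialization is byte-stable and re-parses identically", {
  m <- chain_abcd()
  pw <- pathway("p", c("R1", "R2", "R3"))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_escher_json(build_escher_map(pw, m), f1)
  write_escher_json(build_escher_map(pw, m), f2)
  expect_identical(readLines(f1), readLines(f2))

  doc <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  expect_length(doc, 2)
  expect_true("schema" %in% names(doc[[1]]))

  f3 <- withr::local_tempfile(fileext = ".json")
  write_escher_json(read_escher_json(f1), f3)
  expect_identical(readLines(f1), readLines(f3))
})

test_that("structural validation names the offending segment", {
  m <- chain_abcd()
  map <- build_escher_map(pathway("p", "R1"), m)
  map$body$reactions[[1]]$segments[[1]]$to_node_id <- "999"
  expect_error(write_escher_json(map, withr::local_tempfile(fileext = ".json")),
               "999")
  expect_error(build_escher_map(pathway("p", "R1"), new_model()), "not in model")
})

test_that("linear gradient interpolation hits the documented midpoint", {
  st <- map_flux_to_style(c(R1 = 0, R2 = 5, R3 = 10), gradient_spec())
  expect_equal(st$R2$color, "#FF8080")
  expect_equal(st$R1$color, "#FFFFFF")
  expect_equal(st$R3$color, "#FF0000")
  expect_equal(st$R3$width, 10)
  expect_equal(st$R1$width, 2)

  # quantile: rank midpoint regardless of skew
  stq <- map_flux_to_style(c(R1 = 0, R2 = 1, R3 = 100),
                           gradient_spec(normalization = "quantile"))
  expect_equal(stq$R2$color, "#FF8080")

  # degenerate cases saturate at the top stop
  expect_equal(map_flux_to_style(c(R1 = 7.3), gradient_spec())$R1$color, "#FF0000")
  expect_equal(map_flux_to_style(c(R1 = 2, R2 = 2), gradient_spec())$R1$color,
               "#FF0000")
})

test_that("style mapping is monotone; quantile styling survives monotone transforms", {
  set.seed(77)
  for (i in 1:8) {
    v <- stats::setNames(round(stats::runif(6, 0, 50), 3), paste0("R", 1:6))
    for (norm in c("linear", "quantile")) {
      st <- map_flux_to_style(v, gradient_spec(normalization = norm))
      t <- vapply(st, `[[`, numeric(1), "t")
      o <- order(abs(v))
      expect_true(all(diff(t[o]) >= -1e-12), label = paste(norm, i))
    }
    stq1 <- map_flux_to_style(v, gradient_spec(normalization = "quantile"))
    stq2 <- map_flux_to_style(v^3, gradient_spec(normalization = "quantile"))
    expect_equal(vapply(stq1, `[[`, character(1), "color"),
                 vapply(stq2, `[[`, character(1), "color"))
  }
})

test_that("gradient specs validate their stops", {
  expect_error(gradient_spec(list(list(position = 0, color = "#FFFFFF"))), "stops")
  expect_error(gradient_spec(list(list(position = 0.2, color = "#FFFFFF"),
                                  list(position = 1, color = "#FF0000"))), "stops")
  expect_error(gradient_spec(c("#FFFFFF", "notacolor")), "hex")
  g <- gradient_spec(c("#000000", "#808080", "#FFFFFF"))
  expect_equal(vapply(g$stops, `[[`, numeric(1), "position"), c(0, 0.5, 1))
})
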