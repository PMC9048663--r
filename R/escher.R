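#' Topological ordering of a pathway's reactions
#'
#' Builds the directed reaction graph with an edge u -> v whenever some
#' product of u is a substrate of v, using each reaction's effective
#' orientation (declared/bound-implied; backward reactions are flipped,
#' reversible ones keep their stoichiometric orientation), and returns a
#' deterministic topological order: Kahn's algorithm with a lexicographic
#' min-queue; when a cycle stalls the queue, the lexicographically smallest
#' remaining reaction has its incoming edges removed. Weakly-connected
#' components are ordered independently and concatenated by their smallest
#' member id.
#'
#' @param pw a `cb_pathway`.
#' @param model the owning `cb_model`.
#' @return Character vector: a permutation of `pw$reaction_ids`.
#' @export
order_reactions <- function(pw, model) {
  ids <- pw$reaction_ids
  missing <- setdiff(ids, names(model$reactions))
  if (length(missing)) {
    stop(sprintf("pathway '%s': reaction '%s' not in model", pw$id, missing[1]),
         call. = FALSE)
  }
  sides <- lapply(ids, function(rid) .oriented_sides(model$reactions[[rid]]))
  names(sides) <- ids
  succ <- stats::setNames(lapply(ids, function(u) {
    prods <- sides[[u]]$products
    vs <- Filter(function(v) v != u && any(prods %in% sides[[v]]$substrates), ids)
    sort(unlist(vs, use.names = FALSE))
  }), ids)

  # weakly connected components over the edge set
  comp <- stats::setNames(seq_along(ids), ids)
  for (u in ids) for (v in succ[[u]]) {
    cu <- comp[[u]]; cv <- comp[[v]]
    if (cu != cv) comp[comp == cv] <- cu
  }
  comp_order <- unique(vapply(split(names(comp), comp), function(members)
    min(members), character(1)))
  comp_order <- sort(comp_order)

  out <- character(0)
  for (lead in comp_order) {
    members <- names(comp)[comp == comp[[lead]]]
    indeg <- stats::setNames(integer(length(members)), members)
    for (u in members) for (v in intersect(succ[[u]], members)) {
      indeg[v] <- indeg[v] + 1L
    }
    remaining <- sort(members)
    while (length(remaining)) {
      ready <- remaining[indeg[remaining] == 0L]
      nxt <- if (length(ready)) min(ready) else remaining[1]  # break cycle
      indeg[nxt] <- 0L
      out <- c(out, nxt)
      remaining <- setdiff(remaining, nxt)
      for (v in intersect(succ[[nxt]], remaining)) {
        indeg[v] <- max(0L, indeg[v] - 1L)
      }
    }
  }
  out
}

# Substrates/products under the reaction's effective orientation.
.oriented_sides <- function(r) {
  s <- r$stoichiometry
  backward <- r$declared_direction == "backward" ||
    (r$declared_direction == "unspecified" && r$upper_bound <= 0 && r$lower_bound < 0)
  if (backward) {
    list(substrates = names(s)[s > 0], products = names(s)[s < 0])
  } else {
    list(substrates = names(s)[s < 0], products = names(s)[s > 0])
  }
}

#' Build an Escher map for a pathway
#'
#' Lays the ordered reactions left-to-right on a main axis: reaction i gets
#' a midmarker node at `x = canvas_margin + i * spacing`. Each reaction's
#' primary substrate and product — the chain-link metabolites, chosen as the
#' metabolite shared with the neighboring reaction, else the
#' highest-|coefficient| participant (ties lexicographic) — sit on the axis
#' at `x -/+ spacing / 2.5`; a primary shared between consecutive reactions
#' is a single node (keeping the position assigned by the reaction that
#' created it). Remaining participants are side metabolites, substrates
#' above and products below the axis at +/- 80, fanned in id order. One
#' segment connects every participant node with the reaction midmarker, so
#' the segment count equals the summed participant count. Node ids are
#' consecutive integer strings from "0".
#'
#' @param pw a `cb_pathway` (its reactions are ordered internally with
#'   [order_reactions()]).
#' @param model the owning `cb_model`.
#' @param spacing horizontal distance between consecutive midmarkers.
#' @param canvas_margin padding added around the node extent.
#' @return An `escher_map`: list of `header` and `body` per the Escher map
#'   JSON standard.
#' @export
build_escher_map <- function(pw, model, spacing = 300, canvas_margin = 150) {
  if (length(pw$reaction_ids) == 0L) stop("empty pathway", call. = FALSE)
  order <- order_reactions(pw, model)
  n <- length(order)
  axis_y <- 400
  side_dy <- 80
  primary_dx <- spacing / 2.5

  nodes <- list()
  node_id_of <- character(0)  # metabolite id -> node id (primary chain nodes only)
  next_node <- 0L
  new_node <- function(node) {
    id <- as.character(next_node)
    next_node <<- next_node + 1L
    nodes[[id]] <<- node
    id
  }
  met_node <- function(mid, x, y, primary) {
    m <- model$metabolites[[mid]]
    new_node(list(node_type = "metabolite", x = x, y = y,
                  bigg_id = mid, name = m$name,
                  label_x = x + 10, label_y = y - 10,
                  node_is_primary = primary))
  }

  sides <- lapply(order, function(rid) .oriented_sides(model$reactions[[rid]]))
  names(sides) <- order
  pick_primary <- function(rid, idx, role) {
    cand <- sides[[rid]][[role]]
    if (!length(cand)) return(NA_character_)
    neighbor <- if (role == "substrates" && idx > 1) {
      sides[[order[idx - 1]]]$products
    } else if (role == "products" && idx < n) {
      sides[[order[idx + 1]]]$substrates
    } else character(0)
    shared <- sort(intersect(cand, neighbor))
    if (length(shared)) return(shared[1])
    s <- model$reactions[[rid]]$stoichiometry
    co <- abs(s[cand])
    sort(cand[co == max(co)])[1]
  }

  reactions_body <- list()
  next_seg <- 0L
  for (i in seq_len(n)) {
    rid <- order[i]
    r <- model$reactions[[rid]]
    x_mid <- canvas_margin + (i - 1) * spacing
    mid_node <- new_node(list(node_type = "midmarker", x = x_mid, y = axis_y))

    prim_sub <- pick_primary(rid, i, "substrates")
    prim_prod <- pick_primary(rid, i, "products")

    participant_nodes <- character(0)  # node id per participant, names = met ids
    place_primary <- function(mid, x) {
      if (!is.na(node_id_of[mid])) return(node_id_of[mid])
      nid <- met_node(mid, x, axis_y, TRUE)
      node_id_of[mid] <<- nid
      nid
    }
    if (!is.na(prim_sub)) {
      participant_nodes[prim_sub] <- place_primary(prim_sub, x_mid - primary_dx)
    }
    if (!is.na(prim_prod)) {
      participant_nodes[prim_prod] <- place_primary(prim_prod, x_mid + primary_dx)
    }
    fan <- function(mids, y) {
      mids <- sort(mids)
      k <- length(mids)
      for (j in seq_along(mids)) {
        x <- x_mid + (j - (k + 1) / 2) * 60
        participant_nodes[mids[j]] <<- met_node(mids[j], x, y, FALSE)
      }
    }
    fan(setdiff(sides[[rid]]$substrates, prim_sub), axis_y - side_dy)
    fan(setdiff(sides[[rid]]$products, prim_prod), axis_y + side_dy)

    segments <- list()
    for (mid in sort(names(participant_nodes))) {
      sid <- as.character(next_seg)
      next_seg <- next_seg + 1L
      to_mid <- mid %in% sides[[rid]]$substrates
      segments[[sid]] <- list(
        from_node_id = if (to_mid) participant_nodes[[mid]] else mid_node,
        to_node_id = if (to_mid) mid_node else participant_nodes[[mid]],
        b1 = NULL, b2 = NULL)
    }
    reactions_body[[as.character(i - 1)]] <- list(
      name = r$name, bigg_id = rid,
      reversibility = r$declared_direction == "reversible",
      label_x = x_mid, label_y = axis_y - 30,
      gene_reaction_rule = r$gene_rule,
      metabolites = lapply(sort(names(r$stoichiometry)), function(m)
        list(bigg_id = m, coefficient = r$stoichiometry[[m]])),
      segments = segments)
  }

  xs <- vapply(nodes, `[[`, numeric(1), "x")
  ys <- vapply(nodes, `[[`, numeric(1), "y")
  map <- structure(list(
    header = list(
      map_name = pw$id,
      map_id = paste0(pw$id, "_map"),
      map_description = sprintf("auto-generated layout of pathway %s (%d reactions)",
                                pw$id, n),
      homepage = "https://escher.github.io",
      schema = "https://escher.github.io/escher/jsonschema/1-0-0#"),
    body = list(
      reactions = reactions_body,
      nodes = nodes,
      text_labels = stats::setNames(list(), character(0)),
      canvas = list(x = min(xs) - canvas_margin, y = min(ys) - canvas_margin,
                    width = diff(range(xs)) + 2 * canvas_margin,
                    height = diff(range(ys)) + 2 * canvas_margin))),
    class = "escher_map")
  validate_escher_map(map)
  map
}

#' Validate an Escher map's structural invariants
#'
#' Node ids must be consecutive integer strings from "0"; every segment
#' endpoint must reference an existing node; every reaction must reach at
#' least one midmarker node through its segments.
#'
#' @param map an `escher_map`.
#' @return Invisibly `TRUE`; otherwise an error naming the offender.
#' @export
validate_escher_map <- function(map) {
  stopifnot(inherits(map, "escher_map"))
  node_ids <- names(map$body$nodes)
  expected <- as.character(seq_along(node_ids) - 1L)
  if (!identical(sort(as.integer(node_ids)), as.integer(expected))) {
    stop("node ids are not consecutive integers starting at \"0\"", call. = FALSE)
  }
  for (rid in names(map$body$reactions)) {
    r <- map$body$reactions[[rid]]
    saw_mid <- FALSE
    for (sid in names(r$segments)) {
      seg <- r$segments[[sid]]
      for (endp in c(seg$from_node_id, seg$to_node_id)) {
        node <- map$body$nodes[[endp]]
        if (is.null(node)) {
          stop(sprintf("segment '%s' of reaction '%s' references missing node '%s'",
                       sid, r$bigg_id, endp), call. = FALSE)
        }
        if (identical(node$node_type, "midmarker")) saw_mid <- TRUE
      }
    }
    if (!saw_mid) {
      stop(sprintf("reaction '%s' has no midmarker reachable via its segments",
                   r$bigg_id), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.escher_map <- function(x, ...) {
  cat(sprintf("<escher_map> %s: %d reactions, %d nodes\n",
              x$header$map_name, length(x$body$reactions), length(x$body$nodes)))
  invisible(x)
}

#' Gradient specification for flux overlays
#'
#' @param stops ordered list of `list(position, color)` pairs (positions
#'   strictly increasing from 0 to 1, colors `#RRGGBB`); or a character
#'   vector of colors spread evenly over \[0, 1\].
#' @param normalization `"linear"` (min-max on |flux|) or `"quantile"`
#'   (average ranks).
#' @return A `gradient_spec`.
#' @export
gradient_spec <- function(stops = c("#FFFFFF", "#FF0000"),
                          normalization = c("linear", "quantile")) {
  normalization <- match.arg(normalization)
  if (is.character(stops)) {
    stopifnot(length(stops) >= 2L)
    pos <- seq(0, 1, length.out = length(stops))
    stops <- Map(function(p, col) list(position = p, color = col), pos, stops)
  }
  pos <- vapply(stops, `[[`, numeric(1), "position")
  cols <- vapply(stops, `[[`, character(1), "color")
  if (length(pos) < 2L || pos[1] != 0 || pos[length(pos)] != 1 ||
      any(diff(pos) <= 0)) {
    stop("gradient stops must be >= 2 with strictly increasing positions from 0 to 1",
         call. = FALSE)
  }
  if (any(!grepl("^#[0-9A-Fa-f]{6}$", cols))) {
    stop("gradient colors must be #RRGGBB hex strings", call. = FALSE)
  }
  structure(list(stops = stops, normalization = normalization),
            class = "gradient_spec")
}

.round_half_up <- function(x) floor(x + 0.5)

.hex_to_rgb <- function(hex) {
  c(strtoi(substr(hex, 2, 3), 16L), strtoi(substr(hex, 4, 5), 16L),
    strtoi(substr(hex, 6, 7), 16L))
}

.rgb_to_hex <- function(rgb) {
  sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])
}

.gradient_color <- function(t, gradient) {
  pos <- vapply(gradient$stops, `[[`, numeric(1), "position")
  k <- max(which(pos <= t + 1e-12))
  if (k == length(pos)) k <- length(pos) - 1L
  p1 <- pos[k]; p2 <- pos[k + 1]
  c1 <- .hex_to_rgb(gradient$stops[[k]]$color)
  c2 <- .hex_to_rgb(gradient$stops[[k + 1]]$color)
  local <- (t - p1) / (p2 - p1)
  .rgb_to_hex(.round_half_up(c1 + local * (c2 - c1)))
}

#' Map fluxes to colors and stroke widths
#'
#' Flux magnitudes are transformed to `t` in \[0, 1\]: linear normalization
#' uses `(|v| - min|v|) / (max|v| - min|v|)` (all-equal inputs map to 1);
#' quantile normalization uses `(rank - 1) / (n - 1)` with average ranks for
#' ties (a single value maps to 1), and is therefore invariant under any
#' strictly monotone transformation of the fluxes. Colors interpolate
#' piecewise-linearly between the gradient stops per RGB channel (rounded
#' half-up); stroke width is `2 + 8 t`.
#'
#' @param fluxes named numeric vector, reaction id to flux.
#' @param gradient a [gradient_spec()].
#' @return Named list: reaction id to `list(color, width, t)`.
#' @export
map_flux_to_style <- function(fluxes, gradient = gradient_spec()) {
  stopifnot(length(fluxes) >= 1L, !is.null(names(fluxes)))
  v <- abs(fluxes)
  n <- length(v)
  t <- if (gradient$normalization == "linear") {
    rng <- range(v)
    if (diff(rng) == 0) rep(1, n) else (v - rng[1]) / diff(rng)
  } else {
    if (n == 1L) 1 else (rank(v, ties.method = "average") - 1) / (n - 1)
  }
  out <- lapply(seq_len(n), function(i)
    list(color = .gradient_color(t[[i]], gradient),
         width = 2 + 8 * t[[i]], t = t[[i]]))
  stats::setNames(out, names(fluxes))
}

#' Serialize an Escher map (and optional style sidecar)
#'
#' Writes the map as the Escher standard two-element JSON array
#' `[header, body]` in canonical form (sorted keys; node/segment mappings
#' ordered by numeric id), so identical maps serialize byte-identically.
#' When `style` is given, per-reaction color/width pairs are written to a
#' sidecar document `<path minus .json>.style.json` — the map schema itself
#' carries geometry only, data overlays are supplied separately at render
#' time.
#'
#' @param map an `escher_map` (validated before writing).
#' @param path output path for the map JSON.
#' @param style optional output of [map_flux_to_style()].
#' @return `path`, invisibly.
#' @export
write_escher_json <- function(map, path, style = NULL) {
  validate_escher_map(map)
  doc <- .canonical_map_doc(map)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  if (!is.null(style)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".style.json")
    sdoc <- lapply(style[order(names(style))], function(s)
      list(color = s$color, width = s$width))
    writeLines(jsonlite::toJSON(sdoc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               sidecar, useBytes = TRUE)
  }
  invisible(path)
}

.num_sort <- function(ids) ids[order(as.integer(ids))]

.canonical_map_doc <- function(map) {
  nodes <- map$body$nodes[.num_sort(names(map$body$nodes))]
  nodes <- lapply(nodes, function(nd) nd[order(names(nd))])
  rxns <- map$body$reactions[.num_sort(names(map$body$reactions))]
  rxns <- lapply(rxns, function(r) {
    r$segments <- lapply(r$segments[.num_sort(names(r$segments))],
                         function(s) s[order(names(s))])
    r[order(names(r))]
  })
  list(map$header[order(names(map$header))],
       list(canvas = map$body$canvas[order(names(map$body$canvas))],
            nodes = nodes,
            reactions = rxns,
            text_labels = map$body$text_labels))
}

#' Read back a serialized Escher map
#'
#' @param path a JSON file written by [write_escher_json()] (or any
#'   two-element `[header, body]` Escher map document).
#' @return An `escher_map`.
#' @export
read_escher_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(doc) != 2L) {
    stop("not an Escher map: expected a two-element [header, body] array",
         call. = FALSE)
  }
  body <- doc[[2]]
  # normalize absent b1/b2 back to NULL entries
  body$reactions <- lapply(body$reactions, function(r) {
    r$segments <- lapply(r$segments, function(s) {
      list(from_node_id = s$from_node_id, to_node_id = s$to_node_id,
           b1 = s$b1, b2 = s$b2)
    })
    r
  })
  if (is.null(body$text_labels) || length(body$text_labels) == 0L) {
    body$text_labels <- stats::setNames(list(), character(0))
  }
  map <- structure(list(header = doc[[1]], body = body), class = "escher_map")
  validate_escher_map(map)
  map
}
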