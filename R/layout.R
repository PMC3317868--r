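# Pathway layout: a layered, KEGG-like top-to-bottom arrangement of the
# bipartite metabolite/reaction graph. Metabolites are ranked by longest
# path from the source metabolites of the selection (those never produced
# within it); reactions sit between the ranks of their substrates and
# products. Within each layer, entities are ordered barycentrically by the
# positions of their neighbors to reduce edge crossings. The procedure is
# fully deterministic: ties break lexicographically.

LAYOUT_MARGIN <- 40
LAYOUT_DX <- 110
LAYOUT_DY <- 90

#' Compute a pathway layout
#'
#' @param model A `stoichiometric_model`.
#' @param pathway_filter `NULL` for the whole model, a single subsystem
#'   label (matched against each reaction's `pathways`), or a character
#'   vector of reaction ids.
#' @param user_layout Optional path to a layout TSV with columns
#'   `entity_id`, `x`, `y` (no header required); listed positions override
#'   the automatic ones, unknown ids are skipped with a warning, and
#'   unlisted entities are placed by the automatic layout.
#' @return A `pathway_layout`: list with `nodes` (data frame `id, x, y`
#'   for metabolites), `edge_routes` (named list, reaction id -> matrix of
#'   polyline points, with the reaction anchor as the middle point),
#'   `reaction_nodes` (data frame `id, x, y`), `canvas` (width, height)
#'   and `source` (`"auto_layout"` or `"user_layout_file"`).
#' @export
layout_pathway <- function(model, pathway_filter = NULL, user_layout = NULL) {
  rids <- select_reactions(model, pathway_filter)
  if (length(rids) == 0L) stop("pathway filter selects no reactions")
  rxns <- model$reactions[rids]
  mids <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)))))

  # bound-aware production/consumption within the selection
  produced <- consumed <- stats::setNames(logical(length(mids)), mids)
  for (r in rxns) {
    st <- r$stoichiometry
    produced[names(st)[st > 0]] <- TRUE
    consumed[names(st)[st < 0]] <- TRUE
    if (r$lower_bound < 0) {  # reversible: both roles
      produced[names(st)[st < 0]] <- TRUE
      consumed[names(st)[st > 0]] <- TRUE
    }
  }
  sources <- mids[consumed[mids] & !produced[mids]]
  if (length(sources) == 0L) sources <- mids[1]  # cyclic selection fallback

  # longest-path ranks over substrate -> product edges, capped for cycles
  rank <- stats::setNames(rep(0L, length(mids)), mids)
  for (pass in seq_len(length(mids) + 1L)) {
    changed <- FALSE
    for (r in rxns) {
      st <- r$stoichiometry
      subs <- names(st)[st < 0]
      prods <- names(st)[st > 0]
      if (length(subs) == 0L || length(prods) == 0L) next
      new_rank <- max(rank[subs]) + 1L
      for (p in prods) {
        if (new_rank > rank[p] && new_rank <= length(mids)) {
          rank[p] <- new_rank
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  # reactions sit midway between their substrate and product layers;
  # single-sided reactions (exchanges, intakes) half a layer outside
  rxn_rank <- vapply(rxns, function(r) {
    st <- r$stoichiometry
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    if (length(subs) && length(prods))
      mean(c(max(rank[subs]), min(rank[prods])))
    else if (length(subs)) max(rank[subs]) + 0.5
    else if (length(prods)) min(rank[prods]) - 0.5
    else 0
  }, 0)
  shift <- min(c(rank, rxn_rank))
  rank <- rank - shift
  rxn_rank <- rxn_rank - shift

  # barycentric x-ordering per layer, seeded lexicographically
  xpos <- stats::setNames(seq_along(mids), sort(mids))
  for (sweep in 1:3) {
    bary <- vapply(mids, function(m) {
      nb <- unlist(lapply(rxns, function(r)
        if (m %in% names(r$stoichiometry))
          setdiff(names(r$stoichiometry), m) else character()))
      if (length(nb)) mean(xpos[nb]) else xpos[m]
    }, 0)
    for (lv in sort(unique(rank))) {
      layer <- mids[rank[mids] == lv]
      ord <- layer[order(bary[layer], layer)]
      xpos[ord] <- seq_along(ord)
    }
  }

  nodes <- data.frame(
    id = mids,
    x = LAYOUT_MARGIN + (xpos[mids] - 1) * LAYOUT_DX,
    y = LAYOUT_MARGIN + rank[mids] * LAYOUT_DY,
    stringsAsFactors = FALSE, row.names = NULL)

  rbary <- vapply(rxns, function(r)
    mean(nodes$x[match(names(r$stoichiometry), nodes$id)]), 0)
  reaction_nodes <- data.frame(
    id = rids,
    x = rbary,
    y = LAYOUT_MARGIN + rxn_rank * LAYOUT_DY,
    stringsAsFactors = FALSE, row.names = NULL)

  source_kind <- "auto_layout"
  if (!is.null(user_layout)) {
    tab <- utils::read.table(user_layout, sep = "\t", header = FALSE,
                             col.names = c("entity_id", "x", "y"),
                             stringsAsFactors = FALSE, comment.char = "#")
    if (is.character(tab$x)) {  # header row present
      tab <- tab[suppressWarnings(!is.na(as.numeric(tab$x))), ]
      tab$x <- as.numeric(tab$x); tab$y <- as.numeric(tab$y)
    }
    known <- tab$entity_id %in% c(mids, rids)
    if (any(!known))
      warning("layout file references unknown ids, skipped: ",
              paste(tab$entity_id[!known], collapse = ", "), call. = FALSE)
    tab <- tab[known, , drop = FALSE]
    for (i in seq_len(nrow(tab))) {
      hit <- match(tab$entity_id[i], nodes$id)
      if (!is.na(hit)) { nodes$x[hit] <- tab$x[i]; nodes$y[hit] <- tab$y[i] }
      hit <- match(tab$entity_id[i], reaction_nodes$id)
      if (!is.na(hit)) {
        reaction_nodes$x[hit] <- tab$x[i]
        reaction_nodes$y[hit] <- tab$y[i]
      }
    }
    source_kind <- "user_layout_file"
  }

  edge_routes <- lapply(rids, function(rid) {
    st <- rxns[[rid]]$stoichiometry
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    pt <- function(ids) if (length(ids))
      c(mean(nodes$x[match(ids, nodes$id)]),
        mean(nodes$y[match(ids, nodes$id)])) else NULL
    rp <- unlist(reaction_nodes[match(rid, reaction_nodes$id), c("x", "y")])
    pts <- rbind(pt(subs), rp, pt(prods))
    dimnames(pts) <- NULL
    pts
  })
  names(edge_routes) <- rids

  all_x <- c(nodes$x, reaction_nodes$x)
  all_y <- c(nodes$y, reaction_nodes$y)
  structure(list(nodes = nodes, edge_routes = edge_routes,
                 reaction_nodes = reaction_nodes,
                 canvas = c(width = max(all_x) + LAYOUT_MARGIN,
                            height = max(all_y) + LAYOUT_MARGIN),
                 source = source_kind),
            class = "pathway_layout")
}

select_reactions <- function(model, pathway_filter) {
  rids <- names(model$reactions)
  if (is.null(pathway_filter)) return(rids)
  stopifnot(is.character(pathway_filter))
  if (length(pathway_filter) == 1L && !pathway_filter %in% rids) {
    # treat as a subsystem label
    hit <- vapply(model$reactions, function(r)
      pathway_filter %in% r$pathways, TRUE)
    return(rids[hit])
  }
  missing <- setdiff(pathway_filter, rids)
  if (length(missing))
    stop("unknown reactions in pathway filter: ",
         paste(missing, collapse = ", "))
  pathway_filter
}

#' @export
print.pathway_layout <- function(x, ...) {
  cat("Pathway layout (", x$source, "): ", nrow(x$nodes), " metabolites, ",
      length(x$edge_routes), " reactions, canvas ",
      x$canvas[1], "x", x$canvas[2], "\n", sep = "")
  invisible(x)
}
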