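#' Find dead-end (orphan) metabolites
#'
#' A non-boundary metabolite is *never produced* when no reaction can give
#' it a positive net rate under its flux bounds: a positive coefficient with
#' `upper_bound > 0`, or a negative coefficient with `lower_bound < 0`
#' (reverse operation). *Never consumed* is symmetric. The test is
#' bound-aware, not merely topological: an irreversible consumer cannot act
#' as a producer even though the edge exists.
#'
#' @param model A `stoichiometric_model`.
#' @param tol Bounds within `tol` of zero count as closed.
#' @return A list with character vectors `never_produced` and
#'   `never_consumed` (boundary metabolites excluded).
#' @export
find_orphan_metabolites <- function(model, tol = 1e-9) {
  can_produce <- can_consume <- stats::setNames(
    logical(length(model$metabolites)), names(model$metabolites))
  for (r in model$reactions) {
    fwd <- r$upper_bound > tol   # reaction can run forward
    bwd <- r$lower_bound < -tol  # reaction can run in reverse
    st <- r$stoichiometry
    pos <- names(st)[st > 0]
    neg <- names(st)[st < 0]
    if (fwd) {
      can_produce[pos] <- TRUE
      can_consume[neg] <- TRUE
    }
    if (bwd) {
      can_produce[neg] <- TRUE
      can_consume[pos] <- TRUE
    }
  }
  internal <- !vapply(model$metabolites, `[[`, TRUE, "boundary")
  ids <- names(model$metabolites)[internal]
  list(never_produced = ids[!can_produce[ids]],
       never_consumed = ids[!can_consume[ids]])
}

#' Group synonymous reactions
#'
#' Two reactions are synonymous when their stoichiometry maps are identical,
#' or identical after negating every coefficient (the same conversion
#' written in the opposite direction). Scalar multiples are *not* merged:
#' under shared bounds `2A -> 2B` has different flux semantics than
#' `A -> B`. Bounds, gene associations and annotations are ignored.
#'
#' @param model A `stoichiometric_model`.
#' @return A list of character vectors, each a group of >= 2 reaction ids,
#'   in model order.
#' @export
find_synonymous_reactions <- function(model) {
  key_of <- function(st) {
    o <- order(names(st))
    paste(names(st)[o], sprintf("%.12g", unname(st[o])),
          sep = ":", collapse = ";")
  }
  keys <- vapply(model$reactions, function(r) {
    k1 <- key_of(r$stoichiometry)
    k2 <- key_of(-r$stoichiometry)
    min(k1, k2)  # direction-independent canonical key
  }, "")
  groups <- split(names(model$reactions), keys)
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  # report in model order of each group's first member
  ord <- order(vapply(groups, function(g) match(g[1], names(model$reactions)), 0L))
  unname(groups[ord])
}

#' List producers and consumers of a metabolite
#'
#' Without a flux result the classification uses the declared stoichiometry:
#' positive coefficient = producer, negative = consumer. With a result the
#' realized direction decides: a reversible consumer carrying negative flux
#' is listed among the producers, with its signed flux. Reactions carrying
#' (numerically) zero flux stay on their declared side.
#'
#' @param model A `stoichiometric_model`.
#' @param metabolite_id Metabolite to inspect.
#' @param result Optional `flux_analysis_result` from [run_fba()].
#' @param tol Fluxes within `tol` of zero are classified by coefficient sign.
#' @return A list of two data frames, `producers` and `consumers`, with
#'   columns `reaction`, `coefficient` and (when `result` is given) `flux`.
#' @export
metabolite_connections <- function(model, metabolite_id, result = NULL,
                                   tol = 1e-9) {
  if (!metabolite_id %in% names(model$metabolites))
    stop("unknown metabolite '", metabolite_id, "'")
  rows <- list()
  for (r in model$reactions) {
    coef <- unname(r$stoichiometry[match(metabolite_id,
                                         names(r$stoichiometry))])
    if (is.na(coef) || coef == 0) next
    flux <- if (!is.null(result)) unname(result$fluxes[r$id]) else NA_real_
    side <- if (!is.null(result) && is.finite(flux) && abs(flux) > tol) {
      if (coef * flux > 0) "producer" else "consumer"
    } else {
      if (coef > 0) "producer" else "consumer"
    }
    rows[[length(rows) + 1L]] <-
      data.frame(reaction = r$id, coefficient = unname(coef), flux = flux,
                 side = side, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction = character(), coefficient = numeric(),
               flux = numeric(), side = character())
  if (is.null(result)) tab$flux <- NULL
  list(producers = tab[tab$side == "producer",
                       setdiff(names(tab), "side"), drop = FALSE],
       consumers = tab[tab$side == "consumer",
                       setdiff(names(tab), "side"), drop = FALSE])
}
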