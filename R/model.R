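#' Create a metabolite
#'
#' Metabolites are the rows of the stoichiometric matrix. A boundary
#' metabolite is exempt from the steady-state mass balance (its row is
#' dropped when the linear program is built).
#'
#' @param id Unique metabolite identifier.
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Compartment identifier.
#' @param boundary Logical; `TRUE` exempts the metabolite from mass balance.
#' @param kegg_id Optional KEGG compound identifier (e.g. `"C00031"`).
#' @param annotations Named list of free-form annotations.
#' @return A `metabolite` object (a named list).
#' @export
metabolite <- function(id, name = id, compartment = "c", boundary = FALSE,
                       kegg_id = NULL, annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment,
                 boundary = isTRUE(boundary), kegg_id = kegg_id,
                 annotations = annotations),
            class = "metabolite")
}

#' Create a reaction
#'
#' Stoichiometry follows the usual sign convention: negative coefficients
#' are substrates, positive coefficients products. Bounds are authoritative
#' for the linear program; the `reversible` flag is metadata and is kept in
#' sync (`lower_bound < 0`) by the editing operations, but imported models
#' may disagree and are accepted as-is.
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds (mmol/gDW/h by convention).
#' @param name Human-readable name; defaults to `id`.
#' @param gene_association Optional raw boolean gene-association string.
#' @param ec_numbers Character vector of EC numbers.
#' @param kegg_id Optional KEGG reaction identifier (e.g. `"R00299"`).
#' @param pathways Character vector of subsystem labels.
#' @param is_exchange Logical; single-metabolite boundary reaction.
#' @param annotations Named list of free-form annotations.
#' @return A `reaction` object (a named list).
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     name = id, gene_association = NULL,
                     ec_numbers = character(), kegg_id = NULL,
                     pathways = character(), is_exchange = FALSE,
                     annotations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a non-empty named numeric vector")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 reversible = lower_bound < 0,
                 gene_association = gene_association,
                 ec_numbers = ec_numbers, kegg_id = kegg_id,
                 pathways = pathways, is_exchange = isTRUE(is_exchange),
                 annotations = annotations),
            class = "reaction")
}

#' Assemble a stoichiometric model
#'
#' The editable in-memory representation: ordered metabolite and reaction
#' collections, a compartment table, and an optional linear objective.
#'
#' @param id,name Model identifier and display name.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param compartments Named character vector, compartment id -> name.
#'   Compartments referenced by metabolites are added automatically.
#' @param objective A list with elements `coefficients` (named numeric,
#'   reaction id -> weight) and `direction` (`"maximize"` or `"minimize"`),
#'   or `NULL` for no objective.
#' @param provenance List recording the source dialect and notes.
#' @return A validated `stoichiometric_model`.
#' @export
stoichiometric_model <- function(id = "model", name = id,
                                 metabolites = list(), reactions = list(),
                                 compartments = character(),
                                 objective = NULL,
                                 provenance = list(dialect = "constructed")) {
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  for (m in metabolites) {
    if (!m$compartment %in% names(compartments)) {
      compartments[m$compartment] <- m$compartment
    }
  }
  model <- structure(list(id = id, name = name,
                          metabolites = metabolites, reactions = reactions,
                          compartments = compartments,
                          objective = normalize_objective(objective),
                          provenance = provenance),
                     class = "stoichiometric_model")
  validate_model(model)
  model
}

normalize_objective <- function(objective) {
  if (is.null(objective)) {
    return(list(coefficients = stats::setNames(numeric(0), character(0)),
                direction = "maximize"))
  }
  stopifnot(is.list(objective))
  direction <- match.arg(objective$direction, c("maximize", "minimize"))
  coef <- objective$coefficients
  if (is.null(coef)) coef <- stats::setNames(numeric(0), character(0))
  list(coefficients = coef, direction = direction)
}

#' Validate model invariants
#'
#' Checks id uniqueness, compartment resolution, stoichiometry references,
#' bound ordering and objective references. Called by every editing
#' operation; raises an informative error on the first violation.
#'
#' @param model A `stoichiometric_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoichiometric_model"))
  mids <- names(model$metabolites)
  rids <- names(model$reactions)
  if (anyDuplicated(mids)) stop("duplicate metabolite ids: ",
                                paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids)) stop("duplicate reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (m in model$metabolites) {
    if (!m$compartment %in% names(model$compartments))
      stop("metabolite '", m$id, "' references unknown compartment '",
           m$compartment, "'")
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), mids)
    if (length(missing))
      stop("reaction '", r$id, "' references undeclared metabolites: ",
           paste(missing, collapse = ", "))
    if (length(r$stoichiometry) == 0L)
      stop("reaction '", r$id, "' has empty stoichiometry")
    if (r$lower_bound > r$upper_bound)
      stop("reaction '", r$id, "': lower_bound > upper_bound")
  }
  obj_missing <- setdiff(names(model$objective$coefficients), rids)
  if (length(obj_missing))
    stop("objective references unknown reactions: ",
         paste(obj_missing, collapse = ", "))
  invisible(model)
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  n_ex <- sum(vapply(x$reactions, `[[`, TRUE, "is_exchange"))
  obj <- x$objective
  obj_txt <- if (length(obj$coefficients) == 0L) "none" else
    paste0(obj$direction, " ",
           paste(sprintf("%g*%s", unname(obj$coefficients),
                         names(obj$coefficients)), collapse = " + "))
  cat("Stoichiometric model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      " (", sum(vapply(x$metabolites, `[[`, TRUE, "boundary")), " boundary)\n",
      sep = "")
  cat("  reactions:   ", length(x$reactions), " (", n_ex, " exchange)\n",
      sep = "")
  cat("  compartments:", paste(names(x$compartments), collapse = ", "), "\n")
  cat("  objective:   ", obj_txt, "\n", sep = "")
  invisible(x)
}

#' Set flux bounds on a reaction
#'
#' Replaces both bounds and recomputes the `reversible` flag as
#' `lower < 0`. The model is returned updated; on error it is unchanged.
#'
#' @param model A `stoichiometric_model`.
#' @param reaction_id Reaction to edit.
#' @param lower,upper New bounds; `lower <= upper` required.
#' @return The updated model.
#' @export
set_bounds <- function(model, reaction_id, lower, upper) {
  rxn <- get_reaction(model, reaction_id)
  if (lower > upper)
    stop("set_bounds('", reaction_id, "'): lower (", lower,
         ") > upper (", upper, ")")
  rxn$lower_bound <- as.numeric(lower)
  rxn$upper_bound <- as.numeric(upper)
  rxn$reversible <- lower < 0
  model$reactions[[reaction_id]] <- rxn
  validate_model(model)
  model
}

#' Set a single-reaction objective
#'
#' Replaces the current objective with coefficient 1 on `reaction_id`.
#' Multi-reaction objectives can be set by assigning
#' `model$objective$coefficients` directly.
#'
#' @inheritParams set_bounds
#' @param direction `"maximize"` or `"minimize"`.
#' @return The updated model.
#' @export
set_objective <- function(model, reaction_id, direction = "maximize") {
  get_reaction(model, reaction_id)
  direction <- match.arg(direction, c("maximize", "minimize"))
  model$objective <- list(coefficients = stats::setNames(1, reaction_id),
                          direction = direction)
  validate_model(model)
  model
}

#' Add an exchange reaction for a metabolite
#'
#' The new reaction has stoichiometry `{metabolite: -1}`, so positive flux
#' is excretion and negative flux uptake. The id is `"EX_" + metabolite_id`,
#' with `_1`, `_2`, ... appended on collision.
#'
#' @inheritParams set_bounds
#' @param metabolite_id Metabolite to connect to the environment.
#' @param lower,upper Bounds of the new exchange flux.
#' @return The updated model.
#' @export
add_exchange_reaction <- function(model, metabolite_id, lower = -1000,
                                  upper = 1000) {
  if (!metabolite_id %in% names(model$metabolites))
    stop("unknown metabolite '", metabolite_id, "'")
  base <- paste0("EX_", metabolite_id)
  id <- base
  k <- 0L
  while (id %in% names(model$reactions)) {
    k <- k + 1L
    id <- paste0(base, "_", k)
  }
  rxn <- reaction(id, stats::setNames(-1, metabolite_id),
                  lower_bound = lower, upper_bound = upper,
                  name = paste(model$metabolites[[metabolite_id]]$name,
                               "exchange"),
                  is_exchange = TRUE)
  model$reactions[[id]] <- rxn
  validate_model(model)
  model
}

#' Assign a metabolite or reaction to a compartment
#'
#' Unknown compartments are created on the fly. For reactions the
#' compartment is recorded as an annotation (reactions span compartments;
#' the label is bookkeeping, not mass balance).
#'
#' @inheritParams set_bounds
#' @param entity_id Metabolite or reaction id.
#' @param compartment_id Target compartment; created if new.
#' @return The updated model.
#' @export
assign_compartment <- function(model, entity_id, compartment_id) {
  if (!compartment_id %in% names(model$compartments))
    model$compartments[compartment_id] <- compartment_id
  if (entity_id %in% names(model$metabolites)) {
    model$metabolites[[entity_id]]$compartment <- compartment_id
  } else if (entity_id %in% names(model$reactions)) {
    model$reactions[[entity_id]]$annotations$compartment <- compartment_id
  } else {
    stop("unknown entity '", entity_id, "'")
  }
  validate_model(model)
  model
}

#' Add a reaction to a model
#'
#' @inheritParams set_bounds
#' @param rxn A [reaction()] object whose id is not yet in the model.
#' @return The updated model.
#' @export
add_reaction <- function(model, rxn) {
  stopifnot(inherits(rxn, "reaction"))
  if (rxn$id %in% names(model$reactions))
    stop("reaction id '", rxn$id, "' already exists")
  model$reactions[[rxn$id]] <- rxn
  validate_model(model)
  model
}

#' Delete a reaction from a model
#'
#' Any objective coefficient on the deleted reaction is dropped.
#'
#' @inheritParams set_bounds
#' @return The updated model.
#' @export
delete_reaction <- function(model, reaction_id) {
  get_reaction(model, reaction_id)
  model$reactions[[reaction_id]] <- NULL
  keep <- setdiff(names(model$objective$coefficients), reaction_id)
  model$objective$coefficients <- model$objective$coefficients[keep]
  validate_model(model)
  model
}

#' Rename a metabolite or reaction
#'
#' All stoichiometry and objective references are rewritten consistently.
#'
#' @inheritParams set_bounds
#' @param old_id Existing metabolite or reaction id.
#' @param new_id Replacement id; must not collide.
#' @return The updated model.
#' @export
rename_entity <- function(model, old_id, new_id) {
  if (new_id %in% c(names(model$metabolites), names(model$reactions)))
    stop("id '", new_id, "' already in use")
  if (old_id %in% names(model$metabolites)) {
    idx <- match(old_id, names(model$metabolites))
    model$metabolites[[idx]]$id <- new_id
    names(model$metabolites)[idx] <- new_id
    for (i in seq_along(model$reactions)) {
      st <- model$reactions[[i]]$stoichiometry
      hit <- match(old_id, names(st))
      if (!is.na(hit)) {
        names(st)[hit] <- new_id
        model$reactions[[i]]$stoichiometry <- st
      }
    }
  } else if (old_id %in% names(model$reactions)) {
    idx <- match(old_id, names(model$reactions))
    model$reactions[[idx]]$id <- new_id
    names(model$reactions)[idx] <- new_id
    oc <- model$objective$coefficients
    hit <- match(old_id, names(oc))
    if (!is.na(hit)) {
      names(oc)[hit] <- new_id
      model$objective$coefficients <- oc
    }
  } else {
    stop("unknown entity '", old_id, "'")
  }
  validate_model(model)
  model
}

get_reaction <- function(model, reaction_id) {
  rxn <- model$reactions[[reaction_id]]
  if (is.null(rxn)) stop("unknown reaction '", reaction_id, "'")
  rxn
}

#' Stoichiometric matrix of a model
#'
#' One row per non-boundary metabolite, one column per reaction, in model
#' order. Boundary metabolites are exempt from mass balance and omitted.
#'
#' @param model A `stoichiometric_model`.
#' @return A dense numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  keep <- !vapply(model$metabolites, `[[`, TRUE, "boundary")
  mids <- names(model$metabolites)[keep]
  rids <- names(model$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (r in model$reactions) {
    st <- r$stoichiometry
    rows <- intersect(names(st), mids)
    if (length(rows)) S[rows, r$id] <- st[rows]
  }
  S
}
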