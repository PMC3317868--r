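# Flux analyses: FBA, FVA, flux-sum minimization, producibility.
# All analyses share one linear-program builder: rows are the mass balances
# of non-boundary metabolites (S v = 0), columns the reaction fluxes with
# their box bounds.

build_lp <- function(model) {
  S <- stoichiometric_matrix(model)
  rids <- names(model$reactions)
  list(S = S,
       lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(model$reactions, `[[`, 0, "upper_bound"),
       rids = rids, mids = rownames(S))
}

objective_vector <- function(model, rids) {
  cf <- model$objective$coefficients
  v <- stats::setNames(numeric(length(rids)), rids)
  v[names(cf)] <- cf
  v
}

new_flux_result <- function(status, objective_value = NA_real_,
                            fluxes = NULL, reduced_costs = NULL,
                            shadow_prices = NULL, warnings = character(),
                            direction = "maximize", total_flux = NA_real_) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes, reduced_costs = reduced_costs,
                 shadow_prices = shadow_prices, warnings = warnings,
                 direction = direction, total_flux = total_flux),
            class = "flux_analysis_result")
}

#' @export
print.flux_analysis_result <- function(x, ...) {
  cat("Flux analysis result: status", x$status, "\n")
  if (x$status == "optimal") {
    cat("  objective (", x$direction, "): ",
        sprintf("%.6g", x$objective_value), "\n", sep = "")
    if (is.finite(x$total_flux))
      cat("  total |flux|:", sprintf("%.6g", x$total_flux), "\n")
    cat("  nonzero fluxes:", sum(abs(x$fluxes) > 1e-9), "of",
        length(x$fluxes), "\n")
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the model objective `c'v` subject to steady
#' state `S v = 0` and the reaction bounds. On an optimal solve the result
#' carries the flux vector plus the dual values: shadow prices are the
#' sensitivities of the optimal objective to each metabolite's balance
#' right-hand side (`dz/db_i` for a perturbation `S v = b`), and reduced
#' costs the sensitivities to the active flux bound of each reaction
#' (`dz/dbound`). Infeasible and unbounded models return the status plus a
#' warning string instead of raising an error.
#'
#' @param model A `stoichiometric_model` with a non-empty objective.
#' @return A `flux_analysis_result`.
#' @export
run_fba <- function(model) {
  if (length(model$objective$coefficients) == 0L)
    stop("model has no objective; set one with set_objective() first")
  lp <- build_lp(model)
  cv <- objective_vector(model, lp$rids)
  maximize <- model$objective$direction == "maximize"
  sol <- solve_lp(cv, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub,
                  maximize = maximize)
  if (sol$status != "optimal") {
    msg <- paste0("solution status is '", sol$status, "'")
    warning(msg, call. = FALSE)
    return(new_flux_result(sol$status, warnings = msg,
                           direction = model$objective$direction))
  }
  new_flux_result("optimal", objective_value = sol$objective,
                  fluxes = stats::setNames(sol$x, lp$rids),
                  reduced_costs = stats::setNames(sol$reduced_costs, lp$rids),
                  shadow_prices = stats::setNames(sol$row_duals, lp$mids),
                  direction = model$objective$direction,
                  total_flux = sum(abs(sol$x)))
}

# Finite cap for auxiliary variables (slack of the optimality-fraction row):
# no |c'v| can exceed this under the box bounds.
objective_cap <- function(cv, lb, ub) {
  sum(abs(cv) * pmax(abs(lb), abs(ub))) + 1
}

#' Flux variability analysis
#'
#' For each reaction in `reactions` (default: all), minimizes and maximizes
#' its flux subject to steady state, the bounds, and near-optimality of the
#' model objective: `c'v >= fraction * z*` for maximization objectives
#' (`<=` for minimization), where `z*` is the FBA optimum. Two LPs are
#' solved per reaction.
#'
#' @param model A `stoichiometric_model` with a non-empty objective.
#' @param reactions Optional character vector restricting the analysis to a
#'   reaction subset (the paper's pathway-restricted FVA); `NULL` means all.
#' @param fraction Required optimality fraction in (0, 1]; default 1.
#' @return An `fva_result`: a data frame with columns `reaction`,
#'   `min_flux`, `max_flux`, plus attributes `fraction` and `status`.
#' @export
run_fva <- function(model, reactions = NULL, fraction = 1.0) {
  stopifnot(fraction > 0, fraction <= 1)
  base <- suppressWarnings(run_fba(model))
  lp <- build_lp(model)
  if (base$status != "optimal") {
    out <- data.frame(reaction = character(), min_flux = numeric(),
                      max_flux = numeric())
    attr(out, "status") <- base$status
    attr(out, "fraction") <- fraction
    class(out) <- c("fva_result", class(out))
    return(out)
  }
  if (is.null(reactions) || length(reactions) == 0L) reactions <- lp$rids
  missing <- setdiff(reactions, lp$rids)
  if (length(missing))
    stop("unknown reactions in FVA subset: ", paste(missing, collapse = ", "))

  cv <- objective_vector(model, lp$rids)
  maximize <- model$objective$direction == "maximize"
  n <- length(lp$rids)
  big <- objective_cap(cv, lp$lb, lp$ub)
  # optimality row: c'v - s = 0 with s constrained to the near-optimal range
  A <- rbind(cbind(lp$S, 0), c(cv, -1))
  zstar <- base$objective_value
  s_bounds <- if (maximize) c(fraction * zstar, big) else
    c(-big, fraction * zstar)
  lb <- c(lp$lb, s_bounds[1])
  ub <- c(lp$ub, s_bounds[2])
  b <- rep(0, nrow(A))

  res <- matrix(NA_real_, nrow = length(reactions), ncol = 2)
  for (i in seq_along(reactions)) {
    e <- numeric(n + 1)
    e[match(reactions[i], lp$rids)] <- 1
    lo <- solve_lp(e, A, b, lb, ub, maximize = FALSE)
    hi <- solve_lp(e, A, b, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for '", reactions[i], "' returned status ",
           lo$status, "/", hi$status)
    res[i, ] <- c(lo$objective, hi$objective)
  }
  out <- data.frame(reaction = reactions, min_flux = res[, 1],
                    max_flux = res[, 2], stringsAsFactors = FALSE)
  attr(out, "fraction") <- fraction
  attr(out, "status") <- "optimal"
  class(out) <- c("fva_result", class(out))
  out
}

#' Minimize the total absolute flux at the FBA optimum
#'
#' Runs FBA, then a second linear program minimizing `sum(|v_r|)` subject to
#' steady state, the bounds, and the objective fixed at its optimum. Each
#' flux is split into nonnegative forward and backward parts, so the second
#' program stays linear. This strips futile cycles out of the reported
#' solution, leaving the underlying net fluxes.
#'
#' @param model A `stoichiometric_model` with a non-empty objective.
#' @param exclude_exchanges If `TRUE`, exchange fluxes get zero weight in
#'   the minimized sum (they are still reported and still constrained).
#' @return A `flux_analysis_result` whose `fluxes` are the parsimonious
#'   solution, `objective_value` the preserved FBA optimum, and
#'   `total_flux` the minimized `sum(|v|)` over the weighted reactions.
#'   Dual values are not defined for the recomposed fluxes and are `NULL`.
#' @export
minimize_total_flux <- function(model, exclude_exchanges = FALSE) {
  base <- suppressWarnings(run_fba(model))
  if (base$status != "optimal") return(base)
  lp <- build_lp(model)
  cv <- objective_vector(model, lp$rids)
  n <- length(lp$rids)

  # v = p - q with p, q >= 0; bound cases keep p - q within [lb, ub]
  plb <- pmax(lp$lb, 0); pub <- pmax(lp$ub, 0)
  qlb <- pmax(-lp$ub, 0); qub <- pmax(-lp$lb, 0)
  A <- cbind(lp$S, -lp$S)
  A <- rbind(A, c(cv, -cv))             # objective fixed at its optimum
  b <- c(rep(0, nrow(lp$S)), base$objective_value)
  w <- rep(1, n)
  if (exclude_exchanges)
    w[vapply(model$reactions, `[[`, TRUE, "is_exchange")] <- 0
  sol <- solve_lp(c(w, w), A, b, c(plb, qlb), c(pub, qub), maximize = FALSE)
  if (sol$status != "optimal") {
    msg <- paste0("flux minimization status is '", sol$status, "'")
    warning(msg, call. = FALSE)
    return(new_flux_result(sol$status, warnings = msg,
                           direction = model$objective$direction))
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  new_flux_result("optimal", objective_value = sum(cv * v),
                  fluxes = stats::setNames(v, lp$rids),
                  direction = model$objective$direction,
                  total_flux = sum(w * abs(v)))
}

#' Can the model produce a metabolite?
#'
#' Adds a temporary demand reaction `{metabolite: -1}` with bounds
#' `(0, 1000)` and maximizes its flux under steady state and the original
#' bounds; the model objective is ignored and the model itself is left
#' untouched. The metabolite is producible when the maximal demand exceeds
#' `1e-6`.
#'
#' @param model A `stoichiometric_model`.
#' @param metabolite_id A non-boundary metabolite id.
#' @return A list with `producible` (logical) and `max_rate` (numeric).
#' @export
check_producibility <- function(model, metabolite_id) {
  lp <- build_lp(model)
  if (!metabolite_id %in% lp$mids)
    stop("unknown or boundary metabolite '", metabolite_id, "'")
  producibility_solve(lp, metabolite_id)
}

producibility_solve <- function(lp, metabolite_id) {
  n <- ncol(lp$S)
  demand <- numeric(nrow(lp$S))
  demand[match(metabolite_id, lp$mids)] <- -1
  A <- cbind(lp$S, demand)
  e <- c(numeric(n), 1)
  sol <- solve_lp(e, A, rep(0, nrow(A)), c(lp$lb, 0), c(lp$ub, 1000),
                  maximize = TRUE)
  if (sol$status != "optimal")
    return(list(producible = FALSE, max_rate = 0))
  list(producible = sol$objective > 1e-6, max_rate = sol$objective)
}

#' Producibility of every metabolite
#'
#' Applies [check_producibility()] to each non-boundary metabolite; the
#' result is independent of iteration order.
#'
#' @param model A `stoichiometric_model`.
#' @return A data frame with columns `metabolite`, `producible`, `max_rate`,
#'   one row per non-boundary metabolite in model order.
#' @export
check_all_producibility <- function(model) {
  lp <- build_lp(model)
  rows <- lapply(lp$mids, function(mid) {
    r <- producibility_solve(lp, mid)
    data.frame(metabolite = mid, producible = r$producible,
               max_rate = r$max_rate, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(metabolite = character(), producible = logical(),
                      max_rate = numeric()))
  do.call(rbind, rows)
}
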