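# Independent oracles used to cross-check the solver and analyses.
# They never call solve_lp(): optima are found by exhaustive enumeration of
# basic feasible solutions (polytope vertices), which is exact for the
# small, fully bounded fixture and random models used in tests.

# Enumerate all basic feasible solutions of {A x = b, lb <= x <= ub}.
# Fixes (n - rank) variables at a bound in every possible way and solves
# for the rest; infeasible or inconsistent combinations are dropped.
enumerate_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  n <- ncol(A)
  r <- qr(A)$rank
  n_fix <- n - r
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  vertices <- list()
  fix_sets <- if (n_fix == 0) list(integer(0)) else
    asplit(utils::combn(n, n_fix), 2)
  for (fixed in fix_sets) {
    fixed <- as.integer(fixed)
    basic <- setdiff(seq_len(n), fixed)
    grid <- if (length(fixed) == 0) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(c(1, 2)), length(fixed))))
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[fixed] <- ifelse(grid[g, ] == 1, lb[fixed], ub[fixed])
      rhs <- b - if (length(fixed))
        drop(A[, fixed, drop = FALSE] %*% x[fixed]) else 0
      xb <- tryCatch(qr.solve(A[, basic, drop = FALSE], rhs, tol = 1e-10),
                     error = function(e) NULL)
      if (is.null(xb)) next
      x[basic] <- xb
      if (max(abs(drop(A %*% x) - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      vertices[[length(vertices) + 1L]] <- pmin(pmax(x, lb), ub)
    }
  }
  if (length(vertices) == 0) return(NULL)
  unique(do.call(rbind, vertices))
}

# FBA oracle: optimum of c'v over the vertices of {S v = 0, bounds}.
oracle_fba <- function(model) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  cv <- numeric(ncol(S))
  names(cv) <- colnames(S)
  cv[names(model$objective$coefficients)] <- model$objective$coefficients
  V <- enumerate_vertices(S, rep(0, nrow(S)), lb, ub)
  if (is.null(V)) return(list(status = "infeasible"))
  vals <- drop(V %*% cv)
  best <- if (model$objective$direction == "maximize") max(vals) else
    min(vals)
  list(status = "optimal", objective = best,
       vertices = V, values = vals)
}

# FVA oracle: per-reaction min/max over the vertices of the polytope lifted
# by the optimality constraint c'v = s, s in the near-optimal range.
oracle_fva <- function(model, fraction = 1.0) {
  base <- oracle_fba(model)
  stopifnot(base$status == "optimal")
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  cv <- numeric(ncol(S))
  names(cv) <- colnames(S)
  cv[names(model$objective$coefficients)] <- model$objective$coefficients
  big <- sum(abs(cv) * pmax(abs(lb), abs(ub))) + 1
  A <- rbind(cbind(S, 0), c(cv, -1))
  if (model$objective$direction == "maximize") {
    slb <- fraction * base$objective; sub <- big
  } else {
    slb <- -big; sub <- fraction * base$objective
  }
  V <- enumerate_vertices(A, rep(0, nrow(A)), c(lb, slb), c(ub, sub))
  stopifnot(!is.null(V))
  n <- ncol(S)
  data.frame(reaction = colnames(S),
             min_flux = apply(V[, seq_len(n), drop = FALSE], 2, min),
             max_flux = apply(V[, seq_len(n), drop = FALSE], 2, max),
             stringsAsFactors = FALSE)
}

# Split-variable flux-sum-minimization oracle: minimizes sum(p + q) over the
# vertices of {S(p - q) = 0, c'(p - q) = z*, split bounds}.
oracle_min_total_flux <- function(model) {
  base <- oracle_fba(model)
  stopifnot(base$status == "optimal")
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  cv <- numeric(ncol(S))
  names(cv) <- colnames(S)
  cv[names(model$objective$coefficients)] <- model$objective$coefficients
  A <- rbind(cbind(S, -S), c(cv, -cv))
  b <- c(rep(0, nrow(S)), base$objective)
  plb <- pmax(lb, 0); pub <- pmax(ub, 0)
  qlb <- pmax(-ub, 0); qub <- pmax(-lb, 0)
  V <- enumerate_vertices(A, b, c(plb, qlb), c(pub, qub))
  stopifnot(!is.null(V))
  n <- ncol(S)
  totals <- rowSums(V)
  k <- which.min(totals)
  v <- V[k, seq_len(n)] - V[k, n + seq_len(n)]
  list(total = totals[k], fluxes = stats::setNames(v, colnames(S)))
}

# Producibility oracle: maximal demand flux via the lifted demand column.
oracle_producibility <- function(model, metabolite_id) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  demand <- numeric(nrow(S))
  demand[match(metabolite_id, rownames(S))] <- -1
  A <- cbind(S, demand)
  V <- enumerate_vertices(A, rep(0, nrow(A)), c(lb, 0), c(ub, 1000))
  if (is.null(V)) return(list(producible = FALSE, max_rate = 0))
  mx <- max(V[, ncol(A)])
  list(producible = mx > 1e-6, max_rate = mx)
}

# Boolean truth-table oracle for gene associations: translates the raw
# string into an R logical expression and evaluates it with eval().
oracle_evaluate_gpr <- function(raw, genes, knocked_out) {
  expr <- raw
  expr <- gsub("\\band\\b", "&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% knocked_out), envir = env)
  eval(parse(text = expr), envir = env)
}

# Random GPR expression generator for property tests.
random_gpr <- function(genes, depth = 2) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- vapply(seq_len(k), function(i) random_gpr(genes, depth - 1), "")
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}

# Objective-ready fixture set used by several suites.
fixture_models <- function() {
  list(chain = set_objective(chain_model(), "R_out"),
       branch = set_objective(branch_model(), "R_out"),
       loop = set_objective(loop_model(), "R_out"),
       demo = set_objective(demo_model(), "EX_pyr_e"))
}
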