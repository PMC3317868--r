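test_that("FBA on the chain model: optimum, fluxes, duals", {
  m <- set_objective(chain_model(), "R_out")
  res <- run_fba(m)
  expect_identical(res$status, "optimal")
  expect_equal(res$objective_value, 10)
  expect_equal(unname(res$fluxes), rep(10, 3))

  # reduced cost of the binding intake bound, against a finite-difference
  # oracle: raise ub(R_in) by 1e-3 and measure the slope
  expect_equal(unname(res$reduced_costs["R_in"]), 1, tolerance = 1e-6)
  bumped <- run_fba(set_bounds(m, "R_in", 0, 10 + 1e-3))
  slope <- (bumped$objective_value - res$objective_value) / 1e-3
  expect_equal(unname(res$reduced_costs["R_in"]), slope, tolerance = 1e-6)
})

test_that("infeasible and unbounded models return a status plus warning", {
  m <- set_objective(chain_model(), "R_out")
  m <- set_bounds(m, "R1", 12, 1000)  # 12 > max intake of 10
  expect_warning(res <- run_fba(m), "infeasible")
  expect_identical(res$status, "infeasible")
  expect_match(res$warnings, "infeasible")
  expect_null(res$fluxes)

  unb <- stoichiometric_model(
    id = "unb",
    metabolites = list(metabolite("A")),
    reactions = list(reaction("Rin", c(A = 1), 0, Inf),
                     reaction("Rout", c(A = -1), 0, Inf)),
    objective = list(coefficients = c(Rout = 1), direction = "maximize"))
  expect_warning(res <- run_fba(unb), "unbounded")
  expect_identical(res$status, "unbounded")

  expect_error(run_fba(chain_model()), "no objective")
})

test_that("mass balance and bound residuals stay within tolerance", {
  for (m in fixture_models()) {
    res <- run_fba(m)
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% res$fluxes)), 1e-6)
    lb <- vapply(m$reactions, `[[`, 0, "lower_bound")
    ub <- vapply(m$reactions, `[[`, 0, "upper_bound")
    expect_true(all(res$fluxes >= lb - 1e-6 & res$fluxes <= ub + 1e-6))
  }
})

test_that("FVA delimits the solution space and honors subsets", {
  m <- set_objective(branch_model(), "R_out")
  fva <- run_fva(m)
  expect_equal(fva$min_flux[fva$reaction == "R2"], 0, tolerance = 1e-6)
  expect_equal(fva$max_flux[fva$reaction == "R2"], 10, tolerance = 1e-6)
  expect_equal(fva$min_flux[fva$reaction == "R_out"], 10, tolerance = 1e-6)
  expect_equal(fva$max_flux[fva$reaction == "R_out"], 10, tolerance = 1e-6)

  # vertex-enumeration oracle on the same model
  ora <- oracle_fva(m)
  expect_equal(fva$min_flux, ora$min_flux[match(fva$reaction, ora$reaction)],
               tolerance = 1e-6)
  expect_equal(fva$max_flux, ora$max_flux[match(fva$reaction, ora$reaction)],
               tolerance = 1e-6)

  sub <- run_fva(m, reactions = "R2")
  expect_equal(nrow(sub), 1L)
  expect_identical(sub$reaction, "R2")
  expect_error(run_fva(m, reactions = "NOPE"), "unknown reactions")

  # suboptimal FVA widens (or keeps) every interval
  relaxed <- run_fva(m, fraction = 0.5)
  expect_true(all(relaxed$min_flux <= fva$min_flux + 1e-9))
  expect_true(all(relaxed$max_flux >= fva$max_flux - 1e-9))
})

test_that("FVA propagates infeasibility of the base problem", {
  m <- set_objective(chain_model(), "R_out")
  m <- set_bounds(m, "R1", 12, 1000)
  fva <- suppressWarnings(run_fva(m))
  expect_identical(attr(fva, "status"), "infeasible")
  expect_equal(nrow(fva), 0L)
})

test_that("flux-sum minimization removes futile cycles, keeps the optimum", {
  m <- fixture_models()$loop
  fba <- run_fba(m)
  pf <- minimize_total_flux(m)
  expect_equal(pf$objective_value, fba$objective_value, tolerance = 1e-6)
  expect_equal(unname(pf$fluxes["R4"]), 0, tolerance = 1e-6)
  expect_equal(pf$total_flux, 30, tolerance = 1e-6)
  expect_lte(pf$total_flux, sum(abs(fba$fluxes)) + 1e-9)

  # independent split-variable oracle
  ora <- oracle_min_total_flux(m)
  expect_equal(pf$total_flux, ora$total, tolerance = 1e-6)

  # unique-solution model: identical fluxes to plain FBA
  ch <- fixture_models()$chain
  pf2 <- minimize_total_flux(ch)
  expect_equal(pf2$fluxes, run_fba(ch)$fluxes, tolerance = 1e-9)
  expect_equal(pf2$total_flux, 30, tolerance = 1e-9)
})

test_that("exchange exclusion weights the minimized sum, not the bounds", {
  m <- fixture_models()$loop
  pf <- minimize_total_flux(m, exclude_exchanges = TRUE)
  expect_equal(pf$objective_value, 10, tolerance = 1e-6)
  # R_out is flagged exchange; its flux stays 10 but leaves the sum
  expect_equal(pf$total_flux, 20, tolerance = 1e-6)
})

test_that("producibility adds a demand, solves, and leaves no trace", {
  m <- chain_model()
  n_before <- length(m$reactions)
  pr <- check_producibility(m, "B")
  expect_true(pr$producible)
  expect_equal(pr$max_rate, 10, tolerance = 1e-6)
  expect_length(m$reactions, n_before)

  # a metabolite with no producing route
  md <- m
  md$metabolites[["C"]] <- metabolite("C")
  md <- add_reaction(md, reaction("R7", c(C = -1, B = 1), 0, 1000))
  pr <- check_producibility(md, "C")
  expect_false(pr$producible)
  expect_equal(pr$max_rate, 0, tolerance = 1e-9)
  expect_error(check_producibility(m, "nope"), "unknown or boundary")

  # closed exchanges shut production down entirely
  closed <- set_bounds(m, "R_in", 0, 0)
  tab <- check_all_producibility(closed)
  expect_false(any(tab$producible))
})

test_that("strong duality holds on every fixture", {
  for (m in fixture_models()) {
    res <- run_fba(m)
    x <- res$fluxes
    # b = 0, so the dual objective reduces to the reduced-cost terms of
    # the variables sitting at their active bounds
    dual_obj <- sum(res$reduced_costs * x)
    expect_equal(res$objective_value, dual_obj, tolerance = 1e-6,
                 info = m$id)
  }
})

test_that("FBA optimum agrees with pracma::linprog on the chain model", {
  skip_if_not_installed("pracma")
  m <- set_objective(chain_model(), "R_out")
  S <- stoichiometric_matrix(m)
  lb <- vapply(m$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(m$reactions, `[[`, 0, "upper_bound")
  cv <- c(0, 0, 1)
  # chain bounds are lb = 0, so the box reduces to x <= ub over x >= 0
  ref <- pracma::linprog(cv, A = diag(3), b = ub,
                         Aeq = S, beq = rep(0, nrow(S)),
                         maximize = TRUE, maxiter = 200)
  expect_equal(run_fba(m)$objective_value, ref$fval, tolerance = 1e-6)
})

test_that("solver handles minimization duals with the stated convention", {
  # minimize R_out on the chain: optimum 0, all duals consistent with
  # dz/d(bound): raising lb(R_in) forces flux, raising z
  m <- set_objective(chain_model(), "R_out", "minimize")
  m <- set_bounds(m, "R_in", 2, 10)
  res <- run_fba(m)
  expect_equal(res$objective_value, 2, tolerance = 1e-9)
  bumped <- run_fba(set_bounds(m, "R_in", 2 + 1e-3, 10))
  slope <- (bumped$objective_value - res$objective_value) / 1e-3
  expect_equal(unname(res$reduced_costs["R_in"]), slope, tolerance = 1e-6)
})
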