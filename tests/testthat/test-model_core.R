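test_that("set_bounds replaces bounds, recomputes reversibility, validates", {
  m <- set_objective(chain_model(), "R_out")
  m5 <- set_bounds(m, "R_in", 0, 5)
  expect_equal(run_fba(m5)$objective_value, 5)
  expect_false(m5$reactions$R_in$reversible)

  mr <- set_bounds(m, "R1", -10, 10)
  expect_true(mr$reactions$R1$reversible)

  expect_error(set_bounds(m, "R1", 3, 2), "lower")
  expect_error(set_bounds(m, "nope", 0, 1), "unknown reaction")
  # failed edit leaves the model unchanged
  expect_identical(m$reactions$R1$lower_bound, 0)
})

test_that("set_objective replaces the objective and checks existence", {
  m <- chain_model()
  mx <- set_objective(m, "R_out", "maximize")
  expect_equal(run_fba(mx)$objective_value, 10)
  mn <- set_objective(m, "R_out", "minimize")
  expect_equal(run_fba(mn)$objective_value, 0)
  expect_error(set_objective(m, "nonexistent"), "unknown reaction")
  # prior objective replaced, not merged
  m2 <- set_objective(mx, "R_in", "maximize")
  expect_identical(names(m2$objective$coefficients), "R_in")
})

test_that("add_exchange_reaction constructs EX_ ids with collision suffix", {
  m <- chain_model()
  m1 <- add_exchange_reaction(m, "B", -10, 0)
  expect_true("EX_B" %in% names(m1$reactions))
  expect_equal(m1$reactions$EX_B$stoichiometry, c(B = -1))
  expect_true(m1$reactions$EX_B$is_exchange)
  m2 <- add_exchange_reaction(m1, "B", 0, 5)
  expect_true("EX_B_1" %in% names(m2$reactions))
  expect_error(add_exchange_reaction(m, "nope", 0, 1), "unknown metabolite")
})

test_that("assign_compartment creates compartments on the fly", {
  m <- chain_model()
  m1 <- assign_compartment(m, "A", "mito")
  expect_true("mito" %in% names(m1$compartments))
  expect_identical(m1$metabolites$A$compartment, "mito")
  n_before <- length(m1$compartments)
  m2 <- assign_compartment(m1, "B", "mito")
  expect_equal(length(m2$compartments), n_before)
  expect_error(assign_compartment(m, "nope", "x"), "unknown entity")
})

test_that("orphan detection is bound-aware and matches the LP oracle", {
  m <- chain_model()
  orph <- find_orphan_metabolites(m)
  expect_length(orph$never_produced, 0)
  expect_length(orph$never_consumed, 0)

  # D produced by irreversible R5: B -> D, never consumed
  md <- m
  md$metabolites[["D"]] <- metabolite("D")
  md <- add_reaction(md, reaction("R5", c(B = -1, D = 1), 0, 1000))
  orph <- find_orphan_metabolites(md)
  expect_identical(orph$never_consumed, "D")
  expect_length(orph$never_produced, 0)

  # a metabolite touched only by a reversible reaction is in neither list
  mr <- m
  mr$metabolites[["E"]] <- metabolite("E")
  mr <- add_reaction(mr, reaction("R6", c(B = -1, E = 1), -1000, 1000))
  orph <- find_orphan_metabolites(mr)
  expect_false("E" %in% c(orph$never_produced, orph$never_consumed))

  # brute-force oracle on random models: maximize/minimize each
  # metabolite's net rate over box fluxes, ignoring all other balances
  for (seed in 1:5) {
    rm <- generate_random_model(6, seed = seed)
    orph <- find_orphan_metabolites(rm)
    S <- stoichiometric_matrix(rm)
    lb <- vapply(rm$reactions, `[[`, 0, "lower_bound")
    ub <- vapply(rm$reactions, `[[`, 0, "upper_bound")
    for (mid in rownames(S)) {
      row <- S[mid, ]
      max_rate <- sum(pmax(row * ub, row * lb))
      min_rate <- sum(pmin(row * ub, row * lb))
      expect_equal(mid %in% orph$never_produced, max_rate <= 1e-9,
                   info = paste(rm$id, mid))
      expect_equal(mid %in% orph$never_consumed, min_rate >= -1e-9,
                   info = paste(rm$id, mid))
    }
  }
})

test_that("synonymous reactions group exact and negated stoichiometries", {
  m <- branch_model()
  groups <- find_synonymous_reactions(m)
  expect_length(groups, 1)
  expect_setequal(groups[[1]], c("R2", "R3"))

  # reverse writing of the same conversion groups too
  m4 <- add_reaction(chain_model(), reaction("R4", c(B = -1, A = 1), 0, 10))
  groups <- find_synonymous_reactions(m4)
  expect_length(groups, 1)
  expect_setequal(groups[[1]], c("R1", "R4"))

  # scaled stoichiometry stays distinct
  m6 <- add_reaction(chain_model(), reaction("R6", c(A = -2, B = 2), 0, 10))
  expect_length(find_synonymous_reactions(m6), 0)
})

test_that("synonym grouping is a partition, invariant under reordering", {
  m <- branch_model()
  m <- add_reaction(m, reaction("R5", c(B = -1, A = 1), 0, 10))
  g1 <- find_synonymous_reactions(m)
  ids <- unlist(g1)
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(ids %in% names(m$reactions)))
  m_rev <- m
  m_rev$reactions <- rev(m_rev$reactions)
  g2 <- find_synonymous_reactions(m_rev)
  norm <- function(g) sort(vapply(g, function(x) paste(sort(x), collapse = "+"), ""))
  expect_identical(norm(g1), norm(g2))
})

test_that("metabolite_connections classifies by realized direction", {
  m <- set_objective(chain_model(), "R_out")
  conn <- metabolite_connections(m, "A")
  expect_identical(conn$producers$reaction, "R_in")
  expect_identical(conn$consumers$reaction, "R1")
  expect_error(metabolite_connections(m, "nope"), "unknown metabolite")

  res <- run_fba(m)
  conn <- metabolite_connections(m, "A", res)
  expect_equal(conn$producers$flux, 10)
  expect_equal(conn$consumers$flux, 10)

  # reversible reaction carrying negative flux flips to its realized side
  mr <- chain_model()
  mr$reactions$R1$stoichiometry <- c(A = 1, B = -1)  # written backwards
  mr <- set_bounds(mr, "R1", -1000, 1000)
  mr <- set_objective(mr, "R_out")
  res <- run_fba(mr)
  expect_equal(unname(res$fluxes["R1"]), -10)
  conn <- metabolite_connections(mr, "B", res)
  expect_true("R1" %in% conn$producers$reaction)   # coef -1, flux -10
  S <- stoichiometric_matrix(mr)
  expect_lt(max(abs(S %*% res$fluxes)), 1e-9)      # brute-force mass balance
})

test_that("batch commands apply in order and stop on error", {
  m <- chain_model()
  res <- apply_batch_commands(m, c("set_bound R_in upper 5",
                                   "set_objective R_out max"))
  expect_true(res$ok)
  expect_equal(run_fba(res$model)$objective_value, 5)

  bad <- apply_batch_commands(m, "set_bound NOPE upper 5")
  expect_false(bad$ok)
  expect_equal(bad$log$line, 1)
  expect_match(bad$log$message, "unknown reaction")
  expect_true(isTRUE(models_canonically_equal(bad$model, m)))

  expect_error(apply_batch_commands(m, character(0)), "empty")

  # partial effects persist when a later line fails
  partial <- apply_batch_commands(m, c("set_bound R_in upper 5",
                                       "rename MISSING x"))
  expect_false(partial$ok)
  expect_equal(partial$model$reactions$R_in$upper_bound, 5)
  expect_equal(partial$log$line[nrow(partial$log)], 2)
})

test_that("batch application is compositional and comment-aware", {
  s1 <- c("# tighten the intake", "set_bound R_in upper 7")
  s2 <- c("add_exchange A -5 0", "set_objective R_out max")
  m <- chain_model()
  joint <- apply_batch_commands(m, c(s1, s2))
  stepwise <- apply_batch_commands(
    apply_batch_commands(m, s1)$model, s2)
  expect_true(joint$ok && stepwise$ok)
  expect_true(isTRUE(models_canonically_equal(joint$model, stepwise$model)))
})

test_that("all batch verbs round through the editing operations", {
  m <- chain_model()
  script <- c("add_reaction R9 A:-1,B:1 0 50",
              "set_compartment A mito",
              "rename R9 R9b",
              "delete_reaction R9b",
              "set_bound R1 both -5 5")
  res <- apply_batch_commands(m, script)
  expect_true(res$ok)
  expect_false("R9b" %in% names(res$model$reactions))
  expect_identical(res$model$metabolites$A$compartment, "mito")
  expect_true(res$model$reactions$R1$reversible)
  bad <- apply_batch_commands(m, "frobnicate x y")
  expect_false(bad$ok)
  expect_match(bad$log$message, "unknown batch verb")
  validate_model(res$model)
})

test_that("model invariants survive every editing operation", {
  m <- set_objective(demo_model(), "EX_pyr_e")
  m <- set_bounds(m, "PGI", -500, 500)
  m <- add_exchange_reaction(m, "pyr_c", 0, 3)
  m <- assign_compartment(m, "pyr_c", "peroxisome")
  m <- rename_entity(m, "PYK", "PYK_renamed")
  m <- delete_reaction(m, "TPI")
  expect_silent(validate_model(m))
  expect_true("PYK_renamed" %in% names(m$objective$coefficients) ||
              "EX_pyr_e" %in% names(m$objective$coefficients))
  # renaming a metabolite rewrites stoichiometry references
  m <- rename_entity(m, "pyr_c", "pyruvate_c")
  expect_silent(validate_model(m))
  expect_true("pyruvate_c" %in% names(m$reactions$PYK_renamed$stoichiometry))
})
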