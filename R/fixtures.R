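# Built-in fixture models. The demo model is a small glycolysis-style
# network (deterministic content); chain/branch/loop models are the minimal
# networks used throughout the documentation and tests; the random-model
# generator produces seeded small networks for oracle comparisons and
# larger ones for scale checks.

#' Three-reaction linear chain model
#'
#' `R_in: -> A` (bounds 0..10), `R1: A -> B`, `R_out: B ->`. Maximizing
#' `R_out` gives objective 10 with all fluxes 10.
#'
#' @return A `stoichiometric_model` without an objective.
#' @export
chain_model <- function() {
  stoichiometric_model(
    id = "M_chain", name = "linear chain",
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("R_in", c(A = 1), 0, 10, name = "intake"),
      reaction("R1", c(A = -1, B = 1), 0, 1000),
      reaction("R_out", c(B = -1), 0, 1000, name = "outflow",
               is_exchange = TRUE)))
}

#' Parallel-branch model
#'
#' The chain model with two parallel `A -> B` routes (`R2`, `R3`) instead
#' of one; the branch split is undetermined at the FBA optimum, which FVA
#' reveals as a `(0, 10)` range on each branch.
#'
#' @return A `stoichiometric_model` without an objective.
#' @export
branch_model <- function() {
  stoichiometric_model(
    id = "M_branch", name = "parallel branches",
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("R_in", c(A = 1), 0, 10, name = "intake"),
      reaction("R2", c(A = -1, B = 1), 0, 1000),
      reaction("R3", c(A = -1, B = 1), 0, 1000),
      reaction("R_out", c(B = -1), 0, 1000, name = "outflow",
               is_exchange = TRUE)))
}

#' Futile-cycle model
#'
#' The chain model plus an irreversible pair `R2: A -> B`, `R4: B -> A`
#' (both with upper bound 1000). Plain FBA may put any amount of flux
#' through the cycle; flux-sum minimization drives `R4` to zero.
#'
#' @return A `stoichiometric_model` without an objective.
#' @export
loop_model <- function() {
  stoichiometric_model(
    id = "M_loop", name = "futile cycle",
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("R_in", c(A = 1), 0, 10, name = "intake"),
      reaction("R1", c(A = -1, B = 1), 0, 1000),
      reaction("R2", c(A = -1, B = 1), 0, 1000),
      reaction("R4", c(B = -1, A = 1), 0, 1000),
      reaction("R_out", c(B = -1), 0, 1000, name = "outflow",
               is_exchange = TRUE)))
}

#' Glycolysis-style demo model
#'
#' A deterministic toy network emulating upper and lower glycolysis:
#' glucose exchange with uptake bound 10, a transport step, ten internal
#' reactions over two subsystems (Transport, Glycolysis), the PFK/FBPase
#' futile-cycle pair, gene associations on several enzymes and KEGG
#' compound ids on key metabolites. The objective is deliberately unset;
#' the intended workflow is `set_objective(demo_model(), "EX_pyr_e")`,
#' after which FBA yields 20 (two pyruvate per glucose at uptake 10).
#'
#' @return A `stoichiometric_model` without an objective.
#' @export
demo_model <- function() {
  mets <- list(
    metabolite("glc_e", "glucose (extracellular)", "e", kegg_id = "C00031"),
    metabolite("glc_c", "glucose", "c", kegg_id = "C00031"),
    metabolite("g6p_c", "glucose 6-phosphate", "c", kegg_id = "C00668"),
    metabolite("f6p_c", "fructose 6-phosphate", "c", kegg_id = "C00085"),
    metabolite("fbp_c", "fructose 1,6-bisphosphate", "c"),
    metabolite("dhap_c", "dihydroxyacetone phosphate", "c"),
    metabolite("g3p_c", "glyceraldehyde 3-phosphate", "c"),
    metabolite("pep_c", "phosphoenolpyruvate", "c"),
    metabolite("pyr_c", "pyruvate", "c", kegg_id = "C00022"),
    metabolite("pyr_e", "pyruvate (extracellular)", "e", kegg_id = "C00022"))
  rxns <- list(
    reaction("EX_glc_e", c(glc_e = -1), -10, 0, name = "glucose exchange",
             is_exchange = TRUE, pathways = "Transport"),
    reaction("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000,
             name = "glucose transport", gene_association = "g_glt1",
             pathways = "Transport"),
    reaction("HEX1", c(glc_c = -1, g6p_c = 1), 0, 1000,
             name = "hexokinase", gene_association = "g_hk1 or g_hk2",
             ec_numbers = "2.7.1.1", kegg_id = "R00299",
             pathways = "Glycolysis"),
    reaction("PGI", c(g6p_c = -1, f6p_c = 1), -1000, 1000,
             name = "glucose-6-phosphate isomerase",
             gene_association = "g_pgi1", ec_numbers = "5.3.1.9",
             kegg_id = "R00771", pathways = "Glycolysis"),
    reaction("PFK", c(f6p_c = -1, fbp_c = 1), 0, 1000,
             name = "phosphofructokinase",
             gene_association = "g_pfk1 and g_pfk2",
             ec_numbers = "2.7.1.11", kegg_id = "R00756",
             pathways = "Glycolysis"),
    reaction("FBP", c(fbp_c = -1, f6p_c = 1), 0, 1000,
             name = "fructose bisphosphatase", gene_association = "g_fbp1",
             ec_numbers = "3.1.3.11", pathways = "Glycolysis"),
    reaction("FBA", c(fbp_c = -1, dhap_c = 1, g3p_c = 1), 0, 1000,
             name = "fructose-bisphosphate aldolase",
             ec_numbers = "4.1.2.13", pathways = "Glycolysis"),
    reaction("TPI", c(dhap_c = -1, g3p_c = 1), -1000, 1000,
             name = "triose-phosphate isomerase", ec_numbers = "5.3.1.1",
             pathways = "Glycolysis"),
    reaction("GLYC_L", c(g3p_c = -1, pep_c = 1), 0, 1000,
             name = "lower glycolysis (lumped)", pathways = "Glycolysis"),
    reaction("PYK", c(pep_c = -1, pyr_c = 1), 0, 1000,
             name = "pyruvate kinase", gene_association = "g_pyk1",
             ec_numbers = "2.7.1.40", kegg_id = "R00200",
             pathways = "Glycolysis"),
    reaction("PYRt", c(pyr_c = -1, pyr_e = 1), 0, 1000,
             name = "pyruvate transport", pathways = "Transport"),
    reaction("EX_pyr_e", c(pyr_e = -1), 0, 1000, name = "pyruvate exchange",
             is_exchange = TRUE, pathways = "Transport"))
  stoichiometric_model(
    id = "demo_glycolysis", name = "glycolysis demo",
    metabolites = mets, reactions = rxns,
    compartments = c(c = "cytosol", e = "extracellular"))
}

#' Generate a seeded random stoichiometric model
#'
#' Builds a connected network with all bounds finite: a backbone chain
#' `M1 -> M2 -> ... -> Mk` of unit conversions, an intake exchange on `M1`,
#' an outflow exchange on `Mk`, and additional random reactions linking
#' randomly chosen metabolite pairs (some reversible). The zero flux vector
#' is always feasible (every bound interval contains 0), the objective
#' maximizes the outflow exchange, and identical seeds give identical
#' models. Small instances (a handful of reactions) are sized for
#' exhaustive vertex-enumeration cross-checks; large `n_reactions` gives a
#' scale-test network.
#'
#' @param n_reactions Total number of reactions, at least 2.
#' @param seed Integer seed; fully determines the model.
#' @return A `stoichiometric_model` with a maximization objective on its
#'   outflow exchange.
#' @export
generate_random_model <- function(n_reactions, seed = 1L) {
  if (n_reactions < 2L) stop("n_reactions must be at least 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_internal <- n_reactions - 2L  # two slots reserved for the exchanges
  n_mets <- max(2L, min(n_internal + 1L, ceiling(n_reactions * 0.5)))
  mids <- sprintf("M%d", seq_len(n_mets))
  mets <- lapply(mids, metabolite)

  rxns <- list()
  cap <- function() sample(5:20, 1)
  # backbone chain keeps the network connected
  n_chain <- min(n_internal, n_mets - 1L)
  for (i in seq_len(n_chain)) {
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("R%d", i),
      stats::setNames(c(-1, 1), c(mids[i], mids[i + 1L])),
      lower_bound = if (stats::runif(1) < 0.3) -cap() else 0,
      upper_bound = cap())
  }
  # extra random links
  k <- length(rxns)
  while (length(rxns) < n_internal) {
    k <- k + 1L
    pair <- sample(n_mets, 2L)
    coefs <- sample(1:2, 2L, replace = TRUE)
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("R%d", k),
      stats::setNames(c(-coefs[1], coefs[2]), mids[pair]),
      lower_bound = if (stats::runif(1) < 0.4) -cap() else 0,
      upper_bound = cap())
  }
  rxns[[length(rxns) + 1L]] <- reaction(
    "EX_in", stats::setNames(-1, mids[1]), -10, 0, is_exchange = TRUE)
  rxns[[length(rxns) + 1L]] <- reaction(
    "EX_out", stats::setNames(-1, mids[n_mets]), 0, 10, is_exchange = TRUE)

  stoichiometric_model(
    id = sprintf("random_%d_%d", n_reactions, seed),
    metabolites = mets, reactions = rxns,
    objective = list(coefficients = c(EX_out = 1), direction = "maximize"),
    provenance = list(dialect = "constructed",
                      notes = sprintf("seed=%d", seed)))
}

# save/restore the RNG state so generators do not disturb user code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
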