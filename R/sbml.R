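# SBML input/output in three dialects:
#   L2_NOTES - SBML Level 2 with COBRA-style key:value lines in reaction
#              notes (LOWER_BOUND, UPPER_BOUND, OBJECTIVE_COEFFICIENT,
#              GENE_ASSOCIATION, SUBSYSTEM, PROTEIN_CLASS, ...)
#   L3_FBC   - SBML Level 3 with the Flux Balance Constraints package (v2)
#   PLAIN    - bare stoichiometry; constraints are synthesized on import so
#              the result is always a runnable constraint-based model
# Reading is prefix-robust (XPath on local-name()); writing is deterministic
# text generation validated by the round-trip tests.

SBML_L2_NS <- "http://www.sbml.org/sbml/level2/version4"
SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

NOTE_KEYS <- c("LOWER_BOUND", "UPPER_BOUND", "OBJECTIVE_COEFFICIENT",
               "FLUX_VALUE", "GENE_ASSOCIATION", "SUBSYSTEM",
               "PROTEIN_CLASS")

#' Detect the SBML dialect of a document
#'
#' `L3_FBC` when the Flux Balance Constraints namespace is declared and
#' used; otherwise `L2_NOTES` when any reaction note carries a recognized
#' COBRA-style keyword; otherwise `PLAIN`. Detection is deterministic for a
#' given byte stream.
#'
#' @param input File path or a literal XML string.
#' @return One of `"L3_FBC"`, `"L2_NOTES"`, `"PLAIN"`.
#' @export
detect_dialect <- function(input) {
  doc <- xml2::read_xml(input)
  detect_dialect_doc(doc)
}

detect_dialect_doc <- function(doc) {
  ns <- tryCatch(xml2::xml_ns(doc), error = function(e) character())
  fbc_declared <- any(grepl("fbc", unlist(as.list(ns)), fixed = TRUE))
  if (fbc_declared) {
    fbc_elems <- xml2::xml_find_first(
      doc, "//*[contains(namespace-uri(), 'fbc')]")
    fbc_attr <- FALSE
    for (node in xml2::xml_find_all(doc, "//*[local-name()='reaction' or local-name()='model' or local-name()='sbml']")) {
      if (any(grepl("(lowerFluxBound|upperFluxBound|strict|required)",
                    names(xml2::xml_attrs(node))))) {
        fbc_attr <- TRUE
        break
      }
    }
    if (!inherits(fbc_elems, "xml_missing") || fbc_attr) return("L3_FBC")
  }
  notes <- xml2::xml_find_all(
    doc, "//*[local-name()='reaction']/*[local-name()='notes']")
  pat <- paste0("(", paste(c(NOTE_KEYS, "GENE ASSOCIATION"), collapse = "|"),
                ")")
  for (nt in notes) {
    if (grepl(pat, xml2::xml_text(nt), ignore.case = TRUE))
      return("L2_NOTES")
  }
  "PLAIN"
}

# --- reading -----------------------------------------------------------

#' Read an SBML model
#'
#' Accepts all three dialects. PLAIN input is auto-constrained: reversible
#' reactions get bounds `(-1000, 1000)`, irreversible `(0, 1000)`, and no
#' objective is set (analyses refuse to run until the user sets one).
#' Note-encoded gene associations, EC numbers, subsystems and KEGG ids are
#' harvested into the model; unrecognized note lines are preserved verbatim
#' in the annotations.
#'
#' @param input File path or literal XML string.
#' @return A `stoichiometric_model` whose `provenance$dialect` records the
#'   detected dialect.
#' @export
read_sbml <- function(input) {
  doc <- xml2::read_xml(input)
  dialect <- detect_dialect_doc(doc)
  mnode <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(mnode, "xml_missing")) stop("no <model> element found")
  model_id <- attr_any(mnode, "id", "imported_model")
  model_name <- attr_any(mnode, "name", model_id)

  comp_nodes <- xml2::xml_find_all(
    mnode, "./*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  compartments <- character()
  for (cn in comp_nodes) {
    cid <- attr_any(cn, "id")
    compartments[cid] <- attr_any(cn, "name", cid)
  }
  if (length(compartments) == 0L) compartments <- c(c = "c")

  sp_nodes <- xml2::xml_find_all(
    mnode, "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  metabolites <- list()
  for (sn in sp_nodes) {
    sid <- attr_any(sn, "id")
    notes <- parse_notes(sn)
    comp <- attr_any(sn, "compartment", names(compartments)[1])
    if (!comp %in% names(compartments)) compartments[comp] <- comp
    ann <- list()
    if (length(notes$other)) ann$notes <- notes$other
    metabolites[[sid]] <- metabolite(
      id = sid, name = attr_any(sn, "name", sid), compartment = comp,
      boundary = identical(attr_any(sn, "boundaryCondition", "false"), "true"),
      kegg_id = notes$kegg_id, annotations = ann)
  }

  # FBC support tables
  params <- list()
  for (pn in xml2::xml_find_all(
    mnode, "./*[local-name()='listOfParameters']/*[local-name()='parameter']")) {
    params[[attr_any(pn, "id")]] <- parse_num(attr_any(pn, "value", "0"))
  }
  gene_labels <- list()
  for (gp in xml2::xml_find_all(
    mnode, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")) {
    gid <- attr_any(gp, "id")
    gene_labels[[gid]] <- attr_any(gp, "label", sub("^G_", "", gid))
  }

  rx_nodes <- xml2::xml_find_all(
    mnode, "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("model declares no reactions")
  reactions <- list()
  obj_coef <- numeric()
  undeclared <- character()
  for (rn in rx_nodes) {
    rid <- attr_any(rn, "id")
    rev_attr <- attr_any(rn, "reversible", "true")  # SBML default is true
    reversible <- identical(rev_attr, "true")
    st <- numeric()
    for (sr in xml2::xml_find_all(
      rn, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      sp <- attr_any(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) -
        parse_num(attr_any(sr, "stoichiometry", "1"))
    }
    for (sr in xml2::xml_find_all(
      rn, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      sp <- attr_any(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) +
        parse_num(attr_any(sr, "stoichiometry", "1"))
    }
    undeclared <- c(undeclared, setdiff(names(st), names(metabolites)))

    notes <- parse_notes(rn)
    default_lb <- if (reversible) -1000 else 0
    lb <- default_lb
    ub <- 1000
    if (dialect == "L3_FBC") {
      lb_ref <- attr_any(rn, "lowerFluxBound")
      ub_ref <- attr_any(rn, "upperFluxBound")
      if (!is.null(lb_ref) && !is.null(params[[lb_ref]])) lb <- params[[lb_ref]]
      if (!is.null(ub_ref) && !is.null(params[[ub_ref]])) ub <- params[[ub_ref]]
    } else if (dialect == "L2_NOTES") {
      if (!is.null(notes$lower_bound)) lb <- notes$lower_bound
      if (!is.null(notes$upper_bound)) ub <- notes$upper_bound
    }
    if (lb > ub) {
      warning("reaction '", rid, "': imported bounds reversed (", lb, " > ",
              ub, "); swapping", call. = FALSE)
      tmp <- lb; lb <- ub; ub <- tmp
    }

    gpr <- notes$gene_association
    if (is.null(gpr)) {
      ga_node <- xml2::xml_find_first(
        rn, "./*[local-name()='geneProductAssociation']")
      if (!inherits(ga_node, "xml_missing")) {
        child <- xml2::xml_find_first(ga_node, "./*")
        if (!inherits(child, "xml_missing"))
          gpr <- fbc_association_string(child, gene_labels)
      }
    }
    if (!is.null(notes$objective_coefficient) &&
        notes$objective_coefficient != 0)
      obj_coef[rid] <- notes$objective_coefficient

    ann <- list()
    if (length(notes$other)) ann$notes <- notes$other
    if (!is.null(notes$flux_value)) ann$flux_value <- notes$flux_value
    reactions[[rid]] <- reaction(
      id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub,
      name = attr_any(rn, "name", rid), gene_association = gpr,
      ec_numbers = notes$ec_numbers, kegg_id = notes$kegg_id,
      pathways = notes$pathways,
      is_exchange = length(st) == 1L || grepl("^EX_", rid),
      annotations = ann)
    reactions[[rid]]$reversible <- reversible  # imported flag kept as-is
  }
  if (length(undeclared))
    stop("reactions reference undeclared species: ",
         paste(unique(undeclared), collapse = ", "))

  objective <- NULL
  if (dialect == "L3_FBC") {
    objective <- read_fbc_objective(mnode)
  } else if (length(obj_coef)) {
    dir <- "maximize"
    mn <- parse_notes(mnode)
    if (!is.null(mn$objective_direction) &&
        grepl("^min", mn$objective_direction, ignore.case = TRUE))
      dir <- "minimize"
    objective <- list(coefficients = obj_coef, direction = dir)
  }

  stoichiometric_model(id = model_id, name = model_name,
                       metabolites = metabolites, reactions = reactions,
                       compartments = compartments, objective = objective,
                       provenance = list(dialect = dialect))
}

read_fbc_objective <- function(mnode) {
  lo <- xml2::xml_find_first(mnode, "./*[local-name()='listOfObjectives']")
  if (inherits(lo, "xml_missing")) return(NULL)
  active <- attr_any(lo, "activeObjective")
  objs <- xml2::xml_find_all(lo, "./*[local-name()='objective']")
  if (length(objs) == 0L) return(NULL)
  pick <- objs[[1]]
  if (!is.null(active)) {
    for (o in objs) if (identical(attr_any(o, "id"), active)) pick <- o
  }
  coef <- numeric()
  for (fo in xml2::xml_find_all(
    pick, ".//*[local-name()='fluxObjective']")) {
    coef[attr_any(fo, "reaction")] <- parse_num(attr_any(fo, "coefficient", "1"))
  }
  if (length(coef) == 0L) return(NULL)
  dir <- attr_any(pick, "type", "maximize")
  list(coefficients = coef,
       direction = if (grepl("^min", dir)) "minimize" else "maximize")
}

fbc_association_string <- function(node, gene_labels) {
  ln <- xml2::xml_name(node)
  if (ln == "geneProductRef") {
    ref <- attr_any(node, "geneProduct")
    lbl <- gene_labels[[ref]]
    return(if (is.null(lbl)) sub("^G_", "", ref) else lbl)
  }
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, fbc_association_string, "",
                  gene_labels = gene_labels)
  op <- if (ln == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

# Harvest key:value note lines; unrecognized lines are preserved verbatim.
parse_notes <- function(node) {
  out <- list(ec_numbers = character(), pathways = character(),
              other = character())
  nt <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(nt, "xml_missing")) return(out)
  ps <- xml2::xml_find_all(nt, ".//*[local-name()='p']")
  lines <- if (length(ps)) xml2::xml_text(ps) else
    strsplit(xml2::xml_text(nt), "\n", fixed = TRUE)[[1]]
  for (line in trimws(lines)) {
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^([A-Za-z_ ]+?)[[:space:]]*:[[:space:]]*(.*)$",
                                  line))[[1]]
    if (length(m) != 3L) {
      out$other <- c(out$other, line)
      next
    }
    key <- gsub(" ", "_", toupper(trimws(m[2])))
    val <- trimws(m[3])
    switch(key,
      LOWER_BOUND = { out$lower_bound <- parse_num(val) },
      UPPER_BOUND = { out$upper_bound <- parse_num(val) },
      OBJECTIVE_COEFFICIENT = { out$objective_coefficient <- parse_num(val) },
      OBJECTIVE_DIRECTION = { out$objective_direction <- val },
      FLUX_VALUE = { out$flux_value <- parse_num(val) },
      GENE_ASSOCIATION = { if (nzchar(val)) out$gene_association <- val },
      SUBSYSTEM = { if (nzchar(val)) out$pathways <- c(out$pathways, val) },
      PROTEIN_CLASS = {
        if (nzchar(val))
          out$ec_numbers <- c(out$ec_numbers,
                              strsplit(val, "[,;[:space:]]+")[[1]])
      },
      KEGG_ID = { if (nzchar(val)) out$kegg_id <- val },
      { out$other <- c(out$other, line) }
    )
  }
  out
}

attr_any <- function(node, name, default = NULL) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit)) unname(at[hit[1]]) else default
}

parse_num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    lx <- tolower(trimws(x))
    if (lx %in% c("inf", "+inf", "infinity")) return(Inf)
    if (lx %in% c("-inf", "-infinity")) return(-Inf)
    stop("not a number: '", x, "'")
  }
  v
}

# --- writing -----------------------------------------------------------

#' Write a model as SBML
#'
#' Emits either the Level 2 notes dialect or Level 3 with the Flux Balance
#' Constraints package. Everything the dialect can represent is written:
#' stoichiometry, bounds, objective, gene associations (as notes in both
#' dialects, plus FBC gene-product associations in L3), subsystems, EC
#' numbers and KEGG ids. `read_sbml(write_sbml(m))` is canonically equal
#' to `m`.
#'
#' @param model A `stoichiometric_model`.
#' @param dialect `"L3_FBC"` (default) or `"L2_NOTES"`.
#' @param path Optional output file; when `NULL` the XML text is returned.
#' @return The XML document as a single string, invisibly when `path` is
#'   given.
#' @export
write_sbml <- function(model, dialect = c("L3_FBC", "L2_NOTES"),
                       path = NULL) {
  dialect <- match.arg(dialect)
  validate_model(model)
  xml <- paste(if (dialect == "L3_FBC") sbml_l3_text(model) else
                 sbml_l2_text(model),
               collapse = "\n")
  if (!is.null(path)) {
    writeLines(xml, path, useBytes = TRUE)
    return(invisible(xml))
  }
  xml
}

xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

fmt_num <- function(x) sprintf("%.15g", x)

notes_block <- function(lines, indent) {
  if (length(lines) == 0L) return(character())
  pad <- strrep(" ", indent)
  c(paste0(pad, "<notes>"),
    paste0(pad, "  <body xmlns=\"http://www.w3.org/1999/xhtml\">"),
    paste0(pad, "    <p>", xesc(lines), "</p>"),
    paste0(pad, "  </body>"),
    paste0(pad, "</notes>"))
}

reaction_note_lines <- function(r, model, include_bounds) {
  lines <- character()
  if (include_bounds) {
    lines <- c(lines, paste0("LOWER_BOUND: ", fmt_num(r$lower_bound)),
               paste0("UPPER_BOUND: ", fmt_num(r$upper_bound)))
    oc <- model$objective$coefficients
    if (r$id %in% names(oc))
      lines <- c(lines,
                 paste0("OBJECTIVE_COEFFICIENT: ", fmt_num(oc[[r$id]])))
  }
  if (!is.null(r$gene_association) && nzchar(r$gene_association))
    lines <- c(lines, paste0("GENE_ASSOCIATION: ", r$gene_association))
  for (p in r$pathways) lines <- c(lines, paste0("SUBSYSTEM: ", p))
  for (ec in r$ec_numbers) lines <- c(lines, paste0("PROTEIN_CLASS: ", ec))
  if (!is.null(r$kegg_id)) lines <- c(lines, paste0("KEGG ID: ", r$kegg_id))
  c(lines, r$annotations$notes)
}

species_lines <- function(model, constant_attr) {
  out <- character()
  for (m in model$metabolites) {
    attrs <- paste0("id=\"", xesc(m$id), "\" name=\"", xesc(m$name),
                    "\" compartment=\"", xesc(m$compartment), "\"",
                    if (m$boundary) " boundaryCondition=\"true\"" else
                      " boundaryCondition=\"false\"",
                    constant_attr)
    lines <- character()
    if (!is.null(m$kegg_id)) lines <- c(lines, paste0("KEGG ID: ", m$kegg_id))
    lines <- c(lines, m$annotations$notes)
    if (length(lines)) {
      out <- c(out, paste0("      <species ", attrs, ">"),
               notes_block(lines, 8), "      </species>")
    } else {
      out <- c(out, paste0("      <species ", attrs, "/>"))
    }
  }
  out
}

species_ref_lines <- function(st) {
  out <- character()
  sub <- st[st < 0]
  prod <- st[st > 0]
  if (length(sub)) {
    out <- c(out, "        <listOfReactants>",
             sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\"%s/>",
                     xesc(names(sub)), fmt_num(-unname(sub)),
                     " constant=\"true\""),
             "        </listOfReactants>")
  }
  if (length(prod)) {
    out <- c(out, "        <listOfProducts>",
             sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\"%s/>",
                     xesc(names(prod)), fmt_num(unname(prod)),
                     " constant=\"true\""),
             "        </listOfProducts>")
  }
  out
}

sbml_l2_text <- function(model) {
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<sbml xmlns=\"", SBML_L2_NS,
                  "\" level=\"2\" version=\"4\">"),
           paste0("  <model id=\"", xesc(model$id), "\" name=\"",
                  xesc(model$name), "\">"))
  if (length(model$objective$coefficients))
    out <- c(out, notes_block(paste0("OBJECTIVE_DIRECTION: ",
                                     model$objective$direction), 4))
  out <- c(out, "    <listOfCompartments>",
           sprintf("      <compartment id=\"%s\" name=\"%s\" size=\"1\"/>",
                   xesc(names(model$compartments)),
                   xesc(unname(model$compartments))),
           "    </listOfCompartments>",
           "    <listOfSpecies>",
           species_lines(model, ""),
           "    </listOfSpecies>",
           "    <listOfReactions>")
  for (r in model$reactions) {
    out <- c(out,
             sprintf("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\">",
                     xesc(r$id), xesc(r$name),
                     if (r$reversible) "true" else "false"),
             notes_block(reaction_note_lines(r, model, TRUE), 8),
             species_ref_lines_l2(r$stoichiometry),
             "      </reaction>")
  }
  c(out, "    </listOfReactions>", "  </model>", "</sbml>")
}

species_ref_lines_l2 <- function(st) {
  out <- character()
  sub <- st[st < 0]
  prod <- st[st > 0]
  if (length(sub)) {
    out <- c(out, "        <listOfReactants>",
             sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\"/>",
                     xesc(names(sub)), fmt_num(-unname(sub))),
             "        </listOfReactants>")
  }
  if (length(prod)) {
    out <- c(out, "        <listOfProducts>",
             sprintf("          <speciesReference species=\"%s\" stoichiometry=\"%s\"/>",
                     xesc(names(prod)), fmt_num(unname(prod))),
             "        </listOfProducts>")
  }
  out
}

sanitize_gene_id <- function(gene) {
  paste0("G_", gsub("[^A-Za-z0-9_]", "_", gene))
}

fbc_association_xml <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (node$op == "gene")
    return(paste0(pad, "<fbc:geneProductRef fbc:geneProduct=\"",
                  xesc(sanitize_gene_id(node$gene)), "\"/>"))
  tag <- paste0("fbc:", node$op)
  c(paste0(pad, "<", tag, ">"),
    unlist(lapply(node$children, fbc_association_xml, indent = indent + 2)),
    paste0(pad, "</", tag, ">"))
}

sbml_l3_text <- function(model) {
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<sbml xmlns=\"", SBML_L3_NS, "\" xmlns:fbc=\"", FBC_NS,
                  "\" level=\"3\" version=\"1\" fbc:required=\"false\">"),
           paste0("  <model id=\"", xesc(model$id), "\" name=\"",
                  xesc(model$name), "\" fbc:strict=\"false\">"))
  out <- c(out, "    <listOfCompartments>",
           sprintf("      <compartment id=\"%s\" name=\"%s\" constant=\"true\"/>",
                   xesc(names(model$compartments)),
                   xesc(unname(model$compartments))),
           "    </listOfCompartments>",
           "    <listOfSpecies>",
           species_lines(model,
                         " hasOnlySubstanceUnits=\"false\" constant=\"false\""),
           "    </listOfSpecies>")

  # flux-bound parameters, one pair per reaction
  out <- c(out, "    <listOfParameters>")
  rids <- names(model$reactions)
  for (i in seq_along(rids)) {
    r <- model$reactions[[i]]
    out <- c(out,
             sprintf("      <parameter id=\"bnd_%d_lb\" value=\"%s\" constant=\"true\"/>",
                     i, fmt_num(r$lower_bound)),
             sprintf("      <parameter id=\"bnd_%d_ub\" value=\"%s\" constant=\"true\"/>",
                     i, fmt_num(r$upper_bound)))
  }
  out <- c(out, "    </listOfParameters>")

  genes <- list_genes(model)
  if (length(genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf("      <fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\"/>",
                     xesc(vapply(genes, sanitize_gene_id, "")), xesc(genes)),
             "    </fbc:listOfGeneProducts>")
  }

  out <- c(out, "    <listOfReactions>")
  for (i in seq_along(rids)) {
    r <- model$reactions[[i]]
    out <- c(out,
             sprintf(paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\"",
                            " fast=\"false\" fbc:lowerFluxBound=\"bnd_%d_lb\"",
                            " fbc:upperFluxBound=\"bnd_%d_ub\">"),
                     xesc(r$id), xesc(r$name),
                     if (r$reversible) "true" else "false", i, i),
             notes_block(reaction_note_lines(r, model, FALSE), 8))
    expr <- parse_association_or_null(r$gene_association)
    if (!is.null(expr)) {
      out <- c(out, "        <fbc:geneProductAssociation>",
               fbc_association_xml(unclass(expr), 10),
               "        </fbc:geneProductAssociation>")
    }
    out <- c(out, species_ref_lines(r$stoichiometry), "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")

  oc <- model$objective$coefficients
  if (length(oc)) {
    out <- c(out,
             "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
             sprintf("      <fbc:objective fbc:id=\"obj\" fbc:type=\"%s\">",
                     model$objective$direction),
             "        <fbc:listOfFluxObjectives>",
             sprintf("          <fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"%s\"/>",
                     xesc(names(oc)), fmt_num(unname(oc))),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>")
  }
  c(out, "  </model>", "</sbml>")
}

# --- canonical comparison (round-trip oracle support) ------------------

#' Canonical equality of two models
#'
#' Compares metabolite and reaction id sets, stoichiometry maps, bounds
#' (within `tol`), boundary flags, objective, and gene associations (by
#' parsed tree when parseable, raw string otherwise). Annotation ordering
#' and provenance are ignored.
#'
#' @param a,b Models to compare.
#' @param tol Numeric tolerance on bounds and coefficients.
#' @return `TRUE` or a character vector describing the differences.
#' @export
models_canonically_equal <- function(a, b, tol = 1e-9) {
  diffs <- character()
  if (!setequal(names(a$metabolites), names(b$metabolites)))
    diffs <- c(diffs, "metabolite id sets differ")
  if (!setequal(names(a$reactions), names(b$reactions)))
    diffs <- c(diffs, "reaction id sets differ")
  if (length(diffs)) return(diffs)
  for (id in names(a$metabolites)) {
    ma <- a$metabolites[[id]]; mb <- b$metabolites[[id]]
    if (ma$boundary != mb$boundary)
      diffs <- c(diffs, paste0("boundary flag differs: ", id))
    if (!identical(ma$kegg_id, mb$kegg_id))
      diffs <- c(diffs, paste0("kegg id differs: ", id))
  }
  for (id in names(a$reactions)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    sa <- ra$stoichiometry[order(names(ra$stoichiometry))]
    sb <- rb$stoichiometry[order(names(rb$stoichiometry))]
    if (!identical(names(sa), names(sb)) || any(abs(sa - sb) > tol))
      diffs <- c(diffs, paste0("stoichiometry differs: ", id))
    if (abs(ra$lower_bound - rb$lower_bound) > tol ||
        abs(ra$upper_bound - rb$upper_bound) > tol)
      diffs <- c(diffs, paste0("bounds differ: ", id))
    ga <- canonical_gpr(ra$gene_association)
    gb <- canonical_gpr(rb$gene_association)
    if (!identical(ga, gb))
      diffs <- c(diffs, paste0("gene association differs: ", id))
  }
  oa <- a$objective; ob <- b$objective
  ka <- names(oa$coefficients)[order(names(oa$coefficients))]
  kb <- names(ob$coefficients)[order(names(ob$coefficients))]
  if (!identical(ka, kb) ||
      (length(ka) && any(abs(oa$coefficients[ka] - ob$coefficients[ka]) > tol)))
    diffs <- c(diffs, "objective coefficients differ")
  if (length(oa$coefficients) && oa$direction != ob$direction)
    diffs <- c(diffs, "objective direction differs")
  if (length(diffs)) diffs else TRUE
}

canonical_gpr <- function(raw) {
  if (is.null(raw) || !nzchar(trimws(raw))) return(NULL)
  expr <- parse_association_or_null(raw)
  if (is.null(expr)) return(trimws(raw))
  format_gene_association(expr)
}
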