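# Boolean gene-protein-reaction (GPR) associations: parsing, evaluation,
# and knockout simulation. Grammar: identifiers, case-insensitive "and" /
# "or" keywords, parentheses; "and" binds tighter than "or".

#' Parse a gene-association string
#'
#' Accepts the COBRA-era notes dialect: gene identifiers combined with
#' case-insensitive `and` / `or` and parentheses, `and` binding tighter.
#' Whitespace is insignificant. The result is an expression tree of leaf /
#' AND / OR nodes that round-trips to a canonical fully parenthesized
#' string via [format_gene_association()].
#'
#' @param raw Non-empty association string, e.g. `"(g1 and g2) or g3"`.
#' @return A `gene_association` expression tree.
#' @export
parse_gene_association <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(trimws(raw))) stop("empty gene association string")
  toks <- gpr_tokenize(raw)
  st <- list(pos = 1L, toks = toks)
  res <- gpr_parse_or(st)
  if (res$state$pos <= length(toks$type))
    stop("unexpected token '", toks$text[res$state$pos],
         "' at offset ", toks$offset[res$state$pos])
  structure(res$node, class = "gene_association")
}

gpr_tokenize <- function(raw) {
  text <- character(); type <- character(); offset <- integer()
  i <- 1L
  chars <- strsplit(raw, "")[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      text <- c(text, ch); type <- c(type, ch); offset <- c(offset, i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("[[:space:]()]", chars[j])) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "id")
    text <- c(text, word)
    offset <- c(offset, i)
    i <- j
  }
  list(text = text, type = type, offset = offset)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) "eof" else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  first <- gpr_parse_and(st)
  st <- first$state
  children <- list(first$node)
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_and(st)
    st <- nxt$state
    children <- c(children, list(nxt$node))
  }
  node <- if (length(children) == 1L) children[[1]] else
    list(op = "or", children = children)
  list(node = node, state = st)
}

gpr_parse_and <- function(st) {
  first <- gpr_parse_atom(st)
  st <- first$state
  children <- list(first$node)
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_atom(st)
    st <- nxt$state
    children <- c(children, list(nxt$node))
  }
  node <- if (length(children) == 1L) children[[1]] else
    list(op = "and", children = children)
  list(node = node, state = st)
}

gpr_parse_atom <- function(st) {
  tp <- gpr_peek(st)
  if (tp == "id") {
    node <- list(op = "gene", gene = st$toks$text[st$pos])
    st$pos <- st$pos + 1L
    return(list(node = node, state = st))
  }
  if (tp == "(") {
    open_at <- st$toks$offset[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    st <- inner$state
    if (gpr_peek(st) != ")")
      stop("unbalanced parenthesis opened at offset ", open_at)
    st$pos <- st$pos + 1L
    return(list(node = inner$node, state = st))
  }
  off <- if (st$pos <= length(st$toks$offset))
    st$toks$offset[st$pos] else nchar_end(st)
  stop("expected gene or '(' at offset ", off,
       if (tp != "eof") paste0(", found '", st$toks$text[st$pos], "'")
       else ", found end of input")
}

nchar_end <- function(st) {
  if (length(st$toks$offset))
    st$toks$offset[length(st$toks$offset)] + 1L else 1L
}

#' Canonical fully parenthesized form of an association
#'
#' @param expr A `gene_association` tree from [parse_gene_association()].
#' @return A single string; parsing it again yields an equivalent tree.
#' @export
format_gene_association <- function(expr) {
  fmt <- function(node) {
    if (node$op == "gene") return(node$gene)
    paste0("(", paste(vapply(node$children, fmt, ""),
                      collapse = paste0(" ", node$op, " ")), ")")
  }
  fmt(expr)
}

#' @export
print.gene_association <- function(x, ...) {
  cat(format_gene_association(x), "\n")
  invisible(x)
}

#' Evaluate an association under a knockout set
#'
#' A gene leaf is `TRUE` when the gene is not knocked out; AND/OR have the
#' standard boolean semantics. `TRUE` means the reaction retains catalysis.
#'
#' @param expr A `gene_association` tree.
#' @param knocked_out Character vector of knocked-out gene ids.
#' @return Logical scalar.
#' @export
evaluate_association <- function(expr, knocked_out = character()) {
  ev <- function(node) {
    switch(node$op,
           gene = !(node$gene %in% knocked_out),
           and = all(vapply(node$children, ev, TRUE)),
           or = any(vapply(node$children, ev, TRUE)))
  }
  ev(expr)
}

#' List all genes referenced by a model
#'
#' Union of leaves over all parseable gene associations, deduplicated and
#' sorted lexicographically. Unparseable association strings are skipped.
#'
#' @param model A `stoichiometric_model`.
#' @return Sorted character vector of gene ids.
#' @export
list_genes <- function(model) {
  genes <- character()
  for (r in model$reactions) {
    expr <- parse_association_or_null(r$gene_association)
    if (!is.null(expr)) genes <- c(genes, association_genes(expr))
  }
  sort(unique(genes))
}

association_genes <- function(expr) {
  acc <- function(node) {
    if (node$op == "gene") return(node$gene)
    unlist(lapply(node$children, acc))
  }
  acc(expr)
}

parse_association_or_null <- function(raw) {
  if (is.null(raw) || !nzchar(trimws(raw))) return(NULL)
  tryCatch(parse_gene_association(raw), error = function(e) NULL)
}

#' Simulate a gene knockout
#'
#' Every reaction whose gene association evaluates to `FALSE` under the
#' knockout set has both flux bounds set to zero on a working copy; the
#' original model is never mutated. Reactions without an association (or
#' with an unparseable one) are never disabled. Genes absent from every
#' association produce a per-gene warning, not an error.
#'
#' @param model A `stoichiometric_model` with a non-empty objective.
#' @param genes Non-empty character vector of gene ids to knock out.
#' @param use_flux_minimization Run [minimize_total_flux()] instead of plain
#'   [run_fba()] on the knockout model.
#' @return A `knockout_result`: list with `knocked_genes`,
#'   `disabled_reactions`, `analysis` (a `flux_analysis_result`),
#'   `objective_ratio` (knockout / wild type, with 0/0 -> 0) and
#'   `warnings`.
#' @export
simulate_knockout <- function(model, genes, use_flux_minimization = FALSE) {
  stopifnot(length(genes) >= 1L)
  if (length(model$objective$coefficients) == 0L)
    stop("model has no objective; set one with set_objective() first")
  known <- list_genes(model)
  warnings <- character()
  for (g in setdiff(genes, known))
    warnings <- c(warnings,
                  paste0("gene '", g, "' appears in no gene association"))

  wt <- suppressWarnings(run_fba(model))
  ko_model <- model
  disabled <- character()
  for (r in model$reactions) {
    expr <- parse_association_or_null(r$gene_association)
    if (is.null(expr)) next
    if (!evaluate_association(expr, genes)) {
      ko_model <- set_bounds(ko_model, r$id, 0, 0)
      disabled <- c(disabled, r$id)
    }
  }
  analysis <- suppressWarnings(
    if (use_flux_minimization) minimize_total_flux(ko_model)
    else run_fba(ko_model))
  warnings <- c(warnings, analysis$warnings)

  wt_obj <- if (wt$status == "optimal") wt$objective_value else 0
  ko_obj <- if (analysis$status == "optimal") analysis$objective_value else 0
  ratio <- if (abs(wt_obj) < 1e-12 && abs(ko_obj) < 1e-12) 0 else
    ko_obj / wt_obj
  structure(list(knocked_genes = unique(genes),
                 disabled_reactions = disabled,
                 analysis = analysis,
                 objective_ratio = ratio,
                 warnings = warnings),
            class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat("Knockout of {", paste(x$knocked_genes, collapse = ", "), "}\n")
  cat("  disabled reactions:",
      if (length(x$disabled_reactions))
        paste(x$disabled_reactions, collapse = ", ") else "none", "\n")
  cat("  status:", x$analysis$status,
      " objective ratio:", sprintf("%.6g", x$objective_ratio), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
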