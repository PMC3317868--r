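#' Apply a batch-edit script to a model
#'
#' The batch grammar is one command per line, whitespace-separated tokens;
#' `#`-prefixed lines and blank lines are ignored. Supported verbs:
#'
#' \describe{
#'   \item{`set_bound RXN lower|upper|both V [V2]`}{edit one or both bounds}
#'   \item{`set_objective RXN max|min`}{single-reaction objective}
#'   \item{`add_reaction ID MET:COEF,MET:COEF,... LB UB`}{new reaction}
#'   \item{`delete_reaction ID`}{remove a reaction}
#'   \item{`add_exchange MET LB UB`}{exchange reaction for a metabolite}
#'   \item{`set_compartment ENTITY COMP`}{assign/create a compartment}
#'   \item{`rename OLD NEW`}{rename a metabolite or reaction}
#' }
#'
#' Processing is transactional per line: on the first failing line execution
#' stops, edits from earlier lines persist, and the log records the failure
#' and its line number.
#'
#' @param model A `stoichiometric_model`.
#' @param script Character vector of command lines, or a path to a UTF-8
#'   text file when `from_file = TRUE`.
#' @param from_file Read `script` as a file path.
#' @return A list with `model` (possibly partially edited), `log` (data
#'   frame with columns `line`, `command`, `status`, `message`) and `ok`
#'   (logical, all lines succeeded).
#' @export
apply_batch_commands <- function(model, script, from_file = FALSE) {
  if (from_file) script <- readLines(script, encoding = "UTF-8")
  if (length(script) == 0L) stop("empty batch script")
  log <- list()
  ok <- TRUE
  for (i in seq_along(script)) {
    line <- trimws(script[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    res <- tryCatch(
      list(model = apply_batch_line(model, line), msg = "ok"),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      log[[length(log) + 1L]] <- data.frame(
        line = i, command = line, status = "error", message = res,
        stringsAsFactors = FALSE)
      ok <- FALSE
      break
    }
    model <- res$model
    log[[length(log) + 1L]] <- data.frame(
      line = i, command = line, status = "ok", message = "",
      stringsAsFactors = FALSE)
  }
  if (length(log) == 0L) stop("batch script contains no commands")
  list(model = model, log = do.call(rbind, log), ok = ok)
}

apply_batch_line <- function(model, line) {
  tok <- strsplit(line, "[[:space:]]+")[[1]]
  verb <- tok[1]
  args <- tok[-1]
  need <- function(n) {
    if (length(args) < n)
      stop("'", verb, "' expects at least ", n, " arguments, got ",
           length(args))
  }
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("not a number: '", x, "'")
    v
  }
  switch(verb,
    set_bound = {
      need(3)
      rxn <- get_reaction(model, args[1])
      which <- match.arg(args[2], c("lower", "upper", "both"))
      if (which == "both") {
        need(4)
        set_bounds(model, args[1], num(args[3]), num(args[4]))
      } else if (which == "lower") {
        set_bounds(model, args[1], num(args[3]), rxn$upper_bound)
      } else {
        set_bounds(model, args[1], rxn$lower_bound, num(args[3]))
      }
    },
    set_objective = {
      need(2)
      dir <- switch(match.arg(args[2], c("max", "min")),
                    max = "maximize", min = "minimize")
      set_objective(model, args[1], dir)
    },
    add_reaction = {
      need(4)
      st <- parse_stoichiometry_spec(args[2])
      add_reaction(model, reaction(args[1], st, lower_bound = num(args[3]),
                                   upper_bound = num(args[4])))
    },
    delete_reaction = {
      need(1)
      delete_reaction(model, args[1])
    },
    add_exchange = {
      need(3)
      add_exchange_reaction(model, args[1], num(args[2]), num(args[3]))
    },
    set_compartment = {
      need(2)
      assign_compartment(model, args[1], args[2])
    },
    rename = {
      need(2)
      rename_entity(model, args[1], args[2])
    },
    stop("unknown batch verb '", verb, "'")
  )
}

# "A:-1,B:1" -> c(A = -1, B = 1)
parse_stoichiometry_spec <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed stoichiometry spec '", spec, "'")
  coefs <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  if (anyNA(coefs)) stop("non-numeric coefficient in '", spec, "'")
  stats::setNames(coefs, vapply(kv, `[[`, "", 1L))
}
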