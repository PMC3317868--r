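#' Export analysis results as tab-separated values
#'
#' One header line, then one row per model reaction in model order; numbers
#' are rendered with 6 significant digits, `.` decimal separator. FBA-style
#' results get columns `id, name, flux, reduced_cost, lower_bound,
#' upper_bound` followed (when shadow prices are present) by a blank line
#' and a metabolite section `metabolite, shadow_price`. FVA results get
#' `id, name, min_flux, max_flux, lower_bound, upper_bound`.
#'
#' @param result A `flux_analysis_result` or `fva_result`.
#' @param model The model the result was computed on (same reaction ids).
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of TSV lines, invisibly when `path` is given.
#' @export
write_results_tsv <- function(result, model, path = NULL) {
  g6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  rids <- names(model$reactions)
  rnames <- vapply(model$reactions, `[[`, "", "name")
  lbs <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ubs <- vapply(model$reactions, `[[`, 0, "upper_bound")

  if (inherits(result, "fva_result")) {
    if (!all(result$reaction %in% rids))
      stop("FVA result references reactions absent from the model")
    idx <- match(result$reaction, rids)
    lines <- c("id\tname\tmin_flux\tmax_flux\tlower_bound\tupper_bound",
               paste(result$reaction, rnames[idx], g6(result$min_flux),
                     g6(result$max_flux), g6(lbs[idx]), g6(ubs[idx]),
                     sep = "\t"))
  } else if (inherits(result, "flux_analysis_result")) {
    if (result$status != "optimal")
      stop("cannot export a result with status '", result$status, "'")
    if (!setequal(names(result$fluxes), rids))
      stop("result and model reaction ids differ")
    flux <- result$fluxes[rids]
    rc <- if (is.null(result$reduced_costs)) rep(NA_real_, length(rids)) else
      result$reduced_costs[rids]
    lines <- c("id\tname\tflux\treduced_cost\tlower_bound\tupper_bound",
               paste(rids, rnames, g6(flux), g6(rc), g6(lbs), g6(ubs),
                     sep = "\t"))
    if (!is.null(result$shadow_prices) && length(result$shadow_prices)) {
      lines <- c(lines, "", "metabolite\tshadow_price",
                 paste(names(result$shadow_prices),
                       g6(result$shadow_prices), sep = "\t"))
    }
  } else {
    stop("unsupported result class: ", paste(class(result), collapse = "/"))
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
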