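# SVG pathway map rendering. Pure text generation: identical inputs give
# byte-identical output. Each metabolite and each reaction is one
# addressable <g> element; KEGG ids become hyperlinks. Flux results are
# superimposed as stroke width (proportional to |flux|), a diverging color
# (blue negative / grey zero / red positive), dashing for numerically zero
# flux, a printed flux value, and an arrowhead on the realized direction.

#' Style specification for pathway maps
#'
#' @param width_range Length-2 numeric, min/max stroke width in px for the
#'   flux-proportional edges; min must be positive.
#' @param zero_epsilon Flux magnitudes at or below this are drawn as
#'   carrying zero flux (dashed, minimal width).
#' @param label_digits Significant digits for printed flux values.
#' @param colors Named character vector with entries `negative`, `zero`,
#'   `positive`.
#' @return A `style_spec` list.
#' @export
style_spec <- function(width_range = c(1, 6), zero_epsilon = 1e-9,
                       label_digits = 6,
                       colors = c(negative = "#1f5fbf", zero = "#8a8a8a",
                                  positive = "#c23b22")) {
  stopifnot(length(width_range) == 2L, width_range[1] > 0,
            width_range[2] >= width_range[1], zero_epsilon >= 0)
  structure(list(width_range = width_range, zero_epsilon = zero_epsilon,
                 label_digits = label_digits, colors = colors),
            class = "style_spec")
}

#' Map a flux magnitude to a stroke width
#'
#' Linear interpolation of `|flux|` over `[0, vmax]` into the style's width
#' range; `vmax = 0` maps everything to the minimum width and magnitudes
#' above `vmax` are clipped to the maximum.
#'
#' @param flux Signed flux value.
#' @param vmax Largest `|flux|` in the rendered selection; `>= 0`.
#' @param style A [style_spec()].
#' @return Stroke width in px.
#' @export
flux_to_width <- function(flux, vmax, style = style_spec()) {
  stopifnot(vmax >= 0)
  wr <- style$width_range
  if (vmax == 0) return(wr[1])
  wr[1] + (wr[2] - wr[1]) * pmin(abs(flux) / vmax, 1)
}

#' Render a pathway map as SVG
#'
#' Metabolites are labeled circles, reactions polylines with an arrowhead
#' on the realized direction (declared direction when no result is given).
#' With a result, stroke width scales with `|flux|`, numerically zero
#' fluxes are dashed, and the signed flux value is printed beside the
#' reaction (reversible reactions running backwards keep their reference
#' direction in the printed sign; the arrowhead flips). Metabolite groups
#' with a KEGG compound id and reaction groups with a KEGG reaction id are
#' wrapped in hyperlinks to the corresponding KEGG entry pages.
#'
#' @param model A `stoichiometric_model`.
#' @param layout A [layout_pathway()] result covering the selection.
#' @param result Optional `flux_analysis_result`.
#' @param style A [style_spec()].
#' @return An `svg_document`: the SVG 1.1 text with class attributes.
#' @export
render_svg <- function(model, layout, result = NULL, style = style_spec()) {
  stopifnot(inherits(layout, "pathway_layout"))
  rids <- names(layout$edge_routes)
  missing <- setdiff(rids, names(model$reactions))
  if (length(missing))
    stop("layout references reactions absent from the model: ",
         paste(missing, collapse = ", "))
  missing_m <- setdiff(layout$nodes$id, names(model$metabolites))
  if (length(missing_m))
    stop("layout references metabolites absent from the model: ",
         paste(missing_m, collapse = ", "))

  fluxes <- if (!is.null(result)) result$fluxes else NULL
  vmax <- if (!is.null(fluxes)) max(abs(fluxes[rids]), 0) else 0
  num <- function(x) sprintf("%.2f", x)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\" standalone=\"yes\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "xmlns:xlink=\"http://www.w3.org/1999/xlink\" ",
                   "version=\"1.1\" width=\"%s\" height=\"%s\" ",
                   "viewBox=\"0 0 %s %s\">"),
            num(layout$canvas[1]), num(layout$canvas[2]),
            num(layout$canvas[1]), num(layout$canvas[2])),
    "  <defs>",
    paste0("    <marker id=\"arrow\" viewBox=\"0 0 10 10\" refX=\"9\" ",
           "refY=\"5\" markerWidth=\"7\" markerHeight=\"7\" ",
           "orient=\"auto-start-reverse\">"),
    "      <path d=\"M 0 0 L 10 5 L 0 10 z\" fill=\"#333333\"/>",
    "    </marker>",
    "  </defs>")

  for (rid in rids) {
    r <- model$reactions[[rid]]
    pts <- layout$edge_routes[[rid]]
    flux <- if (!is.null(fluxes)) unname(fluxes[rid]) else NA_real_
    has_flux <- !is.null(fluxes) && is.finite(flux)
    zeroish <- has_flux && abs(flux) <= style$zero_epsilon
    width <- if (has_flux) flux_to_width(flux, vmax, style) else
      style$width_range[1]
    color <- if (!has_flux || zeroish) style$colors[["zero"]] else
      if (flux > 0) style$colors[["positive"]] else style$colors[["negative"]]
    # arrowhead on realized direction; reference direction when no result
    draw_pts <- if (has_flux && flux < -style$zero_epsilon)
      pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
    attrs <- sprintf(paste0("points=\"%s\" fill=\"none\" stroke=\"%s\" ",
                            "stroke-width=\"%s\""),
                     paste(num(draw_pts[, 1]), num(draw_pts[, 2]),
                           sep = ",", collapse = " "),
                     color, num(width))
    if (zeroish) attrs <- paste0(attrs, " stroke-dasharray=\"5,4\"")
    if (!zeroish) attrs <- paste0(attrs, " marker-end=\"url(#arrow)\"")
    mid <- pts[ceiling(nrow(pts) / 2), ]
    body <- c(sprintf("    <polyline %s/>", attrs),
              sprintf(paste0("    <text x=\"%s\" y=\"%s\" font-size=\"10\" ",
                             "fill=\"#333333\">%s</text>"),
                      num(mid[1] + 6), num(mid[2] - 6), xesc(r$name)))
    if (has_flux)
      body <- c(body,
                sprintf(paste0("    <text x=\"%s\" y=\"%s\" font-size=\"10\" ",
                               "fill=\"%s\">%s</text>"),
                        num(mid[1] + 6), num(mid[2] + 10), color,
                        sprintf(paste0("%.", style$label_digits, "g"),
                                flux)))
    g <- c(sprintf("  <g id=\"rxn-%s\">", xesc(rid)), body, "  </g>")
    if (!is.null(r$kegg_id))
      g <- c(sprintf("  <a xlink:href=\"https://www.kegg.jp/entry/%s\">",
                     xesc(r$kegg_id)), g, "  </a>")
    lines <- c(lines, g)
  }

  for (i in seq_len(nrow(layout$nodes))) {
    nid <- layout$nodes$id[i]
    m <- model$metabolites[[nid]]
    g <- c(sprintf("  <g id=\"met-%s\">", xesc(nid)),
           sprintf(paste0("    <circle cx=\"%s\" cy=\"%s\" r=\"14\" ",
                          "fill=\"#f5f0dc\" stroke=\"#555555\" ",
                          "stroke-width=\"1\"/>"),
                   num(layout$nodes$x[i]), num(layout$nodes$y[i])),
           sprintf(paste0("    <text x=\"%s\" y=\"%s\" font-size=\"10\" ",
                          "text-anchor=\"middle\">%s</text>"),
                   num(layout$nodes$x[i]), num(layout$nodes$y[i] - 18),
                   xesc(nid)),
           "  </g>")
    if (!is.null(m$kegg_id))
      g <- c(sprintf("  <a xlink:href=\"https://www.kegg.jp/entry/%s\">",
                     xesc(m$kegg_id)), g, "  </a>")
    lines <- c(lines, g)
  }

  lines <- c(lines, "</svg>")
  structure(paste(lines, collapse = "\n"), class = "svg_document")
}

#' Write an SVG document to a file
#'
#' @param doc An `svg_document` from [render_svg()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  stopifnot(inherits(doc, "svg_document"))
  writeLines(unclass(doc), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.svg_document <- function(x, ...) {
  cat("<svg_document>", nchar(unclass(x)), "bytes,",
      lengths(regmatches(x, gregexpr("<g id=", x))), "element groups\n")
  invisible(x)
}
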