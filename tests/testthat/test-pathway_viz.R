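test_that("auto layout ranks the chain top-to-bottom, deterministically", {
  m <- chain_model()
  lay <- layout_pathway(m)
  yA <- lay$nodes$y[lay$nodes$id == "A"]
  yB <- lay$nodes$y[lay$nodes$id == "B"]
  expect_lt(yA, yB)  # longest-path rank: A (source) above B
  rx <- lay$reaction_nodes
  expect_lt(rx$y[rx$id == "R1"], rx$y[rx$id == "R_out"])
  # canvas encloses everything with margin
  expect_true(all(lay$nodes$x >= 10 & lay$nodes$y >= 10))
  expect_true(all(lay$nodes$x <= lay$canvas["width"] - 10))
  expect_true(all(lay$nodes$y <= lay$canvas["height"] - 10))

  lay2 <- layout_pathway(m)
  expect_identical(lay, lay2)

  expect_error(layout_pathway(m, "NoSuchSubsystem"), "selects no reactions")
  expect_error(layout_pathway(m, c("R1", "GHOST")), "unknown reactions")
})

test_that("subsystem filters select reactions by pathway label", {
  d <- demo_model()
  lay <- layout_pathway(d, "Glycolysis")
  expect_setequal(names(lay$edge_routes),
                  c("HEX1", "PGI", "PFK", "FBP", "FBA", "TPI", "GLYC_L",
                    "PYK"))
  lay2 <- layout_pathway(d, c("HEX1", "PGI"))
  expect_length(lay2$edge_routes, 2)
})

test_that("user layout files override positions and skip unknown ids", {
  m <- chain_model()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t200\t300", "GHOST\t1\t1"), f)
  expect_warning(lay <- layout_pathway(m, user_layout = f), "GHOST")
  expect_equal(lay$nodes$x[lay$nodes$id == "A"], 200)
  expect_equal(lay$nodes$y[lay$nodes$id == "A"], 300)
  expect_identical(lay$source, "user_layout_file")
})

test_that("flux_to_width interpolates linearly and clips", {
  st <- style_spec(width_range = c(1, 5))
  expect_equal(flux_to_width(0, 7, st), 1)
  expect_equal(flux_to_width(7, 7, st), 5)
  expect_equal(flux_to_width(-7, 7, st), 5)
  expect_equal(flux_to_width(3.5, 7, st), 3)
  expect_equal(flux_to_width(100, 7, st), 5)   # clipped
  expect_equal(flux_to_width(3, 0, st), 1)     # vmax = 0 -> min width
  # monotone in |flux| over random draws
  set.seed(1)
  f <- sort(abs(stats::rnorm(50, sd = 4)))
  w <- vapply(f, flux_to_width, 0, vmax = 10, style = st)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w >= 1 & w <= 5))
})

test_that("rendered SVG is well-formed with one group per entity", {
  m <- fixture_models()$chain
  res <- run_fba(m)
  lay <- layout_pathway(m)
  svg <- render_svg(m, lay, res)
  doc <- xml2::read_xml(unclass(svg))
  expect_identical(xml2::xml_name(doc), "svg")
  expect_match(unclass(svg), "xmlns=\"http://www.w3.org/2000/svg\"")

  groups <- xml2::xml_find_all(doc, "//*[local-name()='g']")
  ids <- xml2::xml_attr(groups, "id")
  expect_setequal(ids[startsWith(ids, "rxn-")],
                  paste0("rxn-", names(lay$edge_routes)))
  expect_setequal(ids[startsWith(ids, "met-")],
                  paste0("met-", lay$nodes$id))
  expect_identical(anyDuplicated(ids), 0L)

  # equal fluxes: equal stroke widths, all solid, flux labels present
  polys <- xml2::xml_find_all(doc, "//*[local-name()='polyline']")
  widths <- unique(xml2::xml_attr(polys, "stroke-width"))
  expect_length(widths, 1)
  expect_true(all(is.na(xml2::xml_attr(polys, "stroke-dasharray"))))
  expect_match(unclass(svg), ">10<")  # printed flux value
})

test_that("result-free maps use minimal strokes and no flux labels", {
  m <- chain_model()
  lay <- layout_pathway(m)
  svg <- render_svg(m, lay, result = NULL, style = style_spec(c(2, 9)))
  doc <- xml2::read_xml(unclass(svg))
  polys <- xml2::xml_find_all(doc, "//*[local-name()='polyline']")
  expect_true(all(xml2::xml_attr(polys, "stroke-width") == "2.00"))
  texts <- xml2::xml_text(xml2::xml_find_all(doc, "//*[local-name()='text']"))
  expect_false(any(grepl("^10$", texts)))
})

test_that("zero and negative fluxes change dash, color and arrow direction", {
  m <- fixture_models()$loop
  pf <- minimize_total_flux(m)       # R4 carries zero flux
  lay <- layout_pathway(m)
  svg <- unclass(render_svg(m, lay, pf))
  expect_match(svg, "stroke-dasharray")
  doc <- xml2::read_xml(svg)
  r4 <- xml2::xml_find_first(doc, "//*[@id='rxn-R4']/*[local-name()='polyline']")
  expect_false(is.na(xml2::xml_attr(r4, "stroke-dasharray")))

  # negative flux on a reversible reaction reverses the polyline points
  mr <- chain_model()
  mr$reactions$R1$stoichiometry <- c(A = 1, B = -1)
  mr <- set_bounds(mr, "R1", -1000, 1000)
  mr <- set_objective(mr, "R_out")
  res <- run_fba(mr)
  layr <- layout_pathway(mr)
  svgr <- xml2::read_xml(unclass(render_svg(mr, layr, res)))
  fwd <- xml2::xml_attr(xml2::xml_find_first(
    svgr, "//*[@id='rxn-R1']/*[local-name()='polyline']"), "points")
  svgn <- xml2::read_xml(unclass(render_svg(mr, layr)))
  ref <- xml2::xml_attr(xml2::xml_find_first(
    svgn, "//*[@id='rxn-R1']/*[local-name()='polyline']"), "points")
  pts <- strsplit(fwd, " ")[[1]]
  expect_identical(pts, rev(strsplit(ref, " ")[[1]]))
  # the signed value is printed, not negated
  expect_match(as.character(svgr), ">-10<")
})

test_that("KEGG ids become hyperlinks exactly when present", {
  d <- set_objective(demo_model(), "EX_pyr_e")
  lay <- layout_pathway(d, "Glycolysis")
  svg <- unclass(render_svg(d, lay, run_fba(d)))
  expect_match(svg, "xlink:href=\"https://www.kegg.jp/entry/C00031\"")
  expect_match(svg, "xlink:href=\"https://www.kegg.jp/entry/R00299\"")
  doc <- xml2::read_xml(svg)
  links <- xml2::xml_find_all(doc, "//*[local-name()='a']")
  hrefs <- xml2::xml_attr(links, "href")
  n_kegg_rxn <- sum(!vapply(d$reactions[names(lay$edge_routes)],
                            function(r) is.null(r$kegg_id), TRUE))
  n_kegg_met <- sum(!vapply(d$metabolites[lay$nodes$id],
                            function(m) is.null(m$kegg_id), TRUE))
  expect_length(links, n_kegg_rxn + n_kegg_met)
  # no hyperlink without a KEGG id
  svg_chain <- unclass(render_svg(chain_model(), layout_pathway(chain_model())))
  expect_false(grepl("xlink:href", svg_chain))
})

test_that("rendering is a pure function of its inputs", {
  m <- fixture_models()$demo
  res <- run_fba(m)
  lay <- layout_pathway(m, "Glycolysis")
  s1 <- render_svg(m, lay, res)
  s2 <- render_svg(m, lay, res)
  expect_identical(unclass(s1), unclass(s2))
  expect_error(render_svg(chain_model(), lay), "absent from the model")
})
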