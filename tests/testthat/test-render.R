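trees_R <- build_trees(fig2_fixture("I"))
map_R <- compute_relationship_map(trees_R$species, trees_R$phenon)
lay_R <- position_chart(trees_R$species, trees_R$phenon, map_R)
svg_R <- render_chart(lay_R)
doc_R <- xml2::xml_ns_strip(xml2::read_xml(svg_R))

test_that("the chart is well-formed SVG built from known elements", {
  expect_equal(xml2::xml_name(doc_R), "svg")
  els <- unique(xml2::xml_name(xml2::xml_find_all(doc_R, "//*")))
  expect_true(all(els %in% c("svg", "g", "rect", "line", "path", "text",
                             "title", "desc", "image")))
  # one group per species box, one per phenon segment
  expect_length(xml2::xml_find_all(doc_R, "//g[@class='species-box']"), 5)
  expect_length(xml2::xml_find_all(doc_R, "//g[@class='phenon-segment']"), 11)
})

test_that("box sides carry the range's style runs over their drawn extent", {
  runs <- svg_side_style_extents(svg_R, "Aa")
  left <- runs[runs$side == "left", ]
  # frequent for 8 Myr up from the base (13 -> 5 Ma)...
  expect_equal(left$myr[left$style == "frequent"], 8)
  expect_equal(left$age_old[left$style == "frequent"], 13)
  # ...then conjectured for 5 Myr down from the top (5 -> 0 Ma)
  expect_equal(left$myr[left$style == "conjectured"], 5)
  expect_equal(left$age_young[left$style == "conjectured"], 0)
  # both vertical sides carry the same runs
  right <- runs[runs$side == "right", ]
  expect_equal(sort(right$myr), sort(left$myr))
  # base edge is frequent, top edge conjectured
  expect_equal(runs$style[runs$side == "base"], "frequent")
  expect_equal(runs$style[runs$side == "top"], "conjectured")
  # single-style boxes are frequent on all four sides
  bb <- svg_side_style_extents(svg_R, "Bb")
  expect_true(all(bb$style == "frequent"))
})

test_that("box fills use the inherited colour at the configured alpha", {
  fills <- xml2::xml_find_all(doc_R, "//g[@class='species-box']/rect")
  expect_equal(as.numeric(xml2::xml_attr(fills, "fill-opacity")),
               rep(0.25, 5))
  aa_fill <- xml2::xml_find_first(
    doc_R, "//g[@class='species-box' and @data-species='Aa']/rect")
  expect_equal(xml2::xml_attr(aa_fill, "fill"), "green")
})

test_that("species borders render strictly thicker than phenon lines", {
  side_w <- as.numeric(xml2::xml_attr(xml2::xml_find_all(
    doc_R, "//line[@data-side='base' and @data-style='frequent']"),
    "stroke-width"))
  seg_w <- as.numeric(xml2::xml_attr(xml2::xml_find_all(
    doc_R, "//g[@class='phenon-segment']/line[@data-style='frequent']"),
    "stroke-width"))
  expect_true(all(side_w > 1))
  # default styles: the species token is strictly thicker than the
  # phenon token in the emitted document
  st <- default_styles()
  expect_gt(st$stroke_width[st$token == "frequent"],
            st$stroke_width[st$token == "common"])
  # and the settings constructor enforces it
  expect_error(chart_settings(default_species_style = "common",
                              default_phenon_style = "frequent"),
               "strictly thicker")
})

test_that("guide symbols sit at segment extremities", {
  # phenon b: broken pair at 10 Ma between Aa and Bb
  segs <- xml2::xml_find_all(doc_R, "//g[@data-phenon='b']")
  expect_length(segs, 2)
  chev_top <- xml2::xml_find_first(doc_R,
    "//g[@data-phenon='b' and @data-species='Aa']/path[contains(@class,'guide-broken-top')]")
  chev_base <- xml2::xml_find_first(doc_R,
    "//g[@data-phenon='b' and @data-species='Bb']/path[contains(@class,'guide-broken-base')]")
  expect_false(inherits(chev_top, "xml_missing"))
  expect_false(inherits(chev_base, "xml_missing"))
  # still-living phena get the arrowhead at the top
  living <- xml2::xml_find_all(doc_R, "//path[contains(@class,'guide-living')]")
  expect_length(living, 3)  # a, d, e
  # rendered y extents of every segment invert to its ages
  upm <- as.numeric(xml2::xml_attr(doc_R, "data-units-per-myr"))
  mtop <- as.numeric(xml2::xml_attr(doc_R, "data-margin-top"))
  for (g in xml2::xml_find_all(doc_R, "//g[@class='phenon-segment']")) {
    ph <- xml2::xml_attr(g, "data-phenon")
    sp <- xml2::xml_attr(g, "data-species")
    ys <- c(as.numeric(xml2::xml_attr(xml2::xml_find_all(g, "line"), "y1")),
            as.numeric(xml2::xml_attr(xml2::xml_find_all(g, "line"), "y2")))
    want <- lay_R$segments[lay_R$segments$phenon == ph &
                             lay_R$segments$species == sp, ]
    expect_equal((max(ys) - mtop) / upm, want$old_age, tolerance = 1e-6)
    expect_equal((min(ys) - mtop) / upm, want$young_age, tolerance = 1e-6)
  }
})

test_that("popups travel as element titles and labels truncate at '|'", {
  t <- xml2::xml_text(xml2::xml_find_first(
    doc_R, "//g[@data-phenon='b' and @data-species='Bb']/title"))
  expect_equal(t, "phenon b ends in Bb")
  tr <- build_trees(mini_pack(
    c("A", "10", "frequent"), c("A", "0", "TOP"),
    c("px | Author, 1900", "8", "common"),
    c("px | Author, 1900", "2", "TOP", "", "", "phenon", "A")))
  map <- compute_relationship_map(tr$species, tr$phenon)
  svg <- render_chart(position_chart(tr$species, tr$phenon, map))
  d <- xml2::xml_ns_strip(xml2::read_xml(svg))
  lab <- xml2::xml_text(xml2::xml_find_first(d, "//text[@class='phenon-label']"))
  expect_equal(lab, "px")
})

test_that("an empty datapack still renders a valid axis-only chart", {
  tr <- build_trees(parse_datapack(""))
  map <- compute_relationship_map(tr$species, tr$phenon)
  svg <- render_chart(position_chart(tr$species, tr$phenon, map))
  d <- xml2::xml_ns_strip(xml2::read_xml(svg))
  expect_length(xml2::xml_find_all(d, "//g[@class='species-box']"), 0)
  expect_gt(length(xml2::xml_find_all(d, "//g[@class='axis']/line")), 0)
})

test_that("background bands draw behind everything when configured", {
  s <- chart_settings(bands = data.frame(
    old = c(10, 5), young = c(5, 0), color = c("#EEEEDD", "#DDEEEE"),
    label = c("older", "younger")))
  lay <- position_chart(trees_R$species, trees_R$phenon, map_R, s)
  d <- xml2::xml_ns_strip(xml2::read_xml(render_chart(lay)))
  bands <- xml2::xml_find_all(d, "//g[@class='bands']/rect")
  expect_length(bands, 2)
  # bands group precedes the species boxes in document order
  kids <- xml2::xml_name(xml2::xml_children(d))
  expect_lt(which(xml2::xml_attr(xml2::xml_children(d), "class") == "bands"),
            which(xml2::xml_attr(xml2::xml_children(d), "class") == "species-boxes"))
})

test_that("component trees draw one group per range plus branch lines", {
  svg <- render_component_tree(trees_R$species, kind = "species")
  d <- xml2::xml_ns_strip(xml2::read_xml(svg))
  expect_length(xml2::xml_find_all(d, "//g[@class='range']"), 5)
  expect_length(xml2::xml_find_all(d, "//g[@class='branches']/line"), 4)
  expect_length(xml2::xml_find_all(d, "//text[@class='range-label']"), 5)
  # element count audit on a random tree: ranges + branches + labels
  tr <- build_trees(random_fixture(fixture_spec(seed = 3, n_species = 12,
                                                n_phena = 0)))
  d2 <- xml2::xml_ns_strip(xml2::read_xml(
    render_component_tree(tr$species, kind = "species")))
  expect_length(xml2::xml_find_all(d2, "//g[@class='range']"), 12)
  expect_length(xml2::xml_find_all(d2, "//g[@class='branches']/line"),
                nrow(tr$species$branches))
  expect_length(xml2::xml_find_all(d2, "//text[@class='range-label']"), 12)
  # a lone range is a single vertical line
  solo <- build_trees(mini_pack(c("solo", "5", "common"),
                                c("solo", "1", "TOP")))
  d3 <- xml2::xml_ns_strip(xml2::read_xml(
    render_component_tree(solo$species, kind = "species")))
  expect_length(xml2::xml_find_all(d3, "//g[@class='range']//line"), 1)
})

test_that("branches toggled off are hidden but keep the tree intact", {
  tr <- build_trees(mini_pack(
    c("A", "10", "frequent"), c("A", "0", "TOP"),
    c("B", "6", "frequent"), c("B", "0", "TOP"),
    c("A", "6", "branch", "B", "off")))
  expect_equal(tr$species$parent[["B"]], "A")
  d <- xml2::xml_ns_strip(xml2::read_xml(
    render_component_tree(tr$species, kind = "species")))
  expect_length(xml2::xml_find_all(d, "//g[@class='branches']/line"), 0)
})

test_that("phenon_chart drives all three modes end to end", {
  pack <- fig2_fixture("I")
  for (m in c("integrated", "species", "phenon")) {
    svg <- phenon_chart(pack, mode = m)
    expect_silent(xml2::read_xml(svg))
  }
})
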