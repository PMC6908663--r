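# Standalone SVG emission. Documents are assembled as escaped text (the
# element set is small and fixed); xml2 is used on the read side to
# audit what was drawn. Every graphical element carries a class and
# data-* attributes so rendered geometry can be checked: the root
# element records the age map (units per Myr, window, top margin), box
# border runs carry their side and style, phenon segments their taxa.

num <- function(x) sprintf("%.10g", x)

xml_esc <- function(x) {
  if (!any(grepl("[&<>\"]", x))) return(x)
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# build one element; children = character vector of serialized children
tag <- function(.name, ..., children = NULL, text = NULL) {
  attrs <- list(...)
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  astr <- if (length(attrs)) {
    vals <- vapply(attrs, function(v)
      xml_esc(if (is.numeric(v)) num(v) else as.character(v)), character(1))
    paste0(" ", paste0(names(attrs), "=\"", vals, "\"", collapse = " "))
  } else ""
  if (is.null(children) && is.null(text))
    return(paste0("<", .name, astr, "/>"))
  paste0("<", .name, astr, ">",
         if (is.null(text)) "" else xml_esc(text),
         paste0(children, collapse = ""),
         "</", .name, ">")
}

svg_doc <- function(lay, children) {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    tag("svg",
        xmlns = "http://www.w3.org/2000/svg",
        width = lay$width, height = lay$height,
        viewBox = sprintf("0 0 %s %s", num(lay$width), num(lay$height)),
        "font-family" = "sans-serif",
        "data-units-per-myr" = lay$settings$units_per_myr,
        "data-window-old" = lay$window[[1]],
        "data-window-young" = lay$window[[2]],
        "data-margin-top" = lay$settings$margin[["top"]],
        children = children))
}

stroke_attrs <- function(token, styles) {
  st <- style_for(token, styles)
  list(width = st$stroke_width,
       dash = if (nzchar(st$dash)) st$dash else NULL)
}

branch_dash <- function(style) {
  switch(style, dashed = "6,4", dotted = "2,3", NULL)
}

draw_axis <- function(lay) {
  s <- lay$settings
  x <- s$margin[["left"]] + s$axis_width - 6
  out <- tag("line", class = "axis-line",
             x1 = x, y1 = age_to_y(lay, lay$window[[2]]),
             x2 = x, y2 = age_to_y(lay, lay$window[[1]]),
             stroke = "#333333", "stroke-width" = 1)
  span <- lay$window[[1]] - lay$window[[2]]
  tick <- s$tick_every
  if (is.null(tick)) tick <- max(1, round(span / 20))
  ages <- seq(ceiling(lay$window[[2]]), floor(lay$window[[1]]), by = tick)
  for (a in ages) {
    ya <- age_to_y(lay, a)
    out <- c(out,
      tag("line", class = "axis-tick", x1 = x - 4, y1 = ya, x2 = x, y2 = ya,
          stroke = "#333333", "stroke-width" = 1),
      tag("text", class = "axis-label", x = x - 7, y = ya + 3,
          "text-anchor" = "end", "font-size" = 9, fill = "#333333",
          text = num(a)))
  }
  out <- c(out, tag("text", class = "axis-title", x = s$margin[["left"]],
                    y = s$margin[["top"]] - 10, "font-size" = 9,
                    fill = "#333333", text = "Ma"))
  tag("g", class = "axis", children = out)
}

draw_bands <- function(lay) {
  b <- lay$settings$bands
  if (is.null(b) || nrow(b) == 0) return(character())
  out <- character()
  for (i in seq_len(nrow(b))) {
    y1 <- age_to_y(lay, b$young[[i]])
    y2 <- age_to_y(lay, b$old[[i]])
    out <- c(out, tag("rect", class = "band", x = 0, y = y1,
                      width = lay$width, height = y2 - y1, fill = b$color[[i]]))
    if (nzchar(b$label[[i]]))
      out <- c(out, tag("text", class = "band-label", x = lay$width - 4,
                        y = (y1 + y2) / 2, "text-anchor" = "end",
                        "font-size" = 9, fill = "#666666",
                        text = b$label[[i]]))
  }
  tag("g", class = "bands", children = out)
}

# glyphs at segment extremities: origin tick, extinction bar,
# still-living arrowhead, open chevrons at artificial breaks
draw_symbol <- function(symbol, x, y, color, end) {
  path <- function(cls, d, fill = "none")
    tag("path", class = paste("guide", cls), d = d, stroke = color,
        "stroke-width" = 1.2, fill = fill)
  if (end == "top") {
    switch(symbol,
      RANGE_TOP_EXTINCT = tag("line", class = "guide guide-extinct",
        x1 = x - 5, y1 = y, x2 = x + 5, y2 = y, stroke = color,
        "stroke-width" = 2),
      RANGE_TOP_LIVING = path("guide-living",
        sprintf("M %s %s L %s %s L %s %s Z", num(x), num(y), num(x - 4),
                num(y + 7), num(x + 4), num(y + 7)), fill = color),
      BROKEN_TOP = path("guide-broken-top",
        sprintf("M %s %s L %s %s L %s %s", num(x - 4), num(y + 5), num(x),
                num(y), num(x + 4), num(y + 5))))
  } else {
    switch(symbol,
      RANGE_ORIGIN = tag("line", class = "guide guide-origin",
        x1 = x - 4, y1 = y, x2 = x + 4, y2 = y, stroke = color,
        "stroke-width" = 1.5),
      BROKEN_BASE = path("guide-broken-base",
        sprintf("M %s %s L %s %s L %s %s", num(x - 4), num(y - 5), num(x),
                num(y), num(x + 4), num(y - 5))))
  }
}

#' Render the integrated chart as SVG
#'
#' Emits a standalone SVG document: optional background bands, age axis
#' with Myr ticks, one group per species box (translucent fill in the
#' inherited colour; border drawn as separate per-side elements so each
#' side carries its style runs), species branch connectors, one group
#' per phenon segment (style-run lines, guide symbols at the
#' extremities, display label), and in-box phenon connectors. Pop-up
#' text travels as SVG `<title>` elements.
#'
#' @param lay `chart_layout` from [position_chart()].
#' @return SVG document text (single string).
#' @export
render_chart <- function(lay) {
  stopifnot(inherits(lay, "chart_layout"))
  s <- lay$settings
  boxes <- character()
  if (!is.null(lay$boxes)) {
    B <- as.list(lay$boxes)
    side_ix <- split(seq_len(nrow(lay$box_sides)), lay$box_sides$species)
    S <- as.list(lay$box_sides)
    for (i in seq_along(B$species)) {
      kids <- character()
      if (nzchar(B$popup[[i]])) kids <- tag("title", text = B$popup[[i]])
      kids <- c(kids, tag("rect", class = "box-fill",
                          x = B$x_left[[i]], y = B$y_top[[i]],
                          width = B$x_right[[i]] - B$x_left[[i]],
                          height = B$y_bottom[[i]] - B$y_top[[i]],
                          fill = B$color[[i]], "fill-opacity" = s$box_alpha,
                          stroke = "none"))
      for (j in side_ix[[B$species[[i]]]]) {
        sa <- stroke_attrs(S$style[[j]], s$styles)
        kids <- c(kids, tag("line",
          class = paste("box-side", paste0("style-", S$style[[j]])),
          "data-side" = S$side[[j]], "data-style" = S$style[[j]],
          x1 = S$x1[[j]], y1 = S$y1[[j]],
          x2 = S$x2[[j]], y2 = S$y2[[j]],
          stroke = B$color[[i]], "stroke-width" = sa$width,
          "stroke-dasharray" = sa$dash))
      }
      if (isTRUE(s$show_labels))
        kids <- c(kids, tag("text", class = "species-label",
                            x = B$x_center[[i]],
                            y = B$y_top[[i]] - 4, "text-anchor" = "middle",
                            "font-size" = s$font_species, fill = B$color[[i]],
                            "font-style" = "italic",
                            text = display_label(B$species[[i]])))
      boxes <- c(boxes, tag("g", class = "species-box",
                            "data-species" = B$species[[i]], children = kids))
    }
  }

  sp_br <- character()
  if (!is.null(lay$sp_branches)) {
    V <- as.list(lay$sp_branches[lay$sp_branches$visible, , drop = FALSE])
    bw <- style_for(s$default_species_style, s$styles)$stroke_width
    for (i in seq_along(V$parent)) {
      sp_br <- c(sp_br, tag("line", class = "species-branch",
        "data-parent" = V$parent[[i]], "data-child" = V$child[[i]],
        x1 = V$x1[[i]], y1 = V$y[[i]], x2 = V$x2[[i]], y2 = V$y[[i]],
        stroke = V$color[[i]], "stroke-width" = bw,
        "stroke-dasharray" = branch_dash(V$style[[i]])))
    }
  }

  phenons <- character()
  if (!is.null(lay$segments)) {
    G <- as.list(lay$segments)
    if (!is.null(lay$seg_runs)) {
      run_key <- paste(lay$seg_runs$phenon, lay$seg_runs$species, sep = "\r")
      run_ix <- split(seq_len(nrow(lay$seg_runs)), run_key)
      R <- as.list(lay$seg_runs)
    } else run_ix <- list()
    for (i in seq_along(G$phenon)) {
      kids <- character()
      if (nzchar(G$popup[[i]])) kids <- tag("title", text = G$popup[[i]])
      for (j in run_ix[[paste(G$phenon[[i]], G$species[[i]], sep = "\r")]]) {
        sa <- stroke_attrs(R$style[[j]], s$styles)
        kids <- c(kids, tag("line",
          class = paste("segment-run", paste0("style-", R$style[[j]])),
          "data-style" = R$style[[j]],
          x1 = R$x[[j]], y1 = R$y1[[j]],
          x2 = R$x[[j]], y2 = R$y2[[j]],
          stroke = R$color[[j]], "stroke-width" = sa$width,
          "stroke-dasharray" = sa$dash))
      }
      kids <- c(kids,
        draw_symbol(G$top_symbol[[i]], G$x[[i]], G$y_young[[i]],
                    s$guide_color, "top"),
        draw_symbol(G$base_symbol[[i]], G$x[[i]], G$y_old[[i]],
                    s$guide_color, "base"))
      if (isTRUE(s$show_images) && !is.null(s$images) &&
          G$phenon[[i]] %in% names(s$images)) {
        img <- s$images[[G$phenon[[i]]]]
        if (file.exists(img)) {
          kids <- c(kids, tag("image", class = "phenon-image", href = img,
                              x = G$x[[i]] - s$image_width / 2,
                              y = G$y_young[[i]] + 10,
                              width = s$image_width, height = s$image_width))
        } else {
          message("thumbnail not found, skipped: ", img)
        }
      }
      if (isTRUE(s$show_labels))
        kids <- c(kids, tag("text", class = "phenon-label", x = G$x[[i]],
                            y = G$y_young[[i]] - 3, "text-anchor" = "middle",
                            "font-size" = s$font_phenon, fill = G$color[[i]],
                            text = G$label[[i]]))
      phenons <- c(phenons, tag("g", class = "phenon-segment",
                                "data-phenon" = G$phenon[[i]],
                                "data-species" = G$species[[i]],
                                children = kids))
    }
  }

  ph_br <- character()
  if (!is.null(lay$ph_connectors)) {
    bw <- style_for(s$default_phenon_style, s$styles)$stroke_width
    C <- as.list(lay$ph_connectors)
    for (i in seq_along(C$parent)) {
      ph_br <- c(ph_br, tag("line", class = "phenon-branch",
        "data-parent" = C$parent[[i]], "data-child" = C$child[[i]],
        x1 = C$x1[[i]], y1 = C$y[[i]], x2 = C$x2[[i]], y2 = C$y[[i]],
        stroke = "#444444", "stroke-width" = bw))
    }
  }

  svg_doc(lay, c(
    tag("desc", text = "integrated species-phenon tree"),
    draw_bands(lay),
    draw_axis(lay),
    tag("g", class = "species-boxes", children = boxes),
    tag("g", class = "species-branches", children = sp_br),
    tag("g", class = "phenon-layer", children = phenons),
    tag("g", class = "phenon-branches", children = ph_br)))
}

#' Render a plain component tree as SVG
#'
#' Classic range-line chart for one tree on its own (no species boxes):
#' one group per range holding its vertical style-run lines and label,
#' plus horizontal branch connectors. Used for side-by-side comparison
#' with the integrated chart.
#'
#' @param tree an `evo_tree`.
#' @param settings `chart_settings`.
#' @param kind `"species"` or `"phenon"`.
#' @return SVG document text.
#' @export
render_component_tree <- function(tree, settings = chart_settings(),
                                  kind = c("species", "phenon")) {
  kind <- match.arg(kind)
  lay <- layout_component_tree(tree, settings, kind)
  s <- settings
  font <- if (kind == "species") s$font_species else s$font_phenon
  ranges <- character()
  if (!is.null(lay$ranges)) {
    for (i in seq_len(nrow(lay$ranges))) {
      r <- lay$ranges[i, ]
      kids <- character()
      if (nzchar(r$popup)) kids <- tag("title", text = r$popup)
      runs <- lay$range_runs[lay$range_runs$name == r$name, ]
      for (j in seq_len(nrow(runs))) {
        sa <- stroke_attrs(runs$style[[j]], s$styles)
        kids <- c(kids, tag("line",
          class = paste("range-run", paste0("style-", runs$style[[j]])),
          x1 = runs$x[[j]], y1 = runs$y1[[j]],
          x2 = runs$x[[j]], y2 = runs$y2[[j]],
          stroke = runs$color[[j]], "stroke-width" = sa$width,
          "stroke-dasharray" = sa$dash))
      }
      if (r$still_living)
        kids <- c(kids, draw_symbol("RANGE_TOP_LIVING", r$x, r$y_young,
                                    s$guide_color, "top"))
      kids <- c(kids, tag("text", class = "range-label", x = r$x,
                          y = r$y_young - 3, "text-anchor" = "middle",
                          "font-size" = font, fill = r$color, text = r$label))
      ranges <- c(ranges, tag("g", class = "range", "data-name" = r$name,
                              children = kids))
    }
  }
  branches <- character()
  if (!is.null(lay$branches)) {
    vis <- lay$branches[lay$branches$visible, , drop = FALSE]
    bw <- style_for(if (kind == "species") s$default_species_style else
      s$default_phenon_style, s$styles)$stroke_width
    for (i in seq_len(nrow(vis))) {
      br <- vis[i, ]
      branches <- c(branches, tag("line", class = "branch",
        "data-parent" = br$parent, "data-child" = br$child,
        x1 = br$x1, y1 = br$y, x2 = br$x2, y2 = br$y,
        stroke = br$color, "stroke-width" = bw,
        "stroke-dasharray" = branch_dash(br$style)))
    }
  }
  svg_doc(lay, c(
    tag("desc", text = paste(kind, "tree")),
    draw_bands(lay),
    draw_axis(lay),
    tag("g", class = "ranges", children = ranges),
    tag("g", class = "branches", children = branches)))
}

#' One-shot chart from a datapack
#'
#' Convenience wrapper: build the trees, compute the relationship map,
#' lay out and render.
#'
#' @param pack `datapack`.
#' @param settings `chart_settings`.
#' @param mode `"integrated"` (default), `"species"` or `"phenon"`.
#' @return SVG document text.
#' @export
phenon_chart <- function(pack, settings = chart_settings(),
                         mode = c("integrated", "species", "phenon")) {
  mode <- match.arg(mode)
  trees <- build_trees(pack)
  if (mode == "species")
    return(render_component_tree(trees$species, settings, "species"))
  if (mode == "phenon")
    return(render_component_tree(trees$phenon, settings, "phenon"))
  map <- compute_relationship_map(trees$species, trees$phenon,
                                  mode = settings$ordering,
                                  default_phenon_style = settings$default_phenon_style,
                                  default_color = settings$default_color)
  render_chart(position_chart(trees$species, trees$phenon, map, settings))
}

#' Build the trees and relationship map in one call
#'
#' @param pack `datapack`.
#' @param mode within-box ordering, see [compute_relationship_map()].
#' @return list with `species_tree`, `phenon_tree`, `map`.
#' @export
integrate_trees <- function(pack, mode = c("first", "last", "alphabetic")) {
  mode <- match.arg(mode)
  trees <- build_trees(pack)
  list(species_tree = trees$species, phenon_tree = trees$phenon,
       map = compute_relationship_map(trees$species, trees$phenon, mode = mode))
}

#' Measure styled border runs of a rendered species box
#'
#' Parses an emitted SVG document and, for the given species box,
#' returns every border element with its side, style token, and
#' age-extent recovered from the drawn geometry through the document's
#' recorded age map. This audits the rendered output itself rather than
#' the layout that produced it.
#'
#' @param svg SVG document text from [render_chart()].
#' @param species species name.
#' @return data.frame with columns `side`, `style`, `y1`, `y2`,
#'   `age_old`, `age_young`, `myr` (the run's drawn extent in Myr).
#' @export
svg_side_style_extents <- function(svg, species) {
  doc <- xml2::read_xml(svg)
  xml2::xml_ns_strip(doc)
  upm <- as.numeric(xml2::xml_attr(doc, "data-units-per-myr"))
  young <- as.numeric(xml2::xml_attr(doc, "data-window-young"))
  mtop <- as.numeric(xml2::xml_attr(doc, "data-margin-top"))
  to_age <- function(y) (y - mtop) / upm + young
  nodes <- xml2::xml_find_all(doc, sprintf(
    "//g[@class='species-box' and @data-species='%s']/line", species))
  if (length(nodes) == 0)
    stop("no rendered box for species '", species, "'", call. = FALSE)
  y1 <- as.numeric(xml2::xml_attr(nodes, "y1"))
  y2 <- as.numeric(xml2::xml_attr(nodes, "y2"))
  data.frame(
    side = xml2::xml_attr(nodes, "data-side"),
    style = xml2::xml_attr(nodes, "data-style"),
    y1 = y1, y2 = y2,
    age_old = to_age(pmax(y1, y2)),
    age_young = to_age(pmin(y1, y2)),
    myr = abs(y1 - y2) / upm,
    stringsAsFactors = FALSE)
}
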