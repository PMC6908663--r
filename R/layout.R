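# Collision-free horizontal positioning. Each species subtree occupies a
# half-open x interval: the species' own box sits leftmost, its child
# subtrees follow to the right in authored branch order, separated by
# gaps. Vertically, ages map linearly onto the canvas with the young end
# of the plotted window at the top and age increasing downward.

# width of one phenon slot inside a box
slot_width <- function(seg, settings) {
  w <- max(label_width(seg$label_display, settings$font_phenon,
                       settings$label_char_factor),
           settings$min_slot_width)
  if (isTRUE(settings$show_images) &&
      !is.null(settings$images) && seg$phenon %in% names(settings$images))
    w <- max(w, settings$image_width)
  w
}

#' Inner width of a species box
#'
#' The width of a species box depends on the phenon ranges inside it:
#' the sum over phenon slots of max(label width estimate, image width if
#' shown, minimum slot width), plus inter-slot gaps and padding on both
#' sides. A species box without phenon ranges gets the configured
#' minimum width.
#'
#' @param group ordered list of `phenon_segment` (one slot each), e.g.
#'   one element of a relationship map's `groups`.
#' @param settings `chart_settings`.
#' @return width in canvas units.
#' @export
box_inner_width <- function(group, settings) {
  n <- length(group)
  if (n == 0) return(settings$min_box_width)
  slots <- vapply(group, slot_width, numeric(1), settings = settings)
  sum(slots) + (n - 1) * settings$gap_slot + 2 * settings$box_padding
}

# full box width: inner width floored by the minimum and the species'
# own label
box_width_for <- function(species, map, settings) {
  inner <- box_inner_width(map$groups[[species]], settings)
  max(inner, settings$min_box_width,
      label_width(display_label(species), settings$font_species,
                  settings$label_char_factor) + 2 * settings$box_padding)
}

#' Recursive subtree width
#'
#' Width of the subtree rooted at `node`: the node's own box width plus
#' each child subtree's width, separated by the configured gap, with the
#' parent box placed leftmost. Recomputing widths from final positions
#' reproduces the same values (the recursion is its own fixpoint).
#'
#' @param species_tree species `evo_tree`.
#' @param node species name.
#' @param box_widths named numeric vector of per-species box widths.
#' @param settings `chart_settings`.
#' @return width in canvas units.
#' @export
subtree_width <- function(species_tree, node, box_widths, settings) {
  kids <- species_tree$children[[node]]
  w <- unname(box_widths[[node]])
  for (ch in kids) w <- w + settings$gap_subtree +
      subtree_width(species_tree, ch, box_widths, settings)
  w
}

age_window <- function(species_tree, phenon_tree, settings) {
  if (!is.null(settings$window)) return(unname(settings$window))
  bases <- c(vapply(species_tree$ranges, base_age, numeric(1)),
             vapply(phenon_tree$ranges, base_age, numeric(1)))
  if (length(bases) == 0) return(c(10, 0))
  c(ceiling(max(bases)), 0)
}

#' Age-to-canvas mapping
#'
#' Linear vertical map: the young end of the plotted window is at the
#' top margin and age increases downward at `units_per_myr` per Myr.
#'
#' @param layout a `chart_layout` (or any list with `settings` and
#'   `window`).
#' @param age age(s) in Ma.
#' @param y canvas y coordinate(s).
#' @return numeric vector.
#' @export
age_to_y <- function(layout, age) {
  layout$settings$margin[["top"]] +
    (age - layout$window[[2]]) * layout$settings$units_per_myr
}

#' @rdname age_to_y
#' @export
y_to_age <- function(layout, y) {
  (y - layout$settings$margin[["top"]]) / layout$settings$units_per_myr +
    layout$window[[2]]
}

#' Position the integrated chart
#'
#' Computes collision-free positions for every species box, the phenon
#' segments inside each box (slot order following the map's group
#' order), the species branch connectors, and the in-box phenon branch
#' connectors. Sibling subtree x extents are disjoint; a phenon split
#' across boxes gets one x per box.
#'
#' @param species_tree,phenon_tree the two `evo_tree`s.
#' @param map `relationship_map` from [compute_relationship_map()].
#' @param settings `chart_settings`.
#' @return object of class `chart_layout` with components `boxes`,
#'   `box_sides`, `segments`, `seg_runs`, `sp_branches`,
#'   `ph_connectors`, `window`, `width`, `height`, `settings`.
#' @export
position_chart <- function(species_tree, phenon_tree, map,
                           settings = chart_settings()) {
  window <- age_window(species_tree, phenon_tree, settings)
  lay <- list(settings = settings, window = window)
  y <- function(age) age_to_y(lay, age)
  sp_colors <- resolve_colors(species_tree, default = settings$default_color)

  box_widths <- setNames(
    vapply(map$species_order, box_width_for, numeric(1),
           map = map, settings = settings),
    map$species_order)

  boxes <- list(); box_sides <- list(); segments <- list()
  seg_runs <- list(); sp_branches <- list(); ph_connectors <- list()

  place_box <- function(sp, x0) {
    bw <- box_widths[[sp]]
    r <- species_tree$ranges[[sp]]
    yb <- y(base_age(r)); yt <- y(top_age(r))
    boxes[[sp]] <<- data.frame(
      species = sp, x_left = x0, x_right = x0 + bw, x_center = x0 + bw / 2,
      y_top = yt, y_bottom = yb, base_age = base_age(r),
      top_age = top_age(r), color = unname(sp_colors[[sp]]),
      still_living = isTRUE(r$still_living), popup = r$popup,
      stringsAsFactors = FALSE)
    runs <- style_segments(r, default = settings$default_species_style)
    nr <- nrow(runs)
    # vertical runs on both sides, then the horizontal base/top edges,
    # which carry the style in force at that end of the range
    box_sides[[sp]] <<- data.frame(
      species = sp,
      side = c(rep(c("left", "right"), each = nr), "base", "top"),
      style = c(runs$style, runs$style, runs$style[[1]], runs$style[[nr]]),
      x1 = c(rep(x0, nr), rep(x0 + bw, nr), x0, x0),
      y1 = c(y(runs$old), y(runs$old), yb, yt),
      x2 = c(rep(x0, nr), rep(x0 + bw, nr), x0 + bw, x0 + bw),
      y2 = c(y(runs$young), y(runs$young), yb, yt),
      age_old = c(runs$old, runs$old, base_age(r), top_age(r)),
      age_young = c(runs$young, runs$young, base_age(r), top_age(r)),
      stringsAsFactors = FALSE)

    # phenon slots, left to right in group order
    group <- map$groups[[sp]]
    xcur <- x0 + settings$box_padding
    slot_x <- numeric(0)
    for (k in seq_along(group)) {
      seg <- group[[k]]
      sw <- slot_width(seg, settings)
      xs <- xcur + sw / 2
      slot_x[seg$phenon] <- xs
      segments[[length(segments) + 1L]] <<- data.frame(
        phenon = seg$phenon, species = sp, x = xs,
        old_age = seg$old_age, young_age = seg$young_age,
        y_old = y(seg$old_age), y_young = y(seg$young_age),
        top_symbol = seg$top_symbol, base_symbol = seg$base_symbol,
        color = seg$color, label = seg$label_display,
        popup = seg$popup, still_living = seg$still_living,
        stringsAsFactors = FALSE)
      st <- seg$styles
      if (nrow(st) > 0)
        seg_runs[[length(seg_runs) + 1L]] <<- data.frame(
          phenon = seg$phenon, species = sp, x = xs,
          old = st$old, young = st$young, style = st$style,
          y1 = y(st$old), y2 = y(st$young), color = seg$color,
          stringsAsFactors = FALSE)
      xcur <- xcur + sw + settings$gap_slot
    }
    # in-box phenon-tree connectors
    if (length(group) > 1) {
      b <- phenon_tree$branches
      for (seg in group) {
        p <- phenon_tree$parent[seg$phenon]
        if (length(p) == 0 || is.na(p)) next
        p <- unname(p)
        if (!(p %in% names(slot_x))) next
        age <- b$age[b$child == seg$phenon][[1]]
        r_iv <- map$species_intervals[map$species_intervals$species == sp, ]
        if (age >= r_iv$top - .AGE_TOL && age <= r_iv$base + .AGE_TOL)
          ph_connectors[[length(ph_connectors) + 1L]] <<- data.frame(
            species = sp, parent = p, child = seg$phenon, age = age,
            x1 = unname(slot_x[[p]]), x2 = unname(slot_x[[seg$phenon]]),
            y = y(age), stringsAsFactors = FALSE)
      }
    }
    invisible(bw)
  }

  place_subtree <- function(sp, x0) {
    bw <- place_box(sp, x0)
    xcur <- x0 + bw
    for (ch in species_tree$children[[sp]]) {
      xcur <- xcur + settings$gap_subtree
      cw <- subtree_width(species_tree, ch, box_widths, settings)
      place_subtree(ch, xcur)
      b <- species_tree$branches
      bi <- which(b$child == ch)[[1]]
      sp_branches[[length(sp_branches) + 1L]] <<- data.frame(
        parent = sp, child = ch, age = b$age[[bi]],
        x1 = boxes[[sp]]$x_right, x2 = boxes[[ch]]$x_center,
        y = y(b$age[[bi]]), style = b$style[[bi]],
        color = unname(sp_colors[[ch]]), visible = b$visible[[bi]],
        popup = b$popup[[bi]], label = b$label[[bi]],
        stringsAsFactors = FALSE)
      xcur <- xcur + cw
    }
  }

  roots <- species_tree$roots
  if (length(roots) > 1) {
    bases <- vapply(roots, function(r) base_age(species_tree$ranges[[r]]),
                    numeric(1))
    roots <- roots[order(-bases, method = "radix")]
  }
  x0 <- settings$margin[["left"]] + settings$axis_width
  for (r in roots) {
    place_subtree(r, x0)
    x0 <- x0 + subtree_width(species_tree, r, box_widths, settings) +
      settings$gap_subtree
  }
  content_right <- if (length(boxes)) x0 - settings$gap_subtree else x0

  bind <- function(l) if (length(l)) do.call(rbind, c(l, make.row.names = FALSE)) else NULL
  lay$boxes <- bind(unname(boxes))
  lay$box_sides <- bind(unname(box_sides))
  lay$segments <- bind(segments)
  lay$seg_runs <- bind(seg_runs)
  lay$sp_branches <- bind(sp_branches)
  lay$ph_connectors <- bind(ph_connectors)
  lay$width <- content_right + settings$margin[["right"]]
  lay$height <- age_to_y(lay, window[[1]]) + settings$margin[["bottom"]]
  class(lay) <- "chart_layout"
  lay
}

#' Position a plain component tree
#'
#' Classic range-line layout (no boxes) for a species or phenon tree on
#' its own: vertical range lines with per-interval styles, horizontal
#' branch connectors, labels at range tops. Uses the same subtree-width
#' recursion as the integrated chart with each range's slot sized to its
#' label.
#'
#' @param tree an `evo_tree`.
#' @param settings `chart_settings`.
#' @param kind `"species"` or `"phenon"`; selects the default line style
#'   and label font.
#' @return `chart_layout`-like object with `ranges`, `range_runs`,
#'   `branches`, `window`, `width`, `height`, `settings`.
#' @export
layout_component_tree <- function(tree, settings = chart_settings(),
                                  kind = c("species", "phenon")) {
  kind <- match.arg(kind)
  font <- if (kind == "species") settings$font_species else settings$font_phenon
  default_style <- if (kind == "species") settings$default_species_style else
    settings$default_phenon_style
  window <- if (!is.null(settings$window)) unname(settings$window) else {
    bases <- vapply(tree$ranges, base_age, numeric(1))
    if (length(bases) == 0) c(10, 0) else c(ceiling(max(bases)), 0)
  }
  lay <- list(settings = settings, window = window)
  y <- function(age) age_to_y(lay, age)
  colors <- resolve_colors(tree, default = settings$default_color)
  widths <- setNames(vapply(names(tree$ranges), function(n)
    max(label_width(display_label(n), font, settings$label_char_factor),
        settings$min_slot_width), numeric(1)), names(tree$ranges))

  ranges <- list(); runs <- list(); branches <- list()
  place <- function(n, x0) {
    w <- widths[[n]]
    xc <- x0 + w / 2
    r <- tree$ranges[[n]]
    ranges[[n]] <<- data.frame(
      name = n, x = xc, base_age = base_age(r), top_age = top_age(r),
      y_old = y(base_age(r)), y_young = y(top_age(r)),
      color = unname(colors[[n]]), label = display_label(n),
      still_living = isTRUE(r$still_living), popup = r$popup,
      stringsAsFactors = FALSE)
    st <- style_segments(r, default = default_style)
    runs[[n]] <<- data.frame(name = n, x = xc, old = st$old, young = st$young,
                             style = st$style, y1 = y(st$old), y2 = y(st$young),
                             color = unname(colors[[n]]),
                             stringsAsFactors = FALSE)
    xcur <- x0 + w
    for (ch in tree$children[[n]]) {
      xcur <- xcur + settings$gap_subtree
      cw <- sub_w(ch)
      place(ch, xcur)
      b <- tree$branches
      bi <- which(b$child == ch)[[1]]
      branches[[length(branches) + 1L]] <<- data.frame(
        parent = n, child = ch, age = b$age[[bi]],
        x1 = xc, x2 = ranges[[ch]]$x, y = y(b$age[[bi]]),
        style = b$style[[bi]], color = unname(colors[[ch]]),
        visible = b$visible[[bi]], stringsAsFactors = FALSE)
      xcur <- xcur + cw
    }
  }
  sub_w <- function(n) {
    w <- widths[[n]]
    for (ch in tree$children[[n]]) w <- w + settings$gap_subtree + sub_w(ch)
    w
  }
  roots <- tree$roots
  if (length(roots) > 1) {
    key <- switch(settings$ordering,
      first = -vapply(roots, function(r) base_age(tree$ranges[[r]]), numeric(1)),
      last = vapply(roots, function(r) top_age(tree$ranges[[r]]), numeric(1)),
      alphabetic = tolower(display_label(roots)))
    roots <- roots[order(key, method = "radix")]
  }
  x0 <- settings$margin[["left"]] + settings$axis_width
  for (r in roots) {
    place(r, x0)
    x0 <- x0 + sub_w(r) + settings$gap_subtree
  }
  content_right <- if (length(ranges)) x0 - settings$gap_subtree else x0
  bind <- function(l) if (length(l)) do.call(rbind, c(l, make.row.names = FALSE)) else NULL
  lay$kind <- kind
  lay$ranges <- bind(unname(ranges))
  lay$range_runs <- bind(unname(runs))
  lay$branches <- bind(branches)
  lay$width <- content_right + settings$margin[["right"]]
  lay$height <- age_to_y(lay, window[[1]]) + settings$margin[["bottom"]]
  class(lay) <- "chart_layout"
  lay
}
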