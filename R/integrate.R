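# The integration algorithm: walk each phenon range rootward along the
# ancestral chain of its terminal species, cutting the range at every
# species origination age that falls strictly inside it, and collect the
# resulting segments into a one-to-many species -> phenon relationship
# map. Guide-symbol annotations distinguish true range ends from the
# artificial breaks.

SYM_RANGE_TOP_EXTINCT <- "RANGE_TOP_EXTINCT"
SYM_RANGE_TOP_LIVING <- "RANGE_TOP_LIVING"
SYM_BROKEN_TOP <- "BROKEN_TOP"
SYM_RANGE_ORIGIN <- "RANGE_ORIGIN"
SYM_BROKEN_BASE <- "BROKEN_BASE"

#' Ancestral chain of a species
#'
#' @param species_tree species `evo_tree`.
#' @param species range name.
#' @return character vector `[species, parent, grandparent, ...]` up to
#'   the root of its forest component.
#' @export
ancestral_chain <- function(species_tree, species) {
  if (!(species %in% names(species_tree$ranges)))
    stop("unknown species '", species, "'", call. = FALSE)
  chain <- species
  cur <- species
  repeat {
    p <- species_tree$parent[cur]
    if (length(p) == 0 || is.na(p)) break
    cur <- unname(p)
    chain <- c(chain, cur)
  }
  chain
}

new_phenon_segment <- function(phenon, species, old_age, young_age,
                               top_symbol, base_symbol, styles,
                               popup = "", color = NA_character_,
                               still_living = FALSE, label_full = phenon) {
  s <- list(phenon = phenon, species = species,
            old_age = old_age, young_age = young_age,
            top_symbol = top_symbol, base_symbol = base_symbol,
            styles = styles, popup = popup, color = color,
            still_living = still_living,
            label_full = label_full,
            label_display = split_display_label(label_full)$display)
  class(s) <- "phenon_segment"
  s
}

#' Split a phenon range across its chain of species boxes
#'
#' Starting from the phenon's TOP (LAD) inside its terminal species, the
#' range is walked rootward along [ancestral_chain()]. Whenever the
#' current species' base age (its origination / branch-connection age)
#' is younger than the phenon's remaining extent, the range is cut
#' there: the part already covered stays in the current species with a
#' `BROKEN_BASE` mark, and the rest transfers to the parent species box
#' with a matching `BROKEN_TOP` at the same age. The oldest segment
#' carries `RANGE_ORIGIN`; the youngest carries `RANGE_TOP_LIVING` or
#' `RANGE_TOP_EXTINCT`. Style intervals, pop-up text, and labels are
#' duplicated onto every segment (styles re-cut at the break ages).
#'
#' A phenon whose base age coincides with a species origination age puts
#' its origin in that species' box (no zero-length segment rootward of
#' it). A phenon TOP at or above the terminal species' base age, or
#' below its top age, is the error "phenon ends outside its species"; a
#' phenon base older than the chain root's base age is "phenon predates
#' root species".
#'
#' @param phenon a phenon `taxon_range` with `terminal_species` set.
#' @param species_tree species `evo_tree` containing that species.
#' @param default_style style token for unspecified intervals of the
#'   phenon (the phenon default, normally "common").
#' @param tol absolute age tolerance in Ma.
#' @return list of `phenon_segment`, youngest first.
#' @export
split_phenon <- function(phenon, species_tree, default_style = "common",
                         tol = .AGE_TOL) {
  stopifnot(inherits(phenon, "taxon_range"))
  if (!isTRUE(phenon$is_phenon) || is.na(phenon$terminal_species))
    stop("range '", phenon$name, "' is not a phenon with a terminal species",
         call. = FALSE)
  chain <- ancestral_chain(species_tree, phenon$terminal_species)
  term <- species_tree$ranges[[chain[[1]]]]
  p_top <- top_age(phenon)
  p_base <- base_age(phenon)
  if (p_top < top_age(term) - tol || p_top >= base_age(term) - tol)
    stop(sprintf(
      "phenon '%s' ends outside its species: TOP %g Ma not within ['%s' %g-%g Ma)",
      phenon$name, p_top, term$name, top_age(term), base_age(term)),
      call. = FALSE)
  root_base <- base_age(species_tree$ranges[[chain[[length(chain)]]]])
  if (p_base > root_base + tol)
    stop(sprintf(
      "phenon '%s' predates root species: BASE %g Ma older than root '%s' FAD %g Ma",
      phenon$name, p_base, chain[[length(chain)]], root_base), call. = FALSE)

  styles <- style_segments(phenon, default = default_style)
  segs <- list()
  cur_top <- p_top
  i <- 1L
  repeat {
    host <- chain[[i]]
    host_base <- base_age(species_tree$ranges[[host]])
    if (p_base > host_base + tol) {
      # range continues past this species' origin: cut and transfer
      if (host_base > cur_top + tol)
        segs[[length(segs) + 1L]] <- list(species = host, old = host_base,
                                          young = cur_top)
      cur_top <- max(cur_top, host_base)
      i <- i + 1L
    } else {
      segs[[length(segs) + 1L]] <- list(species = host, old = p_base,
                                        young = cur_top)
      break
    }
  }
  n <- length(segs)
  lapply(seq_len(n), function(k) {
    s <- segs[[k]]
    new_phenon_segment(
      phenon = phenon$name, species = s$species,
      old_age = s$old, young_age = s$young,
      top_symbol = if (k == 1L) {
        if (isTRUE(phenon$still_living)) SYM_RANGE_TOP_LIVING else SYM_RANGE_TOP_EXTINCT
      } else SYM_BROKEN_TOP,
      base_symbol = if (k == n) SYM_RANGE_ORIGIN else SYM_BROKEN_BASE,
      styles = clip_styles(styles, s$old, s$young, tol = tol),
      popup = phenon$popup, still_living = isTRUE(phenon$still_living),
      label_full = phenon$name
    )
  })
}

# deterministic pre-order of an evo_tree: roots in First-Occurrence
# order (oldest base age first, stable), children in authored branch order
preorder_names <- function(tree) {
  roots <- tree$roots
  if (length(roots) > 1) {
    bases <- vapply(roots, function(r) base_age(tree$ranges[[r]]), numeric(1))
    roots <- roots[order(-bases, method = "radix")]
  }
  out <- character()
  walk <- function(n) {
    out <<- c(out, n)
    for (ch in tree$children[[n]]) walk(ch)
  }
  for (r in roots) walk(r)
  out
}

#' Compute the species-phenon relationship map
#'
#' Runs [split_phenon()] for every phenon and groups the resulting
#' segments by host species. Species are indexed by a deterministic
#' pre-order traversal of the species tree (forest roots in
#' First-Occurrence order); within each species box, members are ordered
#' by [order_group()] applied to the box's disconnected subtrees.
#' Relationship ids are `"<speciesIndex>-<memberIndex>"`, strictly
#' sequential within a species. Species with no phena get an empty
#' group.
#'
#' @param species_tree,phenon_tree the two `evo_tree`s from
#'   [build_trees()].
#' @param mode within-box ordering: `"first"`, `"last"` or
#'   `"alphabetic"`.
#' @param default_phenon_style style token for unspecified phenon
#'   intervals.
#' @param default_color colour for uncoloured lineages.
#' @param tol absolute age tolerance in Ma.
#' @return object of class `relationship_map`: `species_order` (indexed
#'   species names), `entries` (data.frame `id`, `species`, `phenon`,
#'   `old_age`, `young_age`), `groups` (species -> ordered list of
#'   `phenon_segment`), `segments` (species -> segments in phenon
#'   traversal order, for regrouping), `species_intervals`, `mode`.
#' @export
compute_relationship_map <- function(species_tree, phenon_tree,
                                     mode = c("first", "last", "alphabetic"),
                                     default_phenon_style = "common",
                                     default_color = "#000000",
                                     tol = .AGE_TOL) {
  mode <- match.arg(mode)
  colors <- resolve_colors(phenon_tree, default = default_color)
  species_order <- preorder_names(species_tree)
  phenon_order <- preorder_names(phenon_tree)
  segments <- setNames(vector("list", length(species_order)), species_order)
  failures <- character()
  for (ph in phenon_order) {
    segs <- tryCatch(
      split_phenon(phenon_tree$ranges[[ph]], species_tree,
                   default_style = default_phenon_style, tol = tol),
      error = function(e) conditionMessage(e))
    if (is.character(segs)) {
      failures <- c(failures, segs)
      next
    }
    for (s in segs) {
      s$color <- unname(colors[[ph]])
      segments[[s$species]] <- c(segments[[s$species]], list(s))
    }
  }
  if (length(failures))
    stop("phenon integration failed:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  intervals <- do.call(rbind, lapply(species_order, function(sp) {
    r <- species_tree$ranges[[sp]]
    data.frame(species = sp, base = base_age(r), top = top_age(r),
               stringsAsFactors = FALSE)
  }))
  map <- structure(
    list(species_order = species_order, segments = segments,
         species_intervals = intervals, mode = mode,
         groups = NULL, entries = NULL),
    class = "relationship_map")
  groups <- list()
  entries <- list()
  for (si in seq_along(species_order)) {
    sp <- species_order[[si]]
    subtrees <- subtrees_in_box(map, phenon_tree, sp)
    ordered <- order_group(subtrees, mode = mode)
    members <- do.call(c, c(list(list()), ordered))
    groups[[sp]] <- members
    if (length(members))
      entries[[sp]] <- data.frame(
        id = sprintf("%d-%d", si, seq_along(members)),
        species = sp,
        phenon = vapply(members, `[[`, character(1), "phenon"),
        old_age = vapply(members, `[[`, numeric(1), "old_age"),
        young_age = vapply(members, `[[`, numeric(1), "young_age"),
        stringsAsFactors = FALSE)
  }
  map$groups <- groups
  map$entries <- if (length(entries)) do.call(rbind, c(entries, make.row.names = FALSE)) else
    data.frame(id = character(), species = character(), phenon = character(),
               old_age = numeric(), young_age = numeric(),
               stringsAsFactors = FALSE)
  map
}

#' Disconnected phenon subtrees within one species box
#'
#' The break-up of phenon ranges disrupts the phenon tree, leaving each
#' species box with a forest of segment subtrees. Two segments in the
#' same box are connected exactly when the phenon tree has a branch
#' between their phena whose branch-point age lies inside the box's time
#' extent; every other segment roots its own (possibly singleton)
#' subtree.
#'
#' @param map a `relationship_map` (its raw per-species segments are
#'   regrouped; ordering is not consulted).
#' @param phenon_tree the phenon `evo_tree`.
#' @param species species name.
#' @return list of subtrees; each subtree is a list of `phenon_segment`
#'   in pre-order (root first, children in authored branch order).
#' @export
subtrees_in_box <- function(map, phenon_tree, species) {
  segs <- map$segments[[species]]
  if (is.null(segs) || length(segs) == 0) return(list())
  iv <- map$species_intervals
  iv <- iv[iv$species == species, ]
  in_box <- setNames(seq_along(segs),
                     vapply(segs, `[[`, character(1), "phenon"))
  # in-box parent: phenon-tree parent hosted here with branch age inside box
  has_parent <- vapply(names(in_box), function(ph) {
    p <- phenon_tree$parent[ph]
    if (length(p) == 0 || is.na(p)) return(FALSE)
    if (!(unname(p) %in% names(in_box))) return(FALSE)
    b <- phenon_tree$branches
    age <- b$age[b$child == ph][[1]]
    age >= iv$top - .AGE_TOL && age <= iv$base + .AGE_TOL
  }, logical(1))
  roots <- names(in_box)[!has_parent]
  walk <- function(ph) {
    out <- list(segs[[in_box[[ph]]]])
    for (ch in phenon_tree$children[[ph]]) {
      if (ch %in% names(in_box) && has_parent[[ch]])
        out <- c(out, walk(ch))
    }
    out
  }
  lapply(roots, walk)
}

#' Order a box's subtrees
#'
#' Stable sort of subtree roots: First Occurrence puts the oldest base
#' age first, Last Occurrence the youngest top age first, Alphabetic
#' sorts case-insensitively on the root's display label. Ties preserve
#' input order; each subtree keeps its internal pre-order.
#'
#' @param subtrees list of subtrees as from [subtrees_in_box()] (a bare
#'   list of `phenon_segment`s is treated as singleton subtrees).
#' @param mode `"first"`, `"last"` or `"alphabetic"`.
#' @return the subtrees, reordered.
#' @export
order_group <- function(subtrees, mode = c("first", "last", "alphabetic")) {
  mode <- match.arg(mode)
  if (length(subtrees) == 0) return(subtrees)
  subtrees <- lapply(subtrees, function(s)
    if (inherits(s, "phenon_segment")) list(s) else s)
  key <- switch(mode,
    first = -vapply(subtrees, function(s)
      max(vapply(s, `[[`, numeric(1), "old_age")), numeric(1)),
    last = vapply(subtrees, function(s)
      min(vapply(s, `[[`, numeric(1), "young_age")), numeric(1)),
    alphabetic = tolower(vapply(subtrees, function(s)
      s[[1]]$label_display, character(1)))
  )
  subtrees[order(key, method = "radix")]
}

#' Export the relationship map as a table
#'
#' One row per species-phenon relationship, mirroring the one-to-many
#' map: relationship id, species name, phenon group size, phenon name,
#' and the relation rendered as `species <- phenon`. Ids are strictly
#' sequential within each species group.
#'
#' @param map a `relationship_map`.
#' @param path optional file; when given the table is written as
#'   tab-delimited text with a header.
#' @return data.frame with columns `relationship_id`, `species`,
#'   `group_size`, `phenon`, `relation`.
#' @export
relationship_table <- function(map, path = NULL) {
  e <- map$entries
  sizes <- vapply(map$groups, length, integer(1))
  tab <- data.frame(
    relationship_id = e$id,
    species = e$species,
    group_size = unname(sizes[e$species]),
    phenon = e$phenon,
    relation = sprintf("%s ← %s", e$species, e$phenon),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  tab
}

#' @export
print.relationship_map <- function(x, ...) {
  sizes <- vapply(x$groups, length, integer(1))
  cat(sprintf("<relationship_map> %d species, %d phenon segments (%s ordering)\n",
              length(x$species_order), nrow(x$entries), x$mode))
  for (i in seq_along(x$species_order)) {
    sp <- x$species_order[[i]]
    g <- x$groups[[sp]]
    cat(sprintf("  %d %-12s [%d] %s\n", i, sp, sizes[[sp]],
                paste(vapply(g, `[[`, character(1), "phenon"), collapse = ", ")))
  }
  invisible(x)
}
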