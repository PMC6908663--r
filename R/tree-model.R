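# Validated species/phenon tree structures (forests) built from datapack
# rows. A taxon range is an ordered (old -> young) list of dated points;
# an evo_tree is a forest of ranges connected by dated branches.

base_age <- function(range) range$points$age[[1]]
top_age <- function(range) range$points$age[[nrow(range$points)]]

new_taxon_range <- function(name, points, is_phenon, terminal_species,
                            popup = "") {
  r <- list(
    name = name,
    points = points,            # data.frame(age, abundance, popup), old -> young
    is_phenon = is_phenon,
    terminal_species = terminal_species,
    still_living = points$age[[nrow(points)]] <= .AGE_TOL,
    popup = popup
  )
  class(r) <- "taxon_range"
  r
}

new_evo_tree <- function(ranges, branches) {
  parent <- setNames(branches$parent, branches$child)
  children <- lapply(setNames(nm = names(ranges)), function(n)
    branches$child[branches$parent == n])
  roots <- names(ranges)[!(names(ranges) %in% branches$child)]
  t <- list(ranges = ranges, branches = branches, parent = parent,
            children = children, roots = roots)
  class(t) <- "evo_tree"
  t
}

#' @export
print.evo_tree <- function(x, ...) {
  cat(sprintf("<evo_tree> %d ranges, %d branches, %d root(s)\n",
              length(x$ranges), nrow(x$branches), length(x$roots)))
  invisible(x)
}

empty_branches <- function() {
  data.frame(parent = character(), child = character(), age = numeric(),
             label = character(), style = character(), popup = character(),
             color = character(), visible = logical(), priority = character(),
             stringsAsFactors = FALSE)
}

# collect point and branch tables from parsed rows
collect_rows <- function(pack) {
  kinds <- vapply(pack$rows, `[[`, character(1), "kind")
  cellmat <- function(rows, n) {
    # rows' cells as a character matrix, padded with ""
    m <- matrix("", nrow = length(rows), ncol = n)
    for (i in seq_along(rows)) {
      cs <- rows[[i]]$cells
      k <- min(length(cs), n)
      if (k > 0) m[i, seq_len(k)] <- cs[seq_len(k)]
    }
    m
  }
  br_rows <- pack$rows[kinds == ROW_BRANCH]
  if (length(br_rows)) {
    m <- cellmat(br_rows, 10)
    brs <- data.frame(
      parent = trimws(m[, 1]), child = trimws(m[, 4]),
      age = as.numeric(trimws(m[, 2])),
      label = m[, 6], style = tolower(trimws(m[, 7])),
      popup = m[, 8], color = trimws(m[, 9]),
      visible = tolower(trimws(m[, 5])) != "off",
      priority = m[, 10],
      line = vapply(br_rows, `[[`, integer(1), "line_number"),
      stringsAsFactors = FALSE)
  } else {
    brs <- empty_branches()
    brs$line <- integer()
  }
  pt_rows <- pack$rows[kinds != ROW_BRANCH]
  if (length(pt_rows)) {
    m <- cellmat(pt_rows, 7)
    is_top <- kinds[kinds != ROW_BRANCH] == ROW_PHENON_TOP
    pts <- data.frame(
      label = trimws(m[, 1]), age = as.numeric(trimws(m[, 2])),
      abundance = trimws(m[, 3]), popup = m[, 4],
      line = vapply(pt_rows, `[[`, integer(1), "line_number"),
      is_top = is_top, stringsAsFactors = FALSE)
    phenon_link <- lapply(split(which(is_top), pts$label[is_top]), function(ix)
      lapply(ix, function(i) list(species = trimws(m[i, 7]),
                                  line = pts$line[[i]])))
  } else {
    pts <- data.frame(label = character(), age = numeric(),
                      abundance = character(), popup = character(),
                      line = integer(), is_top = logical(),
                      stringsAsFactors = FALSE)
    phenon_link <- list()
  }
  list(points = pts, branches = brs, phenon_link = phenon_link)
}

#' Validate a datapack
#'
#' Checks the structural rules an evolutionary-tree datapack must obey
#' before the species and phenon trees can be built: point ages, range
#' durations, branch targets and ages, the one-parent/acyclic tree
#' discipline, and the phenon-to-species links.
#'
#' @param pack a parsed `datapack`.
#' @param tol absolute age tolerance in Ma.
#' @return data.frame report with columns `severity` ("error"/"warning"),
#'   `line` (first offending line, NA when not row-specific) and
#'   `message`. Zero rows means the pack is valid.
#' @export
validate_datapack <- function(pack, tol = .AGE_TOL) {
  rep <- data.frame(severity = character(), line = integer(),
                    message = character(), stringsAsFactors = FALSE)
  err <- function(line, msg)
    rep <<- rbind(rep, data.frame(severity = "error",
                                  line = if (is.null(line)) NA_integer_ else line,
                                  message = msg, stringsAsFactors = FALSE))
  cr <- collect_rows(pack)
  pts <- cr$points
  brs <- cr$branches
  labels <- unique(pts$label)
  is_phenon <- setNames(labels %in% names(cr$phenon_link), labels)
  by_label <- split(seq_len(nrow(pts)), pts$label)

  for (lab in labels) {
    ix <- by_label[[lab]]
    ages <- pts$age[ix]
    tops <- pts$is_top[ix]
    if (sum(tops) > 1)
      err(pts$line[ix][tops][2],
          sprintf("range '%s' has more than one phenon TOP row (duplicate label?)", lab))
    if (anyDuplicated(ages))
      err(pts$line[ix][[1]], sprintf("range '%s' has duplicate point ages", lab))
    if (length(ix) < 2)
      err(pts$line[ix][[1]],
          sprintf("range '%s' has a single dated point (zero-duration ranges are rejected)", lab))
    else if (max(ages) - min(ages) <= tol)
      err(pts$line[ix][[1]], sprintf("range '%s' has zero duration", lab))
  }
  links <- cr$phenon_link
  for (lab in names(links)) {
    sp <- links[[lab]][[1]]$species
    if (!(sp %in% labels))
      err(links[[lab]][[1]]$line,
          sprintf("phenon '%s' links to unknown species '%s'", lab, sp))
    else if (isTRUE(is_phenon[[sp]]))
      err(links[[lab]][[1]]$line,
          sprintf("phenon '%s' links to '%s', which is itself a phenon", lab, sp))
  }
  if (nrow(brs) > 0) {
    for (i in seq_len(nrow(brs))) {
      bp <- brs$parent[[i]]; bc <- brs$child[[i]]
      bage <- brs$age[[i]]; bline <- brs$line[[i]]
      if (!(bp %in% labels)) {
        err(bline, sprintf("branch to unknown parent '%s'", bp)); next
      }
      if (!(bc %in% labels)) {
        err(bline, sprintf("branch to unknown child '%s'", bc)); next
      }
      if (is_phenon[[bp]] != is_phenon[[bc]])
        err(bline, sprintf(
          "branch '%s' -> '%s' crosses between the species and phenon trees",
          bp, bc))
      pa <- pts$age[by_label[[bp]]]
      ca <- pts$age[by_label[[bc]]]
      if (bage > max(pa) + tol || bage < min(pa) - tol)
        err(bline, sprintf(
          "branch age %g Ma lies outside parent range '%s' (%g-%g Ma)",
          bage, bp, min(pa), max(pa)))
      if (abs(bage - max(ca)) > tol)
        err(bline, sprintf(
          "child '%s' base age %g Ma does not equal its branch age %g Ma",
          bc, max(ca), bage))
    }
    dup <- brs$child[duplicated(brs$child)]
    for (d in unique(dup))
      err(brs$line[brs$child == d][2],
          sprintf("range '%s' has more than one parent", d))
    # cycle check: walk rootward from every node (each child has <= 1 parent)
    parent <- setNames(brs$parent, brs$child)
    for (n in labels) {
      seen <- character()
      cur <- n
      while (!is.na(parent[cur] %||% NA_character_)) {
        if (cur %in% seen) {
          err(NA, sprintf("cycle detected through range '%s'", n))
          break
        }
        seen <- c(seen, cur)
        cur <- parent[[cur]]
      }
    }
  }
  rep
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Build species and phenon trees from a datapack
#'
#' Partitions ranges by the phenon TOP marker (a range whose TOP row
#' carries the "phenon" flag is a phenon; everything else is a species),
#' attaches dated branches, and validates the result. Disconnected
#' phenon subtrees and isolated phenon ranges are retained as extra
#' forest roots.
#'
#' @inheritParams validate_datapack
#' @return list with components `species` and `phenon`, each an
#'   `evo_tree`: `ranges` (name -> `taxon_range`), `branches`
#'   (data.frame), `parent`, `children`, `roots`.
#' @export
build_trees <- function(pack, tol = .AGE_TOL) {
  rep <- validate_datapack(pack, tol = tol)
  errs <- rep[rep$severity == "error", ]
  if (nrow(errs) > 0)
    stop("datapack validation failed:\n",
         paste(sprintf("  line %s: %s",
                       ifelse(is.na(errs$line), "-", errs$line), errs$message),
               collapse = "\n"), call. = FALSE)
  cr <- collect_rows(pack)
  pts <- cr$points
  by_label <- split(seq_len(nrow(pts)), pts$label)
  ranges <- list()
  for (lab in unique(pts$label)) {
    ix <- by_label[[lab]]
    ix <- ix[order(-pts$age[ix])]
    link <- cr$phenon_link[[lab]]
    ranges[[lab]] <- new_taxon_range(
      name = lab,
      points = data.frame(age = pts$age[ix], abundance = pts$abundance[ix],
                          popup = pts$popup[ix], stringsAsFactors = FALSE),
      is_phenon = !is.null(link),
      terminal_species = if (!is.null(link)) link[[1]]$species else NA_character_,
      popup = pts$popup[ix][[length(ix)]]
    )
  }
  is_ph <- vapply(ranges, `[[`, logical(1), "is_phenon")
  brs <- cr$branches
  brs$line <- NULL
  ph_child <- brs$child %in% names(ranges)[is_ph]
  list(
    species = new_evo_tree(ranges[!is_ph], brs[!ph_child, , drop = FALSE]),
    phenon = new_evo_tree(ranges[is_ph], brs[ph_child, , drop = FALSE])
  )
}

# normalize a datapack colour cell: "", "r/g/b", "#hex" or an SVG name
normalize_color <- function(x) {
  x <- trimws(x)
  if (x == "") return(NA_character_)
  if (grepl("^\\d+/\\d+/\\d+$", x)) {
    v <- as.integer(strsplit(x, "/", fixed = TRUE)[[1]])
    return(sprintf("#%02X%02X%02X", min(v[1], 255), min(v[2], 255), min(v[3], 255)))
  }
  x
}

#' Resolve inherited range colours
#'
#' When a colour is assigned to a branch, the child range and all its
#' descendants inherit it until a later branch assigns a new colour.
#' Roots and unassigned lineages get the default colour.
#'
#' @param tree an `evo_tree`.
#' @param default colour for ranges with no assignment anywhere rootward.
#' @return named character vector: range name -> concrete colour.
#' @export
resolve_colors <- function(tree, default = "#000000") {
  branch_col <- setNames(vapply(tree$branches$color, normalize_color,
                                character(1), USE.NAMES = FALSE),
                         tree$branches$child)
  out <- setNames(rep(NA_character_, length(tree$ranges)), names(tree$ranges))
  assign_down <- function(name, inherited) {
    own <- branch_col[name]
    col <- if (length(own) == 1 && !is.na(own)) own else inherited
    out[[name]] <<- col
    for (ch in tree$children[[name]]) assign_down(ch, col)
  }
  for (r in tree$roots) assign_down(r, default)
  out
}

#' Per-interval line styles of a range
#'
#' Decomposes a range into contiguous, non-overlapping style intervals
#' covering `[top_age, base_age]`. The style of each interval is the
#' abundance token of the point at its older end; empty tokens (and the
#' TOP marker) take the supplied default.
#'
#' @param range a `taxon_range`.
#' @param default style token for unspecified intervals.
#' @return data.frame with columns `old`, `young`, `style`, ordered old
#'   to young.
#' @export
style_segments <- function(range, default = "frequent") {
  p <- range$points
  n <- nrow(p)
  if (n < 2)
    return(data.frame(old = numeric(), young = numeric(), style = character(),
                      stringsAsFactors = FALSE))
  style <- p$abundance[-n]
  style[style == "" | style == "TOP"] <- default
  data.frame(old = p$age[-n], young = p$age[-1], style = style,
             stringsAsFactors = FALSE)
}

# clip style segments of a range to [young, old]
clip_styles <- function(styles, old, young, tol = .AGE_TOL) {
  keep <- styles$old > young + tol & styles$young < old - tol
  s <- styles[keep, , drop = FALSE]
  if (nrow(s) > 0) {
    s$old <- pmin(s$old, old)
    s$young <- pmax(s$young, young)
  }
  rownames(s) <- NULL
  s
}
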