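# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# Brute-force split of a phenon interval along the ancestral chain of
# its terminal species: cut at every chain origination age strictly
# inside the open phenon interval, then host each piece in the youngest
# chain species whose base age reaches the piece's old end. Works only
# from the raw ranges and parent pointers.
oracle_split <- function(trees, phenon_name, tol = 1e-9) {
  ph <- trees$phenon$ranges[[phenon_name]]
  p_top <- min(ph$points$age)
  p_base <- max(ph$points$age)
  chain <- character()
  cur <- ph$terminal_species
  repeat {
    chain <- c(chain, cur)
    p <- trees$species$parent[cur]
    if (length(p) == 0 || is.na(p)) break
    cur <- unname(p)
  }
  bases <- vapply(chain, function(s) max(trees$species$ranges[[s]]$points$age),
                  numeric(1))
  interior <- bases[bases > p_top + tol & bases < p_base - tol]
  cuts <- sort(unique(c(p_top, interior, p_base)))
  out <- data.frame(species = character(), old = numeric(), young = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(length(cuts) - 1)) {
    young <- cuts[[i]]; old <- cuts[[i + 1]]
    host <- chain[[which(bases >= old - tol)[[1]]]]
    out <- rbind(out, data.frame(species = host, old = old, young = young,
                                 stringsAsFactors = FALSE))
  }
  out
}

# segments actually produced by the package, as a comparable data.frame
observed_split <- function(trees, phenon_name) {
  segs <- split_phenon(trees$phenon$ranges[[phenon_name]], trees$species)
  do.call(rbind, lapply(segs, function(s)
    data.frame(species = s$species, old = s$old_age, young = s$young_age,
               stringsAsFactors = FALSE)))
}

# O(n^2) scan for strictly overlapping box rectangles
count_box_overlaps <- function(boxes, eps = 1e-9) {
  n <- nrow(boxes)
  bad <- 0L
  if (n < 2) return(bad)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      xo <- min(boxes$x_right[i], boxes$x_right[j]) -
        max(boxes$x_left[i], boxes$x_left[j])
      yo <- min(boxes$y_bottom[i], boxes$y_bottom[j]) -
        max(boxes$y_top[i], boxes$y_top[j])
      if (xo > eps && yo > eps) bad <- bad + 1L
    }
  }
  bad
}

# connected components of the in-box segment graph, as sets of phenon
# names (graph built directly from branch rows, BFS, no tree recursion)
oracle_box_components <- function(trees, map, species) {
  segs <- map$segments[[species]]
  if (length(segs) == 0) return(list())
  phens <- vapply(segs, `[[`, character(1), "phenon")
  iv <- map$species_intervals[map$species_intervals$species == species, ]
  b <- trees$phenon$branches
  adj <- setNames(vector("list", length(phens)), phens)
  for (k in seq_len(nrow(b))) {
    if (b$parent[k] %in% phens && b$child[k] %in% phens &&
        b$age[k] >= iv$top - 1e-9 && b$age[k] <= iv$base + 1e-9) {
      adj[[b$parent[k]]] <- c(adj[[b$parent[k]]], b$child[k])
      adj[[b$child[k]]] <- c(adj[[b$child[k]]], b$parent[k])
    }
  }
  seen <- character()
  comps <- list()
  for (p in phens) {
    if (p %in% seen) next
    comp <- character(); queue <- p
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      if (q %in% comp) next
      comp <- c(comp, q)
      queue <- c(queue, setdiff(adj[[q]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# minimal phenon-segment stand-in for ordering tests
fake_seg <- function(name, old, young) {
  structure(list(phenon = name, species = "S", old_age = old,
                 young_age = young, top_symbol = "RANGE_TOP_EXTINCT",
                 base_symbol = "RANGE_ORIGIN",
                 styles = data.frame(old = old, young = young,
                                     style = "common",
                                     stringsAsFactors = FALSE),
                 popup = "", color = NA_character_, still_living = FALSE,
                 label_full = name,
                 label_display = split_display_label(name)$display),
            class = "phenon_segment")
}

# structural datapack equality: row kinds and cells, cell for cell
packs_equal <- function(a, b) {
  if (length(a$rows) != length(b$rows)) return(FALSE)
  if (!identical(a$column_name, b$column_name)) return(FALSE)
  for (i in seq_along(a$rows)) {
    if (!identical(a$rows[[i]]$kind, b$rows[[i]]$kind)) return(FALSE)
    if (!identical(a$rows[[i]]$cells, b$rows[[i]]$cells)) return(FALSE)
  }
  TRUE
}

# tiny hand-built pack from body lines (header added)
mini_pack <- function(..., strict = TRUE) {
  parse_datapack(c("test\tevolutionary-tree",
                   vapply(list(...), function(cells)
                     paste0("\t", paste(cells, collapse = "\t")),
                     character(1))),
                 strict = strict)
}
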