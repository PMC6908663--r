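# Deterministic example datapacks and a randomized generator, so every
# stage of the pipeline is testable without external downloads. Both
# emit datapack text and run it through the parser, exercising the full
# input path.

#' Canonical worked-example datapack
#'
#' Builds the small improvised evolutionary-tree example used throughout
#' the documentation: a black ancestor giving rise to a green descendant
#' Aa, in turn to a blue group (Bb, ancestral to Be and Bf), with a
#' phenon tree (phenon, a--f) linked to those species. Variant `"I"` is
#' the connected example; variant `"III"` adds a disconnected phenon
#' tree (h--i) and an isolated phenon range (g) assigned along the
#' Bb--Be lineage series.
#'
#' Species (base--top, Ma): ancestor 18--13; Aa 13--0, still living,
#' frequent 13--5 then conjectured 5--0; Bb 10--2; Be 6--0 still living;
#' Bf 4--1. Phena: phenon 18--13 ending in ancestor; a 13--0 in Aa
#' (conjectured 5--0, still living); b 12--8 in Bb; c 9--3 in Be;
#' d 8--0 in Be (still living); e 4--0, child of d at 4 Ma, in Be
#' (still living); f 7--1, child of d at 7 Ma, in Bf.
#'
#' @param variant `"I"` or `"III"`.
#' @return a parsed `datapack`.
#' @export
fig2_fixture <- function(variant = c("I", "III")) {
  variant <- match.arg(variant)
  row <- function(...) paste0("\t", paste(c(...), collapse = "\t"))
  lines <- c(
    "integrated-example\tevolutionary-tree",
    "# species ranges",
    row("ancestor", "18", "frequent"),
    row("ancestor", "13", "TOP"),
    row("Aa", "13", "frequent"),
    row("Aa", "5", "conjectured"),
    row("Aa", "0", "TOP", "Aa: still-living species lineage"),
    row("Bb", "10", "frequent"),
    row("Bb", "2", "TOP"),
    row("Be", "6", "frequent"),
    row("Be", "0", "TOP"),
    row("Bf", "4", "frequent"),
    row("Bf", "1", "TOP"),
    "# species branches",
    row("ancestor", "13", "branch", "Aa", "on", "", "", "", "green"),
    row("Aa", "10", "branch", "Bb", "on", "", "", "", "#3366CC"),
    row("Bb", "6", "branch", "Be", "on", "", "", "", "#99CCFF"),
    row("Bb", "4", "branch", "Bf", "on", "", "", "", "#003380"),
    "# phenon ranges (TOP rows carry the species link)",
    row("phenon", "18", "frequent"),
    row("phenon", "13", "TOP", "", "", "phenon", "ancestor"),
    row("a", "13", "frequent"),
    row("a", "5", "conjectured"),
    row("a", "0", "TOP", "", "", "phenon", "Aa"),
    row("b", "12", "frequent"),
    row("b", "8", "TOP", "phenon b ends in Bb", "", "phenon", "Bb"),
    row("c", "9", "frequent"),
    row("c", "3", "TOP", "", "", "phenon", "Be"),
    row("d", "8", "frequent"),
    row("d", "0", "TOP", "", "", "phenon", "Be"),
    row("e", "4", "frequent"),
    row("e", "0", "TOP", "", "", "phenon", "Be"),
    row("f", "7", "frequent"),
    row("f", "1", "TOP", "", "", "phenon", "Bf"),
    "# phenon branches",
    row("phenon", "13", "branch", "a", "on", "", "", "", "green"),
    row("a", "12", "branch", "b", "on", "", "", "", "#3366CC"),
    row("b", "9", "branch", "c", "on", "", "", "", "#99CCFF"),
    row("b", "8", "branch", "d", "on"),
    row("d", "4", "branch", "e", "on"),
    row("d", "7", "branch", "f", "on", "", "", "", "#003380")
  )
  if (variant == "III") {
    lines <- c(lines,
      "# disconnected additions: isolated phenon g, tree h-i",
      row("g", "5", "common"),
      row("g", "3", "TOP", "", "", "phenon", "Be"),
      row("h", "9", "common"),
      row("h", "7", "TOP", "", "", "phenon", "Bb"),
      row("i", "8", "common"),
      row("i", "3", "TOP", "", "", "phenon", "Bb"),
      row("h", "8", "branch", "i", "on")
    )
  }
  parse_datapack(lines)
}

#' Specification for the randomized fixture generator
#'
#' @param seed RNG seed; generation is reproducible per seed.
#' @param n_species number of species lineages (>= 1).
#' @param n_phena number of phenon ranges (>= 0).
#' @param max_depth maximum species-tree depth (root = depth 1).
#' @param age_window plotted interval `c(old, young)` in Ma.
#' @param crossing_prob chance that a phenon spans its species' origin
#'   (and so is broken across boxes).
#' @param coincident_prob chance, for a non-crossing phenon, that its
#'   origin coincides exactly with its species' origin (in the
#'   planktonic-foraminifer case study roughly 40% of lineage origins
#'   coincide with a contained phenon).
#' @param living_fraction chance a species (or a phenon in a
#'   still-living species) extends to the present.
#' @param style_change_prob chance a range carries a mid-range style
#'   change.
#' @param link_prob chance a phenon is attached as a child in the phenon
#'   tree (lower values leave more disconnected trees/ranges).
#' @param color_prob chance a branch row carries a colour assignment.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_species = 8L, n_phena = 20L,
                         max_depth = 6L, age_window = c(30, 0),
                         crossing_prob = 0.35, coincident_prob = 0.4,
                         living_fraction = 0.25, style_change_prob = 0.25,
                         link_prob = 0.5, color_prob = 0.3) {
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (n_phena < 0) stop("n_phena must be >= 0", call. = FALSE)
  stopifnot(age_window[1] > age_window[2], age_window[2] >= 0, max_depth >= 1)
  structure(list(seed = seed, n_species = n_species, n_phena = n_phena,
                 max_depth = max_depth, age_window = age_window,
                 crossing_prob = crossing_prob,
                 coincident_prob = coincident_prob,
                 living_fraction = living_fraction,
                 style_change_prob = style_change_prob,
                 link_prob = link_prob, color_prob = color_prob),
            class = "fixture_spec")
}

# random age on a 0.01 Myr grid (avoids float-tie pathologies while still
# exercising the tolerance path)
r_age <- function(lo, hi) {
  if (hi < lo) hi <- lo
  min(max(round(runif(1, lo, hi), 2), round(lo, 2)), round(hi, 2))
}

#' Generate a random valid datapack
#'
#' Draws a species tree by recursive budding inside the age window,
#' then phena inside (and, with `crossing_prob`, rootward across) the
#' species, and assembles datapack text that is guaranteed to pass
#' validation and complete the full pipeline. Phenon-tree branches are
#' attached where ages permit, so disconnected phenon trees and
#' isolated ranges occur naturally.
#'
#' @param spec a [fixture_spec()].
#' @return a parsed `datapack`.
#' @export
random_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    old_end <- spec$age_window[[1]]
    tokens <- c("frequent", "common", "rare", "conjectured")
    palette <- c("#1B9E77", "#D95F02", "#7570B3", "#E7298A", "#66A61E",
                 "#E6AB02", "#A6761D", "#336699")
    sp_name <- sprintf("S%03d", seq_len(spec$n_species))
    base <- numeric(spec$n_species); top <- numeric(spec$n_species)
    parent <- rep(NA_integer_, spec$n_species)
    depth <- integer(spec$n_species)
    base[1] <- max(2, round(old_end * runif(1, 0.8, 1), 2))
    top[1] <- if (runif(1) < spec$living_fraction) 0 else r_age(0.5, base[1] - 1)
    depth[1] <- 1L
    i <- 2L
    while (i <= spec$n_species) {
      ok <- which(base - top >= 1 & depth < spec$max_depth)
      if (length(ok) == 0) ok <- which(base - top >= 1)
      p <- if (length(ok) == 1) ok else sample(ok, 1)
      b_age <- r_age(top[p] + 0.3, base[p] - 0.3)
      if (b_age - 0.5 < 0) next
      base[i] <- b_age
      top[i] <- if (runif(1) < spec$living_fraction) 0 else
        r_age(0, max(0, b_age - 0.5))
      if (base[i] - top[i] < 0.3) top[i] <- max(0, round(base[i] - 0.5, 2))
      parent[i] <- p
      depth[i] <- depth[p] + 1L
      i <- i + 1L
    }

    ph_name <- if (spec$n_phena > 0) sprintf("P%03d", seq_len(spec$n_phena)) else character()
    ph_sp <- integer(spec$n_phena)
    ph_base <- numeric(spec$n_phena); ph_top <- numeric(spec$n_phena)
    for (j in seq_len(spec$n_phena)) {
      s <- sample.int(spec$n_species, 1)
      ph_sp[j] <- s
      t <- if (top[s] <= 0 && runif(1) < spec$living_fraction) 0 else
        r_age(top[s], base[s] - 0.2)
      if (t >= base[s] - 0.1) t <- max(top[s], round(base[s] - 0.2, 2))
      ph_top[j] <- t
      chain <- s
      cur <- s
      while (!is.na(parent[cur])) { cur <- parent[cur]; chain <- c(chain, cur) }
      if (length(chain) > 1 && runif(1) < spec$crossing_prob) {
        k <- sample.int(min(length(chain) - 1, 3), 1)  # cross k origins
        lo <- base[chain[k]]
        hi <- base[chain[k + 1]]
        b <- r_age(min(lo + 0.05, hi), hi)
        if (b <= lo) b <- hi
        ph_base[j] <- b
      } else if (runif(1) < spec$coincident_prob) {
        ph_base[j] <- base[s]
      } else {
        b <- r_age(t + 0.1, base[s] - 0.05)
        if (b <= t) b <- base[s]
        ph_base[j] <- b
      }
    }
    ph_parent <- rep(NA_integer_, spec$n_phena)
    for (j in seq_len(spec$n_phena)) {
      if (j == 1 || runif(1) >= spec$link_prob) next
      cand <- which(seq_len(spec$n_phena) < j &
                      ph_top < ph_base[j] - 0.01 & ph_base >= ph_base[j])
      if (length(cand)) ph_parent[j] <- if (length(cand) == 1) cand else sample(cand, 1)
    }

    row <- function(...) paste0("\t", paste(c(...), collapse = "\t"))
    fmt <- function(x) sprintf("%.10g", x)
    lines <- sprintf("random-fixture-%d\tevolutionary-tree", spec$seed)
    range_rows <- function(name, b, t, top_extra = character()) {
      style <- sample(tokens, 1)
      out <- row(name, fmt(b), style)
      if (runif(1) < spec$style_change_prob && b - t >= 0.4) {
        m <- r_age(t + 0.1, b - 0.1)
        if (m > t && m < b)
          out <- c(out, row(name, fmt(m), sample(setdiff(tokens, style), 1)))
      }
      c(out, row(name, fmt(t), "TOP", "", top_extra))
    }
    for (k in seq_len(spec$n_species))
      lines <- c(lines, range_rows(sp_name[k], base[k], top[k]))
    for (k in seq_len(spec$n_species)) {
      if (is.na(parent[k])) next
      col <- if (runif(1) < spec$color_prob) sample(palette, 1) else ""
      lines <- c(lines, row(sp_name[parent[k]], fmt(base[k]), "branch",
                            sp_name[k], "on", "", "", "", col))
    }
    for (j in seq_len(spec$n_phena))
      lines <- c(lines, range_rows(ph_name[j], ph_base[j], ph_top[j],
                                   c("", "phenon", sp_name[ph_sp[j]])))
    for (j in seq_len(spec$n_phena)) {
      if (is.na(ph_parent[j])) next
      col <- if (runif(1) < spec$color_prob) sample(palette, 1) else ""
      lines <- c(lines, row(ph_name[ph_parent[j]], fmt(ph_base[j]), "branch",
                            ph_name[j], "on", "", "", "", col))
    }
    parse_datapack(lines)
  })
}
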