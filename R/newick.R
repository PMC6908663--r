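# Optional newick export for interop. Ancestor-descendant range trees
# map naturally onto newick with node labels and branch lengths in Myr
# (ancestor base age minus descendant base age); forests yield one
# string per root.

#' Export a tree's topology as newick
#'
#' Branch lengths are durations in Myr between origination ages
#' (ancestor base age minus descendant base age); every range appears as
#' a labelled node. Intended for interop checks only -- styles, colours
#' and range extents do not survive the trip.
#'
#' @param tree an `evo_tree`.
#' @return character vector, one newick string (with trailing `;`) per
#'   forest root.
#' @export
to_newick <- function(tree) {
  sanitize <- function(x) gsub("[ ,():;\\[\\]]", "_", x)
  rec <- function(name) {
    kids <- tree$children[[name]]
    inner <- if (length(kids)) {
      parts <- vapply(kids, function(ch) {
        len <- base_age(tree$ranges[[name]]) - base_age(tree$ranges[[ch]])
        paste0(rec(ch), ":", trimws(formatC(len, format = "fg", digits = 10)))
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    } else ""
    paste0(inner, sanitize(name))
  }
  vapply(tree$roots, function(r) paste0(rec(r), ";"), character(1),
         USE.NAMES = FALSE)
}
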