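#' Default line-style table
#'
#' Maps abundance tokens to stroke widths (px) and SVG dash patterns. The
#' species default token ("frequent") is strictly thicker than the phenon
#' default ("common") so species box borders stand out from the phenon
#' range lines drawn inside them.
#'
#' @return data.frame with columns `token`, `stroke_width`, `dash`
#'   (empty string = solid).
#' @export
default_styles <- function() {
  data.frame(
    token = c("frequent", "common", "rare", "conjectured", "sample-only"),
    stroke_width = c(2.0, 1.0, 1.0, 1.0, 1.0),
    dash = c("", "", "2,3", "6,4", "1,4"),
    stringsAsFactors = FALSE
  )
}

# look up a style token; unknown tokens fall back to the phenon default
# ("common") with a warning
style_for <- function(token, styles) {
  i <- match(token, styles$token)
  if (is.na(i)) {
    warning("unknown abundance token '", token, "': using 'common'",
            call. = FALSE)
    i <- match("common", styles$token)
  }
  styles[i, , drop = FALSE]
}

#' Chart settings
#'
#' Tunable parameters for layout and rendering of integrated
#' species-phenon charts. All geometry is in abstract canvas units
#' (1 unit = 1 px at SVG scale 1); vertical scale is `units_per_myr`
#' canvas units per million years.
#'
#' @param units_per_myr vertical scale, canvas units per Myr.
#' @param font_species,font_phenon label font sizes (px).
#' @param box_alpha species-box fill opacity, strictly between 0 and 1,
#'   so phenon lines and labels stay legible over the inherited colour.
#' @param min_box_width minimum species-box width; applies in particular
#'   to species boxes that contain no phenon ranges.
#' @param min_slot_width minimum width reserved for one phenon range
#'   inside a box.
#' @param gap_subtree horizontal gap between sibling subtrees.
#' @param gap_slot horizontal gap between phenon slots inside a box.
#' @param box_padding inner padding on each side of a species box.
#' @param label_char_factor label width estimate = characters x font size
#'   x this factor (deterministic, no font metrics needed).
#' @param ordering within-column and within-box ordering of disconnected
#'   phenon trees/ranges: `"first"` (First Occurrence, the default),
#'   `"last"` (Last Occurrence) or `"alphabetic"`.
#' @param default_species_style,default_phenon_style style tokens used
#'   for range intervals with no explicit abundance; the species default
#'   must render strictly thicker than the phenon default.
#' @param default_color colour used for ranges that inherit no branch
#'   colour.
#' @param guide_color accent colour for the guide symbols at phenon
#'   segment extremities.
#' @param show_labels draw taxon labels.
#' @param show_images reserve slot width for per-phenon thumbnail images
#'   listed in `images` (a named character vector of file paths).
#' @param images optional named character vector: phenon name -> image
#'   path (thumbnails are referenced, never embedded; missing files are
#'   skipped with a note).
#' @param image_width thumbnail width in canvas units when shown.
#' @param window plotted age interval `c(old, young)` in Ma; `NULL` means
#'   0 to the oldest base age rounded up to a whole Myr.
#' @param bands optional background interval bands: data.frame with
#'   columns `old`, `young`, `color` and optionally `label`.
#' @param margin canvas margins `c(top, right, bottom, left)`.
#' @param axis_width width reserved for the age axis.
#' @param tick_every age-axis tick spacing in Myr (`NULL` = automatic).
#' @param styles style table, see [default_styles()].
#' @return object of class `chart_settings`.
#' @export
chart_settings <- function(units_per_myr = 20,
                           font_species = 11,
                           font_phenon = 9,
                           box_alpha = 0.25,
                           min_box_width = 30,
                           min_slot_width = 18,
                           gap_subtree = 14,
                           gap_slot = 8,
                           box_padding = 6,
                           label_char_factor = 0.6,
                           ordering = c("first", "last", "alphabetic"),
                           default_species_style = "frequent",
                           default_phenon_style = "common",
                           default_color = "#000000",
                           guide_color = "#CC0000",
                           show_labels = TRUE,
                           show_images = FALSE,
                           images = NULL,
                           image_width = 24,
                           window = NULL,
                           bands = NULL,
                           margin = c(top = 30, right = 20, bottom = 20, left = 10),
                           axis_width = 46,
                           tick_every = NULL,
                           styles = default_styles()) {
  ordering <- match.arg(ordering)
  stopifnot(
    is.numeric(units_per_myr), units_per_myr > 0,
    font_species > 0, font_phenon > 0,
    min_box_width > 0, min_slot_width > 0,
    gap_subtree >= 0, gap_slot >= 0, box_padding >= 0,
    label_char_factor > 0, image_width > 0,
    length(margin) == 4, all(margin >= 0), axis_width >= 0
  )
  if (!is.numeric(box_alpha) || box_alpha <= 0 || box_alpha >= 1)
    stop("box_alpha must lie strictly between 0 and 1", call. = FALSE)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] > window[2], window[2] >= 0)
  }
  if (!is.null(bands)) {
    bands <- as.data.frame(bands, stringsAsFactors = FALSE)
    stopifnot(all(c("old", "young", "color") %in% names(bands)))
    if (is.null(bands$label)) bands$label <- ""
  }
  sw <- function(tok) style_for(tok, styles)$stroke_width
  if (!(sw(default_species_style) > sw(default_phenon_style)))
    stop("species default style must be strictly thicker than the phenon default",
         call. = FALSE)
  s <- list(
    units_per_myr = units_per_myr, font_species = font_species,
    font_phenon = font_phenon, box_alpha = box_alpha,
    min_box_width = min_box_width, min_slot_width = min_slot_width,
    gap_subtree = gap_subtree, gap_slot = gap_slot,
    box_padding = box_padding, label_char_factor = label_char_factor,
    ordering = ordering,
    default_species_style = default_species_style,
    default_phenon_style = default_phenon_style,
    default_color = default_color, guide_color = guide_color,
    show_labels = show_labels, show_images = show_images,
    images = images, image_width = image_width,
    window = window, bands = bands,
    margin = setNames(as.numeric(margin), c("top", "right", "bottom", "left")),
    axis_width = axis_width, tick_every = tick_every, styles = styles
  )
  class(s) <- "chart_settings"
  s
}

#' Read chart settings from a YAML file
#'
#' Any key accepted by [chart_settings()] may be given; unknown keys are
#' an error. `bands` is a list of `{old, young, color, label}` mappings.
#'
#' @param path YAML file path.
#' @return `chart_settings` object.
#' @export
read_settings <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(chart_settings))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown settings key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$bands))
    raw$bands <- do.call(rbind, lapply(raw$bands, function(b)
      data.frame(old = b$old, young = b$young, color = b$color,
                 label = if (is.null(b$label)) "" else b$label,
                 stringsAsFactors = FALSE)))
  if (!is.null(raw$margin)) raw$margin <- unlist(raw$margin)
  do.call(chart_settings, raw)
}

# deterministic label width estimate (no font metrics)
label_width <- function(text, font_size, factor) {
  nchar(text, type = "chars") * font_size * factor
}
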