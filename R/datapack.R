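# Tab-delimited "datapack" dialect for evolutionary-tree columns.
#
# Each data row holds cells for spreadsheet columns B..K (the leading tab
# field, column A, is carried by spreadsheet exports and ignored here).
# Three row kinds:
#   range point: Label (B), Age Ma (C), Abundance (D), Pop-up (E)
#   branch:      Parent (B), Age (C), "branch" (D), Child (E), on/off (F),
#                BranchLabel (G), Dashed/Dotted (H), Pop-up (I),
#                BranchColor (J), Priority (K)
#   phenon TOP:  Label (B), Age (C), "TOP" (D), Pop-up (E), blank (F),
#                "phenon" (G), Species-name (H)
# A TOP row without the "phenon" flag is an ordinary range point marking
# the young end of a species range.

ROW_RANGE_POINT <- "RANGE_POINT"
ROW_BRANCH <- "BRANCH"
ROW_PHENON_TOP <- "PHENON_TOP"

# cell accessor: 1 = column B ... 10 = column K; out of range reads ""
cell <- function(cells, i) {
  if (i <= length(cells)) cells[[i]] else ""
}

# classify one row's cells; returns list(kind=..) or list(error=..)
classify_cells <- function(cells) {
  label <- trimws(cell(cells, 1))
  age_txt <- trimws(cell(cells, 2))
  d <- trimws(cell(cells, 3))
  g <- trimws(cell(cells, 6))
  age <- suppressWarnings(as.numeric(age_txt))
  if (tolower(d) == "branch") {
    if (label == "") return(list(error = "branch row with empty parent name (column B)"))
    if (is.na(age)) return(list(error = sprintf("branch row with non-numeric age '%s' (column C)", age_txt)))
    if (trimws(cell(cells, 4)) == "")
      return(list(error = "branch row with empty child name (column E)"))
    return(list(kind = ROW_BRANCH))
  }
  if (d == "TOP" && tolower(g) == "phenon") {
    if (label == "") return(list(error = "phenon TOP row with empty label (column B)"))
    if (is.na(age)) return(list(error = sprintf("phenon TOP row with non-numeric age '%s' (column C)", age_txt)))
    if (trimws(cell(cells, 7)) == "")
      return(list(error = "phenon TOP row with empty species name (column H)"))
    return(list(kind = ROW_PHENON_TOP))
  }
  if (label == "") return(list(error = "row with empty label (column B)"))
  if (age_txt == "" || is.na(age))
    return(list(error = sprintf("range point with non-numeric age '%s' (column C)", age_txt)))
  if (age < 0)
    return(list(error = sprintf("range point with negative age %s Ma", age_txt)))
  list(kind = ROW_RANGE_POINT)
}

#' Parse a datapack
#'
#' Reads the tab-delimited evolutionary-tree datapack dialect. Blank
#' lines and lines starting with `#` are skipped. An optional header line
#' `<column name>\tevolutionary-tree` names the column; headerless input
#' gets the default name `"untitled"`. Every other non-blank line must
#' classify as exactly one of the three row kinds.
#'
#' @param text file content: a single string or a character vector of
#'   lines.
#' @param strict if `TRUE` (default), any unparseable row raises an error
#'   naming its line number(s); if `FALSE`, the returned pack carries the
#'   problems in `attr(, "errors")` (a data.frame with `line`, `message`).
#' @param source_path optional provenance string stored on the pack.
#' @return object of class `datapack`: list with `column_name`, `rows`
#'   (each row a list with `kind`, `cells` for columns B..K with trailing
#'   blanks trimmed, and `line_number`), `source_path`.
#' @seealso [read_datapack()], [write_datapack()]
#' @export
parse_datapack <- function(text, strict = TRUE, source_path = NULL) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", text)
  rows <- list()
  errors <- data.frame(line = integer(), message = character(),
                       stringsAsFactors = FALSE)
  column_name <- "untitled"
  header_seen <- FALSE
  first_content <- TRUE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (trimws(line) == "" || grepl("^\\s*#", line)) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (first_content) {
      first_content <- FALSE
      if (length(fields) >= 2 &&
          tolower(trimws(fields[[2]])) == "evolutionary-tree") {
        column_name <- trimws(fields[[1]])
        header_seen <- TRUE
        next
      }
    }
    cells <- if (length(fields) >= 2) fields[-1] else character()
    while (length(cells) > 0 && trimws(cells[[length(cells)]]) == "")
      cells <- cells[-length(cells)]
    cls <- classify_cells(cells)
    if (!is.null(cls$error)) {
      errors <- rbind(errors, data.frame(line = ln, message = cls$error,
                                         stringsAsFactors = FALSE))
    } else {
      rows[[length(rows) + 1L]] <- list(kind = cls$kind, cells = cells,
                                        line_number = ln)
    }
  }
  if (strict && nrow(errors) > 0)
    stop("datapack parse error(s):\n",
         paste(sprintf("  line %d: %s", errors$line, errors$message),
               collapse = "\n"), call. = FALSE)
  pack <- structure(
    list(column_name = column_name, rows = rows, source_path = source_path,
         header_seen = header_seen),
    class = "datapack"
  )
  attr(pack, "errors") <- errors
  pack
}

#' Read a datapack file
#'
#' `.txt` and `.dpk` paths are treated identically as tab-delimited text.
#'
#' @inheritParams parse_datapack
#' @param path file path.
#' @return `datapack` object.
#' @export
read_datapack <- function(path, strict = TRUE) {
  parse_datapack(readLines(path, warn = FALSE), strict = strict,
                 source_path = path)
}

#' Write a datapack
#'
#' Serializes a `datapack` back to the tab-delimited dialect. The
#' round-trip `parse_datapack(write_datapack(pack))` is the structural
#' identity on row kinds and cells.
#'
#' @param pack `datapack` object.
#' @param path optional output file; when given, the text is also written
#'   there.
#' @return the datapack text, a single string, invisibly when `path` is
#'   given.
#' @export
write_datapack <- function(pack, path = NULL) {
  stopifnot(inherits(pack, "datapack"))
  header <- paste(pack$column_name, "evolutionary-tree", sep = "\t")
  body <- vapply(pack$rows, function(r)
    paste0("\t", paste(r$cells, collapse = "\t")), character(1))
  text <- paste(c(header, body), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' Split a display label at "|"
#'
#' Phenon names may carry an alternative short label: text after the
#' first `|` is excluded from display (e.g. a name authored as
#' `"bullbrooki | Bolli, 1957; Globorotalia"` displays as
#' `"bullbrooki"`). Names without `|` display in full.
#'
#' @param name raw, non-empty range label.
#' @return list with `display` (trimmed text before the first `|`) and
#'   `full` (the raw name).
#' @export
split_display_label <- function(name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (grepl("|", name, fixed = TRUE)) {
    display <- trimws(sub("\\|.*$", "", name))
  } else {
    display <- name
  }
  list(display = display, full = name)
}

# vectorized display part only
display_label <- function(names) {
  vapply(names, function(n) split_display_label(n)$display, character(1),
         USE.NAMES = FALSE)
}

#' @export
print.datapack <- function(x, ...) {
  kinds <- vapply(x$rows, `[[`, character(1), "kind")
  cat(sprintf("<datapack> column '%s': %d rows (%d range points, %d branches, %d phenon links)\n",
              x$column_name, length(x$rows),
              sum(kinds == ROW_RANGE_POINT), sum(kinds == ROW_BRANCH),
              sum(kinds == ROW_PHENON_TOP)))
  invisible(x)
}
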