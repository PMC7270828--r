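# Map mock-genome coordinates (e.g. differentially methylated cytosines
# reported by an external caller) back to the reconstructed fragments they
# fall in.

#' Load 1-based positions from a text table
#'
#' Reads integer positions from the given column of a whitespace- or
#' tab-separated table (a single-column file works with `column = 1`).
#' A header line whose target field is non-numeric is skipped.
#'
#' @param path Text file.
#' @param column 1-based column index holding the positions (default 2,
#'   matching methylation-caller output whose second column is the
#'   coordinate).
#' @return Integer vector of positions.
#' @export
load_positions <- function(path, column = 2L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(integer(0))
  fields <- strsplit(lines, "[\t ]+")
  vals <- vapply(fields, function(f) {
    if (length(f) < column) NA_character_ else f[[column]]
  }, character(1))
  if (anyNA(vals)) stop("line(s) with fewer than ", column, " columns")
  first_num <- suppressWarnings(as.numeric(vals[1]))
  if (is.na(first_num)) {            # header
    vals <- vals[-1]
  }
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num) || any(num != floor(num)))
    stop("non-integer position(s) in column ", column)
  as.integer(num)
}

#' Load a boundary table written by [write_reconstruction()]
#'
#' @param path `boundaries.tsv` path (columns `name`, `start`, `end`,
#'   extra columns ignored).
#' @return `data.frame` with `name`, `start`, `end`, sorted by `start`.
#' @export
load_boundaries <- function(path) {
  bt <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(name = "character"),
                          stringsAsFactors = FALSE)
  bt[order(bt$start), c("name", "start", "end")]
}

#' Resolve mock-genome positions to fragments
#'
#' Binary-search interval lookup: each 1-based position is mapped to the
#' fragment whose boundary interval contains it; positions inside spacers
#' or outside the mock genome get `NA`. Output order follows input order.
#'
#' @param positions Integer vector of 1-based mock-genome coordinates.
#' @param boundaries Boundary `data.frame` (`name`, `start`, `end`),
#'   sorted and disjoint.
#' @return `data.frame` with `position`, `fragment` (`NA` if unplaced) and
#'   `offset` (1-based position within the fragment).
#' @export
seek_fragments <- function(positions, boundaries) {
  if (nrow(boundaries) > 1L) {
    if (is.unsorted(boundaries$start, strictly = TRUE) ||
        any(boundaries$start[-1] <= boundaries$end[-nrow(boundaries)]))
      stop("boundary table must be sorted and disjoint")
  }
  idx <- findInterval(positions, boundaries$start)
  inside <- idx >= 1L & positions <= boundaries$end[pmax(idx, 1L)]
  frag <- ifelse(inside, boundaries$name[pmax(idx, 1L)], NA_character_)
  offset <- ifelse(inside,
                   positions - boundaries$start[pmax(idx, 1L)] + 1L,
                   NA_integer_)
  data.frame(position = positions, fragment = frag,
             offset = as.integer(offset), stringsAsFactors = FALSE)
}
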