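# The text facet: the table of distinct string values in a column with
# their occurrence counts.  This is the structure every clustering stage
# operates on and rewrites.

#' Build a text facet from a column of values
#'
#' Tabulates the distinct values of a character vector with their occurrence
#' counts, ordered by decreasing count (ties alphabetically).  The sum of
#' counts always equals the input length.
#'
#' @param values character vector, one record per element.
#' @return a \code{facet_table}: a data frame with columns \code{value}
#'   and \code{count}.
#' @examples
#' build_facet(c("negative", "negative", "native"))
#' @export
build_facet <- function(values) {
  values <- as.character(values)
  if (!length(values)) return(facet_table(character(0), integer(0)))
  tab <- table(values)
  facet_table(names(tab), as.integer(tab))
}

#' Construct a facet table from values and counts
#'
#' @param value character vector of distinct values.
#' @param count positive integer vector of occurrence counts.
#' @return a \code{facet_table} data frame, ordered by decreasing count then
#'   value.
#' @export
facet_table <- function(value, count) {
  value <- as.character(value)
  count <- as.integer(count)
  stopifnot(length(value) == length(count))
  if (anyDuplicated(value)) stop("facet values must be distinct")
  if (length(count) && any(is.na(count) | count < 1L))
    stop("facet counts must be positive integers")
  ord <- order(-count, value, method = "radix")
  structure(
    data.frame(value = value[ord], count = count[ord],
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("facet_table", "data.frame"))
}

#' Coerce to a facet table
#'
#' @param x a named integer vector (names are values), a two-column data
#'   frame (\code{value}, \code{count}), or a \code{facet_table}.
#' @return a \code{facet_table}.
#' @export
as_facet_table <- function(x) {
  if (inherits(x, "facet_table")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("value", "count") %in% names(x)))
    return(facet_table(x$value, x$count))
  }
  if (!is.null(names(x))) return(facet_table(names(x), as.integer(x)))
  stop("cannot coerce to facet_table; supply a named vector or data frame")
}

#' @export
print.facet_table <- function(x, n = 10L, ...) {
  cat("<facet_table> ", nrow(x), " distinct values, ",
      sum(x$count), " total occurrences\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more values\n")
  invisible(x)
}

#' Total number of occurrences in a facet
#'
#' @param facet a \code{facet_table}.
#' @return integer scalar, the sum of counts.
#' @export
facet_total <- function(facet) {
  stopifnot(inherits(facet, "facet_table"))
  sum(facet$count)
}

#' Choose the canonical value of a cluster
#'
#' The member with the highest occurrence count wins; ties break to the
#' lexicographically smallest value (C locale), then to first occurrence.
#' This mirrors frequency-ordered value merging: the overwhelmingly more
#' frequent spelling of a term is taken as correct.
#'
#' @param value character vector of member values.
#' @param count integer vector of member counts.
#' @return a single string, the canonical value.
#' @examples
#' choose_canonical(c("Clonorchis sinensis", "clonorchis sinesis"), c(900, 4))
#' @export
choose_canonical <- function(value, count) {
  value <- as.character(value)
  count <- as.integer(count)
  if (!length(value)) stop("cannot choose a canonical value of an empty cluster")
  stopifnot(length(value) == length(count))
  ord <- order(-count, value, seq_along(value), method = "radix")
  value[ord[1L]]
}
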