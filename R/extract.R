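# Term extraction: pull target-vocabulary mentions out of free-text
# reports, by regular expression and/or by approximate dictionary lookup
# (loose gate, so misspelled mentions survive extraction and can be fixed
# downstream by the clustering pipeline).

#' Extraction specification
#'
#' @param patterns character vector of regular expressions (\code{regex}
#'   and \code{both} modes).
#' @param dictionary character vector of target terms (\code{dictionary}
#'   and \code{both} modes).
#' @param mode one of \code{"regex"}, \code{"dictionary"}, \code{"both"}.
#' @param max_distance normalized Levenshtein gate for dictionary matches
#'   (default 0.35, deliberately loose so typos are still extracted).
#' @param ignore_case case-insensitive regex matching (default TRUE).
#' @return an object of class \code{"extraction_spec"}.
#' @export
extraction_spec <- function(patterns = NULL, dictionary = NULL,
                            mode = c("regex", "dictionary", "both"),
                            max_distance = 0.35, ignore_case = TRUE) {
  mode <- match.arg(mode)
  if (mode %in% c("regex", "both") && !length(patterns))
    stop("mode '", mode, "' requires at least one pattern")
  if (mode %in% c("dictionary", "both") && !length(dictionary))
    stop("mode '", mode, "' requires a non-empty dictionary")
  for (p in patterns) {
    ok <- tryCatch({ grepl(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("invalid regular expression: ", p)
  }
  stopifnot(max_distance >= 0, max_distance <= 1)
  structure(list(patterns = patterns, dictionary = dictionary, mode = mode,
                 max_distance = max_distance,
                 ignore_case = isTRUE(ignore_case)),
            class = "extraction_spec")
}

# regex matches of one report, with positions
.regex_hits <- function(text, patterns, ignore_case) {
  hits <- data.frame(start = integer(0), end = integer(0),
                     match = character(0), stringsAsFactors = FALSE)
  for (p in patterns) {
    m <- gregexpr(p, text, perl = TRUE, ignore.case = ignore_case)[[1]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    hits <- rbind(hits, data.frame(
      start = as.integer(m), end = as.integer(m) + len - 1L,
      match = substring(text, m, m + len - 1L), stringsAsFactors = FALSE))
  }
  hits
}

# approximate dictionary matches on whitespace-delimited token spans of the
# same token length as each dictionary term
.dict_hits <- function(text, dictionary, max_distance) {
  toks <- regmatches(text, gregexpr("[^ \t]+", text))[[1]]
  pos <- gregexpr("[^ \t]+", text)[[1]]
  if (!length(toks) || pos[1L] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  starts <- as.integer(pos)
  ends <- starts + attr(pos, "match.length") - 1L
  hits <- list()
  for (term in dictionary) {
    k <- length(strsplit(term, " ", fixed = TRUE)[[1]])
    if (length(toks) < k) next
    for (i in seq_len(length(toks) - k + 1L)) {
      span <- paste(toks[i:(i + k - 1L)], collapse = " ")
      d <- normalized_levenshtein(span, term)
      if (d <= max_distance) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = starts[i], end = ends[i + k - 1L], match = span,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Extract target terms from raw report text
#'
#' Returns every matching substring, in reading order, across all reports.
#' In regex mode, matches of any pattern; in dictionary mode, any
#' whitespace-delimited token span within the normalized-distance gate of a
#' dictionary term (so "Clonorchis sinesis" is extracted for the dictionary
#' term "Clonorchis sinensis"); \code{both} combines the two.  Overlapping
#' matches are resolved greedily left to right.
#'
#' @param reports character vector of raw report strings.
#' @param spec an \code{\link{extraction_spec}}.
#' @return character vector of extracted term mentions, order preserved.
#' @examples
#' extract_terms("stool exam: negative for ova",
#'               extraction_spec(patterns = "negative|positive"))
#' @export
extract_terms <- function(reports, spec) {
  stopifnot(inherits(spec, "extraction_spec"))
  out <- character(0)
  for (text in as.character(reports)) {
    hits <- switch(spec$mode,
      regex = .regex_hits(text, spec$patterns, spec$ignore_case),
      dictionary = .dict_hits(text, spec$dictionary, spec$max_distance),
      both = rbind(
        .regex_hits(text, spec$patterns, spec$ignore_case),
        .dict_hits(text, spec$dictionary, spec$max_distance)))
    if (!nrow(hits)) next
    hits <- hits[order(hits$start, -(hits$end - hits$start)), , drop = FALSE]
    taken <- integer(0)
    for (r in seq_len(nrow(hits))) {
      if (hits$start[r] %in% taken) next
      span <- hits$start[r]:hits$end[r]
      if (any(span %in% taken)) next
      taken <- c(taken, span)
      out <- c(out, hits$match[r])
    }
  }
  out
}
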