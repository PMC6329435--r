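# String distances for nearest-neighbour clustering.  All comparisons are
# performed on lowercased, whitespace-trimmed forms: case and spacing
# variants are the keyers' job, and distance should not double-count them.

.norm_dist <- function(x) tolower(trimws(as.character(x)))

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming \code{a} into \code{b}, computed on
#' lowercased, trimmed forms via \code{\link[utils]{adist}}.  Symmetric,
#' zero on identical strings, and satisfies the triangle inequality.
#'
#' @param a,b character vectors (recycled to common length).
#' @return non-negative integer vector of distances.
#' @examples
#' levenshtein("native", "negative")    # 2
#' levenshtein("", "abc")               # 3
#' @export
levenshtein <- function(a, b) {
  a <- .norm_dist(a); b <- .norm_dist(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i]))
  out
}

#' Normalized Levenshtein distance
#'
#' \code{levenshtein(a, b) / max(nchar(a), nchar(b))} on lowercased trimmed
#' forms; lies in \eqn{[0, 1]}.  This is the default nearest-neighbour
#' metric: normalizing by the longer string makes the cluster radius
#' comparable across short and long vocabulary terms.
#'
#' @param a,b character vectors (recycled to common length).
#' @return numeric vector in \eqn{[0, 1]}.
#' @examples
#' normalized_levenshtein("eolimax", "endolimax")   # 2/9
#' normalized_levenshtein("negaitve", "negative")   # 0.25
#' @export
normalized_levenshtein <- function(a, b) {
  a <- .norm_dist(a); b <- .norm_dist(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  mx <- pmax(nchar(a), nchar(b))
  if (any(mx == 0L))
    stop("normalized_levenshtein() is undefined when both strings are empty")
  levenshtein(a, b) / mx
}

#' Character inconsistency rate between a typo and its correct word
#'
#' \code{100 * levenshtein(typo, correct) / min(nchar(typo),
#' nchar(correct))}, rounded to the nearest integer percent.  Normalizing by
#' the shorter string expresses how much of the smaller word disagrees: for
#' "native" against "negative" the two differing characters out of six give
#' 33\%, which is why that pair resists every clustering method.
#'
#' @param typo non-empty character vector of misspelled forms.
#' @param correct character vector of reference forms.
#' @return integer percentage vector.
#' @examples
#' inconsistency_rate("native", "negative")   # 33
#' @export
inconsistency_rate <- function(typo, correct) {
  typo <- .norm_dist(typo); correct <- .norm_dist(correct)
  if (any(!nzchar(typo)))
    stop("inconsistency_rate() requires a non-empty typo string")
  n <- max(length(typo), length(correct))
  typo <- rep_len(typo, n); correct <- rep_len(correct, n)
  mn <- pmin(nchar(typo), nchar(correct))
  as.integer(round(100 * levenshtein(typo, correct) / mn))
}

# --- compression distance -------------------------------------------------

#' Order-2 adaptive-context code length
#'
#' Reference byte compressor for \code{\link{compression_distance}}: an
#' adaptive context model of order 2 (each byte is predicted from the two
#' preceding bytes with Laplace-smoothed counts over the 256-symbol
#' alphabet, counts updated after every byte).  Returns the ideal code
#' length in bytes, \eqn{\sum -\log_2 p / 8}, rather than an actual encoded
#' bitstream; the quantity is deterministic and is all the distance needs.
#'
#' @param x a single string.
#' @return numeric scalar, ideal compressed length in bytes.
#' @export
compress_o2 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  if (!length(bytes)) return(0)
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  c1 <- 256L; c2 <- 256L  # virtual start-of-string context
  bits <- 0
  for (b in bytes) {
    ctx <- paste0(c1, ",", c2)
    key <- paste0(ctx, ",", b)
    cnt <- get0(key, envir = counts, ifnotfound = 0L)
    tkey <- paste0(ctx, ",T")
    tot <- get0(tkey, envir = counts, ifnotfound = 0L)
    bits <- bits - log2((cnt + 1) / (tot + 256))
    counts[[key]] <- cnt + 1L
    counts[[tkey]] <- tot + 1L
    c1 <- c2; c2 <- b
  }
  bits / 8
}

#' Compression distance between two strings
#'
#' Normalized compression distance with a pluggable byte compressor:
#' \deqn{d(a, b) = (C(ab) + C(ba)) / (C(aa) + C(bb))}
#' where \eqn{C(x)} is the compressed length of \eqn{x} under
#' \code{compressor}.  Exactly symmetric by construction; \eqn{d(a, a)}
#' approaches the compressor's floor.  Any deterministic compressor mapping
#' a string to a non-negative length satisfies the contract; the default is
#' \code{\link{compress_o2}}.  Computed on lowercased trimmed forms.
#'
#' @param a,b single strings.
#' @param compressor function taking one string, returning its compressed
#'   length.
#' @return non-negative numeric scalar.
#' @export
compression_distance <- function(a, b, compressor = compress_o2) {
  a <- .norm_dist(a)[1L]; b <- .norm_dist(b)[1L]
  num <- compressor(paste0(a, b)) + compressor(paste0(b, a))
  den <- compressor(paste0(a, a)) + compressor(paste0(b, b))
  if (den == 0) return(0)
  num / den
}

#' Nearest-neighbour distance specification
#'
#' @param method one of \code{"normalized_levenshtein"},
#'   \code{"levenshtein"}, \code{"compression"}.
#' @param threshold cluster radius: values at pairwise distance
#'   \code{<= threshold} are joined.  Defaults to 0.23 for
#'   \code{"normalized_levenshtein"} (see the package vignette for the
#'   calibration) and must lie in \eqn{[0, 1]} for that method.
#' @param block_chars candidate-blocking substring length (default 6); only
#'   pairs sharing a substring of this length are compared when the facet is
#'   large enough for blocking to engage.
#' @return an object of class \code{"distance_spec"}.
#' @export
distance_spec <- function(method = c("normalized_levenshtein", "levenshtein",
                                     "compression"),
                          threshold = NULL, block_chars = 6L) {
  method <- match.arg(method)
  if (is.null(threshold))
    threshold <- switch(method,
                        normalized_levenshtein = 0.23,
                        levenshtein = 1,
                        compression = 0.3)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  if (method == "normalized_levenshtein" && threshold > 1)
    stop("threshold for normalized_levenshtein must lie in [0, 1]")
  block_chars <- as.integer(block_chars)
  stopifnot(length(block_chars) == 1L, block_chars >= 1L)
  structure(list(method = method, threshold = threshold,
                 block_chars = block_chars),
            class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat("<distance_spec> ", x$method, ", radius ", format(x$threshold),
      ", block_chars ", x$block_chars, "\n", sep = "")
  invisible(x)
}

# pairwise distance between two normalized string vectors under a spec
.pair_dist <- function(spec, a, b) {
  switch(spec$method,
    levenshtein = as.numeric(levenshtein(a, b)),
    normalized_levenshtein = normalized_levenshtein(a, b),
    compression = mapply(compression_distance, a, b, USE.NAMES = FALSE))
}
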