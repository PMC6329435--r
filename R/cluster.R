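# Clustering stages: key collision (group values sharing a key) and
# blocked nearest-neighbour (connected components at a distance radius).

.new_cluster <- function(value, count, method_id, stage_index = NA_integer_) {
  ord <- order(-count, value, method = "radix")
  structure(list(members = data.frame(value = value[ord], count = count[ord],
                                      stringsAsFactors = FALSE,
                                      row.names = NULL),
                 canonical = choose_canonical(value, count),
                 method_id = method_id,
                 stage_index = stage_index),
            class = "value_cluster")
}

#' @export
print.value_cluster <- function(x, ...) {
  cat("<cluster> [", x$method_id, "] canonical: ", x$canonical, "\n", sep = "")
  print.data.frame(x$members)
  invisible(x)
}

#' Key-collision clustering
#'
#' Maps every facet value to its collision key under \code{spec} and groups
#' values sharing a non-empty key.  Groups of size one are discarded; an
#' empty key is never treated as a collision (unkeyable junk must not be
#' merged together).  Each cluster's canonical value is chosen by
#' \code{\link{choose_canonical}}.
#'
#' @param facet a \code{facet_table}.
#' @param spec a \code{\link{key_spec}}.
#' @return list of clusters (possibly empty).
#' @examples
#' f <- facet_table(c("Negative", "Negaitve"), c(5000, 3))
#' key_collision_cluster(f, key_spec("ngram_fingerprint", 1))
#' @export
key_collision_cluster <- function(facet, spec) {
  facet <- as_facet_table(facet)
  stopifnot(inherits(spec, "key_spec"))
  if (!nrow(facet)) return(list())
  keys <- apply_key(spec, facet$value)
  keep <- nzchar(keys)
  groups <- split(which(keep), keys[keep])
  groups <- groups[lengths(groups) >= 2L]
  lab <- .stage_label(spec)
  out <- lapply(groups, function(idx) {
    .new_cluster(facet$value[idx], facet$count[idx], lab)
  })
  names(out) <- NULL
  # deterministic order: by canonical value
  out[order(vapply(out, `[[`, character(1), "canonical"), method = "radix")]
}

# candidate pairs for nearest-neighbour clustering.  Exhaustive when the
# facet is small; otherwise blocked: only pairs of values sharing at least
# one substring of length block_chars are compared.
.candidate_pairs <- function(norm, block_chars, max_exhaustive) {
  n <- length(norm)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  if (n <= max_exhaustive) {
    idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
    return(cbind(idx[, "row"], idx[, "col"]))
  }
  buckets <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(n)) {
    L <- nchar(norm[i])
    if (L < block_chars) next
    subs <- unique(substring(norm[i], 1:(L - block_chars + 1L),
                             block_chars:L))
    for (s in subs) {
      buckets[[s]] <- c(get0(s, envir = buckets, ifnotfound = integer(0)), i)
    }
  }
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  rows <- list()
  for (s in ls(buckets, sorted = FALSE)) {
    idx <- buckets[[s]]
    if (length(idx) < 2L) next
    idx <- sort(idx)
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):length(idx)) {
        key <- paste0(idx[a], "_", idx[b])
        if (is.null(get0(key, envir = seen, ifnotfound = NULL))) {
          seen[[key]] <- TRUE
          rows[[length(rows) + 1L]] <- c(idx[a], idx[b])
        }
      }
    }
  }
  if (!length(rows)) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, rows)
}

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Nearest-neighbour clustering
#'
#' Joins facet values whose pairwise distance under \code{spec} is at most
#' the radius \code{spec$threshold}; clusters are the connected components
#' (single linkage), so a typo of a typo still reaches the canonical value.
#' Candidate pairs are exhaustive for facets of at most
#' \code{max_exhaustive} values and otherwise generated by substring
#' blocking: only pairs sharing a substring of length
#' \code{spec$block_chars} are compared.
#'
#' @param facet a \code{facet_table}.
#' @param spec a \code{\link{distance_spec}}.
#' @param max_exhaustive facets with at most this many values skip blocking
#'   and compare all pairs (default 2000).  Set to 0 to force blocking, for
#'   example to check blocking against the exhaustive result.
#' @return list of clusters (possibly empty).
#' @examples
#' f <- facet_table(c("Endolimax", "Eolimax", "Endolix"), c(800, 2, 1))
#' nn_cluster(f, distance_spec("normalized_levenshtein", 0.23))
#' @export
nn_cluster <- function(facet, spec, max_exhaustive = 2000L) {
  facet <- as_facet_table(facet)
  stopifnot(inherits(spec, "distance_spec"))
  n <- nrow(facet)
  if (n < 2L) return(list())
  norm <- .norm_dist(facet$value)
  pairs <- .candidate_pairs(norm, spec$block_chars, max_exhaustive)
  if (!nrow(pairs)) return(list())
  d <- .pair_dist(spec, norm[pairs[, 1L]], norm[pairs[, 2L]])
  joined <- pairs[d <= spec$threshold, , drop = FALSE]
  if (!nrow(joined)) return(list())
  parent <- seq_len(n)
  for (r in seq_len(nrow(joined))) {
    ra <- .uf_find(parent, joined[r, 1L])
    rb <- .uf_find(parent, joined[r, 2L])
    root <- min(ra, rb)  # root at the smaller index for stable output order
    parent[ra] <- root; parent[rb] <- root
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  comps <- split(seq_len(n), roots)
  comps <- comps[lengths(comps) >= 2L]
  lab <- .stage_label(spec)
  out <- lapply(comps, function(idx) {
    .new_cluster(facet$value[idx], facet$count[idx], lab)
  })
  names(out) <- NULL
  out[order(vapply(out, `[[`, character(1), "canonical"), method = "radix")]
}
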