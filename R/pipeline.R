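# The sequential cleaning pipeline: run each clustering stage in order,
# merge accepted clusters onto their canonical value, re-facet, continue.

#' Pipeline configuration
#'
#' The default stage order runs the cheap, high-precision keyers first and
#' the distance stage last: fingerprint, n-gram fingerprint (n = 2 then
#' n = 1), the English phonetic keyer, Cologne phonetics, then
#' nearest-neighbour clustering on normalized Levenshtein distance at
#' radius 0.23.  A compression-distance stage can be appended but is off by
#' default.
#'
#' @param key_stages ordered list of \code{\link{key_spec}} objects.
#' @param nn_stages ordered list of \code{\link{distance_spec}} objects.
#' @param auto_accept if \code{TRUE} (default) every proposed cluster is
#'   merged; if \code{FALSE} the pipeline works against a review file at
#'   \code{review_path}: when the file does not exist yet, all stage
#'   proposals are written there for editing and nothing is merged; when it
#'   exists, only rows whose \code{decision} is \code{"accept"} are merged,
#'   honouring any \code{canonical_override}.
#' @param review_path path of the review CSV used when
#'   \code{auto_accept = FALSE}.
#' @return an object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(key_stages = default_key_stages(),
                            nn_stages = default_nn_stages(),
                            auto_accept = TRUE,
                            review_path = NULL) {
  stopifnot(is.list(key_stages), is.list(nn_stages))
  lapply(key_stages, function(s) stopifnot(inherits(s, "key_spec")))
  lapply(nn_stages, function(s) stopifnot(inherits(s, "distance_spec")))
  if (!isTRUE(auto_accept) && is.null(review_path))
    stop("auto_accept = FALSE requires a review_path")
  structure(list(key_stages = key_stages, nn_stages = nn_stages,
                 auto_accept = isTRUE(auto_accept),
                 review_path = review_path),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_key_stages <- function() {
  list(key_spec("fingerprint"),
       key_spec("ngram_fingerprint", 2L),
       key_spec("ngram_fingerprint", 1L),
       key_spec("phonetic_en"),
       key_spec("phonetic_cologne"))
}

#' @rdname pipeline_config
#' @param nn_threshold radius for the default nearest-neighbour stage.
#' @param block_chars blocking substring length for the default stage.
#' @export
default_nn_stages <- function(nn_threshold = 0.23, block_chars = 6L) {
  list(distance_spec("normalized_levenshtein", nn_threshold, block_chars))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> ", length(x$key_stages), " key-collision stage(s), ",
      length(x$nn_stages), " nearest-neighbour stage(s); ",
      if (x$auto_accept) "auto-accept" else
        paste0("review file: ", x$review_path), "\n", sep = "")
  invisible(x)
}

.empty_plan <- function() {
  structure(
    data.frame(wrong = character(0), canonical = character(0),
               count = integer(0), stage = integer(0),
               method = character(0), stringsAsFactors = FALSE),
    class = c("merge_plan", "data.frame"))
}

#' @export
print.merge_plan <- function(x, ...) {
  cat("<merge_plan> ", nrow(x), " merge(s)\n", sep = "")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

# rewrite a facet applying value -> canonical merges, summing counts
.apply_merges <- function(facet, map) {
  if (!length(map)) return(facet)
  v <- facet$value
  hit <- v %in% names(map)
  v[hit] <- unname(map[v[hit]])
  tapped <- tapply(facet$count, v, sum)
  facet_table(names(tapped), as.integer(tapped))
}

#' Resolve a merge plan to its final mapping
#'
#' Merges applied at a later stage may remap a value that earlier merges
#' already target; the resolved mapping follows such chains to the final
#' canonical form each wrong value ends up as.
#'
#' @param plan a \code{merge_plan} (or a \code{cleaning_result}).
#' @return named character vector: names are wrong values, elements their
#'   final canonical form.
#' @export
resolve_mapping <- function(plan) {
  if (inherits(plan, "cleaning_result")) plan <- plan$plan
  if (!nrow(plan)) return(stats::setNames(character(0), character(0)))
  map <- stats::setNames(plan$canonical, plan$wrong)
  for (i in seq_len(length(map) + 1L)) {
    hit <- map %in% names(map) & map != names(map)
    if (!any(hit)) break
    map[hit] <- unname(map[map[hit]])
  }
  map
}

#' Run the sequential cleaning pipeline on a facet
#'
#' Applies each configured clustering stage in order.  After every stage the
#' accepted clusters are merged — each member is rewritten to the cluster's
#' canonical value and counts are summed — and the next stage runs on the
#' rewritten facet.  Total occurrence count is conserved throughout.
#'
#' @param facet a \code{facet_table} (or anything
#'   \code{\link{as_facet_table}} accepts).
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose log per-stage cluster and merge counts (default
#'   \code{getOption("textfacet.verbose", FALSE)}).
#' @return an object of class \code{"cleaning_result"}: a list with the
#'   cumulative \code{plan} (a \code{merge_plan}), the final \code{facet},
#'   the \code{initial} facet and the \code{config}.
#' @examples
#' fx <- table1_fixture()
#' res <- run_pipeline(fx$facet, pipeline_config())
#' res$facet
#' @export
run_pipeline <- function(facet, config = pipeline_config(),
                         verbose = getOption("textfacet.verbose", FALSE)) {
  facet <- as_facet_table(facet)
  stopifnot(inherits(config, "pipeline_config"))
  initial <- facet
  stages <- c(config$key_stages, config$nn_stages)
  decisions <- NULL
  collect_only <- FALSE
  if (!config$auto_accept) {
    if (file.exists(config$review_path)) {
      decisions <- read_review_file(config$review_path)
    } else {
      collect_only <- TRUE
    }
  }
  plan_rows <- list()
  review_rows <- list()
  for (si in seq_along(stages)) {
    spec <- stages[[si]]
    clusters <- if (inherits(spec, "key_spec")) {
      key_collision_cluster(facet, spec)
    } else {
      nn_cluster(facet, spec)
    }
    lab <- .stage_label(spec)
    if (verbose)
      message(sprintf("stage %d [%s]: %d cluster(s)", si, lab,
                      length(clusters)))
    if (!length(clusters)) next
    map <- character(0)
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      canon <- cl$canonical
      members <- cl$members
      if (collect_only) {
        review_rows[[length(review_rows) + 1L]] <- data.frame(
          cluster_id = paste0("s", si, "c", ci),
          stage = si, method = lab,
          member = members$value, count = members$count,
          proposed_canonical = canon,
          decision = "accept", canonical_override = "",
          stringsAsFactors = FALSE)
        next
      }
      if (!is.null(decisions)) {
        rows <- decisions[decisions$stage == si &
                          decisions$method == lab &
                          decisions$member %in% members$value, , drop = FALSE]
        rows <- rows[rows$decision == "accept", , drop = FALSE]
        if (!nrow(rows)) next
        ov <- rows$canonical_override
        canon <- if (any(nzchar(ov))) ov[nzchar(ov)][1L] else canon
        members <- members[members$value %in% rows$member, , drop = FALSE]
      }
      wrong <- setdiff(members$value, canon)
      if (!length(wrong)) next
      wc <- members$count[match(wrong, members$value)]
      plan_rows[[length(plan_rows) + 1L]] <- data.frame(
        wrong = wrong, canonical = canon, count = wc,
        stage = si, method = lab, stringsAsFactors = FALSE)
      map[wrong] <- canon
    }
    if (verbose && length(map))
      message(sprintf("stage %d [%s]: merged %d value(s)", si, lab,
                      length(map)))
    facet <- .apply_merges(facet, map)
  }
  if (collect_only) {
    review <- if (length(review_rows)) do.call(rbind, review_rows) else NULL
    write_review_file(review, config$review_path)
    if (verbose)
      message("wrote review file (no merges applied): ", config$review_path)
  }
  plan <- if (length(plan_rows)) {
    structure(do.call(rbind, plan_rows),
              class = c("merge_plan", "data.frame"))
  } else .empty_plan()
  rownames(plan) <- NULL
  structure(list(plan = plan, facet = facet, initial = initial,
                 config = config),
            class = "cleaning_result")
}

#' @export
print.cleaning_result <- function(x, ...) {
  cat("<cleaning_result>\n",
      "  values:      ", nrow(x$initial), " -> ", nrow(x$facet), "\n",
      "  occurrences: ", facet_total(x$initial), " (conserved: ",
      facet_total(x$facet) == facet_total(x$initial), ")\n",
      "  merges:      ", nrow(x$plan), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cleaning_result <- function(object, ...) {
  by_stage <- if (nrow(object$plan)) {
    stats::aggregate(wrong ~ stage + method, data = object$plan, FUN = length)
  } else NULL
  structure(list(n_initial = nrow(object$initial),
                 n_final = nrow(object$facet),
                 total = facet_total(object$initial),
                 merges = nrow(object$plan),
                 by_stage = by_stage),
            class = "summary.cleaning_result")
}

#' @export
print.summary.cleaning_result <- function(x, ...) {
  cat("Cleaning pipeline summary\n",
      "  distinct values: ", x$n_initial, " -> ", x$n_final, "\n",
      "  total occurrences: ", x$total, "\n",
      "  merges applied: ", x$merges, "\n", sep = "")
  if (!is.null(x$by_stage)) {
    cat("  merges by stage:\n")
    for (i in seq_len(nrow(x$by_stage)))
      cat(sprintf("    stage %d [%s]: %d\n", x$by_stage$stage[i],
                  x$by_stage$method[i], x$by_stage$wrong[i]))
  }
  invisible(x)
}

#' Clean a raw column of values end to end
#'
#' Convenience wrapper: facets \code{values}, runs the pipeline, and
#' rewrites the column through the resolved mapping.
#'
#' @param values character vector of raw values.
#' @inheritParams run_pipeline
#' @return a \code{cleaning_result} with an extra element \code{cleaned},
#'   the rewritten input column.
#' @export
clean_column <- function(values, config = pipeline_config(),
                         verbose = getOption("textfacet.verbose", FALSE)) {
  res <- run_pipeline(build_facet(values), config, verbose = verbose)
  map <- resolve_mapping(res$plan)
  cleaned <- as.character(values)
  hit <- cleaned %in% names(map)
  cleaned[hit] <- unname(map[cleaned[hit]])
  res$cleaned <- cleaned
  res
}
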