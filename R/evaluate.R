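# Correction-rate and accuracy metrics against a gold standard.
#
# Vocabulary of the metrics: a "word" is an individual wrong string; a
# "pattern" is a class of wrong strings belonging to one correct term (by
# default each distinct wrong string is its own pattern).  Rates are the
# percentage of patterns (or words) the systematic stages converted to
# their correct value; accuracy weights by occurrence counts.

#' Gold-standard mapping
#'
#' @param wrong character vector of wrong strings.
#' @param correct character vector: the correct term each wrong string must
#'   map to (recycled if length 1).
#' @param pattern_id pattern identifier per wrong string; defaults to the
#'   wrong string itself, making every distinct wrong string its own
#'   pattern.
#' @return an object of class \code{"gold_standard"}: a data frame with
#'   columns \code{wrong}, \code{correct}, \code{pattern_id}.
#' @export
gold_standard <- function(wrong, correct, pattern_id = NULL) {
  wrong <- as.character(wrong)
  correct <- rep_len(as.character(correct), length(wrong))
  if (anyDuplicated(wrong))
    stop("every wrong string must map to exactly one correct string")
  if (is.null(pattern_id)) pattern_id <- wrong
  pattern_id <- rep_len(as.character(pattern_id), length(wrong))
  structure(
    data.frame(wrong = wrong, correct = correct, pattern_id = pattern_id,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("gold_standard", "data.frame"))
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> ", nrow(x), " wrong string(s), ",
      length(unique(x$pattern_id)), " pattern(s), ",
      length(unique(x$correct)), " correct term(s)\n", sep = "")
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

.rate2 <- function(corrected, total) round(100 * corrected / total, 2L)

#' Pattern-level correction rate
#'
#' The number of corrected typographical-error patterns divided by the
#' total number of patterns, times 100, reported to two decimals.
#'
#' @param corrected_patterns,total_patterns non-negative counts;
#'   \code{total_patterns} must be at least 1.
#' @return percentage, rounded to 2 decimals.
#' @examples
#' pattern_correction_rate(39, 45)   # 86.67
#' pattern_correction_rate(43, 45)   # 95.56
#' @export
pattern_correction_rate <- function(corrected_patterns, total_patterns) {
  stopifnot(length(total_patterns) == 1L, length(corrected_patterns) == 1L)
  if (total_patterns < 1) stop("rate undefined: total_patterns must be >= 1")
  stopifnot(corrected_patterns >= 0, corrected_patterns <= total_patterns)
  .rate2(corrected_patterns, total_patterns)
}

#' Word-level correction rate
#'
#' The number of corrected typographical-error words divided by the total
#' number of error words, times 100, reported to two decimals.
#'
#' @param corrected_words,total_words non-negative counts;
#'   \code{total_words} must be at least 1.
#' @return percentage, rounded to 2 decimals.
#' @examples
#' word_correction_rate(71, 72)   # 98.61
#' @export
word_correction_rate <- function(corrected_words, total_words) {
  stopifnot(length(total_words) == 1L, length(corrected_words) == 1L)
  if (total_words < 1) stop("rate undefined: total_words must be >= 1")
  stopifnot(corrected_words >= 0, corrected_words <= total_words)
  .rate2(corrected_words, total_words)
}

#' Score a cleaning run against a gold standard
#'
#' A wrong string counts as corrected if and only if the resolved merge
#' plan maps it to its gold correct term — joining some other cluster does
#' not count.  Accuracy is occurrence-weighted: the percentage of all
#' occurrences in the facet that end up as their intended term after
#' cleaning (correct terms must stay themselves; wrong strings must reach
#' their gold term).
#'
#' @param plan a \code{merge_plan} or a \code{cleaning_result}.
#' @param gold a \code{\link{gold_standard}} covering every wrong string in
#'   the facet; a facet value that is neither a correct term nor in the
#'   gold mapping raises an error naming it.
#' @param facet the facet the pipeline was run on (before cleaning).
#' @param correct_terms the full set of legitimate terms; defaults to the
#'   correct terms appearing in \code{gold}, but should be the whole
#'   vocabulary when some terms have no recorded typo.
#' @return an object of class \code{"cleaning_report"}: list with
#'   \code{pattern_rate}, \code{word_rate}, \code{accuracy} (percent) and
#'   \code{residuals} (uncorrected wrong strings).
#' @examples
#' fx <- table1_fixture()
#' res <- run_pipeline(fx$facet)
#' score(res, fx$gold, fx$facet)
#' @export
score <- function(plan, gold, facet, correct_terms = unique(gold$correct)) {
  if (inherits(plan, "cleaning_result")) plan <- plan$plan
  stopifnot(inherits(gold, "gold_standard"))
  facet <- as_facet_table(facet)
  correct_terms <- unique(c(correct_terms, gold$correct))
  unknown <- setdiff(facet$value, c(correct_terms, gold$wrong))
  if (length(unknown))
    stop("gold standard does not cover facet value(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  map <- resolve_mapping(plan)
  final_of <- function(v) {
    out <- v
    hit <- out %in% names(map)
    out[hit] <- unname(map[out[hit]])
    out
  }
  g <- gold[gold$wrong %in% facet$value, , drop = FALSE]
  corrected <- final_of(g$wrong) == g$correct
  word_rate <- if (nrow(g)) .rate2(sum(corrected), nrow(g)) else 100
  pat_ok <- if (nrow(g)) tapply(corrected, g$pattern_id, all) else logical(0)
  pattern_rate <- if (length(pat_ok)) {
    .rate2(sum(pat_ok), length(pat_ok))
  } else 100
  intended <- facet$value
  wrong_idx <- match(facet$value, gold$wrong)
  intended[!is.na(wrong_idx)] <- gold$correct[wrong_idx[!is.na(wrong_idx)]]
  good <- final_of(facet$value) == intended
  accuracy <- .rate2(sum(facet$count[good]), sum(facet$count))
  structure(list(pattern_rate = pattern_rate,
                 word_rate = word_rate,
                 accuracy = accuracy,
                 residuals = sort(g$wrong[!corrected], method = "radix"),
                 n_patterns = length(pat_ok),
                 n_words = nrow(g)),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n",
      sprintf("  pattern correction rate: %6.2f%%  (%d patterns)\n",
              x$pattern_rate, x$n_patterns),
      sprintf("  word correction rate:    %6.2f%%  (%d error words)\n",
              x$word_rate, x$n_words),
      sprintf("  accuracy (occurrences):  %6.2f%%\n", x$accuracy),
      "  residuals: ",
      if (length(x$residuals)) paste(x$residuals, collapse = ", ") else
        "(none)",
      "\n", sep = "")
  invisible(x)
}
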