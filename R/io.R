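# Readers and writers: report columns, merge mappings, review files, gold
# standards, cleaning reports, and YAML pipeline configuration.

# delimiter sniffing on the first line; plain text when neither , nor \t
.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE, encoding = "UTF-8")
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read a column of report strings
#'
#' CSV/TSV dialect is auto-detected from the first line; a file with
#' neither delimiter is read as plain text, one record per line.  UTF-8
#' with or without a BOM is accepted.
#'
#' @param path input file.
#' @param column column name for delimited input; ignored for plain text.
#' @return character vector of records.
#' @export
read_column <- function(path, column = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniff_sep(path)
  if (sep == "" && is.null(column)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    return(sub("^﻿", "", lines))
  }
  if (sep == "") sep <- ","  # single-column file addressed by header name
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", fileEncoding = "UTF-8-BOM",
                          check.names = FALSE)
  if (is.null(column)) {
    if (ncol(df) == 1L) return(as.character(df[[1L]]))
    stop("file has ", ncol(df), " columns; name one of: ",
         paste(names(df), collapse = ", "))
  }
  if (!column %in% names(df))
    stop("no column '", column, "'; available columns: ",
         paste(names(df), collapse = ", "))
  as.character(df[[column]])
}

#' Write / read a merge mapping
#'
#' The mapping file is a CSV with columns \code{wrong}, \code{canonical},
#' \code{stage}, \code{method}; \code{read_mapping(write_mapping(x))}
#' round-trips.
#'
#' @param plan a \code{merge_plan} or \code{cleaning_result}.
#' @param path output file.
#' @return \code{write_mapping} returns \code{path} invisibly;
#'   \code{read_mapping} returns a \code{merge_plan}.
#' @export
write_mapping <- function(plan, path) {
  if (inherits(plan, "cleaning_result")) plan <- plan$plan
  out <- plan[, c("wrong", "canonical", "stage", "method"), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  need <- c("wrong", "canonical", "stage", "method")
  if (!all(need %in% names(df)))
    stop("mapping file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  df$count <- NA_integer_
  df <- df[, c("wrong", "canonical", "count", "stage", "method")]
  structure(df, class = c("merge_plan", "data.frame"))
}

#' Write / read a cluster review file
#'
#' The review file is the non-interactive stand-in for a value-merging UI:
#' one row per cluster member with the proposed canonical, an editable
#' \code{decision} column (\code{accept}/\code{reject}) and an editable
#' \code{canonical_override}.
#'
#' @param review data frame with columns \code{cluster_id}, \code{stage},
#'   \code{method}, \code{member}, \code{count}, \code{proposed_canonical},
#'   \code{decision}, \code{canonical_override}; \code{NULL} writes an
#'   empty template.
#' @param path file path.
#' @return \code{write_review_file} returns \code{path} invisibly;
#'   \code{read_review_file} returns the data frame.
#' @export
write_review_file <- function(review, path) {
  cols <- c("cluster_id", "stage", "method", "member", "count",
            "proposed_canonical", "decision", "canonical_override")
  if (is.null(review)) {
    review <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
  }
  stopifnot(all(cols %in% names(review)))
  utils::write.csv(review[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_review_file
#' @export
read_review_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM",
                        colClasses = c(canonical_override = "character"))
  df$canonical_override[is.na(df$canonical_override)] <- ""
  df
}

#' Write / read a gold standard
#'
#' CSV with columns \code{wrong}, \code{correct}, \code{pattern_id}.
#'
#' @param gold a \code{\link{gold_standard}}.
#' @param path file path.
#' @return \code{write_gold} returns \code{path} invisibly;
#'   \code{read_gold} returns a \code{gold_standard}.
#' @export
write_gold <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  utils::write.csv(as.data.frame(gold), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gold
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  need <- c("wrong", "correct")
  if (!all(need %in% names(df)))
    stop("gold file must have columns: ", paste(need, collapse = ", "))
  gold_standard(df$wrong, df$correct,
                if ("pattern_id" %in% names(df)) df$pattern_id else NULL)
}

#' Write a cleaning report
#'
#' Writes the rates and residual list as CSV and logs a human-readable
#' summary.
#'
#' @param report a \code{cleaning_report} from \code{\link{score}}.
#' @param path file path.
#' @param quiet suppress the logged summary.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, quiet = FALSE) {
  stopifnot(inherits(report, "cleaning_report"))
  df <- data.frame(
    metric = c("pattern_correction_rate", "word_correction_rate",
               "accuracy", "n_patterns", "n_error_words", "n_residuals",
               if (length(report$residuals))
                 paste0("residual_", seq_along(report$residuals))),
    value = c(report$pattern_rate, report$word_rate, report$accuracy,
              report$n_patterns, report$n_words, length(report$residuals),
              report$residuals),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!quiet) print(report)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors \code{\link{pipeline_config}}:
#' \preformatted{
#' key_stages:
#'   - method: fingerprint
#'   - method: ngram_fingerprint
#'     ngram_size: 1
#' nn_stages:
#'   - method: normalized_levenshtein
#'     threshold: 0.23
#'     block_chars: 6
#' auto_accept: true
#' review_path: review.csv
#' }
#' Omitted sections fall back to the package defaults.
#'
#' @param path YAML file.
#' @return a \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  key_stages <- if (is.null(y$key_stages)) default_key_stages() else {
    lapply(y$key_stages, function(s)
      key_spec(s$method, if (is.null(s$ngram_size)) 2L else s$ngram_size))
  }
  nn_stages <- if (is.null(y$nn_stages)) default_nn_stages() else {
    lapply(y$nn_stages, function(s)
      distance_spec(s$method,
                    threshold = s$threshold,
                    block_chars = if (is.null(s$block_chars)) 6L else
                      s$block_chars))
  }
  pipeline_config(key_stages, nn_stages,
                  auto_accept = !isFALSE(y$auto_accept),
                  review_path = y$review_path)
}
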