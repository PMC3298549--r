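## Delimited assertion-corpus reader/writer. Column order: subject,
## predicate, object, source_id, publication_date, confidence, then any
## optional extras (source_type, impact_factor, classes). Tab-separated,
## header row required.

ASSERTION_CORE_COLS <- c("subject", "predicate", "object", "source_id",
                         "publication_date", "confidence")

#' Read an assertion corpus from a delimited file
#'
#' @param path TSV file with a header; required columns `subject`,
#'   `predicate`, `object`, `source_id`; optional `publication_date`,
#'   `confidence`, `source_type`, `impact_factor`, `year`,
#'   `subject_class`, `predicate_class`, `object_class`.
#' @return an assertion data.frame accepted by [contextualize()] /
#'   [reify()] / [encodeCorpus()].
#' @export
readAssertions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          comment.char = "")
  need <- c("subject", "predicate", "object", "source_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("assertion file lacks column(s): ", paste(miss, collapse = ", "))
  chr_cols <- c(need, "source_type", "publication_date", "version",
                "subject_class", "predicate_class", "object_class")
  for (col in intersect(chr_cols, names(df)))
    df[[col]] <- as.character(df[[col]])
  df
}

#' Write an assertion corpus to a delimited file
#'
#' @param records assertion data.frame (core columns first, extras kept).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeAssertions <- function(records, path) {
  core <- intersect(ASSERTION_CORE_COLS, names(records))
  rest <- setdiff(names(records), core)
  utils::write.table(records[, c(core, rest)], path, sep = "\t",
                     quote = TRUE, row.names = FALSE)
  invisible(path)
}
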