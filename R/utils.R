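# Shared low-level helpers: CURIE handling, strict TSV IO, deterministic sort.

#' Test whether strings are CURIEs (PREFIX:LOCALID, single colon)
#' @param x character vector
#' @return logical vector
#' @keywords internal
is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+$", x)
}

#' CURIE prefix (text before the colon)
#' @param x character vector of CURIEs
#' @keywords internal
curie_prefix <- function(x) {
  sub(":.*$", "", x)
}

# locale-independent sort; fixture determinism depends on this
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

trim <- function(x) sub("^[ \t]+", "", sub("[ \t]+$", "", x))

# collapse internal whitespace runs and casefold, for label matching
norm_label <- function(x) {
  tolower(gsub("[ \t]+", " ", trim(x)))
}

#' Read a headered, tab-delimited, UTF-8 table with all-character columns
#' @param file path
#' @return data.frame, character columns, no factors
#' @keywords internal
read_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = "character",
                    stringsAsFactors = FALSE, na.strings = NULL,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a headered, tab-delimited, UTF-8 table
#' @param x data.frame
#' @param file path
#' @keywords internal
write_tsv <- function(x, file) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(file)
}

stop_data <- function(class, fmt, ..., data = list()) {
  cond <- errorCondition(sprintf(fmt, ...),
                         class = c(class, "phenoprio_error"))
  for (nm in names(data)) cond[[nm]] <- data[[nm]]
  stop(cond)
}
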