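# Shared helpers: condition classes, chromosome ordering, numeric parsing.

stop_io      <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = c("exoncnv_io_error", "exoncnv_error"))
stop_schema  <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = c("exoncnv_schema_error", "exoncnv_error"))
stop_parse   <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = c("exoncnv_parse_error", "exoncnv_error"))
stop_config  <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = c("exoncnv_config_error", "exoncnv_error"))
stop_content <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = c("exoncnv_content_error", "exoncnv_error"))
stop_value   <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = c("exoncnv_value_error", "exoncnv_error"))
stop_lookup  <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = c("exoncnv_lookup_error", "exoncnv_error"))

#' Natural chromosome ordering
#'
#' Orders chromosome labels 1..22, X, Y, MT first, then any remaining labels
#' lexicographically. A leading "chr" prefix is ignored for comparison but
#' preserved in the data itself.
#'
#' @param chromosome Character vector of chromosome labels.
#' @return Integer permutation suitable for subsetting, as from [order()].
#' @export
chromosome_order <- function(chromosome) {
  key <- chromosome_sort_key(chromosome)
  order(key$rank, key$label)
}

chromosome_sort_key <- function(chromosome) {
  core <- toupper(sub("^chr", "", chromosome, ignore.case = TRUE))
  core[core == "M"] <- "MT"
  known <- c(as.character(1:22), "X", "Y", "MT")
  rank <- match(core, known)
  rank[is.na(rank)] <- length(known) + 1L
  list(rank = rank, label = core)
}

chromosome_core <- function(chromosome) {
  sub("^chr", "", chromosome, ignore.case = TRUE)
}

same_chromosome <- function(a, b) {
  toupper(chromosome_core(a)) == toupper(chromosome_core(b))
}

# Parse a character column to numeric with row-accurate error reporting.
# Cells "", "." and NA are treated as missing; missing mandatory cells are
# rejected when allow_na = FALSE.
parse_numeric_column <- function(x, column, allow_na = FALSE) {
  x <- as.character(x)
  blank <- is.na(x) | x == "" | x == "."
  value <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(value)
  if (any(bad)) {
    stop_parse("non-numeric value '%s' in column '%s' at data row %d",
               x[which(bad)[1]], column, which(bad)[1])
  }
  if (!allow_na && any(blank)) {
    stop_content("missing mandatory value in column '%s' at data row %d",
                 column, which(blank)[1])
  }
  value
}

# Read a tab-separated file with a header row into an all-character data frame.
read_tsv_character <- function(path) {
  if (!file.exists(path)) {
    stop_io("file not found: %s", path)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

# Format numbers for TSV output: floats at 6 decimal places, integers plain,
# missing values as empty cells.
format_tsv_number <- function(x, digits = 6) {
  out <- ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  out
}

format_tsv_integer <- function(x) {
  ifelse(is.na(x), "", format(x, scientific = FALSE, trim = TRUE))
}

# Write lines atomically: write to a temporary file in the same directory,
# then rename over the destination.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_io("directory does not exist: %s", dir)
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- tryCatch({
    writeLines(lines, tmp, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(tmp)) {
    stop_io("cannot write to %s", path)
  }
  if (!suppressWarnings(file.rename(tmp, path))) {
    unlink(tmp)
    stop_io("cannot move output into place at %s", path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
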