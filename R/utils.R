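#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Condition helpers: all package errors are classed so callers can
## distinguish validation, schema, config and I/O failures.
enmStop <- function(msg, class = "enmkit_error", call. = FALSE) {
  stop(structure(
    class = c(class, "enmkit_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

enmWarn <- function(msg, class = "enmkit_warning") {
  warning(structure(
    class = c(class, "enmkit_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

## Coerce to length-1 character/numeric/integer, mapping NULL and "" to NA.
chr1 <- function(x, default = NA_character_) {
  if (is.null(x) || length(x) == 0) return(default)
  x <- as.character(x)[1]
  if (is.na(x)) default else x
}

num1 <- function(x, default = NA_real_) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) return(default)
  as.numeric(x)[1]
}

int1 <- function(x, default = NA_integer_) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) return(default)
  as.integer(x)[1]
}

isNonEmptyString <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) && nzchar(x)
}

## A1 spreadsheet notation ("B2") -> c(row, col), 1-based.
cellToRC <- function(a1) {
  if (!isNonEmptyString(a1) || !grepl("^[A-Za-z]+[0-9]+$", a1))
    enmStop(sprintf("invalid cell address '%s'", a1), "enmkit_config_error")
  letters_part <- gsub("[0-9]+$", "", a1)
  digits_part <- gsub("^[A-Za-z]+", "", a1)
  col <- 0L
  for (ch in strsplit(toupper(letters_part), "")[[1]])
    col <- col * 26L + (utf8ToInt(ch) - 64L)
  c(row = as.integer(digits_part), col = col)
}
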