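## RFC 4122 namespace UUID for URLs, as raw bytes:
## 6ba7b811-9dad-11d1-80b4-00c04fd430c8
.NAMESPACE_URL_BYTES <- as.raw(strtoi(
  c("6b", "a7", "b8", "11", "9d", "ad", "11", "d1",
    "80", "b4", "00", "c0", "4f", "d4", "30", "c8"), 16L))

## All identifiers in the store are minted under this fixed namespace so
## that re-importing the same source field always yields the same record.
.ENM_NAMESPACE <- "https://example.org/enm#"

#' Deterministic prefixed identifiers for imported records
#'
#' Mints an identifier of the form \code{PREF-xxxxxxxx-xxxx-3xxx-yxxx-xxxxxxxxxxxx}
#' from a source field (for example the material name in a spreadsheet row).
#' The UUID part is a name-based UUID version 3: the MD5 digest of the RFC
#' 4122 URL namespace bytes followed by the UTF-8 bytes of
#' \code{"https://example.org/enm#"} concatenated with \code{sourceField}.
#' The same (prefix, field) pair therefore always produces the same
#' identifier, so repeated imports of a template update rather than
#' duplicate records.
#'
#' @param prefix four-character upper-case source code, e.g. \code{"FCSV"}
#'   for CSV imports or \code{"NWKI"} for wiki dumps.
#' @param sourceField non-empty character scalar the identifier is derived
#'   from.
#' @return character scalar, the prefixed identifier.
#' @examples
#' makeIdentifier("FCSV", "row-key-1")
#' @export
makeIdentifier <- function(prefix, sourceField) {
  if (!isNonEmptyString(prefix) || !grepl("^[A-Z0-9]{4}$", prefix))
    enmStop(sprintf("identifier prefix must match ^[A-Z0-9]{4}$, got '%s'",
                    chr1(prefix, "")), "enmkit_validation_error")
  if (!isNonEmptyString(sourceField))
    enmStop("sourceField must be a non-empty string", "enmkit_validation_error")
  name <- paste0(.ENM_NAMESPACE, sourceField)
  h <- digest::digest(c(.NAMESPACE_URL_BYTES, charToRaw(enc2utf8(name))),
                      algo = "md5", serialize = FALSE)
  bytes <- strtoi(substring(h, seq(1L, 31L, 2L), seq(2L, 32L, 2L)), 16L)
  bytes[7] <- bitwOr(bitwAnd(bytes[7], 0x0FL), 0x30L)  # version 3
  bytes[9] <- bitwOr(bitwAnd(bytes[9], 0x3FL), 0x80L)  # RFC 4122 variant
  hx <- sprintf("%02x", bytes)
  uuid <- paste0(
    paste(hx[1:4], collapse = ""), "-", paste(hx[5:6], collapse = ""), "-",
    paste(hx[7:8], collapse = ""), "-", paste(hx[9:10], collapse = ""), "-",
    paste(hx[11:16], collapse = ""))
  paste0(prefix, "-", uuid)
}

.UUID_REGEX <- paste0(
  "^[A-Z0-9]{4}-[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-",
  "[0-9a-f]{4}-[0-9a-f]{12}$")

isPrefixedIdentifier <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) && grepl(.UUID_REGEX, x)
}
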