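## Internal helpers: hashing, canonical JSON, small utilities.
## Every digest in the system is SHA-256 rendered as 64 lowercase hex chars.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' SHA-256 digest of a byte sequence or string
#'
#' The single hash function used throughout the platform: block chaining,
#' payload addressing, shard digests, proposal digests and Data IDs all use
#' SHA-256 rendered as 64 lowercase hexadecimal characters.
#'
#' @param x A raw vector or a single character string (hashed as UTF-8).
#' @return A 64-character lowercase hex digest.
#' @export
#' @examples
#' sha256_hex("abc")
sha256_hex <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- charToRaw(enc2utf8(x))
  }
  if (!is.raw(x)) stop("sha256_hex() expects a raw vector or a single string")
  as.vector(as.character(openssl::sha256(x)))
}

is_hex_digest <- function(x, n = 64L) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(sprintf("^[0-9a-f]{%d}$", n), x)
}

ZERO_DIGEST <- strrep("0", 64)

## Minimal canonical JSON writer. jsonlite's serializer is avoided for the
## canonical byte forms so that escaping and key order are fully pinned down:
## keys sorted bytewise (C locale), no insignificant whitespace, strings
## escaped with the mandatory JSON escapes only.
## vectorized over its argument
json_escape <- function(s) {
  s <- enc2utf8(s)
  need <- grepl("[\\\\\"[:cntrl:]]", s)
  if (!any(need)) return(s)
  e <- s[need]
  e <- gsub("\\", "\\\\", e, fixed = TRUE)
  e <- gsub("\"", "\\\"", e, fixed = TRUE)
  e <- gsub("\n", "\\n", e, fixed = TRUE)
  e <- gsub("\r", "\\r", e, fixed = TRUE)
  e <- gsub("\t", "\\t", e, fixed = TRUE)
  ## remaining control characters (rare in metadata) as \u00XX
  ctrl <- grepl("[[:cntrl:]]", e)
  e[ctrl] <- vapply(e[ctrl], function(x) {
    chars <- strsplit(x, "")[[1]]
    cp <- vapply(chars, utf8ToInt, integer(1))
    bad <- cp < 0x20L
    chars[bad] <- sprintf("\\u%04x", cp[bad])
    paste0(chars, collapse = "")
  }, character(1))
  s[need] <- e
  s
}

json_str <- function(s) paste0("\"", json_escape(s), "\"")

## canonical object from a named character list: keys sorted by code point
json_obj_sorted <- function(values) {
  if (length(values) == 0L) return("{}")
  nm <- names(values)
  ord <- order(nm, method = "radix")
  vals <- vapply(values, as.character, character(1))[ord]
  paste0("{", paste0(json_str(nm[ord]), ":", json_str(vals), collapse = ","), "}")
}

#' Deterministic ISO 8601 UTC instant from seconds since the epoch
#'
#' Orderers stamp blocks from a logical clock rather than wall time, so
#' replicas and re-runs are bit-reproducible; this renders such a clock
#' value as the timestamp stored in a block.
#'
#' @param seconds Number of seconds since 1970-01-01T00:00:00Z.
#' @return A string like `"1970-01-01T00:00:05Z"`.
#' @export
utc_instant <- function(seconds) {
  format(as.POSIXct(as.numeric(seconds), origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

GENESIS_TIMESTAMP <- "1970-01-01T00:00:00Z"

new_id <- function(prefix, n = 8L) {
  paste0(prefix, "-", paste0(sample(c(0:9, letters[1:6]), n, replace = TRUE), collapse = ""))
}
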