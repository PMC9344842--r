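## Metadata templates and record validation -- the computation the
## endorser-validator-committer (EVC) nodes execute during endorsement.

#' The 15 Dublin Core element names, in canonical order
#'
#' The descriptive-metadata base standard every template extends.
#'
#' @return A character vector of length 15.
#' @export
dublin_core_elements <- function() {
  c("Creator", "Contributor", "Publisher", "Title", "Date", "Language",
    "Format", "Subject", "Description", "Identifier", "Relation", "Source",
    "Type", "Coverage", "Rights")
}

FIELD_KINDS <- c("free-text", "controlled-vocabulary", "language-code",
                 "date", "integer", "decimal", "identifier")

VIOLATION_KINDS <- c("missing-required", "unknown-field", "bad-language-code",
                     "not-in-vocabulary", "bad-date", "bad-number",
                     "unknown-template")

#' Specify one template field
#'
#' @param name Field name; nonempty, unique within a template.
#' @param required Must a conforming record carry a nonempty value?
#' @param kind One of `"free-text"`, `"controlled-vocabulary"`,
#'   `"language-code"`, `"date"`, `"integer"`, `"decimal"`, `"identifier"`.
#' @param vocabulary Allowed values; mandatory (nonempty) for
#'   controlled-vocabulary fields, ignored otherwise.
#' @param units Free-text unit annotation, documentation only.
#' @return A `field_spec` object.
#' @export
field_spec <- function(name, required = FALSE, kind = "free-text",
                       vocabulary = NULL, units = NULL) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("field name must be a nonempty string")
  kind <- match.arg(kind, FIELD_KINDS)
  if (kind == "controlled-vocabulary" &&
      (is.null(vocabulary) || length(vocabulary) == 0L))
    stop("controlled-vocabulary field '", name, "' needs a nonempty vocabulary")
  structure(
    list(name = name, required = isTRUE(required), kind = kind,
         vocabulary = if (!is.null(vocabulary)) as.character(vocabulary),
         units = units),
    class = "field_spec")
}

#' Construct a metadata template
#'
#' A template is the predefined standard the quality-control system enforces:
#' a named, versioned, ordered set of field specifications. The base Dublin
#' Core template carries exactly the 15 classic elements; extensions carry
#' all base fields plus their additions.
#'
#' @param template_id Template identifier.
#' @param fields List of [field_spec()] objects, in order.
#' @param version Integer template version, >= 1.
#' @param base `template_id` of the template this one extends, or `NULL`.
#' @return A `metadata_template`.
#' @export
metadata_template <- function(template_id, fields, version = 1L, base = NULL) {
  stopifnot(is.character(template_id), length(template_id) == 1L, nzchar(template_id))
  version <- as.integer(version)
  if (is.na(version) || version < 1L) stop("template version must be an integer >= 1")
  if (!all(vapply(fields, inherits, logical(1), "field_spec")))
    stop("fields must be a list of field_spec objects")
  nms <- vapply(fields, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate field name(s) in template '", template_id, "': ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(fields) <- nms
  structure(
    list(template_id = template_id, version = version, base = base,
         fields = fields),
    class = "metadata_template")
}

#' @export
print.metadata_template <- function(x, ...) {
  cat("<metadata_template> ", x$template_id, " v", x$version,
      if (!is.null(x$base)) paste0(" (extends ", x$base, ")"),
      ": ", length(x$fields), " fields\n", sep = "")
  invisible(x)
}

template_field_names <- function(template) names(template$fields)

#' Load a metadata template from a JSON document
#'
#' Templates are JSON objects with keys `template_id`, `version`, `base`
#' and `fields` (each field an object with `name`, `required`, `kind`,
#' `vocabulary`, `units`). A document whose `base` is non-null lists only
#' its additional fields; they are appended to the resolved base template,
#' which must be supplied via `registry`.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @param registry Named list of already-loaded `metadata_template`s used to
#'   resolve `base` references.
#' @return A resolved `metadata_template` (extensions contain all base
#'   fields followed by their own additions).
#' @export
load_template <- function(source, registry = list()) {
  doc <- tryCatch(
    jsonlite::fromJSON(source, simplifyVector = FALSE),
    error = function(e) stop("malformed template document: ", conditionMessage(e)))
  if (!is.list(doc) || is.null(doc$template_id) || is.null(doc$fields))
    stop("malformed template document: template_id and fields are required")
  own <- lapply(doc$fields, function(f) {
    field_spec(name = f$name, required = isTRUE(f$required),
               kind = f$kind %||% "free-text",
               vocabulary = if (!is.null(f$vocabulary)) unlist(f$vocabulary),
               units = f$units)
  })
  base_id <- doc$base
  fields <- own
  if (!is.null(base_id)) {
    base <- registry[[base_id]]
    if (is.null(base))
      stop("template '", doc$template_id, "' extends unknown base '", base_id, "'")
    fields <- c(unname(base$fields), own)
  }
  metadata_template(doc$template_id, fields,
                    version = doc$version %||% 1L, base = base_id)
}

#' Write a template to its JSON document form
#'
#' Inverse of [load_template()] for standalone (non-extension) templates;
#' extension templates are written fully resolved with `base = NULL`.
#'
#' @param template A `metadata_template`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_template <- function(template, path = NULL) {
  doc <- list(
    template_id = template$template_id,
    version = template$version,
    base = NULL,
    fields = lapply(unname(template$fields), function(f) {
      list(name = f$name, required = f$required, kind = f$kind,
           vocabulary = f$vocabulary, units = f$units)
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Load one of the packaged templates
#'
#' Ships the Dublin Core base plus the two fiber-experiment extensions used
#' throughout the test corpus: `"manufacture"` (core-shell hydrogel fiber
#' fabrication parameters) and `"measurement"` (optical-microscopy fiber
#' characterization).
#'
#' @param name `"dublin-core"`, `"manufacture"` or `"measurement"`.
#' @return A resolved `metadata_template`.
#' @export
builtin_template <- function(name = c("dublin-core", "manufacture", "measurement")) {
  name <- match.arg(name)
  dir <- system.file("extdata", "templates", package = "fairledger", mustWork = TRUE)
  base <- load_template(file.path(dir, "dublin-core.json"))
  if (name == "dublin-core") return(base)
  load_template(file.path(dir, paste0(name, ".json")),
                registry = list("dublin-core" = base))
}

#' Construct a metadata record
#'
#' A record is a flat map of field name to text value, tagged with the
#' template it claims to conform to. All values are text; numeric fields are
#' parsed from their string form during validation.
#'
#' @param template_id Template the record claims conformance with.
#' @param values Named list or named character vector of field values.
#' @return A `metadata_record`.
#' @export
metadata_record <- function(template_id, values = list()) {
  stopifnot(is.character(template_id), length(template_id) == 1L)
  values <- as.list(values)
  if (length(values) > 0L && (is.null(names(values)) || any(!nzchar(names(values)))))
    stop("record values must all be named")
  if (anyDuplicated(names(values))) stop("duplicate field names in record")
  structure(list(template_id = template_id, values = values),
            class = "metadata_record")
}

#' @export
print.metadata_record <- function(x, ...) {
  cat("<metadata_record> template", x$template_id, "with",
      length(x$values), "values\n", sep = " ")
  invisible(x)
}

#' Canonical byte serialization of a record
#'
#' Every node must hash identical metadata identically, so records have one
#' canonical byte form: compact UTF-8 JSON with keys sorted bytewise and no
#' insignificant whitespace. Equal records (same key-value map, any insertion
#' order) yield identical bytes; the form round-trips through
#' [parse_record_bytes()].
#'
#' @param record A `metadata_record`.
#' @return A raw vector.
#' @export
canonical_bytes <- function(record) {
  stopifnot(inherits(record, "metadata_record"))
  ok <- vapply(record$values, function(v)
    is.character(v) && length(v) == 1L && !is.na(v), logical(1))
  if (length(ok) && !all(ok))
    stop("non-text record value(s): ",
         paste(names(record$values)[!ok], collapse = ", "))
  txt <- paste0("{\"template_id\":", json_str(record$template_id),
                ",\"values\":", json_obj_sorted(record$values), "}")
  charToRaw(txt)
}

#' Parse the canonical byte form back into a record
#'
#' @param bytes Raw vector produced by [canonical_bytes()].
#' @return A `metadata_record`.
#' @export
parse_record_bytes <- function(bytes) {
  doc <- jsonlite::fromJSON(rawToChar(bytes), simplifyVector = FALSE)
  metadata_record(doc$template_id, lapply(doc$values, as.character))
}

#' SHA-256 digest of a record's canonical bytes
#'
#' @param record A `metadata_record`.
#' @return A 64-character hex digest.
#' @export
record_digest <- function(record) sha256_hex(canonical_bytes(record))

## -- validation ------------------------------------------------------------

violation <- function(field, kind, message) {
  tibble::tibble(field = field, kind = kind, message = message)
}

.schema_cache <- new.env(parent = emptyenv())

no_violations <- function() {
  if (is.null(.schema_cache$empty))
    .schema_cache$empty <- tibble::tibble(field = character(), kind = character(),
                                          message = character())
  .schema_cache$empty
}

new_validation_report <- function(violations) {
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("<validation_report> valid\n")
  } else {
    cat("<validation_report> INVALID:", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}

#' @rdname validate_record
#' @param x,... Report to tidy; unused.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$violations

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(valid = x$valid, n_violations = nrow(x$violations))
}

is_blank <- function(v) is.null(v) || !nzchar(trimws(v))

re_language <- "^[A-Za-z]{2}$"
re_date     <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"
re_integer  <- "^[+-]?[0-9]+$"
re_decimal  <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

## Two-letter language codes of ISO 639-1, for the optional allowlist check.
iso639_1_codes <- function() {
  c("aa","ab","ae","af","ak","am","an","ar","as","av","ay","az","ba","be",
    "bg","bh","bi","bm","bn","bo","br","bs","ca","ce","ch","co","cr","cs",
    "cu","cv","cy","da","de","dv","dz","ee","el","en","eo","es","et","eu",
    "fa","ff","fi","fj","fo","fr","fy","ga","gd","gl","gn","gu","gv","ha",
    "he","hi","ho","hr","ht","hu","hy","hz","ia","id","ie","ig","ii","ik",
    "io","is","it","iu","ja","jv","ka","kg","ki","kj","kk","kl","km","kn",
    "ko","kr","ks","ku","kv","kw","ky","la","lb","lg","li","ln","lo","lt",
    "lu","lv","mg","mh","mi","mk","ml","mn","mr","ms","mt","my","na","nb",
    "nd","ne","ng","nl","nn","no","nr","nv","ny","oc","oj","om","or","os",
    "pa","pi","pl","ps","pt","qu","rm","rn","ro","ru","rw","sa","sc","sd",
    "se","sg","si","sk","sl","sm","sn","so","sq","sr","ss","st","su","sv",
    "sw","ta","te","tg","th","ti","tk","tl","tn","to","tr","ts","tt","tw",
    "ty","ug","uk","ur","uz","ve","vi","vo","wa","wo","xh","yi","yo","za",
    "zh","zu")
}

check_field_value <- function(spec, value) {
  switch(spec$kind,
    "language-code" = {
      if (!grepl(re_language, value))
        return(violation(spec$name, "bad-language-code",
                         sprintf("'%s' is not a two-letter language code", value)))
      NULL
    },
    "controlled-vocabulary" = {
      if (!value %in% spec$vocabulary)
        return(violation(spec$name, "not-in-vocabulary",
                         sprintf("'%s' not in {%s}", value,
                                 paste(spec$vocabulary, collapse = ", "))))
      NULL
    },
    "date" = {
      ok <- grepl(re_date, value) &&
        !is.na(suppressWarnings(as.Date(value, format = "%Y-%m-%d")))
      if (!ok)
        return(violation(spec$name, "bad-date",
                         sprintf("'%s' is not an ISO 8601 date (YYYY-MM-DD)", value)))
      NULL
    },
    "integer" = {
      if (!grepl(re_integer, value))
        return(violation(spec$name, "bad-number",
                         sprintf("'%s' is not an integer", value)))
      NULL
    },
    "decimal" = {
      if (!grepl(re_decimal, value))
        return(violation(spec$name, "bad-number",
                         sprintf("'%s' is not a number", value)))
      NULL
    },
    NULL)  # free-text, identifier: presence is the only check
}

#' Validate a metadata record against a template
#'
#' The quality-control computation endorser nodes execute: every required
#' field must be present and nonempty; no field may be absent from the
#' template; language-code fields must be exactly two ASCII letters
#' (compared case-insensitively against the optional allowlist);
#' controlled-vocabulary values must be members; date fields must be ISO 8601
#' calendar dates (`YYYY-MM-DD`); integer and decimal fields must parse.
#' Problems are reported, never raised.
#'
#' @param record A `metadata_record`.
#' @param template A `metadata_template`, or a named list of templates
#'   (a registry) from which the record's `template_id` is resolved; an
#'   unresolvable id yields a single `unknown-template` violation.
#' @param language_allowlist Optional character vector of acceptable
#'   language codes (e.g. [iso639_1_codes()]); `NULL` (the default) applies
#'   the purely syntactic two-letter rule.
#' @return A `validation_report`: `valid` flag plus a tibble of
#'   `(field, kind, message)` violations; `valid` is `TRUE` iff the tibble
#'   is empty.
#' @export
#' @examples
#' tpl <- builtin_template("dublin-core")
#' rec <- metadata_record("dublin-core",
#'   stats::setNames(as.list(rep("x", 15)), dublin_core_elements()))
#' rec$values$Language <- "en"
#' validate_record(rec, tpl)$valid
validate_record <- function(record, template, language_allowlist = NULL) {
  stopifnot(inherits(record, "metadata_record"))
  if (!inherits(template, "metadata_template")) {
    template <- template[[record$template_id]]
    if (is.null(template))
      return(new_validation_report(
        violation(NA_character_, "unknown-template",
                  sprintf("no registered template '%s'", record$template_id))))
  }
  v <- list()
  present <- names(record$values)
  nonblank <- present[!vapply(record$values, is_blank, logical(1))]
  for (spec in template$fields) {
    if (spec$required && !spec$name %in% nonblank)
      v[[length(v) + 1L]] <- violation(spec$name, "missing-required",
                                       sprintf("required field '%s' is missing or empty", spec$name))
  }
  for (nm in present) {
    if (!nm %in% template_field_names(template)) {
      v[[length(v) + 1L]] <- violation(nm, "unknown-field",
                                       sprintf("field '%s' is not in template '%s'",
                                               nm, template$template_id))
      next
    }
    if (!nm %in% nonblank) next  # blank optional value: nothing to parse
    chk <- check_field_value(template$fields[[nm]], as.character(record$values[[nm]]))
    if (!is.null(chk)) v[[length(v) + 1L]] <- chk
    if (is.null(chk) && !is.null(language_allowlist) &&
        template$fields[[nm]]$kind == "language-code" &&
        !tolower(record$values[[nm]]) %in% tolower(language_allowlist)) {
      v[[length(v) + 1L]] <- violation(nm, "bad-language-code",
                                       sprintf("'%s' is not an allowlisted language code",
                                               record$values[[nm]]))
    }
  }
  new_validation_report(if (length(v)) do.call(rbind, v) else no_violations())
}
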