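test_that("the base template carries the 15 Dublin Core elements in order", {
  tpl <- builtin_template("dublin-core")
  expect_s3_class(tpl, "metadata_template")
  expect_identical(names(tpl$fields), dublin_core_elements())
  expect_length(tpl$fields, 15L)
})

test_that("extension resolution appends fields to the base", {
  base <- builtin_template("dublin-core")
  # identity extension: no added fields, equal to base except template_id
  doc <- '{"template_id":"noop","version":1,"base":"dublin-core","fields":[]}'
  noop <- load_template(doc, registry = list("dublin-core" = base))
  expect_identical(names(noop$fields), names(base$fields))
  expect_identical(unname(noop$fields), unname(base$fields))
  expect_identical(noop$template_id, "noop")
  # manufacture: 15 base + 6 additions = 21, counted independently from the
  # raw documents
  man <- builtin_template("manufacture")
  expect_length(man$fields, 21L)
  dir <- system.file("extdata", "templates", package = "fairledger")
  raw_base <- jsonlite::fromJSON(file.path(dir, "dublin-core.json"), simplifyVector = FALSE)
  raw_ext <- jsonlite::fromJSON(file.path(dir, "manufacture.json"), simplifyVector = FALSE)
  expect_length(man$fields, length(raw_base$fields) + length(raw_ext$fields))
  expect_identical(names(man$fields)[1:15], dublin_core_elements())
})

test_that("malformed and inconsistent template documents are rejected", {
  expect_error(load_template('{"nope":true}'), "malformed")
  expect_error(load_template('{"template_id":"x","version":1,"base":"ghost","fields":[]}'),
               "unknown base")
  dup <- '{"template_id":"x","version":1,"base":null,"fields":[
    {"name":"A","required":true,"kind":"free-text"},
    {"name":"A","required":false,"kind":"free-text"}]}'
  expect_error(load_template(dup), "duplicate")
  expect_error(field_spec("cv", kind = "controlled-vocabulary"), "vocabulary")
})

test_that("record validation enforces every check, one violation per failure", {
  tpl <- builtin_template("dublin-core")
  good <- base_record()
  expect_true(validate_record(good, tpl)$valid)

  # ISO 639-1 style two-letter language rule
  bad_lang <- base_record(list(Language = "eng"))
  rep <- validate_record(bad_lang, tpl)
  expect_false(rep$valid)
  expect_identical(tidy(rep)$kind, "bad-language-code")

  # missing required fields: exactly the set difference is reported
  missing2 <- base_record(list(Creator = "", Rights = ""))
  rep <- validate_record(missing2, tpl)
  expect_identical(sort(tidy(rep)$field), c("Creator", "Rights"))
  expect_identical(unique(tidy(rep)$kind), "missing-required")

  # unknown field
  rep <- validate_record(base_record(list(Smell = "fresh")), tpl)
  expect_identical(tidy(rep)$kind, "unknown-field")

  # bad date / bad number / off-vocabulary
  rep <- validate_record(base_record(list(Date = "15/03/2022")), tpl)
  expect_identical(tidy(rep)$kind, "bad-date")
  man <- builtin_template("manufacture")
  rec <- valid_manufacture_record()
  rec$values$collagen_concentration_mg_per_ml <- "four"
  expect_identical(tidy(validate_record(rec, man))$kind, "bad-number")
  rec <- valid_manufacture_record()
  rec$values$cell_type <- "NIH3T3"
  expect_identical(tidy(validate_record(rec, man))$kind, "not-in-vocabulary")

  # unknown template through a registry
  rep <- validate_record(metadata_record("ghost", list(Title = "x")),
                         list("dublin-core" = tpl))
  expect_false(rep$valid)
  expect_identical(tidy(rep)$kind, "unknown-template")
})

test_that("only two-letter alphabetic language values are accepted", {
  tpl <- builtin_template("dublin-core")
  for (lang in c("e", "eng", "engl", "engli", "e1", "1e", "--")) {
    rep <- validate_record(base_record(list(Language = lang)), tpl)
    expect_false(rep$valid, label = paste("language", lang))
    expect_true("bad-language-code" %in% tidy(rep)$kind)
  }
  for (lang in c("en", "EN", "No", "fr")) {
    expect_true(validate_record(base_record(list(Language = lang)), tpl)$valid,
                label = paste("language", lang))
  }
})

test_that("the optional allowlist tightens the language check case-insensitively", {
  tpl <- builtin_template("dublin-core")
  allow <- iso639_1_codes()
  expect_true(validate_record(base_record(list(Language = "EN")), tpl,
                              language_allowlist = allow)$valid)
  rep <- validate_record(base_record(list(Language = "qx")), tpl,
                         language_allowlist = allow)
  expect_identical(tidy(rep)$kind, "bad-language-code")
  # off by default: any two letters pass
  expect_true(validate_record(base_record(list(Language = "qx")), tpl)$valid)
})

test_that("an empty record is valid when nothing is required", {
  tpl <- metadata_template("lax", list(field_spec("A"), field_spec("B")))
  expect_true(validate_record(metadata_record("lax"), tpl)$valid)
})

test_that("validation is idempotent and monotone in required fields", {
  man <- builtin_template("manufacture")
  recs <- c(lapply(1:3, valid_manufacture_record),
            list(base_record(list(Language = "english"), template_id = "manufacture")))
  for (rec in recs) {
    r1 <- validate_record(rec, man)
    r2 <- validate_record(rec, man)
    expect_identical(r1$valid, r2$valid)
    expect_identical(tidy(r1), tidy(r2))
    # adding a required field never turns an invalid record valid
    stricter <- metadata_template("stricter",
                                  c(unname(man$fields),
                                    list(field_spec("extra_field", required = TRUE))))
    if (!r1$valid) expect_false(validate_record(rec, stricter)$valid)
  }
})

test_that("records valid under an extension are valid under the base", {
  base <- builtin_template("dublin-core")
  man <- builtin_template("manufacture")
  for (i in 1:5) {
    rec <- valid_manufacture_record(i)
    expect_true(validate_record(rec, man)$valid)
    restricted <- metadata_record("dublin-core",
                                  rec$values[names(rec$values) %in% names(base$fields)])
    expect_true(validate_record(restricted, base)$valid)
  }
})

test_that("canonical bytes are insertion-order independent and round-trip", {
  v <- list(Title = "t", Creator = "c", Date = "2022-01-01")
  r1 <- metadata_record("dublin-core", v)
  r2 <- metadata_record("dublin-core", v[c(3, 1, 2)])
  expect_identical(canonical_bytes(r1), canonical_bytes(r2))
  back <- parse_record_bytes(canonical_bytes(r1))
  expect_identical(back$template_id, r1$template_id)
  expect_identical(back$values[order(names(back$values))],
                   r1$values[order(names(r1$values))])
  # a one-character difference changes the digest
  r3 <- metadata_record("dublin-core", modifyList(v, list(Title = "T")))
  expect_false(identical(record_digest(r1), record_digest(r3)))
  # escaping round-trips through the canonical form
  tricky <- metadata_record("x", list(A = 'quote " backslash \\ newline \n tab \t'))
  expect_identical(parse_record_bytes(canonical_bytes(tricky))$values$A,
                   tricky$values$A)
  expect_error(canonical_bytes(metadata_record("x", list(A = "ok")) |>
                                 (\(r) { r$values$A <- 42; r })()),
               "non-text")
})

test_that("canonicalization is injective over the fixture corpus", {
  corpus <- generate_corpus(seed = 7L, n_records = 20L)
  digests <- vapply(corpus$record, record_digest, character(1))
  expect_identical(anyDuplicated(digests), 0L)
})

test_that("an independent JSON parser agrees with the canonical serialization", {
  rec <- valid_manufacture_record()
  doc <- jsonlite::fromJSON(rawToChar(canonical_bytes(rec)), simplifyVector = FALSE)
  expect_identical(doc$template_id, "manufacture")
  expect_identical(sort(names(doc$values)), sort(names(rec$values)))
  expect_identical(doc$values$cell_type, rec$values$cell_type)
  # keys appear sorted bytewise in the serialized form
  expect_identical(names(doc$values), sort(names(rec$values), method = "radix"))
})
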